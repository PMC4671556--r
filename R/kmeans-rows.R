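#' Parameters for the k-means row-clustering baseline
#'
#' @param k Number of clusters (default 10).
#' @param n_iterations Maximum Lloyd iterations per replicate (default 100).
#' @param n_replicates Random restarts; the solution with the lowest total
#'   within-cluster distance is kept (default 1).
#' @param distance Distance between a gene row and a centroid; only
#'   `"pearson"` (d = 1 - r) is supported.
#' @param seed Integer seed for centroid initialisation.
#' @return A `kmeans_params` list.
#' @export
kmeans_params <- function(k = 10L, n_iterations = 100L, n_replicates = 1L,
                          distance = "pearson", seed = 1L) {
  distance <- match.arg(distance, "pearson")
  if (k < 1 || n_iterations < 1 || n_replicates < 1) {
    stop("k, n_iterations and n_replicates must be positive", call. = FALSE)
  }
  structure(list(k = as.integer(k), n_iterations = as.integer(n_iterations),
                 n_replicates = as.integer(n_replicates), distance = distance,
                 seed = as.integer(seed)),
            class = "kmeans_params")
}

#' k-means clustering of gene rows under Pearson distance
#'
#' One-way baseline for the biclustering stage: partitions gene rows into
#' `k` clusters by Lloyd iterations under the correlation distance
#' d(x, c) = 1 - cor(x, c); each returned [bicluster()] carries a cluster's
#' rows together with all condition columns. Rows with zero variance (where
#' Pearson correlation is undefined) are assigned to the centroid nearest
#' in Euclidean distance, with a warning; a cluster that empties is
#' reseeded with the row farthest from its current centroid. Ties always
#' resolve to the lowest index.
#'
#' @param em An [expression_matrix()] (plain matrices accepted).
#' @param params A [kmeans_params()] list; `k` must not exceed the number
#'   of gene rows.
#' @return List of `k` [bicluster()] objects forming a partition of the
#'   rows.
#' @export
kmeans_rows <- function(em, params = kmeans_params()) {
  A <- unclass(em)
  storage.mode(A) <- "double"
  n <- nrow(A)
  if (params$k > n) stop("k must not exceed the number of rows", call. = FALSE)
  zero_var <- apply(A, 1, function(r) stats::sd(r, na.rm = TRUE) == 0 ||
                      !is.finite(stats::sd(r, na.rm = TRUE)))
  if (any(zero_var)) {
    warning(sprintf(paste("%d zero-variance row(s) assigned by Euclidean",
                          "fallback (Pearson distance undefined)"),
                    sum(zero_var)), call. = FALSE)
  }
  best <- NULL
  withr::with_seed(params$seed, {
    for (rep in seq_len(params$n_replicates)) {
      fit <- lloyd_pearson(A, params$k, params$n_iterations, zero_var)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
  })
  lapply(seq_len(params$k), function(cl) {
    rows <- which(best$assign == cl)
    bicluster(rows, seq_len(ncol(A)),
              gene_ids = rownames(A)[rows],
              condition_ids = colnames(A))
  })
}

# distance of every row to one centroid (Pearson; Euclidean fallback when
# either side has zero variance)
row_centroid_dist <- function(A, centroid, zero_var) {
  r <- suppressWarnings(as.vector(cor(t(A), centroid,
                                      use = "pairwise.complete.obs")))
  d <- 1 - r
  bad <- !is.finite(d) | zero_var
  if (any(bad)) {
    d[bad] <- rowMeans((A[bad, , drop = FALSE] -
                          matrix(centroid, sum(bad), length(centroid),
                                 byrow = TRUE))^2, na.rm = TRUE)
  }
  d
}

lloyd_pearson <- function(A, k, n_iterations, zero_var) {
  n <- nrow(A)
  centroids <- A[sample.int(n, k), , drop = FALSE]
  assign_old <- rep(0L, n)
  for (it in seq_len(n_iterations)) {
    D <- vapply(seq_len(k),
                function(cl) row_centroid_dist(A, centroids[cl, ], zero_var),
                numeric(n))
    assign <- max.col(-D, ties.method = "first")
    # reseed empty clusters with the row farthest from its centroid
    repeat {
      empty <- setdiff(seq_len(k), unique(assign))
      if (!length(empty)) break
      cl <- empty[1L]
      d_own <- D[cbind(seq_len(n), assign)]
      movable <- which(tabulate(assign, k)[assign] > 1L)
      far <- movable[which.max(d_own[movable])]
      assign[far] <- cl
    }
    if (all(assign == assign_old)) break
    assign_old <- assign
    for (cl in seq_len(k)) {
      centroids[cl, ] <- colMeans(A[assign == cl, , drop = FALSE],
                                  na.rm = TRUE)
    }
  }
  D <- vapply(seq_len(k),
              function(cl) row_centroid_dist(A, centroids[cl, ], zero_var),
              numeric(n))
  list(assign = assign_old,
       objective = sum(D[cbind(seq_len(n), assign_old)]))
}
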