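#' Parameters for Cheng-Church biclustering
#'
#' @param delta Upper bound on the mean squared residue of a returned
#'   bicluster (default 0.5).
#' @param alpha Multiple-node-deletion factor > 1 (default 1.2): rows and
#'   columns whose residue exceeds `alpha` times the current MSR are
#'   deleted together.
#' @param n_biclusters Number of biclusters to extract (default 10).
#' @param seed Integer seed controlling the random masking of discovered
#'   biclusters.
#' @return A `cc_params` list.
#' @export
cc_params <- function(delta = 0.5, alpha = 1.2, n_biclusters = 10L,
                      seed = 1L) {
  if (delta < 0) stop("delta must be >= 0", call. = FALSE)
  if (alpha <= 1) stop("alpha must be > 1", call. = FALSE)
  if (n_biclusters < 1) stop("n_biclusters must be positive", call. = FALSE)
  structure(list(delta = delta, alpha = alpha,
                 n_biclusters = as.integer(n_biclusters),
                 seed = as.integer(seed)),
            class = "cc_params")
}

#' Cheng-Church biclustering
#'
#' Greedy delta-bicluster search: starting from the full matrix, (1)
#' multiple node deletion removes, while MSR > delta, every row/column
#' whose mean squared residue exceeds `alpha` x MSR; (2) single node
#' deletion removes the single worst row or column until MSR <= delta;
#' (3) node addition re-admits rows/columns whose residue against the
#' current bicluster does not exceed its MSR; (4) the found bicluster's
#' cells are masked with uniform random values over the data range and the
#' search repeats. Every returned bicluster satisfies `msr <= delta`.
#' Missing cells are excluded from all means and residue sums.
#'
#' @param em An [expression_matrix()] (plain matrices are accepted).
#' @param params A [cc_params()] list.
#' @return List of [bicluster()] objects (at most `n_biclusters`; the
#'   search stops early if masking leads back to an already-found
#'   bicluster).
#' @export
cheng_church <- function(em, params = cc_params()) {
  A <- unclass(em)
  storage.mode(A) <- "double"
  lo <- min(A, na.rm = TRUE)
  hi <- max(A, na.rm = TRUE)
  W <- A
  out <- list()
  withr::with_seed(params$seed, {
    for (b in seq_len(params$n_biclusters)) {
      bc <- cc_find_one(W, params$delta, params$alpha)
      # masked cells steer the search but must not let a reported
      # bicluster break the delta contract on the real data: trim against
      # the original matrix until it holds there too
      bc <- cc_trim_to_delta(A, bc$rows, bc$cols, params$delta)
      dup <- any(vapply(out, function(p) {
        identical(p$rows, bc$rows) && identical(p$cols, bc$cols)
      }, TRUE))
      if (dup) break
      out[[length(out) + 1L]] <- bc
      # mask so the next round searches elsewhere
      W[bc$rows, bc$cols] <- runif(length(bc$rows) * length(bc$cols), lo, hi)
    }
  })
  lapply(out, function(bc) {
    bicluster(bc$rows, bc$cols,
              gene_ids = rownames(A)[bc$rows],
              condition_ids = colnames(A)[bc$cols])
  })
}

# Single-node deletion on the original matrix until MSR <= delta
cc_trim_to_delta <- function(A, I, J, delta) {
  repeat {
    H <- msr_submatrix(A[I, J, drop = FALSE])
    if (H <= delta || (length(I) == 1L && length(J) == 1L)) break
    res <- row_col_residues(A[I, J, drop = FALSE])
    worst_r <- if (length(I) > 1L) max(res$row) else -Inf
    worst_c <- if (length(J) > 1L) max(res$col) else -Inf
    if (worst_r >= worst_c) {
      I <- I[-which.max(res$row)]
    } else {
      J <- J[-which.max(res$col)]
    }
  }
  list(rows = I, cols = J)
}

# One delta-bicluster on the working matrix
cc_find_one <- function(W, delta, alpha) {
  I <- seq_len(nrow(W))
  J <- seq_len(ncol(W))

  # phase 1: multiple node deletion
  repeat {
    H <- msr_submatrix(W[I, J, drop = FALSE])
    if (H <= delta) break
    res <- row_col_residues(W[I, J, drop = FALSE])
    drop_r <- res$row > alpha * H
    if (all(drop_r)) drop_r[which.min(res$row)] <- FALSE
    changed <- any(drop_r) && length(I) > 1L
    if (changed) I <- I[!drop_r]
    H <- msr_submatrix(W[I, J, drop = FALSE])
    if (H <= delta) break
    res <- row_col_residues(W[I, J, drop = FALSE])
    drop_c <- res$col > alpha * H
    if (all(drop_c)) drop_c[which.min(res$col)] <- FALSE
    if (any(drop_c) && length(J) > 1L) {
      J <- J[!drop_c]
      changed <- TRUE
    }
    if (!changed) break
  }

  # phase 2: single node deletion
  repeat {
    H <- msr_submatrix(W[I, J, drop = FALSE])
    if (H <= delta || (length(I) == 1L && length(J) == 1L)) break
    res <- row_col_residues(W[I, J, drop = FALSE])
    worst_r <- if (length(I) > 1L) max(res$row) else -Inf
    worst_c <- if (length(J) > 1L) max(res$col) else -Inf
    if (worst_r >= worst_c) {
      I <- I[-which.max(res$row)]
    } else {
      J <- J[-which.max(res$col)]
    }
  }

  # phase 3: node addition - re-admit, one at a time in increasing
  # residue order, every row/column whose addition keeps MSR <= delta
  repeat {
    grew <- FALSE
    add_c <- candidate_residues(W, I, J, margin = "col")
    for (j in setdiff(order(add_c), J)) {
      if (!is.finite(add_c[j])) break
      J2 <- sort(c(J, j))
      if (msr_submatrix(W[I, J2, drop = FALSE]) <= delta) {
        J <- J2
        grew <- TRUE
      }
    }
    add_r <- candidate_residues(W, I, J, margin = "row")
    for (i in setdiff(order(add_r), I)) {
      if (!is.finite(add_r[i])) break
      I2 <- sort(c(I, i))
      if (msr_submatrix(W[I2, J, drop = FALSE]) <= delta) {
        I <- I2
        grew <- TRUE
      }
    }
    if (!grew) break
  }

  list(rows = I, cols = J)
}

# Residue of every row (or column) of W against the bicluster (I, J) model:
# rows/cols already inside get their within-bicluster residue, candidates
# outside get the residue their admission would contribute.
candidate_residues <- function(W, I, J, margin = c("row", "col")) {
  margin <- match.arg(margin)
  sub <- W[I, J, drop = FALSE]
  a_iJ <- rowMeans(sub, na.rm = TRUE)
  a_Ij <- colMeans(sub, na.rm = TRUE)
  a_IJ <- mean(sub, na.rm = TRUE)
  if (margin == "col") {
    cols <- W[I, , drop = FALSE]
    cand_mean <- colMeans(cols, na.rm = TRUE)
    res2 <- (cols - outer(a_iJ, cand_mean, `+`) + a_IJ)^2
    out <- colMeans(res2, na.rm = TRUE)
  } else {
    rows <- W[, J, drop = FALSE]
    cand_mean <- rowMeans(rows, na.rm = TRUE)
    res2 <- (rows - outer(cand_mean, a_Ij, `+`) + a_IJ)^2
    out <- rowMeans(res2, na.rm = TRUE)
  }
  out[is.nan(out)] <- Inf
  out
}
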