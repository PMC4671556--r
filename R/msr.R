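#' Bicluster and bicluster-set containers
#'
#' A bicluster is a subset of gene rows `I` and condition columns `J` of an
#' expression matrix over which the selected genes behave coherently.
#'
#' @param rows Integer vector of row indices (non-empty, unique).
#' @param cols Integer vector of column indices (non-empty, unique).
#' @param gene_ids,condition_ids Optional identifier vectors for the
#'   selected rows/columns (carried along for downstream network lookups).
#' @return An object of class `bicluster`.
#' @export
bicluster <- function(rows, cols, gene_ids = NULL, condition_ids = NULL) {
  rows <- sort(unique(as.integer(rows)))
  cols <- sort(unique(as.integer(cols)))
  if (!length(rows) || !length(cols)) {
    stop("a bicluster needs at least one row and one column", call. = FALSE)
  }
  structure(list(rows = rows, cols = cols, gene_ids = gene_ids,
                 condition_ids = condition_ids),
            class = "bicluster")
}

#' @export
print.bicluster <- function(x, ...) {
  cat(sprintf("<bicluster: %d genes x %d conditions>\n",
              length(x$rows), length(x$cols)))
  invisible(x)
}

#' Turn a list of biclusters into a tidy table
#'
#' @param x A list of [bicluster()] objects.
#' @param ... Unused.
#' @return A tibble with one row per bicluster: index, gene/condition
#'   counts, and list-columns of the member identifiers.
#' @export
tidy_biclusters <- function(x, ...) {
  tibble::tibble(
    bicluster = seq_along(x),
    n_genes = vapply(x, function(b) length(b$rows), 0L),
    n_conditions = vapply(x, function(b) length(b$cols), 0L),
    genes = lapply(x, function(b) b$gene_ids %||% b$rows),
    conditions = lapply(x, function(b) b$condition_ids %||% b$cols)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean squared residue of a submatrix
#'
#' The coherence score of a bicluster: the mean, over selected non-missing
#' cells, of the squared residual after removing row effects, column
#' effects and the overall mean of the submatrix,
#' \deqn{MSR = \frac{1}{|I||J|} \sum_{i \in I, j \in J}
#'   (a_{ij} - a_{iJ} - a_{Ij} + a_{IJ})^2.}
#' It is exactly 0 for any additive ("shifting") pattern
#' \eqn{a_{ij} = r_i + c_j} and is invariant to adding a constant to any
#' whole row or column. Missing cells are excluded from every mean and
#' from the residue sum, with the non-missing count replacing
#' \eqn{|I||J|}.
#'
#' @param em An [expression_matrix()] (or plain numeric matrix).
#' @param rows Row indices or gene IDs (non-empty).
#' @param cols Column indices or condition IDs (non-empty).
#' @return Non-negative scalar.
#' @examples
#' msr(matrix(c(1, 3, 2, 5), 2, 2), 1:2, 1:2) # 0.0625
#' @export
msr <- function(em, rows = seq_len(nrow(em)), cols = seq_len(ncol(em))) {
  if (!length(rows) || !length(cols)) {
    stop("rows and cols must be non-empty", call. = FALSE)
  }
  sub <- unclass(em)[rows, cols, drop = FALSE]
  msr_submatrix(sub)
}

# MSR of a plain (possibly NA-holding) submatrix
msr_submatrix <- function(sub) {
  n_ok <- sum(!is.na(sub))
  if (n_ok == 0L) return(0)
  a_iJ <- rowMeans(sub, na.rm = TRUE)
  a_Ij <- colMeans(sub, na.rm = TRUE)
  a_IJ <- mean(sub, na.rm = TRUE)
  res <- sub - outer(a_iJ, a_Ij, `+`) + a_IJ
  sum(res^2, na.rm = TRUE) / n_ok
}

# Per-row and per-column mean squared residues of a submatrix (mask-aware);
# rows/cols with no observed cell get residue 0.
row_col_residues <- function(sub) {
  a_iJ <- rowMeans(sub, na.rm = TRUE)
  a_Ij <- colMeans(sub, na.rm = TRUE)
  a_IJ <- mean(sub, na.rm = TRUE)
  res2 <- (sub - outer(a_iJ, a_Ij, `+`) + a_IJ)^2
  rr <- rowMeans(res2, na.rm = TRUE)
  cc <- colMeans(res2, na.rm = TRUE)
  rr[is.nan(rr)] <- 0
  cc[is.nan(cc)] <- 0
  list(row = rr, col = cc)
}
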