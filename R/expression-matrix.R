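#' Expression matrix container
#'
#' A genes-by-conditions real matrix with unique row (gene) and column
#' (condition) identifiers. Missing measurements are held as `NA` and are
#' excluded from all downstream means and residue sums (see [msr()]).
#' Values are used as read: no internal log transform is applied, users
#' pre-transform according to their platform's conventions.
#'
#' @param values Numeric matrix, `n` genes by `m` conditions. `NA` marks a
#'   missing cell; every non-missing entry must be finite.
#' @param gene_ids Character vector of `n` unique gene identifiers.
#' @param condition_ids Character vector of `m` unique condition identifiers.
#'
#' @return An object of class `expression_matrix`: the numeric matrix with
#'   `gene_ids` as rownames and `condition_ids` as colnames.
#' @examples
#' em <- expression_matrix(matrix(1:6, 2, 3), c("G1", "G2"), c("c1", "c2", "c3"))
#' dim(em)
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              condition_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(condition_ids)) {
    stop("gene_ids and condition_ids are required", call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  condition_ids <- as.character(condition_ids)
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("expression matrix must have at least one row and one column",
         call. = FALSE)
  }
  if (length(gene_ids) != nrow(values) ||
      length(condition_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique", call. = FALSE)
  if (anyDuplicated(condition_ids)) {
    stop("condition_ids must be unique", call. = FALSE)
  }
  if (any(is.infinite(values))) {
    stop("non-missing expression values must be finite", call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, condition_ids)
  class(values) <- c("expression_matrix", class(values))
  values
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix: %d genes x %d conditions, %d missing>\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' @describeIn expression_matrix Long-format view: one row per
#'   (gene, condition) cell, with a `missing` flag.
#' @param x An `expression_matrix`.
#' @param ... Unused.
#' @export
tidy.expression_matrix <- function(x, ...) {
  tibble::tibble(
    gene = rep(rownames(x), times = ncol(x)),
    condition = rep(colnames(x), each = nrow(x)),
    value = as.vector(unclass(x)),
    missing = is.na(as.vector(unclass(x)))
  )
}
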