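#' Parameters for complex-set evaluation
#'
#' @param os_match_threshold A reference complex counts as matched when
#'   some predicted complex reaches this overlap score (default 0.2, an
#'   inclusive `>=` bound). The same cutoff gates which pairs may enter
#'   the maximum matching behind [mmr()].
#' @return An `eval_params` list.
#' @export
eval_params <- function(os_match_threshold = 0.2) {
  stopifnot(os_match_threshold >= 0, os_match_threshold <= 1)
  structure(list(os_match_threshold = os_match_threshold),
            class = "eval_params")
}

#' Overlap score between two complexes
#'
#' OS(A, B) = |A n B|^2 / (|A| |B|): symmetric, in \[0, 1\], and equal to
#' 1 exactly when the two member sets coincide.
#'
#' @param A,B Non-empty character vectors of protein IDs.
#' @return Scalar overlap score.
#' @examples
#' overlap_score(c("a", "b", "c"), c("a", "b", "x", "y", "z", "w")) # 4/18
#' @export
overlap_score <- function(A, B) {
  A <- unique(A); B <- unique(B)
  if (!length(A) || !length(B)) {
    stop("overlap_score needs non-empty sets", call. = FALSE)
  }
  length(intersect(A, B))^2 / (length(A) * length(B))
}

# reference x predicted matrix of overlap counts t_ij
overlap_counts <- function(ref, pred) {
  m <- vapply(pred, function(P) {
    vapply(ref, function(R) length(intersect(R, P)), 0L)
  }, integer(length(ref)))
  matrix(m, nrow = length(ref), ncol = length(pred))
}

# reference x predicted matrix of overlap scores
os_matrix <- function(ref, pred) {
  t_ij <- overlap_counts(ref, pred)
  t_ij^2 / outer(lengths(ref), lengths(pred))
}

#' Number of reference complexes matched by a prediction
#'
#' A reference complex is matched when at least one predicted complex
#' overlaps it with OS at or above the threshold.
#'
#' @param pred,ref [complex_set()] objects (predicted and reference).
#' @param params An [eval_params()] list.
#' @return Integer count in \[0, |ref|\].
#' @export
matched_reference_count <- function(pred, ref, params = eval_params()) {
  if (!length(pred) || !length(ref)) return(0L)
  os <- os_matrix(ref, pred)
  sum(apply(os, 1, max) >= params$os_match_threshold)
}

#' Clustering-wise sensitivity, positive predictive value and accuracy
#'
#' With t_ij the number of shared proteins between reference complex i and
#' predicted complex j:
#' Sn = sum_i max_j t_ij / sum_i |ref_i|;
#' PPV = sum_j max_i t_ij / sum_j sum_i t_ij;
#' Acc = sqrt(Sn x PPV).
#' The PPV denominator counts only realized overlaps, so predictions
#' disjoint from every reference complex affect neither sum; with no
#' predictions (or no overlap at all) all three scores are defined as 0.
#'
#' @param pred,ref [complex_set()] objects.
#' @return Named list with `sn`, `ppv`, `acc`.
#' @export
sn_ppv_acc <- function(pred, ref) {
  if (!length(pred) || !length(ref)) return(list(sn = 0, ppv = 0, acc = 0))
  t_ij <- overlap_counts(ref, pred)
  sn <- sum(apply(t_ij, 1, max)) / sum(lengths(ref))
  denom <- sum(t_ij)
  ppv <- if (denom > 0) sum(apply(t_ij, 2, max)) / denom else 0
  list(sn = sn, ppv = ppv, acc = sqrt(sn * ppv))
}

#' Maximum matching ratio
#'
#' Builds the bipartite graph between reference and predicted complexes
#' weighted by overlap score (pairs below `os_match_threshold` excluded),
#' solves the exact maximum-weight one-to-one matching, and divides the
#' total matched weight by the number of reference complexes.
#'
#' @param pred,ref [complex_set()] objects.
#' @param params An [eval_params()] list.
#' @return Scalar in \[0, 1\].
#' @export
mmr <- function(pred, ref, params = eval_params()) {
  if (!length(pred) || !length(ref)) return(0)
  os <- os_matrix(ref, pred)
  os[os < params$os_match_threshold] <- 0
  pairs <- which(os > 0, arr.ind = TRUE)
  if (!nrow(pairs)) return(0)
  n_ref <- length(ref)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, n_ref), rep(TRUE, length(pred))),
    edges = as.vector(t(cbind(pairs[, 1], n_ref + pairs[, 2]))),
    directed = FALSE)
  m <- igraph::max_bipartite_match(g, weights = os[pairs])
  m$matching_weight / n_ref
}

#' Two-sided paired t-test
#'
#' Paired t on the differences d = y - x, against the Student t
#' distribution with n - 1 degrees of freedom. Degenerate conventions:
#' all-zero differences give (t = 0, p = 1); a constant nonzero
#' difference, where the variance is 0 but the mean is not, gives
#' (t = +/-Inf, p = 0).
#'
#' @param x,y Equal-length numeric vectors (length >= 2).
#' @return Named list with `statistic`, `df`, `p_value`.
#' @examples
#' paired_t_test(c(1, 2, 3), c(2, 3, 5)) # t = 4, p ~ 0.057
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- y - x
  m <- mean(d)
  s <- stats::sd(d)
  df <- n - 1
  if (s == 0) {
    if (m == 0) return(list(statistic = 0, df = df, p_value = 1))
    return(list(statistic = sign(m) * Inf, df = df, p_value = 0))
  }
  t_stat <- m / (s / sqrt(n))
  list(statistic = t_stat, df = df, p_value = 2 * pt(-abs(t_stat), df))
}

#' Evaluate a predicted complex set against a reference catalogue
#'
#' Assembles the matched-reference count, the clustering-wise Sn/PPV/Acc,
#' and the maximum matching ratio into one report.
#'
#' @param pred,ref [complex_set()] objects (predicted, reference).
#' @param params An [eval_params()] list.
#' @return An `evaluation_report` (see [tidy.evaluation_report()]).
#' @export
evaluate_complexes <- function(pred, ref, params = eval_params()) {
  scores <- sn_ppv_acc(pred, ref)
  structure(list(
    n_matched = as.integer(matched_reference_count(pred, ref, params)),
    n_detected = length(pred),
    n_reference = length(ref),
    sn = scores$sn, ppv = scores$ppv, acc = scores$acc,
    mmr = mmr(pred, ref, params),
    os_match_threshold = params$os_match_threshold
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Complex evaluation (OS >= %.2f)\n",
    "  matched reference complexes: %d / %d\n",
    "  detected complexes:          %d\n",
    "  Sn %.4f | PPV %.4f | Acc %.4f | MMR %.4f\n"),
    x$os_match_threshold, x$n_matched, x$n_reference, x$n_detected,
    x$sn, x$ppv, x$acc, x$mmr))
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return `tidy()`: one row per metric (`metric`, `value`); `glance()`:
#'   a one-row tibble with every field.
#' @export
tidy.evaluation_report <- function(x, ...) {
  tibble::tibble(
    metric = c("n_matched", "n_detected", "sn", "ppv", "acc", "mmr"),
    value = c(x$n_matched, x$n_detected, x$sn, x$ppv, x$acc, x$mmr))
}

#' @rdname tidy.evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Bar chart of an evaluation report's quality scores
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot object showing Sn, PPV, Acc and MMR.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$metric %in% c("sn", "ppv", "acc", "mmr"), ]
  df$metric <- factor(toupper(df$metric), levels = c("SN", "PPV", "ACC", "MMR"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "score",
                  title = sprintf("%d/%d reference complexes matched",
                                  object$n_matched, object$n_reference)) +
    ggplot2::theme_minimal()
}
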