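# Independent oracles used to cross-check the package's implementations.

# Brute-force mean squared residue: explicit double loop over the cells,
# skipping missing ones, no shared code with msr().
msr_oracle <- function(A, rows, cols) {
  sub <- A[rows, cols, drop = FALSE]
  row_means <- apply(sub, 1, function(r) mean(r[!is.na(r)]))
  col_means <- apply(sub, 2, function(cc) mean(cc[!is.na(cc)]))
  all_mean <- mean(sub[!is.na(sub)])
  total <- 0
  count <- 0L
  for (i in seq_along(rows)) {
    for (j in seq_along(cols)) {
      if (is.na(sub[i, j])) next
      resid <- sub[i, j] - row_means[i] - col_means[j] + all_mean
      total <- total + resid^2
      count <- count + 1L
    }
  }
  if (count == 0L) 0 else as.numeric(total / count)
}

# Exhaustive maximum-weight one-to-one matching over a reference x
# predicted weight matrix (recursion over reference rows; each row matches
# one unused column or none).
mmr_oracle <- function(w, threshold = 0.2) {
  w[w < threshold] <- 0
  n <- nrow(w)
  m <- ncol(w)
  best_from <- function(i, used) {
    if (i > n) return(0)
    best <- best_from(i + 1L, used)  # leave row i unmatched
    for (j in seq_len(m)) {
      if (!used[j] && w[i, j] > 0) {
        used[j] <- TRUE
        best <- max(best, w[i, j] + best_from(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  best_from(1L, rep(FALSE, m)) / n
}

# Random complex set over a protein universe (sizes 2-6)
random_complex_set <- function(n_complexes, universe) {
  complex_set(lapply(seq_len(n_complexes), function(i) {
    sample(universe, sample(2:6, 1))
  }), allow_duplicates = TRUE)
}

# A small labelled graph from an edge string like "a-b b-c"
graph_from_spec <- function(spec) {
  pairs <- strsplit(strsplit(spec, " ")[[1]], "-", fixed = TRUE)
  ppi_network(do.call(rbind, pairs))
}

make_clique_edges <- function(ids) {
  t(combn(ids, 2))
}
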