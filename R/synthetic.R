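#' Parameters for the coupled synthetic benchmark
#'
#' Defines a planted-truth study: an expression matrix carrying additive
#' (shifting-pattern) biclusters, a PPI network carrying the matching
#' planted complexes, and the ground-truth catalogue. Each planted complex
#' occupies exactly one planted bicluster (its gene rows are the complex
#' members), so recovery has an unambiguous ceiling; background genes and
#' random cross edges give pruning and biclustering genuine rejection work.
#'
#' Planted cell (i, j) of block b takes the value
#' mu_b + r_i + c_j + Normal(0, noise_sd) with block mean mu_b ~
#' N(0, block_mean_sd), gene offsets r_i ~ N(0, offset_sd) and condition
#' offsets c_j ~ N(0, offset_sd); background cells are Normal(0, 1). The
#' additive model means a planted block's ideal mean squared residue tends
#' to 0 as `noise_sd` does. Defaults keep planted blocks on the
#' background's scale: what distinguishes them is coherence (low residue),
#' not magnitude, as in real log-scale expression modules.
#'
#' @param n_genes Total genes / proteins (default 300).
#' @param m_conditions Expression conditions (default 24).
#' @param n_complexes Planted complexes (default 10).
#' @param complex_size_range Inclusive size range for each planted
#'   complex (default 6-12); complexes are disjoint.
#' @param p_in Edge probability within a complex (default 0.9).
#' @param p_out Edge probability elsewhere (default 0.02); must be below
#'   `p_in`.
#' @param noise_sd Standard deviation of planted-cell noise (default 0.3).
#' @param n_planted_conditions Conditions spanned by each planted
#'   bicluster (default 12).
#' @param block_mean_sd Spread of per-block means mu_b (default 1).
#' @param offset_sd Spread of gene and condition offsets within a block
#'   (default 0.5).
#' @param seed Integer seed; every generator is bit-reproducible under it.
#' @return A `synth_params` list.
#' @export
synth_params <- function(n_genes = 300L, m_conditions = 24L,
                         n_complexes = 10L, complex_size_range = c(6L, 12L),
                         p_in = 0.9, p_out = 0.02, noise_sd = 0.3,
                         n_planted_conditions = 12L, block_mean_sd = 1,
                         offset_sd = 0.5, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (p_in < 0 || p_in > 1 || p_out < 0 || p_out > 1) {
    stop("edge probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (p_out >= p_in) stop("p_in must exceed p_out", call. = FALSE)
  if (n_complexes * max(complex_size_range) > n_genes) {
    stop("planted complexes do not fit in n_genes", call. = FALSE)
  }
  if (n_planted_conditions > m_conditions) {
    stop("planted columns exceed m_conditions", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes),
                 m_conditions = as.integer(m_conditions),
                 n_complexes = as.integer(n_complexes),
                 complex_size_range = as.integer(complex_size_range),
                 p_in = p_in, p_out = p_out, noise_sd = noise_sd,
                 n_planted_conditions = as.integer(n_planted_conditions),
                 block_mean_sd = block_mean_sd, offset_sd = offset_sd,
                 seed = as.integer(seed)),
            class = "synth_params")
}

seed_offset <- function(seed, k) {
  as.integer((as.numeric(seed) + k) %% (.Machine$integer.max - 7))
}

# The shared planted structure both generators re-derive from params$seed:
# complex memberships (disjoint random gene rows) and each planted
# bicluster's condition columns.
synth_truth <- function(params) {
  withr::with_seed(seed_offset(params$seed, 0), {
    size_choices <- seq(params$complex_size_range[1],
                        params$complex_size_range[2])
    sizes <- size_choices[sample.int(length(size_choices),
                                     params$n_complexes, replace = TRUE)]
    member_pool <- sample.int(params$n_genes, sum(sizes))
    splits <- rep(seq_len(params$n_complexes), sizes)
    rows_per_block <- split(member_pool, splits)
    cols_per_block <- lapply(seq_len(params$n_complexes), function(b) {
      sort(sample.int(params$m_conditions, params$n_planted_conditions))
    })
  })
  gene_ids <- sprintf("G%04d", seq_len(params$n_genes))
  complexes <- lapply(rows_per_block, function(r) gene_ids[r])
  structure(list(
    planted_biclusters = lapply(seq_len(params$n_complexes), function(b) {
      list(rows = sort(rows_per_block[[b]]), cols = cols_per_block[[b]])
    }),
    planted_complexes = complex_set(
      complexes, labels = sprintf("planted_%02d", seq_len(params$n_complexes))),
    generation_params = params
  ), class = "synthetic_truth")
}

#' Generate a synthetic expression matrix with planted biclusters
#'
#' Background cells are standard normal; planted blocks follow the
#' additive shifting model described in [synth_params()]. Identical
#' parameters and seed give a bit-identical matrix.
#'
#' @param params A [synth_params()] list.
#' @return List with `expression` (an [expression_matrix()]) and `truth`
#'   (a `synthetic_truth`).
#' @export
generate_expression <- function(params = synth_params()) {
  truth <- synth_truth(params)
  n <- params$n_genes
  m <- params$m_conditions
  withr::with_seed(seed_offset(params$seed, 1), {
    A <- matrix(rnorm(n * m), n, m)
    for (b in seq_len(params$n_complexes)) {
      pb <- truth$planted_biclusters[[b]]
      mu <- rnorm(1, 0, params$block_mean_sd)
      r <- rnorm(length(pb$rows), 0, params$offset_sd)
      cc <- rnorm(length(pb$cols), 0, params$offset_sd)
      noise <- if (params$noise_sd > 0) {
        matrix(rnorm(length(pb$rows) * length(pb$cols), 0, params$noise_sd),
               length(pb$rows), length(pb$cols))
      } else 0
      A[pb$rows, pb$cols] <- mu + outer(r, cc, `+`) + noise
    }
  })
  em <- expression_matrix(A, sprintf("G%04d", seq_len(n)),
                          sprintf("C%02d", seq_len(m)))
  list(expression = em, truth = truth)
}

#' Generate a synthetic PPI network with planted complexes
#'
#' Every within-complex protein pair is an edge independently with
#' probability `p_in`; every other pair with probability `p_out`. All
#' proteins appear as nodes (isolated ones included), mirroring a
#' proteome-wide interaction screen.
#'
#' @param params A [synth_params()] list.
#' @return List with `network` (igraph) and `truth` (a `synthetic_truth`).
#' @export
generate_network <- function(params = synth_params()) {
  truth <- synth_truth(params)
  n <- params$n_genes
  gene_ids <- sprintf("G%04d", seq_len(n))
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  prob <- rep(params$p_out, nrow(pairs))
  block_of <- integer(n)
  for (b in seq_len(params$n_complexes)) {
    block_of[truth$planted_biclusters[[b]]$rows] <- b
  }
  same <- block_of[pairs[, 1]] != 0L &
    block_of[pairs[, 1]] == block_of[pairs[, 2]]
  prob[same] <- params$p_in
  withr::with_seed(seed_offset(params$seed, 2), {
    keep <- runif(nrow(pairs)) < prob
  })
  el <- cbind(gene_ids[pairs[keep, 1]], gene_ids[pairs[keep, 2]])
  list(network = ppi_network(el, nodes = gene_ids), truth = truth)
}

#' Generate a coupled synthetic dataset
#'
#' Expression matrix, PPI network and reference catalogue drawn from one
#' shared planted truth: the reference complexes are exactly the planted
#' complexes, and each complex's genes occupy one planted bicluster.
#'
#' @param params A [synth_params()] list.
#' @return List with `expression`, `network`, `reference` (a
#'   [complex_set()]) and `truth`.
#' @export
generate_coupled_dataset <- function(params = synth_params()) {
  ex <- generate_expression(params)
  nw <- generate_network(params)
  list(expression = ex$expression, network = nw$network,
       reference = ex$truth$planted_complexes, truth = ex$truth)
}

#' Write a truth manifest as key=value text
#'
#' @param truth A `synthetic_truth`.
#' @param path Output path.
#' @export
write_truth_manifest <- function(truth, path) {
  p <- truth$generation_params
  lines <- c(
    sprintf("n_genes=%d", p$n_genes),
    sprintf("m_conditions=%d", p$m_conditions),
    sprintf("n_complexes=%d", p$n_complexes),
    sprintf("complex_size_range=%d,%d", p$complex_size_range[1],
            p$complex_size_range[2]),
    sprintf("p_in=%g", p$p_in),
    sprintf("p_out=%g", p$p_out),
    sprintf("noise_sd=%g", p$noise_sd),
    sprintf("n_planted_conditions=%d", p$n_planted_conditions),
    sprintf("block_mean_sd=%g", p$block_mean_sd),
    sprintf("offset_sd=%g", p$offset_sd),
    sprintf("seed=%d", p$seed),
    vapply(seq_along(truth$planted_biclusters), function(b) {
      pb <- truth$planted_biclusters[[b]]
      sprintf("bicluster_%02d=rows:%s;cols:%s", b,
              paste(pb$rows, collapse = ","),
              paste(pb$cols, collapse = ","))
    }, ""),
    vapply(seq_along(truth$planted_complexes), function(b) {
      sprintf("complex_%02d=%s", b,
              paste(truth$planted_complexes[[b]], collapse = ","))
    }, ""))
  writeLines(lines, path)
  invisible(path)
}
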