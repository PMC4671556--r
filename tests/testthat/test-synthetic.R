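test_that("planted blocks are additive and reproducible", {
  p <- synth_params(n_genes = 40, m_conditions = 15, n_complexes = 1,
                    complex_size_range = c(8, 8), n_planted_conditions = 6,
                    noise_sd = 0, seed = 10)
  out <- generate_expression(p)
  pb <- out$truth$planted_biclusters[[1]]
  expect_equal(msr(out$expression, pb$rows, pb$cols), 0, tolerance = 1e-12)
  out2 <- generate_expression(p)
  expect_identical(unclass(out$expression), unclass(out2$expression))
})

test_that("noisy planted blocks score near the noise floor, below background", {
  p <- synth_params(n_genes = 60, m_conditions = 20, n_complexes = 1,
                    complex_size_range = c(10, 10), n_planted_conditions = 8,
                    noise_sd = 0.3, seed = 21)
  out <- generate_expression(p)
  pb <- out$truth$planted_biclusters[[1]]
  planted_msr <- msr_oracle(unclass(out$expression), pb$rows, pb$cols)
  bg_rows <- setdiff(seq_len(60), pb$rows)[1:10]
  bg_msr <- msr_oracle(unclass(out$expression), bg_rows, pb$cols)
  expect_lt(planted_msr, 0.3)  # on the noise-variance scale
  expect_lt(planted_msr, bg_msr)
})

test_that("network generator plants cliques and respects probabilities", {
  p <- synth_params(n_genes = 30, m_conditions = 10, n_complexes = 1,
                    complex_size_range = c(5, 5), n_planted_conditions = 5,
                    p_in = 1, p_out = 0, noise_sd = 0, seed = 2)
  nw <- generate_network(p)
  members <- nw$truth$planted_complexes[[1]]
  g <- nw$network
  expect_equal(igraph::ecount(g), choose(5, 2))
  sub <- igraph::induced_subgraph(g, members)
  expect_equal(igraph::ecount(sub), choose(5, 2))  # exactly a 5-clique
  expect_equal(sum(igraph::degree(g) == 0), 25L)   # rest isolated

  expect_identical(igraph::as_edgelist(generate_network(p)$network),
                   igraph::as_edgelist(g))
})

test_that("within-complex edge counts follow the binomial contract", {
  counts <- vapply(1:50, function(s) {
    p <- synth_params(n_genes = 40, m_conditions = 10, n_complexes = 1,
                      complex_size_range = c(10, 10),
                      n_planted_conditions = 5, p_in = 0.9, p_out = 0,
                      noise_sd = 0, seed = s)
    nw <- generate_network(p)
    igraph::ecount(igraph::induced_subgraph(nw$network,
                                            nw$truth$planted_complexes[[1]]))
  }, 0)
  n_pairs <- choose(10, 2)
  expected <- 0.9 * n_pairs
  se <- sqrt(n_pairs * 0.9 * 0.1 / 50)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("coupled datasets satisfy the coupling contract", {
  p <- synth_params(n_genes = 120, m_conditions = 16, n_complexes = 10,
                    complex_size_range = c(6, 10), n_planted_conditions = 8,
                    seed = 5)
  d <- generate_coupled_dataset(p)
  expect_length(d$reference, 10L)
  gene_ids <- rownames(d$expression)
  for (b in seq_len(10)) {
    bic_genes <- gene_ids[d$truth$planted_biclusters[[b]]$rows]
    expect_true(all(d$reference[[b]] %in% bic_genes))
  }
})

test_that("generator parameters are validated", {
  expect_error(synth_params(noise_sd = -1), "noise_sd")
  expect_error(synth_params(p_in = 0.1, p_out = 0.5), "exceed")
  expect_error(synth_params(p_out = -0.2), "probabilities")
  expect_error(synth_params(n_genes = 20, n_complexes = 10,
                            complex_size_range = c(6, 12)), "fit")
})
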