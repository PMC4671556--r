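test_that("mcode finds dense cores and ignores pendants", {
  expect_length(detect_mcode(ppi_network()), 0L)

  clique5 <- ppi_network(rbind(make_clique_edges(paste0("c", 1:5)),
                               c("c1", "pend")))
  cs <- detect_mcode(clique5)
  expect_length(cs, 1L)
  expect_setequal(cs[[1]], paste0("c", 1:5))

  two <- ppi_network(rbind(make_clique_edges(paste0("a", 1:4)),
                           make_clique_edges(paste0("b", 1:4))))
  cs2 <- detect_mcode(two)
  expect_length(cs2, 2L)
  expect_setequal(cs2[[1]], paste0("a", 1:4))
  expect_setequal(cs2[[2]], paste0("b", 1:4))
})

test_that("cmc enumerates cliques and honours the strict overlap bound", {
  clique5 <- ppi_network(make_clique_edges(paste0("c", 1:5)))
  cs <- detect_cmc(clique5)
  expect_length(cs, 1L)
  expect_setequal(cs[[1]], paste0("c", 1:5))

  path <- graph_from_spec("a-b b-c c-d")
  expect_length(detect_cmc(path), 0L)

  # two 4-cliques sharing exactly 3 nodes: overlap 3/4 = 0.75 is NOT > 0.75
  shared <- c("s1", "s2", "s3")
  g <- ppi_network(rbind(make_clique_edges(c(shared, "a")),
                         make_clique_edges(c(shared, "b"))))
  cs2 <- detect_cmc(g)
  expect_length(cs2, 2L)

  # two 5-cliques sharing 4 nodes: overlap 4/5 = 0.8 > 0.75 and the lone
  # members see 4/5 of the other clique -> merged into one complex
  s4 <- paste0("t", 1:4)
  g2 <- ppi_network(rbind(make_clique_edges(c(s4, "a")),
                          make_clique_edges(c(s4, "b"))))
  cs3 <- detect_cmc(g2)
  expect_length(cs3, 1L)
  expect_setequal(cs3[[1]], c(s4, "a", "b"))
})

test_that("detected complexes induce connected subgraphs", {
  withr::local_seed(33)
  for (rep in 1:5) {
    g <- igraph::sample_gnp(25, 0.2)
    igraph::V(g)$name <- sprintf("n%02d", 1:25)
    for (cs in list(detect_mcode(g), detect_cmc(g))) {
      for (cx in cs) {
        expect_true(all(cx %in% igraph::V(g)$name))
        sub <- igraph::induced_subgraph(g, cx)
        expect_true(igraph::is_connected(sub))
      }
    }
  }
})

test_that("run_detector maps subnetworks independently and in order", {
  g1 <- ppi_network(make_clique_edges(paste0("a", 1:4)))
  g2 <- ppi_network(make_clique_edges(paste0("b", 1:5)))
  s1 <- subnetwork(g1, igraph::V(g1)$name)
  s2 <- subnetwork(g2, igraph::V(g2)$name)
  out <- run_detector("mcode", list(s1, s2))
  expect_length(out, 2L)
  expect_setequal(out[[1]][[1]], paste0("a", 1:4))
  expect_setequal(out[[2]][[1]], paste0("b", 1:5))
  flipped <- run_detector("mcode", list(s2, s1))
  expect_identical(unclass(flipped[[1]]), unclass(out[[2]]))
  expect_error(run_detector("nope", list(s1)), "unknown detector")
})
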