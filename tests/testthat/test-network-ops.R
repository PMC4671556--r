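test_that("subnetwork extraction keeps edges touching the bicluster", {
  g <- graph_from_spec("a-b b-c c-d")
  s <- extract_bicluster_subnetwork(g, "a")
  expect_setequal(igraph::V(s$network)$name, c("a", "b"))
  expect_equal(igraph::ecount(s$network), 1L)

  expect_warning(empty <- extract_bicluster_subnetwork(g, c("x", "y")),
                 "no proteins")
  expect_equal(igraph::vcount(empty$network), 0L)
  expect_setequal(empty$missing_proteins, c("x", "y"))

  full <- extract_bicluster_subnetwork(g, letters[1:4])
  expect_equal(igraph::ecount(full$network), 3L)
})

test_that("partner-partner edges are excluded from extraction", {
  # b and c are partners of core {a}; their mutual edge must not appear
  g <- graph_from_spec("a-b a-c b-c")
  s <- extract_bicluster_subnetwork(g, "a")
  expect_equal(igraph::ecount(s$network), 2L)
  expect_equal(igraph::get_edge_ids(s$network, c("b", "c"),
                                    error = FALSE), 0)
})

test_that("closed-neighbourhood Jaccard scores match hand counts", {
  tri <- graph_from_spec("v-w w-x x-v")
  expect_equal(score_edge_reliability(tri, "v", "w"), 1.0)

  pend <- graph_from_spec("u-v v-w w-x x-v")
  expect_equal(score_edge_reliability(pend, "u", "v"), 0.5)

  # two hubs, 9 private pendants each, joined by a bridge: 2/20
  el <- rbind(cbind("h1", paste0("p", 1:9)), cbind("h2", paste0("q", 1:9)),
              c("h1", "h2"))
  hub <- ppi_network(el)
  expect_equal(score_edge_reliability(hub, "h1", "h2"), 0.1)

  expect_error(score_edge_reliability(tri, "v", "zz"), "not in the network")
})

test_that("edge scores are symmetric on random graphs", {
  withr::local_seed(30)
  for (rep in 1:5) {
    g <- igraph::sample_gnp(12, 0.3)
    igraph::V(g)$name <- paste0("n", 1:12)
    el <- igraph::as_edgelist(g)
    for (k in seq_len(min(nrow(el), 8))) {
      expect_equal(score_edge_reliability(g, el[k, 1], el[k, 2]),
                   score_edge_reliability(g, el[k, 2], el[k, 1]))
    }
  }
})

test_that("pruning removes low-score edges in a single pass", {
  tri_p <- graph_from_spec("u-v v-w w-x x-v")
  s <- subnetwork(tri_p, igraph::V(tri_p)$name)
  kept <- suppressMessages(prune_network(s, prune_params(0)))
  expect_equal(igraph::ecount(kept$network), 4L)

  pruned <- suppressMessages(prune_network(s, prune_params(0.6)))
  expect_setequal(igraph::V(pruned$network)$name, c("v", "w", "x"))
  expect_equal(igraph::ecount(pruned$network), 3L)

  # single pass on original scores: a chain of triangles sharing vertices
  # would cascade under iterative re-scoring but must not here
  chain <- graph_from_spec("a-b b-c c-a c-d d-e e-c")
  s2 <- subnetwork(chain, igraph::V(chain)$name)
  p2 <- suppressMessages(prune_network(s2, prune_params(0.6)))
  # both triangles survive: only the original scores decide
  expect_equal(igraph::ecount(p2$network),
               sum(jaccard_edge_scores(chain) >= 0.6))
})

test_that("extraction and pruning commute with protein relabelling", {
  withr::local_seed(31)
  g <- igraph::sample_gnp(14, 0.35)
  igraph::V(g)$name <- paste0("p", 1:14)
  core <- paste0("p", c(2, 5, 9))
  res1 <- suppressMessages(suppressWarnings(
    prune_network(extract_bicluster_subnetwork(g, core), prune_params(0.3))))
  relabel <- setNames(paste0("z", sample(14)), paste0("p", 1:14))
  g2 <- g
  igraph::V(g2)$name <- unname(relabel[igraph::V(g)$name])
  res2 <- suppressMessages(suppressWarnings(
    prune_network(extract_bicluster_subnetwork(g2, unname(relabel[core])),
                  prune_params(0.3))))
  canon <- function(s, map = identity) {
    e <- ppi_edges(s$network)
    a <- map(e$from)
    b <- map(e$to)
    sort(paste(pmin(a, b), pmax(a, b)))
  }
  expect_identical(canon(res1, function(x) unname(relabel[x])), canon(res2))
})
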