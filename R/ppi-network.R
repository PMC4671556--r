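#' Protein-protein interaction network container
#'
#' An undirected simple graph over protein identifiers, stored as an
#' [igraph::igraph] object. Self-loops and duplicate edges (in either
#' orientation) are collapsed on construction; identifiers are opaque,
#' case-sensitive strings.
#'
#' @param edges Two-column character matrix or data frame of interacting
#'   protein pairs (one row per interaction), or `NULL` for an edgeless
#'   network.
#' @param nodes Optional character vector of additional protein IDs to
#'   include as (possibly isolated) nodes.
#'
#' @return An undirected simple `igraph` graph whose vertex names are the
#'   protein IDs.
#' @examples
#' g <- ppi_network(rbind(c("A", "B"), c("B", "A"), c("B", "C")))
#' igraph::ecount(g) # 2
#' @export
ppi_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || NROW(edges) == 0L) {
    el <- matrix(character(), ncol = 2)
  } else {
    el <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(el) <- "character"
  }
  loops <- el[, 1] == el[, 2]
  if (any(loops)) {
    message(sprintf("dropping %d self-loop(s)", sum(loops)))
    el <- el[!loops, , drop = FALSE]
  }
  # orientation-invariant dedup
  key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r")
  el <- el[!duplicated(key), , drop = FALSE]
  all_nodes <- unique(c(as.vector(t(el)), as.character(nodes)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(all_nodes), name = all_nodes)
  if (nrow(el) > 0L) g <- igraph::add_edges(g, t(el))
  g
}

#' Edge table of a PPI network
#'
#' @param network An igraph PPI network.
#' @return A tibble with columns `from` and `to` (protein IDs, one row per
#'   undirected edge).
#' @export
ppi_edges <- function(network) {
  el <- igraph::as_edgelist(network, names = TRUE)
  tibble::tibble(from = as.character(el[, 1]), to = as.character(el[, 2]))
}
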