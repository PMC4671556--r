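#' Per-bicluster PPI subnetwork
#'
#' The PPI slice belonging to one bicluster: all interactions of the full
#' network that involve at least one bicluster member, together with the
#' interaction partners those edges pull in. Partner-partner edges are
#' deliberately not included - partners enter as edge endpoints only.
#'
#' @param network Full igraph PPI network.
#' @param core_proteins Character vector: bicluster members found in the
#'   full network.
#' @param origin Optional [bicluster()] this slice came from.
#' @param missing_proteins Bicluster members absent from the network.
#' @return An object of class `subnetwork` with fields `network` (igraph),
#'   `core_proteins`, `origin`, `missing_proteins`.
#' @export
subnetwork <- function(network, core_proteins, origin = NULL,
                       missing_proteins = character()) {
  structure(list(network = network,
                 core_proteins = sort(as.character(core_proteins)),
                 origin = origin,
                 missing_proteins = sort(as.character(missing_proteins))),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("<subnetwork: %d nodes (%d core), %d edges>\n",
              igraph::vcount(x$network), length(x$core_proteins),
              igraph::ecount(x$network)))
  invisible(x)
}

#' @describeIn subnetwork Node table with a `core` flag.
#' @param x A `subnetwork`.
#' @param ... Unused.
#' @export
tidy.subnetwork <- function(x, ...) {
  nodes <- igraph::V(x$network)$name
  tibble::tibble(protein = nodes,
                 core = nodes %in% x$core_proteins,
                 degree = as.integer(igraph::degree(x$network)))
}

#' Extract a bicluster's PPI subnetwork
#'
#' Keeps every edge of the full network with at least one endpoint among
#' the bicluster's proteins; the subnetwork's nodes are the endpoints of
#' those edges. Bicluster proteins absent from the network are recorded
#' (and reported) but are not an error; an empty result is allowed, with a
#' warning.
#'
#' @param network Full igraph PPI network.
#' @param bicluster_proteins Character vector of protein IDs (typically a
#'   bicluster's `gene_ids`).
#' @param origin Optional [bicluster()] to record as provenance.
#' @return A [subnetwork()].
#' @export
extract_bicluster_subnetwork <- function(network, bicluster_proteins,
                                         origin = NULL) {
  bicluster_proteins <- unique(as.character(bicluster_proteins))
  present <- intersect(bicluster_proteins, igraph::V(network)$name)
  absent <- setdiff(bicluster_proteins, present)
  if (length(absent)) {
    message(sprintf("%d bicluster protein(s) absent from the network",
                    length(absent)))
  }
  if (!length(present)) {
    warning("bicluster shares no proteins with the network; empty subnetwork",
            call. = FALSE)
    return(subnetwork(ppi_network(), character(), origin, absent))
  }
  vids <- igraph::V(network)[igraph::V(network)$name %in% present]
  eids <- igraph::incident_edges(network, vids)
  eids <- unique(unlist(lapply(eids, as.integer)))
  if (!length(eids)) {
    warning("bicluster proteins are isolated in the network; empty subnetwork",
            call. = FALSE)
    return(subnetwork(ppi_network(), present, origin, absent))
  }
  g <- igraph::subgraph_from_edges(network, eids, delete.vertices = TRUE)
  subnetwork(g, present, origin, absent)
}

#' Edge reliability by closed-neighbourhood overlap
#'
#' Default edge-reliability scorer: for an edge (u, v) with closed
#' neighbourhoods N+(u) = N(u) \{union} \{u\}, the score is the Jaccard
#' index |N+(u) n N+(v)| / |N+(u) u N+(v)|. It is symmetric, lies in
#' \[0, 1\], and equals 1 exactly when u and v have identical closed
#' neighbourhoods (e.g. any edge of an isolated triangle or clique). A
#' transparent topological stand-in for weighted-clustering-coefficient
#' reliability measures; alternatives can be registered with
#' [register_edge_scorer()].
#'
#' @param network An igraph network.
#' @return Numeric vector of scores, one per edge in igraph edge order.
#' @export
jaccard_edge_scores <- function(network) {
  if (igraph::ecount(network) == 0L) return(numeric())
  nb <- igraph::adjacent_vertices(network, igraph::V(network))
  nb <- lapply(seq_along(nb), function(i) c(i, as.integer(nb[[i]])))
  el <- igraph::as_edgelist(network, names = FALSE)
  vapply(seq_len(nrow(el)), function(k) {
    a <- nb[[el[k, 1]]]
    b <- nb[[el[k, 2]]]
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
}

#' Reliability of a single edge
#'
#' @param network An igraph network.
#' @param u,v Endpoint protein IDs of an existing edge.
#' @param scorer_name Registered scorer to use (default `"jaccard"`).
#' @return Scalar reliability in \[0, 1\].
#' @export
score_edge_reliability <- function(network, u, v, scorer_name = "jaccard") {
  eid <- tryCatch(igraph::get_edge_ids(network, c(u, v), error = FALSE),
                  error = function(e) 0L)
  if (eid == 0L) {
    stop(sprintf("edge %s-%s is not in the network", u, v), call. = FALSE)
  }
  get_edge_scorer(scorer_name)(network)[eid]
}

#' Parameters for subnetwork pruning
#'
#' @param reliability_threshold Edges scoring strictly below this are
#'   removed (default 0.1, so the threshold behaves as a floor: a score
#'   exactly at the threshold is kept).
#' @param scorer_name Registered edge scorer (default `"jaccard"`).
#' @return A `prune_params` list.
#' @export
prune_params <- function(reliability_threshold = 0.1,
                         scorer_name = "jaccard") {
  if (reliability_threshold < 0 || reliability_threshold > 1) {
    stop("reliability_threshold must be in [0, 1]", call. = FALSE)
  }
  structure(list(reliability_threshold = reliability_threshold,
                 scorer_name = scorer_name),
            class = "prune_params")
}

#' Prune unreliable edges from a subnetwork
#'
#' Scores every edge once with the configured scorer, removes edges whose
#' score is strictly below the threshold (a single pass over the original
#' scores - scores are not recomputed as edges drop), then removes nodes
#' left isolated. Never adds edges.
#'
#' @param subnet A [subnetwork()] (a bare igraph is also accepted and
#'   wrapped).
#' @param params A [prune_params()] list.
#' @return A pruned [subnetwork()].
#' @export
prune_network <- function(subnet, params = prune_params()) {
  if (igraph::is_igraph(subnet)) {
    subnet <- subnetwork(subnet, igraph::V(subnet)$name)
  }
  g <- subnet$network
  scores <- get_edge_scorer(params$scorer_name)(g)
  drop <- which(scores < params$reliability_threshold)
  g2 <- igraph::delete_edges(g, drop)
  iso <- which(igraph::degree(g2) == 0)
  g2 <- igraph::delete_vertices(g2, iso)
  message(sprintf("pruning removed %d/%d edge(s) and %d isolated node(s)",
                  length(drop), length(scores), length(iso)))
  subnetwork(g2,
             intersect(subnet$core_proteins, igraph::V(g2)$name),
             subnet$origin, subnet$missing_proteins)
}
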