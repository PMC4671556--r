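#' Parameters for merging per-bicluster complex sets
#'
#' @param overlap_fraction Two complexes are merge candidates when their
#'   shared members exceed this fraction of the smaller complex's size
#'   (strictly greater; default 0.75).
#' @param interaction_fraction Minimum fraction of one complex's members
#'   that must be covered by (shared with, or interacting with) the other
#'   complex for the pair to merge (default 0.5); either orientation
#'   suffices.
#' @return A `merge_params` list.
#' @export
merge_params <- function(overlap_fraction = 0.75,
                         interaction_fraction = 0.5) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1,
            interaction_fraction >= 0, interaction_fraction <= 1)
  structure(list(overlap_fraction = overlap_fraction,
                 interaction_fraction = interaction_fraction),
            class = "merge_params")
}

#' Merge and filter per-bicluster complex sets into one catalogue
#'
#' Pools the complexes detected in every bicluster's subnetwork, drops
#' exact duplicates, and repeatedly merges the highest-overlap pair (A, B)
#' whose shared members exceed `overlap_fraction` of the smaller complex
#' and for which the members of one complex interact with (or are shared
#' with) at least `interaction_fraction` of the other's members, looking
#' up interactions in the full unpruned network since merged complexes may
#' span biclusters. Iterates to a fixpoint in canonical order (size
#' descending, then lexicographic), so the result does not depend on the
#' order of the input sets.
#'
#' @param sets List of [complex_set()] objects (one per bicluster), or a
#'   single `complex_set`.
#' @param network Full igraph PPI network used for the interaction test.
#' @param params A [merge_params()] list.
#' @return A deduplicated, canonically ordered [complex_set()].
#' @export
merge_filter <- function(sets, network, params = merge_params()) {
  if (inherits(sets, "complex_set")) sets <- list(sets)
  pool <- unlist(lapply(sets, unclass), recursive = FALSE, use.names = FALSE)
  if (!length(pool)) {
    warning("empty complex pool", call. = FALSE)
    return(complex_set())
  }
  merged <- merge_pool(
    pool, network,
    overlap_fn = function(A, B) {
      length(intersect(A, B)) / min(length(A), length(B))
    },
    overlap_ok = function(ov) ov > params$overlap_fraction,
    interact_ok = function(A, B) {
      covers(A, B, network, params$interaction_fraction) ||
        covers(B, A, network, params$interaction_fraction)
    })
  canonical_complexes(merged)
}

# Do A's members interact with (or include) at least `frac` of B's members?
covers <- function(A, B, network, frac) {
  nodes <- igraph::V(network)$name
  a_in <- intersect(A, nodes)
  hit <- B %in% A
  if (length(a_in)) {
    nbrs <- unique(unlist(lapply(a_in, function(a) {
      nodes[as.integer(igraph::neighbors(network, a))]
    })))
    hit <- hit | (B %in% nbrs)
  }
  sum(hit) >= frac * length(B)
}
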