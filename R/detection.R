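#' Parameters for MCODE-style detection
#'
#' @param degree_cutoff Minimum degree for a node to be scored (default 2);
#'   lower-degree nodes get weight 0 and can neither seed nor join.
#' @param node_score_cutoff Admission slack in \[0, 1\] (default 0.2): a
#'   node joins a cluster only if its weight is no more than this fraction
#'   below the seed's weight.
#' @param k_core Clusters without a k-core of at least this degree are
#'   discarded (default 2).
#' @param max_depth Maximum distance from the seed explored during
#'   expansion (default 3).
#' @return An `mcode_params` list.
#' @export
mcode_params <- function(degree_cutoff = 2L, node_score_cutoff = 0.2,
                         k_core = 2L, max_depth = 3L) {
  stopifnot(degree_cutoff >= 0, node_score_cutoff >= 0,
            node_score_cutoff <= 1, k_core >= 2, max_depth >= 0)
  structure(list(degree_cutoff = as.integer(degree_cutoff),
                 node_score_cutoff = node_score_cutoff,
                 k_core = as.integer(k_core),
                 max_depth = as.integer(max_depth)),
            class = "mcode_params")
}

# MCODE node weights: (max core number of the node's closed neighbourhood)
# x (density of that highest k-core); 0 below the degree cutoff.
mcode_node_weights <- function(g, degree_cutoff) {
  deg <- igraph::degree(g)
  w <- numeric(igraph::vcount(g))
  scored <- which(deg >= degree_cutoff)
  for (v in scored) {
    nb <- c(v, as.integer(igraph::neighbors(g, v)))
    h <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(h)
    kmax <- max(core)
    hk <- igraph::induced_subgraph(h, which(core == kmax))
    nn <- igraph::vcount(hk)
    dens <- if (nn > 1) 2 * igraph::ecount(hk) / (nn * (nn - 1)) else 0
    w[v] <- kmax * dens
  }
  w
}

#' MCODE-style complex detection
#'
#' Weights each sufficiently connected node by the density-weighted core
#' number of its closed neighbourhood, then grows clusters outward from
#' unassigned seeds in descending weight, admitting neighbours whose
#' weight is within `node_score_cutoff` of the seed's, out to `max_depth`
#' hops. Clusters lacking a `k_core`-core or with fewer than 3 members are
#' discarded; members of kept clusters cannot join later clusters. Ties
#' resolve lexicographically by node ID, so output is deterministic.
#'
#' @param subnet A [subnetwork()] or bare igraph.
#' @param params An [mcode_params()] list.
#' @return A [complex_set()] in canonical order (size descending, then
#'   lexicographic).
#' @export
detect_mcode <- function(subnet, params = mcode_params()) {
  g <- if (igraph::is_igraph(subnet)) subnet else subnet$network
  if (igraph::vcount(g) == 0L) return(complex_set())
  w <- mcode_node_weights(g, params$degree_cutoff)
  nms <- igraph::V(g)$name
  order_seed <- order(-w, nms)
  assigned <- logical(igraph::vcount(g))
  found <- list()
  for (s in order_seed) {
    if (assigned[s] || w[s] <= 0) next
    thr <- (1 - params$node_score_cutoff) * w[s]
    members <- s
    frontier <- s
    depth <- 0L
    while (length(frontier) && depth < params$max_depth) {
      nbrs <- unique(unlist(lapply(frontier, function(v) {
        as.integer(igraph::neighbors(g, v))
      })))
      nbrs <- setdiff(nbrs, members)
      admit <- nbrs[!assigned[nbrs] & w[nbrs] >= thr]
      if (!length(admit)) break
      members <- c(members, admit)
      frontier <- admit
      depth <- depth + 1L
    }
    if (length(members) < 3L) next
    sub <- igraph::induced_subgraph(g, members)
    if (max(igraph::coreness(sub)) < params$k_core) next
    assigned[members] <- TRUE
    found[[length(found) + 1L]] <- nms[members]
  }
  canonical_complexes(found)
}

#' Parameters for CMC-style detection
#'
#' @param overlap_threshold Two cliques are examined for merging only when
#'   their overlap |A n B| / min(|A|, |B|) is strictly greater than this
#'   (default 0.75).
#' @param merge_threshold Minimum inter-connectivity for an examined pair
#'   to merge (default 0.5).
#' @param min_clique_size Smallest maximal clique kept (default 3).
#' @return A `cmc_params` list.
#' @export
cmc_params <- function(overlap_threshold = 0.75, merge_threshold = 0.5,
                       min_clique_size = 3L) {
  stopifnot(overlap_threshold >= 0, overlap_threshold <= 1,
            merge_threshold >= 0, merge_threshold <= 1, min_clique_size >= 3)
  structure(list(overlap_threshold = overlap_threshold,
                 merge_threshold = merge_threshold,
                 min_clique_size = as.integer(min_clique_size)),
            class = "cmc_params")
}

#' CMC-style complex detection
#'
#' Enumerates all maximal cliques of at least `min_clique_size` nodes
#' (pivoting Bron-Kerbosch via igraph), then repeatedly takes the
#' highest-overlap pair with overlap strictly above `overlap_threshold`
#' and merges it into its union when the inter-connectivity - the fraction
#' of realized edges among pairs (a, b) with a in A\\B and b in B - reaches
#' `merge_threshold`, iterating to a fixpoint. Candidate order is
#' canonical (size descending, then lexicographic), so output is
#' deterministic.
#'
#' @param subnet A [subnetwork()] or bare igraph.
#' @param params A [cmc_params()] list.
#' @return A [complex_set()] in canonical order.
#' @export
detect_cmc <- function(subnet, params = cmc_params()) {
  g <- if (igraph::is_igraph(subnet)) subnet else subnet$network
  if (igraph::vcount(g) == 0L) return(complex_set())
  cl <- igraph::max_cliques(g, min = params$min_clique_size)
  if (!length(cl)) return(complex_set())
  pool <- lapply(cl, function(v) sort(igraph::V(g)$name[as.integer(v)]))
  merged <- merge_pool(pool, g,
                       overlap_fn = function(A, B) {
                         length(intersect(A, B)) / min(length(A), length(B))
                       },
                       overlap_ok = function(ov) ov > params$overlap_threshold,
                       interact_ok = function(A, B) {
                         cmc_interconnectivity(A, B, g) >= params$merge_threshold
                       })
  canonical_complexes(merged)
}

# fraction of realized edges among pairs (a, b), a in A\B, b in B
cmc_interconnectivity <- function(A, B, g) {
  a_only <- setdiff(A, B)
  n_pairs <- length(a_only) * length(B)
  if (n_pairs == 0L) return(1)  # containment: nothing left to connect
  cnt <- 0L
  for (a in a_only) {
    nb <- igraph::V(g)$name[as.integer(igraph::neighbors(g, a))]
    cnt <- cnt + sum(B %in% nb)
  }
  cnt / n_pairs
}

# canonical ordering + exact-duplicate drop; returns a complex_set
canonical_complexes <- function(pool) {
  if (!length(pool)) return(complex_set())
  pool <- lapply(pool, function(m) sort(unique(m)))
  key <- vapply(pool, paste, "", collapse = "\r")
  pool <- pool[!duplicated(key)]
  key <- key[!duplicated(key)]
  complex_set(pool[order(-lengths(pool), key)])
}

# generic highest-overlap-first merging to fixpoint over a pool of
# complexes; used by both detect_cmc and merge_filter
merge_pool <- function(pool, g, overlap_fn, overlap_ok, interact_ok) {
  pool <- lapply(pool, function(m) sort(unique(m)))
  key <- vapply(pool, paste, "", collapse = "\r")
  pool <- pool[!duplicated(key)]
  rejected <- character()
  repeat {
    if (length(pool) < 2L) break
    # canonical order: size desc, then lexicographic
    key <- vapply(pool, paste, "", collapse = "\r")
    ord <- order(-lengths(pool), key)
    pool <- pool[ord]
    key <- key[ord]
    n <- length(pool)
    best <- NULL
    best_ov <- -Inf
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        pk <- paste(key[i], key[j], sep = "\n")
        if (pk %in% rejected) next
        ov <- overlap_fn(pool[[i]], pool[[j]])
        if (overlap_ok(ov) && ov > best_ov) {
          best <- c(i, j)
          best_ov <- ov
        }
      }
    }
    if (is.null(best)) break
    i <- best[1]; j <- best[2]
    if (interact_ok(pool[[i]], pool[[j]])) {
      u <- sort(union(pool[[i]], pool[[j]]))
      pool <- c(pool[-c(i, j)], list(u))
      kk <- vapply(pool, paste, "", collapse = "\r")
      pool <- pool[!duplicated(kk)]
    } else {
      rejected <- c(rejected, paste(key[i], key[j], sep = "\n"))
    }
  }
  pool
}

#' Run a registered detector over a list of subnetworks
#'
#' Applies the detector independently to each (typically per-bicluster)
#' subnetwork; the i-th output corresponds to the i-th input.
#'
#' @param name Registered detector name (`"mcode"`, `"cmc"`, or a plugin).
#' @param subnets List of [subnetwork()] objects.
#' @param params Parameter list passed to the detector.
#' @return List of [complex_set()] objects, one per subnetwork.
#' @export
run_detector <- function(name, subnets, params = NULL) {
  fn <- get_detector(name)
  lapply(subnets, function(s) if (is.null(params)) fn(s) else fn(s, params))
}
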