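# Named registries for the three pluggable stages. External algorithms
# (e.g. OPSM/ISA biclusterers or ClusterONE-style detectors wrapped from
# other tools) can be registered without touching the core pipeline.

.bicnet_registry <- new.env(parent = emptyenv())

registry_get <- function(kind, name) {
  tab <- get0(kind, envir = .bicnet_registry)
  fn <- tab[[name]]
  if (is.null(fn)) {
    stop(sprintf("unknown %s '%s'; registered: %s", sub("s$", "", kind),
                 name, paste(names(tab), collapse = ", ")), call. = FALSE)
  }
  fn
}

registry_set <- function(kind, name, fn) {
  tab <- get0(kind, envir = .bicnet_registry, ifnotfound = list())
  tab[[name]] <- fn
  assign(kind, tab, envir = .bicnet_registry)
  invisible(name)
}

#' Register or look up pluggable algorithms
#'
#' Biclusterers map an expression matrix (+ params) to a list of
#' biclusters; detectors map a subnetwork (+ params) to a [complex_set()];
#' edge scorers map a network to a vector of edge reliabilities in
#' \[0, 1\], aligned with the graph's edge order.
#' Built-ins: biclusterers `"cc"`, `"kmeans"`; detectors
#' `"mcode"`, `"cmc"`; scorers `"jaccard"`.
#'
#' @param name Registry key.
#' @param fn Function implementing the contract above.
#' @return `register_*` return `name` invisibly; `get_*` return the
#'   registered function or raise a configuration error.
#' @export
register_biclusterer <- function(name, fn) registry_set("biclusterers", name, fn)

#' @rdname register_biclusterer
#' @export
register_detector <- function(name, fn) registry_set("detectors", name, fn)

#' @rdname register_biclusterer
#' @export
register_edge_scorer <- function(name, fn) registry_set("scorers", name, fn)

#' @rdname register_biclusterer
#' @export
get_biclusterer <- function(name) registry_get("biclusterers", name)

#' @rdname register_biclusterer
#' @export
get_detector <- function(name) registry_get("detectors", name)

#' @rdname register_biclusterer
#' @export
get_edge_scorer <- function(name) registry_get("scorers", name)

register_builtins <- function() {
  registry_set("biclusterers", "cc", function(em, params = cc_params()) {
    cheng_church(em, params)
  })
  registry_set("biclusterers", "kmeans", function(em, params = kmeans_params()) {
    kmeans_rows(em, params)
  })
  registry_set("detectors", "mcode", function(subnet, params = mcode_params()) {
    detect_mcode(subnet, params)
  })
  registry_set("detectors", "cmc", function(subnet, params = cmc_params()) {
    detect_cmc(subnet, params)
  })
  registry_set("scorers", "jaccard", jaccard_edge_scores)
}

.onLoad <- function(libname, pkgname) {
  register_builtins()
}
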