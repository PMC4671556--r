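#' Protein complex set container
#'
#' An ordered collection of protein complexes, each a set of at least two
#' protein IDs. Used both for predicted complexes and for reference
#' catalogues (CYC2008-style). Finalized sets contain no exact-duplicate
#' member sets; intermediates pooled during merging may.
#'
#' @param complexes List of character vectors, each of length >= 2;
#'   duplicate members within a complex are collapsed.
#' @param labels Optional character vector of names, one per complex.
#' @param allow_duplicates Keep exact-duplicate member sets (used for
#'   pre-merge pools)? Default `FALSE` drops them, keeping the first.
#'
#' @return An object of class `complex_set`: a list of sorted character
#'   vectors, possibly named.
#' @examples
#' cs <- complex_set(list(c("A", "B", "C"), c("D", "E")))
#' length(cs)
#' @export
complex_set <- function(complexes = list(), labels = NULL,
                        allow_duplicates = FALSE) {
  complexes <- lapply(complexes, function(m) sort(unique(as.character(m))))
  sizes <- lengths(complexes)
  if (any(sizes < 2L)) {
    stop(sprintf("complex(es) %s have fewer than 2 members",
                 paste(which(sizes < 2L), collapse = ", ")), call. = FALSE)
  }
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(complexes))
    names(complexes) <- labels
  }
  if (!allow_duplicates) {
    key <- vapply(complexes, paste, "", collapse = "\r")
    complexes <- complexes[!duplicated(key)]
  }
  structure(complexes, class = "complex_set")
}

#' @export
print.complex_set <- function(x, ...) {
  cat(sprintf("<complex_set: %d complexes, sizes %s>\n", length(x),
              if (length(x)) paste(range(lengths(x)), collapse = "-") else "-"))
  invisible(x)
}

#' @export
`[.complex_set` <- function(x, i) {
  structure(unclass(x)[i], class = "complex_set")
}

#' @describeIn complex_set One row per (complex, member) pair.
#' @param x A `complex_set`.
#' @param ... Unused.
#' @export
tidy.complex_set <- function(x, ...) {
  lab <- if (is.null(names(x))) sprintf("complex_%03d", seq_along(x)) else names(x)
  tibble::tibble(
    complex = rep(lab, lengths(x)),
    size = rep(lengths(x), lengths(x)),
    member = unlist(x, use.names = FALSE)
  )
}
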