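#' Read a tab-delimited expression matrix
#'
#' Expects a BicAT-style plain matrix: first row is the condition header
#' (its first cell is an ignorable corner label), first column holds gene
#' IDs, remaining cells are tab-separated expression values. Duplicate gene
#' rows collapse to the first occurrence with a warning; cells equal to
#' `missing_token` become missing.
#'
#' @param path Path to the tab-delimited file.
#' @param missing_token String marking a missing cell (default `"NA"`).
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, missing_token = "NA") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop("expression file has no data rows: ", path, call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (length(header) < 2L) {
    stop("expression file has no data columns: ", path, call. = FALSE)
  }
  condition_ids <- header[-1]
  m <- length(condition_ids)
  body <- fields[-1]
  bad <- which(lengths(body) != m + 1L)
  if (length(bad)) {
    stop(sprintf("ragged row(s) at line(s) %s of %s",
                 paste(bad + 1L, collapse = ", "), path), call. = FALSE)
  }
  gene_ids <- vapply(body, `[[`, "", 1L)
  dup <- duplicated(gene_ids)
  if (any(dup)) {
    warning(sprintf("dropping %d duplicate gene row(s): %s", sum(dup),
                    paste(unique(gene_ids[dup]), collapse = ", ")),
            call. = FALSE)
    body <- body[!dup]
    gene_ids <- gene_ids[!dup]
  }
  cells <- matrix(unlist(lapply(body, `[`, -1L)), nrow = length(body),
                  ncol = m, byrow = TRUE)
  miss <- cells == missing_token
  values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  values[miss] <- NA_real_
  if (any(is.na(values) & !miss)) {
    stop("non-numeric cell(s) in expression file: ", path, call. = FALSE)
  }
  expression_matrix(values, gene_ids, condition_ids)
}

#' Write an expression matrix in the tab-delimited layout [read_expression_matrix()] expects
#'
#' @param em An [expression_matrix()].
#' @param path Output path.
#' @param missing_token Token written for missing cells.
#' @export
write_expression_matrix <- function(em, path, missing_token = "NA") {
  vals <- unclass(em)
  body <- apply(vals, 1, function(r) {
    out <- vapply(r, function(v) {
      if (is.na(v)) missing_token else format(v, trim = TRUE, digits = 15)
    }, "")
    paste(out, collapse = "\t")
  })
  writeLines(c(paste(c("gene", colnames(em)), collapse = "\t"),
               paste(rownames(em), body, sep = "\t")), path)
  invisible(path)
}

#' Read a PPI network from a whitespace-separated edge list
#'
#' Each non-comment line names one interaction by its two endpoint protein
#' IDs (extra fields are ignored); lines starting with `#` are skipped.
#' Self-loops are dropped with a message and duplicate pairs in either
#' orientation are collapsed, so the result is a simple undirected graph.
#'
#' @param path Path to the edge-list file.
#' @return An igraph PPI network (see [ppi_network()]).
#' @export
read_ppi_edgelist <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  kept_idx <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  bad <- which(lengths(fields) < 2L)
  if (length(bad)) {
    stop(sprintf("edge-list line(s) %s of %s have fewer than 2 fields",
                 paste(kept_idx[bad], collapse = ", "), path), call. = FALSE)
  }
  if (!length(fields)) return(ppi_network())
  el <- t(vapply(fields, function(f) f[1:2], character(2)))
  ppi_network(el)
}

#' Write a PPI network as a two-column tab-separated edge list
#'
#' @param network An igraph PPI network.
#' @param path Output path.
#' @param isolated Include isolated nodes as `# node <id>` comment lines so
#'   the file round-trips the node set? Default `FALSE`.
#' @export
write_ppi_edgelist <- function(network, path, isolated = FALSE) {
  ed <- ppi_edges(network)
  lines <- paste(ed$from, ed$to, sep = "\t")
  if (isolated) {
    iso <- igraph::V(network)$name[igraph::degree(network) == 0]
    lines <- c(lines, if (length(iso)) paste("#", "node", iso))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a complex catalogue
#'
#' One complex per line, whitespace-separated member IDs (the layout of
#' CYC2008-style catalogues). Writing then reading reproduces the same
#' member sets in the same order. Lines with a single member are rejected.
#'
#' @param path Path to the catalogue file.
#' @return For `read_complexes`, a [complex_set()].
#' @export
read_complexes <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  members <- strsplit(trimws(lines[keep]), "[ \t]+")
  bad <- which(lengths(members) < 2L)
  if (length(bad)) {
    stop(sprintf("complex line(s) %s of %s have fewer than 2 members",
                 paste(which(keep)[bad], collapse = ", "), path),
         call. = FALSE)
  }
  complex_set(members, allow_duplicates = TRUE)
}

#' @rdname read_complexes
#' @param cs A [complex_set()] to write.
#' @export
write_complexes <- function(cs, path) {
  writeLines(vapply(cs, paste, "", collapse = "\t"), path)
  invisible(path)
}
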