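#' Pipeline configuration
#'
#' Bundles the inputs and per-stage parameters of the five-stage pipeline
#' (bicluster, extract, prune, detect, merge) plus evaluation. The
#' defaults reproduce the method's standard settings: Cheng-Church with
#' delta = 0.5, alpha = 1.2, 10 biclusters (k-means baseline: k = 10, 100
#' iterations, 1 replicate, Pearson distance); reliability threshold 0.1;
#' MCODE 2/0.2/2/3; CMC 0.75/0.5; merge 0.75/0.5; OS match threshold 0.2.
#'
#' @param expression_path,network_path,reference_path Input file paths
#'   (may stay `NULL` when in-memory objects are passed to
#'   [run_pipeline()]).
#' @param biclusterer Registered biclusterer name (`"cc"` or `"kmeans"`).
#' @param biclusterer_params Parameter list; defaults to [cc_params()] or
#'   [kmeans_params()] seeded with `seed`.
#' @param prune A [prune_params()] list.
#' @param detector Registered detector name (`"mcode"` or `"cmc"`).
#' @param detector_params Parameter list; defaults to [mcode_params()] or
#'   [cmc_params()].
#' @param merge A [merge_params()] list.
#' @param eval An [eval_params()] list.
#' @param seed Integer seed propagated to seeded stages.
#' @param output_dir Directory for per-stage artifacts (`NULL` = none).
#' @param baseline_prune Should [run_static_baseline()] prune the full
#'   network before detection? Default `TRUE`, matching the dynamic runs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(expression_path = NULL, network_path = NULL,
                            reference_path = NULL, biclusterer = "cc",
                            biclusterer_params = NULL,
                            prune = prune_params(), detector = "mcode",
                            detector_params = NULL, merge = merge_params(),
                            eval = eval_params(), seed = 1L,
                            output_dir = NULL, baseline_prune = TRUE) {
  get_biclusterer(biclusterer)  # fail fast on unknown names
  get_detector(detector)
  get_edge_scorer(prune$scorer_name)
  if (is.null(biclusterer_params)) {
    biclusterer_params <- switch(biclusterer,
                                 cc = cc_params(seed = seed),
                                 kmeans = kmeans_params(seed = seed),
                                 NULL)
  }
  if (is.null(detector_params)) {
    detector_params <- switch(detector, mcode = mcode_params(),
                              cmc = cmc_params(), NULL)
  }
  structure(list(expression_path = expression_path,
                 network_path = network_path,
                 reference_path = reference_path,
                 biclusterer = biclusterer,
                 biclusterer_params = biclusterer_params,
                 prune = prune, detector = detector,
                 detector_params = detector_params, merge = merge,
                 eval = eval, seed = as.integer(seed),
                 output_dir = output_dir, baseline_prune = baseline_prune),
            class = "pipeline_config")
}

#' Serialize / parse a pipeline configuration (YAML)
#'
#' `write_pipeline_config()` then `read_pipeline_config()` reproduces an
#' identical configuration.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  strip <- function(x) {
    if (is.list(x)) {
      lapply(unclass(x), strip)
    } else x
  }
  yaml::write_yaml(strip(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  rebuild <- function(constructor, x) {
    if (is.null(x)) NULL else do.call(constructor, x)
  }
  bic_ctor <- switch(raw$biclusterer, cc = cc_params, kmeans = kmeans_params,
                     NULL)
  det_ctor <- switch(raw$detector, mcode = mcode_params, cmc = cmc_params,
                     NULL)
  pipeline_config(
    expression_path = raw$expression_path,
    network_path = raw$network_path,
    reference_path = raw$reference_path,
    biclusterer = raw$biclusterer,
    biclusterer_params = if (is.null(bic_ctor)) raw$biclusterer_params else
      rebuild(bic_ctor, raw$biclusterer_params),
    prune = rebuild(prune_params, raw$prune),
    detector = raw$detector,
    detector_params = if (is.null(det_ctor)) raw$detector_params else
      rebuild(det_ctor, raw$detector_params),
    merge = rebuild(merge_params, raw$merge),
    eval = rebuild(eval_params, raw$eval),
    seed = raw$seed,
    output_dir = raw$output_dir,
    baseline_prune = isTRUE(raw$baseline_prune))
}

stage_step <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

artifact_path <- function(config, name) {
  if (is.null(config$output_dir)) return(NULL)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  file.path(config$output_dir, name)
}

#' Write / read a bicluster file
#'
#' One bicluster per block: a line of gene IDs, a line of condition IDs
#' (tab-separated), blocks separated by blank lines; `#` lines are
#' comments.
#'
#' @param biclusters List of [bicluster()] objects.
#' @param path File path.
#' @param header Optional comment lines (written prefixed with `#`).
#' @export
write_biclusters <- function(biclusters, path, header = NULL) {
  lines <- unlist(lapply(biclusters, function(b) {
    c(paste(b$gene_ids %||% b$rows, collapse = "\t"),
      paste(b$condition_ids %||% b$cols, collapse = "\t"),
      "")
  }))
  if (!is.null(header)) lines <- c(paste("#", header), lines)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_biclusters
#' @return For `read_biclusters`, a list of lists with `gene_ids` and
#'   `condition_ids`.
#' @export
read_biclusters <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#")]
  blank <- !nzchar(trimws(lines))
  block <- cumsum(blank & !c(TRUE, blank[-length(blank)]))
  keep <- split(lines[!blank], block[!blank])
  lapply(keep, function(bl) {
    stopifnot(length(bl) == 2L)
    list(gene_ids = strsplit(bl[1], "\t", fixed = TRUE)[[1]],
         condition_ids = strsplit(bl[2], "\t", fixed = TRUE)[[1]])
  })
}

#' Run the full dynamic pipeline
#'
#' Executes bicluster -> extract -> prune -> detect -> merge in order and,
#' when a reference catalogue is available, evaluates the final complex
#' set against it. Identical configuration and seed reproduce identical
#' outputs. When `config$output_dir` is set, per-stage artifacts are
#' written (bicluster file, per-bicluster raw and pruned edge lists,
#' per-bicluster complex files, merged catalogue, report).
#'
#' @param config A [pipeline_config()].
#' @param expression,network,reference Optional in-memory inputs
#'   overriding the configured paths.
#' @return A `pipeline_result` list: `complexes` (the final
#'   [complex_set()]), `report` (an `evaluation_report` or `NULL`),
#'   `biclusters`, `subnetworks`, `pruned`, `per_bicluster_complexes`,
#'   and `counts` (stage-boundary tallies).
#' @export
run_pipeline <- function(config = pipeline_config(), expression = NULL,
                         network = NULL, reference = NULL) {
  bic_fn <- get_biclusterer(config$biclusterer)
  det_fn <- get_detector(config$detector)
  get_edge_scorer(config$prune$scorer_name)

  expression <- stage_step("input", {
    expression %||% read_expression_matrix(config$expression_path)
  })
  network <- stage_step("input", {
    network %||% read_ppi_edgelist(config$network_path)
  })
  if (is.null(reference) && !is.null(config$reference_path)) {
    reference <- stage_step("input", read_complexes(config$reference_path))
  }

  biclusters <- stage_step("bicluster", {
    if (is.null(config$biclusterer_params)) bic_fn(expression)
    else bic_fn(expression, config$biclusterer_params)
  })
  if (!is.null(p <- artifact_path(config, "biclusters.txt"))) {
    write_biclusters(biclusters, p,
                     header = sprintf("biclusterer=%s seed=%d",
                                      config$biclusterer, config$seed))
  }
  message(sprintf("stage bicluster: %d bicluster(s)", length(biclusters)))

  subnets <- stage_step("extract", {
    lapply(biclusters, function(b) {
      suppressWarnings(
        extract_bicluster_subnetwork(network, b$gene_ids, origin = b))
    })
  })
  pruned <- stage_step("prune", {
    lapply(subnets, function(s) {
      suppressMessages(prune_network(s, config$prune))
    })
  })
  for (i in seq_along(subnets)) {
    if (!is.null(p <- artifact_path(config, sprintf("subnet_%02d.tsv", i)))) {
      write_ppi_edgelist(subnets[[i]]$network, p)
      write_ppi_edgelist(pruned[[i]]$network,
                         artifact_path(config, sprintf("pruned_%02d.tsv", i)))
    }
  }
  message(sprintf(
    "stage prune (threshold %.2f): %d -> %d edges over %d subnetwork(s)",
    config$prune$reliability_threshold,
    sum(vapply(subnets, function(s) igraph::ecount(s$network), 0)),
    sum(vapply(pruned, function(s) igraph::ecount(s$network), 0)),
    length(subnets)))

  sets <- stage_step("detect", {
    run_detector(config$detector, pruned, config$detector_params)
  })
  for (i in seq_along(sets)) {
    if (!is.null(p <- artifact_path(config,
                                    sprintf("complexes_%02d.txt", i)))) {
      write_complexes(sets[[i]], p)
    }
  }
  message(sprintf("stage detect (%s): %d candidate complex(es)",
                  config$detector, sum(lengths(sets))))

  final <- stage_step("merge", {
    suppressWarnings(merge_filter(sets, network, config$merge))
  })
  if (!is.null(p <- artifact_path(config, "final_complexes.txt"))) {
    write_complexes(final, p)
  }
  message(sprintf("stage merge: %d -> %d complex(es)",
                  sum(lengths(sets)), length(final)))

  report <- NULL
  if (!is.null(reference)) {
    report <- stage_step("evaluate", {
      evaluate_complexes(final, reference, config$eval)
    })
    if (!is.null(p <- artifact_path(config, "report.tsv"))) {
      df <- glance(report)
      utils::write.table(df, p, sep = "\t", row.names = FALSE,
                         quote = FALSE)
    }
  }

  structure(list(complexes = final, report = report,
                 biclusters = biclusters, subnetworks = subnets,
                 pruned = pruned, per_bicluster_complexes = sets,
                 counts = list(n_biclusters = length(biclusters),
                               n_candidates = sum(lengths(sets)),
                               n_final = length(final)),
                 config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result: %d biclusters -> %d candidates -> %d complexes>\n",
    x$counts$n_biclusters, x$counts$n_candidates, x$counts$n_final))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' Static baseline: detection without expression data
#'
#' Applies the configured detector to the full (optionally pruned) PPI
#' network, skipping the biclustering stage entirely. Reports use the
#' same format as [run_pipeline()], enabling paired dynamic-vs-static
#' comparisons.
#'
#' @param config A [pipeline_config()]; `baseline_prune` controls whether
#'   the full network is reliability-pruned first.
#' @param network,reference Optional in-memory inputs overriding paths.
#' @return A `pipeline_result` (with `biclusters = NULL`).
#' @export
run_static_baseline <- function(config = pipeline_config(), network = NULL,
                                reference = NULL) {
  det_fn <- get_detector(config$detector)
  network <- stage_step("input", {
    network %||% read_ppi_edgelist(config$network_path)
  })
  if (is.null(reference) && !is.null(config$reference_path)) {
    reference <- stage_step("input", read_complexes(config$reference_path))
  }
  subnet <- subnetwork(network, igraph::V(network)$name)
  if (isTRUE(config$baseline_prune)) {
    subnet <- stage_step("prune", {
      suppressMessages(prune_network(subnet, config$prune))
    })
  }
  final <- stage_step("detect", {
    if (is.null(config$detector_params)) det_fn(subnet)
    else det_fn(subnet, config$detector_params)
  })
  report <- NULL
  if (!is.null(reference)) {
    report <- evaluate_complexes(final, reference, config$eval)
  }
  structure(list(complexes = final, report = report, biclusters = NULL,
                 subnetworks = list(subnet), pruned = NULL,
                 per_bicluster_complexes = list(final),
                 counts = list(n_biclusters = 0L,
                               n_candidates = length(final),
                               n_final = length(final)),
                 config = config),
            class = "pipeline_result")
}
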