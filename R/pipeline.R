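#' Assemble and validate a pipeline configuration
#'
#' Houses every input path and threshold of the end-to-end analysis:
#' similarity cutoff (default 0.95), PPI minimum combined score (default
#' 900, i.e. STRING 0.9), DE significance level and fold-change floor, and
#' the enrichment significance level.
#'
#' @param components,synonyms,library,docking,controls,expression_matrix,
#'   labels,ppi,annotations input file paths (`synonyms` and `annotations`
#'   may be NULL).
#' @param out_dir output directory (created if needed).
#' @param similarity_cutoff Tanimoto cutoff in `(0, 1]`.
#' @param ppi_min_score integer in `[0, 1000]`.
#' @param de_alpha,de_min_abs_log2fc,enrich_alpha thresholds.
#' @param de_var_equal use the pooled-variance t statistic (see
#'   [differential_genes()]).
#' @param enrich_use_fdr flag enrichment significance on BH q.
#' @param self_de_counts see [prioritize_targets()].
#' @param log2_expression apply `log2(x + 1)` to the expression matrix on
#'   load.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(components, library, docking, controls,
                            expression_matrix, labels, ppi,
                            annotations = NULL, synonyms = NULL,
                            out_dir = "fzhynet_out",
                            similarity_cutoff = 0.95,
                            ppi_min_score = 900L,
                            de_alpha = 0.05, de_min_abs_log2fc = 1.0,
                            de_var_equal = FALSE,
                            enrich_alpha = 0.05, enrich_use_fdr = FALSE,
                            self_de_counts = FALSE,
                            log2_expression = FALSE) {
  cfg <- list(components = components, synonyms = synonyms, library = library,
              docking = docking, controls = controls,
              expression_matrix = expression_matrix, labels = labels,
              ppi = ppi, annotations = annotations, out_dir = out_dir,
              similarity_cutoff = as.numeric(similarity_cutoff),
              ppi_min_score = as.integer(ppi_min_score),
              de_alpha = as.numeric(de_alpha),
              de_min_abs_log2fc = as.numeric(de_min_abs_log2fc),
              de_var_equal = isTRUE(de_var_equal),
              enrich_alpha = as.numeric(enrich_alpha),
              enrich_use_fdr = isTRUE(enrich_use_fdr),
              self_de_counts = isTRUE(self_de_counts),
              log2_expression = isTRUE(log2_expression))
  if (cfg$similarity_cutoff <= 0 || cfg$similarity_cutoff > 1) {
    stop("similarity_cutoff must lie in (0, 1]", call. = FALSE)
  }
  if (is.na(cfg$ppi_min_score) || cfg$ppi_min_score < 0 ||
      cfg$ppi_min_score > 1000) {
    stop("ppi_min_score must lie in [0, 1000]", call. = FALSE)
  }
  for (thr in c("de_alpha", "enrich_alpha")) {
    if (cfg[[thr]] <= 0 || cfg[[thr]] >= 1) {
      stop(thr, " must lie in (0, 1)", call. = FALSE)
    }
  }
  if (cfg$de_min_abs_log2fc < 0) {
    stop("de_min_abs_log2fc must be non-negative", call. = FALSE)
  }
  path_keys <- c("components", "synonyms", "library", "docking", "controls",
                 "expression_matrix", "labels", "ppi", "annotations")
  for (key in path_keys) {
    p <- cfg[[key]]
    if (is.null(p)) next
    if (!file.exists(p)) {
      stop("configured ", key, " file does not exist: ", p, call. = FALSE)
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a flat key=value pipeline configuration file
#'
#' Lines of `key = value`; blank lines and `#` comments ignored. Keys match
#' the arguments of [pipeline_config()]; values are coerced by that
#' function. Relative paths are resolved against the config file's
#' directory. Entries in `...` override file entries.
#'
#' @param path config file path.
#' @param ... overrides passed on to [pipeline_config()].
#' @return validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- lengths(kv) != 3
  if (any(bad)) {
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  args <- stats::setNames(lapply(kv, function(m) {
    v <- trimws(m[[3]])
    if (v %in% c("TRUE", "FALSE")) return(as.logical(v))
    if (grepl("^-?[0-9.]+$", v)) return(as.numeric(v))
    v
  }), vapply(kv, `[[`, character(1), 2))
  base_dir <- dirname(normalizePath(path))
  path_keys <- c("components", "synonyms", "library", "docking", "controls",
                 "expression_matrix", "labels", "ppi", "annotations",
                 "out_dir")
  for (key in intersect(names(args), path_keys)) {
    v <- args[[key]]
    if (is.character(v) && !grepl("^/", v)) args[[key]] <- file.path(base_dir, v)
  }
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(pipeline_config, args)
}

log_line <- function(lines, ...) c(lines, paste0("INFO ", ...))

#' Run the full target-prioritization analysis
#'
#' Executes catalog building, similarity and docking target mapping, CTPI
#' construction, differential expression, PPI filtering, CTPG integration,
#' target prioritization and (if annotations are configured) enrichment of
#' the prioritized set; writes every intermediate table, SIF/GraphML network
#' exports, a JSON run report and a log under `config$out_dir`. Identical
#' configuration and inputs produce identical outputs (the timestamp lives
#' only in the log).
#'
#' @param config a [pipeline_config()].
#' @return the run report, invisibly (a list; also written as
#'   `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  log <- character(0)
  log <- log_line(log, "run started ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  stage <- "catalog"
  report <- tryCatch({
    components <- load_component_table(config$components)
    synonyms <- if (is.null(config$synonyms)) synonym_map() else
      load_synonym_map(config$synonyms)
    catalog <- build_catalog(components, synonyms)
    write_catalog(catalog, out("catalog.tsv"))
    log <- log_line(log, "catalog: ", nrow(catalog), " compounds from ",
                    nrow(components), " rows")

    stage <- "target mapping"
    library_df <- load_reference_library(config$library)
    log <- log_line(log, "similarity cutoff ", config$similarity_cutoff,
                    " (inclusive) against ", nrow(library_df), " drugs")
    sim_e <- similarity_edges(catalog, library_df,
                              cutoff = config$similarity_cutoff)
    docking <- utils::read.delim(config$docking, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE,
                                 fileEncoding = "UTF-8")
    controls <- utils::read.delim(config$controls, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE,
                                  fileEncoding = "UTF-8")
    # docking tables may print display-cased compound names; resolve them
    # through the same normalization + synonym map as the catalog
    docking$compound <- apply_synonyms(docking$compound, synonyms)
    log <- log_line(log, "docking rule: score strictly above per-protein ",
                    "co-crystal control")
    dock_e <- docking_targets(docking, controls)
    targets <- merge_target_sets(sim_e$protein, dock_e$protein)
    utils::write.table(targets, out("targets.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    log <- log_line(log, "targets: ", nrow(targets), " (",
                    sum(targets$provenance != "docking"), " similarity, ",
                    sum(targets$provenance != "similarity"), " docking, ",
                    sum(targets$provenance == "both"), " both)")

    stage <- "CTPI construction"
    ctpi_edges <- unique(rbind(sim_e, dock_e[, c("compound", "protein")]))
    ctpi <- build_ctpi(catalog, targets, ctpi_edges)
    write_sif(ctpi, out("ctpi.sif"), relation = "targets")
    write_graphml(ctpi, out("ctpi.graphml"))
    ctpi_summary <- network_summary(ctpi)

    stage <- "differential expression"
    expr <- load_expression(config$expression_matrix, config$labels,
                            log2 = config$log2_expression)
    log <- log_line(log, "DE thresholds: q < ", config$de_alpha,
                    ", |log2fc| >= ", config$de_min_abs_log2fc,
                    if (config$de_var_equal) " (pooled t)" else " (Welch t)")
    de <- differential_genes(expr, alpha = config$de_alpha,
                             min_abs_log2fc = config$de_min_abs_log2fc,
                             var_equal = config$de_var_equal)
    write_de_table(de, out("de_results.tsv"))
    de_genes <- de$gene[de$significant]
    log <- log_line(log, "DE: ", length(de_genes), " significant of ",
                    sum(de$tested), " tested genes")

    stage <- "PPI filtering"
    ppi <- load_ppi(config$ppi)
    log <- log_line(log, "PPI minimum combined score ", config$ppi_min_score,
                    " (inclusive)")
    ppi_f <- filter_ppi(ppi, min_score = config$ppi_min_score)
    utils::write.table(ppi_f, out("ppi_filtered.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    log <- log_line(log, "PPI: ", nrow(ppi_f), " of ", nrow(ppi),
                    " edges at threshold")

    stage <- "CTPG integration"
    ctpg <- build_ctpg(ctpi, ppi_f, de_genes)
    write_sif(ctpg, out("ctpg.sif"))
    write_graphml(ctpg, out("ctpg.graphml"))
    ctpg_summary <- network_summary(ctpg)

    stage <- "target prioritization"
    prioritized <- prioritize_targets(ctpg,
                                      self_de_counts = config$self_de_counts)
    write_prioritized(prioritized, out("prioritized_targets.tsv"))
    retained <- retained_compounds(prioritized)
    log <- log_line(log, "prioritized ", nrow(prioritized), " of ",
                    ctpg_summary$n_targets, " targets; retained ",
                    length(retained), " of ", nrow(catalog), " compounds")

    enr_sig <- NULL
    if (!is.null(config$annotations) && nrow(prioritized) > 0) {
      stage <- "enrichment"
      collections <- read_gmt(config$annotations)
      background <- unique(c(unlist(collections$members),
                             prioritized$protein))
      enr <- enrich(prioritized$protein, collections,
                    background = background,
                    alpha = config$enrich_alpha,
                    use_fdr = config$enrich_use_fdr)
      write_enrichment(enr, out("enrichment.tsv"))
      enr_sig <- enr[enr$significant, , drop = FALSE]
      for (ns in unique(enr_sig$namespace)) {
        net <- annotation_network(enr_sig, namespace = ns)
        write_graphml(net, out(paste0("annotation_", ns, ".graphml")))
      }
      log <- log_line(log, "enrichment: ", nrow(enr_sig),
                      " significant terms at ",
                      if (config$enrich_use_fdr) "q" else "p", " < ",
                      config$enrich_alpha)
    }

    stage <- "report"
    inputs <- Filter(Negate(is.null),
                     config[c("components", "synonyms", "library", "docking",
                              "controls", "expression_matrix", "labels",
                              "ppi", "annotations")])
    list(
      parameters = config[c("similarity_cutoff", "ppi_min_score", "de_alpha",
                            "de_min_abs_log2fc", "de_var_equal",
                            "enrich_alpha", "enrich_use_fdr",
                            "self_de_counts", "log2_expression")],
      input_md5 = as.list(tools::md5sum(unlist(inputs))),
      catalog = list(n_compounds = nrow(catalog),
                     n_rows = nrow(components)),
      ctpi = ctpi_summary[c("n_compounds", "n_targets", "n_nodes", "n_edges")],
      de = list(n_tested = sum(de$tested), n_significant = length(de_genes)),
      ppi = list(n_edges = nrow(ppi), n_kept = nrow(ppi_f)),
      ctpg = ctpg_summary[c("n_compounds", "n_targets", "n_de", "n_nodes",
                            "n_edges")],
      prioritized_targets = prioritized$protein,
      retained_compounds = retained,
      enrichment = if (is.null(enr_sig)) NULL else
        list(n_significant = nrow(enr_sig),
             top_terms = utils::head(enr_sig$term_id[order(enr_sig$p)], 10))
    )
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log <- log_line(log, "run finished")
  writeLines(log, out("run.log"))
  invisible(report)
}
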