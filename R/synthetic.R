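#' Specification of a synthetic benchmarking universe
#'
#' Describes a seeded synthetic data bundle with planted ground truth:
#' compounds with random binary fingerprints, a reference drug library in
#' which `n_planted_similar` drugs are near-duplicates (Tanimoto >= 0.95) of
#' distinct compounds, docking tables in which planted hits exceed their
#' co-crystal controls, a two-condition expression matrix with
#' `n_planted_de` differential genes at effect size `de_log2fc` on the log2
#' scale, and a PPI table in which exactly `n_planted_bridges` high-score
#' edges connect predicted targets to differential-gene proteins. In the
#' default (noiseless planted structure) configuration the full pipeline
#' must recover exactly the planted bridge targets.
#'
#' Default sizes (30 compounds, 200 library drugs, 150 proteins, 1000 genes,
#' 5 samples per condition, 10 bridges) are a desk-scale miniature of a
#' formula-wide screen: a few dozen ingredients, a reference library an
#' order of magnitude larger, and a microarray-like two-group comparison
#' with few replicates. Expression noise is Gaussian on the log2 scale
#' (sd `noise_sd`, default 0.5), matching microarray-style variability; the
#' planted effect (default 3 log2 units, random sign) is a strong
#' activation-signature change.
#'
#' @param seed RNG seed (integer).
#' @param n_compounds,n_drugs,n_proteins,n_genes,n_samples_per_group sizes.
#' @param fp_size fingerprint bit-space size.
#' @param fp_nbits set bits per random fingerprint.
#' @param n_planted_similar drugs planted as near-duplicates of compounds.
#' @param n_dock_hits planted docking hits (compound-protein pairs).
#' @param n_planted_de planted differential genes (includes the bridge
#'   partner proteins).
#' @param de_log2fc planted absolute effect size, log2 units.
#' @param noise_sd within-group standard deviation, log2 units.
#' @param n_planted_bridges target-DE PPI bridges to plant.
#' @param ppi_score_high combined score of planted bridges (>= 900).
#' @param ppi_score_low_max maximum combined score of background PPI edges
#'   (< 900).
#' @param n_background_ppi number of random sub-threshold PPI edges.
#' @param n_annotation_terms random annotation terms per the pathway and
#'   disease namespaces (one extra pathway term is planted over the bridge
#'   targets).
#' @return validated list of class `universe_spec`.
#' @export
universe_spec <- function(seed = 42L,
                          n_compounds = 30L, n_drugs = 200L,
                          n_proteins = 150L, n_genes = 1000L,
                          n_samples_per_group = 5L,
                          fp_size = 512L, fp_nbits = 64L,
                          n_planted_similar = 10L, n_dock_hits = 30L,
                          n_planted_de = 50L, de_log2fc = 3,
                          noise_sd = 0.5,
                          n_planted_bridges = 10L,
                          ppi_score_high = 950L, ppi_score_low_max = 850L,
                          n_background_ppi = 300L,
                          n_annotation_terms = 20L) {
  spec <- list(seed = as.integer(seed),
               n_compounds = as.integer(n_compounds),
               n_drugs = as.integer(n_drugs),
               n_proteins = as.integer(n_proteins),
               n_genes = as.integer(n_genes),
               n_samples_per_group = as.integer(n_samples_per_group),
               fp_size = as.integer(fp_size), fp_nbits = as.integer(fp_nbits),
               n_planted_similar = as.integer(n_planted_similar),
               n_dock_hits = as.integer(n_dock_hits),
               n_planted_de = as.integer(n_planted_de),
               de_log2fc = as.numeric(de_log2fc),
               noise_sd = as.numeric(noise_sd),
               n_planted_bridges = as.integer(n_planted_bridges),
               ppi_score_high = as.integer(ppi_score_high),
               ppi_score_low_max = as.integer(ppi_score_low_max),
               n_background_ppi = as.integer(n_background_ppi),
               n_annotation_terms = as.integer(n_annotation_terms))
  sizes <- spec[c("n_compounds", "n_drugs", "n_proteins", "n_genes",
                  "n_samples_per_group", "fp_size", "fp_nbits")]
  if (any(unlist(sizes) <= 0)) stop("universe sizes must be positive",
                                    call. = FALSE)
  if (spec$fp_nbits > spec$fp_size) {
    stop("fp_nbits cannot exceed fp_size", call. = FALSE)
  }
  if (spec$n_planted_similar > min(spec$n_compounds, spec$n_drugs)) {
    stop("n_planted_similar exceeds the compound or drug universe",
         call. = FALSE)
  }
  if (spec$n_planted_de > spec$n_genes) {
    stop("n_planted_de exceeds n_genes", call. = FALSE)
  }
  if (spec$n_planted_bridges > spec$n_planted_de) {
    stop("n_planted_bridges exceeds n_planted_de (each bridge needs a ",
         "differential partner protein)", call. = FALSE)
  }
  # targets are drawn from the first 40% of the protein space, DE partners
  # from the rest; both pools must be large enough
  n_pool <- max(1L, spec$n_proteins %/% 5L * 2L)
  if (spec$n_planted_bridges > spec$n_proteins - n_pool) {
    stop("not enough non-target proteins for ", spec$n_planted_bridges,
         " bridge partners", call. = FALSE)
  }
  if (spec$ppi_score_high < 900 || spec$ppi_score_high > 1000) {
    stop("ppi_score_high must lie in [900, 1000]", call. = FALSE)
  }
  if (spec$ppi_score_low_max >= 900 || spec$ppi_score_low_max < 0) {
    stop("ppi_score_low_max must lie in [0, 900)", call. = FALSE)
  }
  if (spec$n_genes < spec$n_proteins) {
    stop("n_genes must be at least n_proteins (protein-coding genes are a ",
         "prefix of the gene universe)", call. = FALSE)
  }
  structure(spec, class = "universe_spec")
}

random_fp <- function(size, nbits) {
  fingerprint(sample.int(size, nbits) - 1L, size)
}

#' Generate a synthetic universe with planted ground truth
#'
#' Draws every input the pipeline consumes (see [universe_spec()]) under the
#' spec's seed; the same spec always yields the same bundle. With `dir` set,
#' the bundle is also written as TSV/GMT/JSON files in the formats the
#' loaders expect.
#'
#' @param spec a [universe_spec()].
#' @param dir optional output directory.
#' @return list with `data` (in-memory inputs: `compounds`, `library`,
#'   `docking`, `controls`, `expression`, `ppi`, `annotations`), `truth`
#'   (planted ground truth: `planted_similar_pairs`, `planted_de_genes`,
#'   `planted_bridge_targets`, `retained_compounds`, `planted_term`) and,
#'   when `dir` is given, `files` (named paths).
#' @export
generate_universe <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "universe_spec"))
  set.seed(spec$seed)
  proteins <- sprintf("P%03d", seq_len(spec$n_proteins))
  n_pool <- max(1L, spec$n_proteins %/% 5L * 2L)
  target_pool <- proteins[seq_len(n_pool)]
  partner_pool <- proteins[-seq_len(n_pool)]

  ## -- compounds ------------------------------------------------------------
  # lowercase names are fixed points of catalog normalization, so generated
  # names survive build_catalog() unchanged
  comp_names <- sprintf("cmp%03d", seq_len(spec$n_compounds))
  comp_fps <- replicate(spec$n_compounds,
                        random_fp(spec$fp_size, spec$fp_nbits),
                        simplify = FALSE)
  compounds <- data.frame(
    herb = rep("synthetic herb", spec$n_compounds),
    component = comp_names,
    fingerprint = vapply(comp_fps, format, character(1)),
    stringsAsFactors = FALSE
  )

  ## -- reference drug library ----------------------------------------------
  # planted drugs: copy a distinct compound's fingerprint and drop one bit,
  # keeping Tanimoto at (b-1)/b >= 0.95 for b >= 20 set bits
  planted_idx <- seq_len(spec$n_planted_similar)
  drug_ids <- sprintf("DRUG%04d", seq_len(spec$n_drugs))
  drug_fps <- vector("list", spec$n_drugs)
  drug_targets <- vector("list", spec$n_drugs)
  for (i in planted_idx) {
    src <- comp_fps[[i]]
    drop <- sample(seq_along(src$bits), 1)
    drug_fps[[i]] <- fingerprint(src$bits[-drop], src$size)
    drug_targets[[i]] <- sort(sample(target_pool,
                                     sample(1:3, 1)), method = "radix")
  }
  for (i in setdiff(seq_len(spec$n_drugs), planted_idx)) {
    repeat {
      fp <- random_fp(spec$fp_size, spec$fp_nbits)
      sims <- vapply(comp_fps, tanimoto, numeric(1), b = fp)
      if (all(sims < 0.95)) break # guarantee: only planted drugs match
    }
    drug_fps[[i]] <- fp
    drug_targets[[i]] <- sort(sample(proteins, sample(0:2, 1)),
                              method = "radix")
  }
  library_df <- data.frame(
    drug_id = drug_ids,
    fingerprint = vapply(drug_fps, format, character(1)),
    targets = vapply(drug_targets, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  planted_similar_pairs <- data.frame(compound = comp_names[planted_idx],
                                      drug_id = drug_ids[planted_idx],
                                      stringsAsFactors = FALSE)
  sim_edges <- do.call(rbind, lapply(planted_idx, function(i) {
    tg <- drug_targets[[i]]
    if (length(tg) == 0) return(NULL)
    data.frame(compound = comp_names[i], protein = tg,
               stringsAsFactors = FALSE)
  }))
  if (is.null(sim_edges)) {
    sim_edges <- data.frame(compound = character(0), protein = character(0))
  }

  ## -- docking tables -------------------------------------------------------
  dock_proteins <- sample(target_pool, min(length(target_pool), 40L))
  controls <- data.frame(
    protein = dock_proteins,
    control_score = round(stats::runif(length(dock_proteins), 60, 100), 2),
    stringsAsFactors = FALSE
  )
  pairs <- expand.grid(compound = comp_names, protein = dock_proteins,
                       stringsAsFactors = FALSE)
  pairs <- pairs[sample.int(nrow(pairs), min(nrow(pairs), 6L * spec$n_dock_hits)), ]
  hit_rows <- seq_len(min(spec$n_dock_hits, nrow(pairs)))
  ctl <- controls$control_score[match(pairs$protein, controls$protein)]
  delta <- stats::runif(nrow(pairs), 2, 10)
  score <- ctl - delta
  score[hit_rows] <- ctl[hit_rows] + delta[hit_rows]
  docking <- data.frame(compound = pairs$compound, protein = pairs$protein,
                        score = round(score, 2), stringsAsFactors = FALSE)
  row.names(docking) <- NULL
  dock_edges <- docking[seq_len(nrow(docking)) %in% hit_rows,
                        c("compound", "protein")]

  ## -- CTPI ground structure ------------------------------------------------
  ctpi_edges <- unique(rbind(sim_edges, dock_edges))
  ctpi_targets <- sort(unique(ctpi_edges$protein), method = "radix")

  ## -- planted bridges and PPI ----------------------------------------------
  bridge_targets <- sort(sample(ctpi_targets,
                                min(spec$n_planted_bridges,
                                    length(ctpi_targets))),
                         method = "radix")
  partners <- sample(partner_pool, length(bridge_targets))
  ppi <- data.frame(protein_a = bridge_targets, protein_b = partners,
                    combined_score = rep(spec$ppi_score_high,
                                         length(bridge_targets)),
                    stringsAsFactors = FALSE)
  if (spec$n_background_ppi > 0) {
    a <- sample(proteins, spec$n_background_ppi, replace = TRUE)
    b <- sample(proteins, spec$n_background_ppi, replace = TRUE)
    keep <- a != b
    bg <- data.frame(
      protein_a = a[keep], protein_b = b[keep],
      combined_score = as.integer(round(stats::runif(sum(keep), 150,
                                                     spec$ppi_score_low_max))),
      stringsAsFactors = FALSE
    )
    ppi <- rbind(ppi, bg)
  }
  row.names(ppi) <- NULL

  ## -- expression matrix ----------------------------------------------------
  extra_genes <- sprintf("G%04d", seq_len(spec$n_genes - spec$n_proteins))
  genes <- c(proteins, extra_genes)
  n_extra_de <- spec$n_planted_de - length(partners)
  extra_de <- if (n_extra_de > 0) sample(extra_genes, n_extra_de) else character(0)
  planted_de <- c(partners, extra_de)
  nsamp <- spec$n_samples_per_group
  samples <- c(sprintf("QSC%02d", seq_len(nsamp)),
               sprintf("ASC%02d", seq_len(nsamp)))
  cond <- rep(c("quiescent", "activated"), each = nsamp)
  base <- stats::runif(length(genes), 4, 12)
  m <- matrix(stats::rnorm(length(genes) * length(samples), mean = base,
                           sd = spec$noise_sd),
              nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  sign <- sample(c(-1, 1), length(planted_de), replace = TRUE)
  m[planted_de, cond == "activated"] <-
    m[planted_de, cond == "activated"] + sign * spec$de_log2fc
  m <- round(m, 4)
  labels <- stats::setNames(cond, samples)

  ## -- annotations -----------------------------------------------------------
  terms <- list()
  terms[[1]] <- list(term_id = "PW0000", term_name = "planted bridge pathway",
                     namespace = "pathway",
                     members = sort(unique(c(bridge_targets,
                                             sample(proteins, 3))),
                                    method = "radix"))
  idx <- 2L
  for (ns in c("pathway", "disease")) {
    for (j in seq_len(spec$n_annotation_terms)) {
      terms[[idx]] <- list(
        term_id = sprintf("%s%04d", if (ns == "pathway") "PW" else "DIS", j),
        term_name = sprintf("synthetic %s term %d", ns, j),
        namespace = ns,
        members = sort(sample(proteins, sample(8:25, 1)), method = "radix")
      )
      idx <- idx + 1L
    }
  }
  annotations <- data.frame(
    term_id = vapply(terms, `[[`, character(1), "term_id"),
    term_name = vapply(terms, `[[`, character(1), "term_name"),
    namespace = vapply(terms, `[[`, character(1), "namespace"),
    stringsAsFactors = FALSE
  )
  annotations$members <- I(lapply(terms, `[[`, "members"))

  ## -- ground truth ----------------------------------------------------------
  bridge_compounds <- sort(unique(
    ctpi_edges$compound[ctpi_edges$protein %in% bridge_targets]),
    method = "radix")
  truth <- list(planted_similar_pairs = planted_similar_pairs,
                planted_de_genes = sort(planted_de, method = "radix"),
                planted_bridge_targets = bridge_targets,
                retained_compounds = bridge_compounds,
                planted_term = "PW0000")

  data <- list(compounds = compounds, library = library_df,
               docking = docking, controls = controls,
               expression = structure(list(values = m, labels = labels),
                                      class = "fzhy_expr"),
               ppi = ppi, annotations = annotations)
  out <- list(spec = spec, data = data, truth = truth)
  if (!is.null(dir)) out$files <- write_universe(out, dir)
  out
}

#' Pipeline configuration for a written synthetic universe
#'
#' @param files named file vector as returned in `generate_universe()$files`.
#' @param out_dir pipeline output directory.
#' @param ... further arguments to [pipeline_config()] (thresholds etc.).
#' @return a `pipeline_config`.
#' @export
universe_config <- function(files, out_dir = tempfile("fzhynet_run"), ...) {
  pipeline_config(components = files[["compounds"]],
                  library = files[["library"]],
                  docking = files[["docking"]],
                  controls = files[["controls"]],
                  expression_matrix = files[["expression"]],
                  labels = files[["labels"]],
                  ppi = files[["ppi"]],
                  annotations = files[["annotations"]],
                  out_dir = out_dir, ...)
}

write_universe <- function(universe, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  wt <- function(df, f) {
    utils::write.table(df, p(f), sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    p(f)
  }
  d <- universe$data
  files <- c(
    compounds = wt(d$compounds, "compounds.tsv"),
    library = wt(d$library, "reference_library.tsv"),
    docking = wt(d$docking, "docking_scores.tsv"),
    controls = wt(d$controls, "docking_controls.tsv"),
    expression = wt(data.frame(gene = rownames(d$expression$values),
                               d$expression$values, check.names = FALSE,
                               stringsAsFactors = FALSE),
                    "expression.tsv"),
    labels = wt(data.frame(sample = names(d$expression$labels),
                           condition = unname(d$expression$labels),
                           stringsAsFactors = FALSE), "labels.tsv"),
    ppi = wt(data.frame(protein1 = d$ppi$protein_a,
                        protein2 = d$ppi$protein_b,
                        combined_score = d$ppi$combined_score,
                        stringsAsFactors = FALSE), "ppi.tsv"),
    annotations = {
      write_gmt(d$annotations, p("annotations.gmt"))
      p("annotations.gmt")
    },
    ground_truth = {
      jsonlite::write_json(universe$truth, p("ground_truth.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      p("ground_truth.json")
    },
    spec = {
      jsonlite::write_json(unclass(universe$spec), p("spec.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      p("spec.json")
    }
  )
  files
}
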