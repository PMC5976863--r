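#!/usr/bin/env Rscript
# Run the full prioritization pipeline on the demo universe and compare the
# prioritized targets with the planted ground truth.

suppressPackageStartupMessages(library(fzhynet))

if (!file.exists("results/universe_seed42/ground_truth.json")) {
  u <- generate_universe(universe_spec(seed = 42),
                         dir = "results/universe_seed42")
} else {
  u <- generate_universe(universe_spec(seed = 42)) # deterministic regeneration
}

files <- c(compounds = "compounds.tsv", library = "reference_library.tsv",
           docking = "docking_scores.tsv", controls = "docking_controls.tsv",
           expression = "expression.tsv", labels = "labels.tsv",
           ppi = "ppi.tsv", annotations = "annotations.gmt")
files <- vapply(files, function(f) file.path("results/universe_seed42", f),
                character(1))

rep <- run_pipeline(universe_config(files, out_dir = "results/pipeline_seed42"))

cat("CTPI: ", rep$ctpi$n_compounds, " compounds, ", rep$ctpi$n_targets,
    " targets, ", rep$ctpi$n_edges, " edges\n", sep = "")
cat("DE:   ", rep$de$n_significant, " significant of ", rep$de$n_tested,
    " tested genes\n", sep = "")
cat("CTPG: ", rep$ctpg$n_nodes, " nodes (", rep$ctpg$n_compounds, "+",
    rep$ctpg$n_targets, "+", rep$ctpg$n_de, "), ", rep$ctpg$n_edges,
    " edges\n\n", sep = "")

got <- rep$prioritized_targets
truth <- u$truth$planted_bridge_targets
cat("prioritized targets: ", paste(got, collapse = ", "), "\n")
cat("planted bridges:     ", paste(truth, collapse = ", "), "\n")
cat("precision:", length(intersect(got, truth)) / max(1, length(got)),
    " recall:", length(intersect(got, truth)) / length(truth), "\n")
cat("retained compounds: ", length(rep$retained_compounds), "of",
    rep$catalog$n_compounds, "\n")
if (!is.null(rep$enrichment)) {
  cat("top enriched term:  ", rep$enrichment$top_terms[1],
      "(planted:", u$truth$planted_term, ")\n")
}
cat("\nfull outputs under results/pipeline_seed42/\n")
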