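#!/usr/bin/env Rscript
# Generate the demo synthetic universe (seed 42) with planted ground truth.
#
# The bundle contains every input the pipeline consumes: compounds with
# binary fingerprints, a 200-drug reference library with 10 planted
# near-duplicate drugs, docking score/control tables with 30 planted hits,
# a 1000-gene quiescent-vs-activated expression matrix with 50 planted
# differential genes, a PPI table with 10 planted high-confidence
# target-DE bridges, and pathway/disease annotation sets.

suppressPackageStartupMessages(library(fzhynet))

spec <- universe_spec(seed = 42)
u <- generate_universe(spec, dir = "results/universe_seed42")

cat("wrote", length(u$files), "files under results/universe_seed42/\n\n")
cat("planted ground truth:\n")
cat("  similar drug pairs:   ", nrow(u$truth$planted_similar_pairs), "\n")
cat("  differential genes:   ", length(u$truth$planted_de_genes), "\n")
cat("  bridge targets:       ",
    paste(u$truth$planted_bridge_targets, collapse = ", "), "\n")
cat("  retained compounds:   ",
    paste(u$truth$retained_compounds, collapse = ", "), "\n")
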