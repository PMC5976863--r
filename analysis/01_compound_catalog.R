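#!/usr/bin/env Rscript
# Catalog the active components of the six-herb FZHY formula.
#
# Reads the packaged herb-component table (46 printed rows), deduplicates
# across herbs, applies the one documented synonym merge (danshensu ==
# tanshinol), and reports the compounds shared by several herbs.

suppressPackageStartupMessages(library(fzhynet))
dir.create("results", showWarnings = FALSE)

fx <- table1_fixture()
comp <- load_component_table(fx[["components"]])
syn <- load_synonym_map(fx[["synonyms"]])

raw <- build_catalog(comp)
catalog <- build_catalog(comp, syn)

cat("herb-component rows:          ", nrow(comp), "\n")
cat("unique names (no synonyms):   ", nrow(raw), "\n")
cat("catalog after synonym merge:  ", nrow(catalog), "\n\n")

sh <- shared_components(catalog)
cat("components present in several herbs:\n")
for (i in seq_len(nrow(sh))) {
  cat("  ", sh$canonical_name[i], " (", sh$n_herbs[i], " herbs: ",
      paste(sh$herbs[[i]], collapse = ", "), ")\n", sep = "")
}

write_catalog(catalog, "results/catalog.tsv")
write_catalog(raw, "results/catalog_unmerged.tsv")
cat("\nwrote results/catalog.tsv and results/catalog_unmerged.tsv\n")
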