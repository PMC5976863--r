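---
title: "Tripartite target prioritization for a multi-herb formula"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tripartite target prioritization for a multi-herb formula}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fzhynet)
```

## The method

Network-pharmacology screens of multi-compound preparations produce large
candidate target sets with no internal ranking. `fzhynet` narrows such a
set by demanding *transcriptomic anchorage*: a candidate target is kept
only if, in an integrated network, it connects at least one compound of
the formula to at least one protein whose gene is differentially expressed
in the disease-relevant comparison (here, quiescent versus activated
hepatic stellate cells).

The pipeline composes five stages:

1. **Catalog.** Herb–component rows are normalized (whitespace collapsed,
   case-folded) and deduplicated. True synonyms — different names for one
   chemical entity — are merged only through an explicit alias → canonical
   map, never by string distance: a fuzzy merge would be untestable and
   silently wrong for congeners like ginsenoside-Rb1/Rb2. The packaged
   map carries a single non-trivial entry (danshensu ≡ tanshinol), the one
   merge consistent with treating the printed 46-row table as 40
   compounds; both the merged (40) and unmerged (41) counts are exposed
   because the discrepancy in the upstream counts cannot be resolved from
   the printed table alone.
2. **Target mapping.** The similarity branch compares binary fingerprints
   with the Tanimoto coefficient and transfers the target annotations of
   every reference drug at similarity ≥ cutoff. The docking branch keeps a
   (compound, protein) pair when its externally computed docking score
   strictly exceeds the protein's co-crystallized-ligand score — the
   positive control defines a per-protein cutoff. Branch results merge
   with provenance (`similarity` / `docking` / `both`), and the bipartite
   compound–target (CTPI) graph keeps exactly the nodes incident to an
   edge.
3. **Differential expression.** Per-gene two-sample t tests on log2
   values, BH adjustment across tested genes, significance iff
   `q < alpha` and `|log2FC| >= min_abs_log2fc`.
4. **CTPG integration and prioritization.** PPI edges at combined score ≥
   threshold whose endpoints both lie in the target-or-DE protein set are
   added to the CTPI; the prioritization rule then reads off the targets
   adjacent to both a compound and a DE protein. DE–DE edges are retained
   in the graph (they describe the transcriptional module) but cannot
   affect prioritization, which inspects only target adjacency.
5. **Enrichment.** Exact hypergeometric upper-tail tests of the
   prioritized set against flat annotation collections, BH within each
   namespace separately — mixing pathway, GO and disease terms in one
   correction would let the largest collection dominate the FDR budget.

The only modelling assumptions are (i) gene-to-protein identity on
symbols, (ii) log2-scale, roughly Gaussian within-group expression, and
(iii) that an undirected high-confidence PPI edge is meaningful evidence
of functional linkage regardless of direction.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `similarity_cutoff` | 0.95 | Tanimoto, inclusive | near-duplicate screen; transfers targets only between almost identical structures |
| docking rule | score > control | dimensionless scores | the co-crystal ligand is the per-protein positive control; ties do not beat a control |
| `ppi_min_score` | 900 | STRING combined score (0–1000), inclusive | 0.9 is STRING's "highest confidence" band; inclusive because the service's own UI treats the slider value inclusively |
| `de_alpha` | 0.05 | probability on BH q | conventional FDR level |
| `de_min_abs_log2fc` | 1.0 | log2 units | two-fold floor guards against statistically significant but biologically trivial shifts |
| `enrich_alpha` | 0.05 | raw p by default | matches the common service-style report; `use_fdr = TRUE` flags on q instead |

Every threshold is configurable in `pipeline_config()`; the run log echoes
each one, so a run is auditable.

## Numerical and edge-case choices

* `tanimoto(∅, ∅) = 1` by convention (featureless compounds are
  indistinguishable); empty-versus-nonempty is 0. Mismatched bit-space
  sizes are a hard error, not silent truncation.
* Genes with zero variance in both groups are excluded from testing and
  reported `tested = FALSE` rather than given p = NA silently inside the
  BH pool, which would distort the adjustment denominator.
* **Welch versus pooled t.** The default DE statistic is the Welch test:
  it does not assume equal variances, which real quiescent/activated
  comparisons rarely satisfy. Its cost at very small group sizes is real,
  however: with 5 samples per group its random Satterthwaite degrees of
  freedom make it conservative — our null-calibration driver measures a
  raw per-gene rejection rate of about 0.044 at nominal 0.05, and an
  occasional strongly shifted gene can still draw a modest p when one
  group's variance estimate blows up. `var_equal = TRUE` selects the
  pooled test, which is exact under an equal-variance Gaussian null and is
  what the calibration suite holds to the nominal level; the threshold
  triple (test, alpha, fold-change floor) is fully configurable so users
  can match other DE pipelines.
* A protein that is both a predicted target and a differential gene keeps
  the role `target`. By default its own DE status is **not** evidence for
  itself — a bridge requires a distinct DE neighbor — because
  self-evidence would let a single noisy DE call promote its own target
  with no network support; `self_de_counts = TRUE` flips this, counting
  the protein as one additional DE neighbor of itself.
* All orderings are deterministic: catalogs sort by canonical name
  (byte-order radix sort, locale-independent), prioritized targets by DE
  neighbor count descending with name tie-break, enrichment by namespace
  then p. Undirected PPI duplicates collapse to the maximum score.
* CTPI edges are deduplicated per (compound, target) pair; whether the
  upstream screen counted multiplicities is unknowable from the published
  totals, and a simple graph is the only defensible reading.
* The enrichment background defaults to the union of all annotation
  members, the only universe recoverable from the annotation files
  themselves; an explicit background may be supplied and is validated to
  contain both the query and every term member.

## What the synthetic universe emulates — and what it does not

`generate_universe()` draws, under one seed: compound fingerprints as
random bit-sets; planted similar drugs that copy a compound's fingerprint
minus one bit (Tanimoto ≥ 0.95 by construction, with resampling to keep
all background drugs below the cutoff); docking tables whose planted hits
sit above and misses below their controls by ≥ 2 score units; an
expression matrix with Gaussian log2 noise (sd 0.5) and 50 planted
differential genes at |log2FC| = 3 with random sign, including the bridge
partner proteins; a PPI table whose 10 planted target–DE bridges score 950
and whose background edges stay below 850; and pathway/disease annotation
sets with one term planted over the bridge targets. The default sizes (30
compounds, 200 drugs, 150 proteins, 1000 genes, 5+5 samples) are a
desk-scale miniature of a formula-wide screen chosen to exercise every
code path in seconds.

Because bridges are the only high-confidence PPI edges and the planted
effect is strong, the noiseless configuration makes exact recovery the
correct answer, so end-to-end precision and recall have a known target of
1.0. Real data differ in every inconvenient way: fingerprints are
correlated by chemistry rather than independent bits; docking scores are
noisy around their controls; microarray noise is heteroskedastic and
correlated across genes; PPI networks are scale-free with hubs, so
high-confidence edges are not confined to true bridges; and annotation
terms overlap heavily. Passing the recovery benchmark therefore shows the
machinery is wired correctly and the rule does what it claims — not that
the prioritization would be this clean on a real compendium.

## Sizes used by the test and benchmark suites

The test suite runs the recovery benchmark at the default universe (seeds
1–20) and the null calibration at 200 replicates × 1000 genes × 5+5
samples; the oracle checks enumerate hypergeometric tails up to N = 30,
compare BH against the brute-force step-up on 1000 random vectors, and
verify prioritization against an exhaustive path check on random graphs of
at most 12 nodes. These sizes give Monte-Carlo standard errors small
enough to be decisive (≈ 5 × 10⁻⁴ on the calibration rate) while keeping
the default suite fast.

## Known limitations

* Identifier spaces are opaque strings; no ID-mapping service is called,
  so inputs must already share a symbol convention.
* The DE stage is a per-gene t test; it does not borrow strength across
  genes (no moderated variance), which matters at n ≤ 3 per group.
* Annotation terms are flat sets; GO graph structure is not used.
* Docking is consumed, never computed: the package filters externally
  produced score tables only.
* The prioritization rule is binary adjacency; it does not weight by edge
  confidence, degree, or number of bridges beyond the reported DE
  neighbor count.
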