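---
title: "Methods: calling direct TF targets from DamID binding and knockdown RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling direct TF targets from DamID binding and knockdown RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

damtargets implements the integrative analysis used to establish a
transcription factor as a master regulator of a cell type's identity
program — here modelled on Prospero (Pros) in *Drosophila* midgut
enteroendocrine (EE) cells. A direct target is a gene that is both bound by
the TF (DamID evidence) and transcriptionally altered when the TF is
depleted (RNA-seq evidence). This vignette explains each stage's model and
assumptions, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the design
was genuinely open.

## Cell-type signatures from RPKM profiles

Bulk transcriptomes of three cell types (EE, progenitor, EC), averaged over
replicates on the RPKM scale, are scored per focal type:

- genes with focal RPKM < 3.5 are removed (the floor is applied before the
  log, so the log argument is always ≥ 3.5);
- fold change = focal RPKM / mean RPKM over all three types;
- score = log10(focal RPKM)/5 + fold change;
- the top 250 by score are that type's signature genes.

The "RPKM" inside the log is read as the focal type's value — the same
number used in the fold change's numerator; the formula is computed "for
each cell type" and only the focal value is type-specific. RPKM per type is
the arithmetic mean over that type's replicates. Ties at the top-250
boundary are broken by gene id, lexicographically, so output is
deterministic. A gene may be a signature candidate for one type while below
the floor in another; the filter uses only the focal type's RPKM.

The score adds an absolute-abundance term (log10/5 — worth 0.2 per decade of
expression) to a comparative-enrichment term (the fold change, worth 1 per
unit); in practice the fold change dominates the ranking and the log term
breaks near-ties in favour of well-expressed genes.

## The negative-binomial differential-count engine

One engine serves both RNA-seq differential expression and DamID fragment
enrichment. It is a deliberately transparent, testable version of the
standard NB machinery, with no GLM iterations, no outlier replacement, no
independent filtering and no fold-change shrinkage:

- **Normalization** — median-of-ratios: the reference is the per-feature
  geometric mean over samples (features with any zero excluded); a sample's
  size factor is the median ratio to that reference. Note the reference
  absorbs `c^(1/n)` of a single-sample scaling, so factors are equivariant
  relative to each other, not absolutely.
- **Dispersion** — per-feature method of moments on normalized counts,
  `alpha = max(0, (s² − µ)/µ²)`, with the variance pooled within groups
  (df-weighted) so real condition effects do not inflate it. Raw estimates
  at 2–3 replicates are extremely noisy, so each is moderated 50/50 toward
  the **plain mean** raw dispersion of the 200 features nearest in mean
  expression. The mean (rather than a median or trimmed mean) is used
  because the method-of-moments estimator is approximately unbiased in
  expectation while robust location estimates sit below the mean of its
  right-skewed distribution; with a low target the engine under-shrinks and
  the null p-value distribution becomes anticonservative. On null
  simulations the local-mean target puts the p < 0.05 rate at ≈ 0.065
  against a nominal 0.05, versus ≈ 0.078 with a median target.
- **Test** — log2 fold change from group means of normalized counts with a
  pseudocount of 0.5 (bounded estimates when one side is all zero), a
  delta-method standard error under the NB variance `µ + αµ²` (accounting
  for per-sample size factors), a two-sided normal Wald p-value, and
  Benjamini–Hochberg adjustment. Features with zero counts in both groups
  get undefined p-values and are excluded from the BH family size.
- **Calls** — strict inequalities at both thresholds: padj < 0.01 **and**
  |log2FC| > 0.5 for expression; a feature exactly on either boundary is not
  called.

The normal reference for the Wald statistic at n = 3 per group is an
approximation; the moderation above is what keeps it honest, and the null
calibration is part of the test suite rather than assumed.

## Permutation GSEA

The enrichment statistic is the weighted Kolmogorov–Smirnov running sum:
walking down the ranked gene list, hits add `|metric|^p / N_R` (p = 1 by
default) and misses subtract `1/(n − n_hits)`; the enrichment score (ES) is
the extremum of largest absolute deviation, and the leading edge is the
hits at or before it (at or after, for negative ES). The default ranking
metric is the Wald statistic; log2FC and signed −log10 p are available.
Ties in the metric are broken by gene id.

NES divides the ES by the mean |ES| of same-sign permutations; the nominal
p-value is `(1 + n_extreme)/(1 + n_same_sign)` over direction-consistent
permutations, so p can never be zero and is floored by the permutation
count. FDR across multiple sets uses the standard pooled-NES procedure.
Sets with no same-sign permutation ES get an undefined NES, reported as NA.

With 3-vs-3 samples only `choose(6,3) = 20` distinct label assignments
exist, so a phenotype-permutation p-value cannot go below 1/20. `mode =
"auto"` therefore switches to gene-set permutation whenever fewer than 100
distinct relabelings exist, and records the switch in the result. Phenotype
mode remains available on request: it enumerates the relabelings
exhaustively (excluding the observed one) and recomputes the ranking for
each, holding dispersions at their observed estimates — re-estimating them
per relabeling would let the null absorb the treatment effect and costs
nothing in calibration at these sizes.

## DamID at GATC-fragment resolution

DpnII cuts at GATC, so the native resolution unit is the fragment between
consecutive GATC sites. The fragment map places a boundary at every
occurrence start (the site is its own reverse complement; one strand
suffices) and closes terminal fragments at the chromosome ends; fragments
tile the genome exactly. All coordinates are 0-based half-open internally
and in BED outputs; GFF3 is converted from 1-based inclusive on ingest.

Aligned intervals are credited to the fragment containing their 5′ start:
DamID fragments begin at GATC cuts, so the 5′ end carries the signal, and a
read straddling a boundary still counts once. Replicate QC is the Pearson
correlation of `log2(normalized count + 1)` across fragments.

Enrichment testing runs the count engine with the Dam-fusion condition as
treatment and Dam-only as control, then applies the one-sided filter
log2FC > 1 and padj < 0.01 (strict). Depleted fragments are reported
separately and never enter peaks. Significant fragments are merged into
peaks as maximal runs, tolerating `max_gap_fragments` non-significant
fragments between members (0 by default — whether published "peaks" are
single fragments or merged runs is ambiguous, so the rule is a parameter
recorded in output metadata). A peak's log2FC is the base-mean-weighted
average over members; genes are assigned when the peak overlaps the gene
body extended 2 kb upstream of the TSS, strand-aware. The 2 kb default
matches the scale of the enhancer examples the analysis is built around;
it, too, is a parameter.

## Target integration

Targets = genes assigned to at least one significant peak ∩ genes called
differentially expressed upon depletion. The intersection is at gene level
(a gene is bound if any peak is assigned to it), "down" marks candidate
activated targets and "up" candidate repressed ones, and the DE universe
recorded alongside the counts is the set of genes with a defined adjusted
p. The signature-overlap report counts how many signature genes are
targets, the fraction of that intersection that is down-regulated, and a
gene-set-permutation GSEA of the intersection against the ranked depletion
list.

## Consensus motif scanning

The 7-position consensus `T-[A/T]-A-G-[A/C/G]-C-[G/A/T]` (IUPAC TWAGVCD) is
parsed into per-position allowed-base sets. Every window on both strands
with at most `max_mismatch` violations is reported, with the violated
positions listed; `N` matches nothing (conservative), case is ignored,
overlapping hits are all kept, and minus-strand hits are reported in
plus-strand coordinates with the matched sequence in motif orientation.
The default is exact matching; the published example of a motif
(`TAAGCTG`) that violates the printed consensus at position 6 shows that
looser matching was tolerated somewhere upstream, so the mismatch budget is
an explicit parameter rather than a guess at intent.

TSS-relative coordinates follow the signed, 1-based, no-zero convention:
+1 is the TSS base, −1 the first base upstream, positive runs downstream
along the gene's orientation. Enhancer extraction takes a signed window,
returns the sequence in gene orientation (reverse-complemented for
minus-strand genes), and reports the absolute interval used.

## The synthetic-data generator

The generator exists so every caller can be scored against known truth
without downloads. It emulates the study's design dimensions:

- three cell types × 3 replicates, 5,000 genes, 200 planted markers per
  type at 8-fold enrichment in their own type;
- a 3-vs-3 control/knockdown experiment in the focal (EE-like) type where
  80% of the focal markers are depleted 4-fold (true log2FC −2) and 5% of
  non-marker genes rise 4-fold — the paper's design has a mostly-down
  signature with a minority of up-regulated exceptions; no rate is given
  for the exceptions, so a small minority was chosen once;
- a 1 Mb single-chromosome genome of i.i.d. random bases (GATC every
  ~256 bp, giving ≈ 4,000 fragments), 20 annotated genes with alternating
  strands, and exact consensus 7-mers planted at the reported
  TSS-relative offsets (−1595, −1471, +1734) on both strands;
- a 2-fusion-vs-3-control DamID design with 100 bound fragments at 8-fold
  enrichment, placed preferentially near annotated TSSs with at least one
  per gene, over a shared log-normal accessibility baseline.

Baseline expression is log-normal (meanlog 4, sdlog 1.5) on an RPKM-like
scale — no distribution is published; this one straddles the 3.5-RPKM
filter so the floor is exercised — converted to expected counts via
log-uniform gene lengths (500–10,000 bp) and a 5-million-read library with
10% log-normal depth jitter. Counts are negative-binomial with variance
`µ + αµ²`, α = 0.05 (typical bulk replicates; the study reports neither
library sizes nor dispersions, so these are conventional, not fitted).
Motif-planted windows (±2.5 kb of the TSS) are cleared of accidental exact
consensus hits by rejection sampling and re-verified after planting, so
planted hits are provably the only exact hits there. The joint simulation
renames the toy genome's genes to well-expressed genes of the expression
simulation (baseline ≥ 20 on the RPKM-like scale; half planted-down, a
tenth planted-up, the rest unaffected) so binding and expression evidence
intersect in one namespace and the expected target set is known exactly.

Everything is seeded: the same configuration and seed give byte-identical
outputs (each generator derives its stream from the seed at a fixed
offset). What the generator does **not** emulate: read-level sequencing
error, alignment artefacts, batch effects, GC or mappability bias,
correlated gene programs, and real genome composition (the toy genome is
i.i.d. uniform). Passing tests therefore demonstrate that the estimators
and callers are correct and calibrated under the stated stochastic model —
not that they are robust to every artefact of real libraries.

## Problem sizes and numerical notes

The test suite and the acceptance script run the generators at the study
design's scale (5,000 genes; ~4,000 fragments) for the headline recovery
checks and at smaller scales (a few hundred genes, 0.2–0.4 Mb toys) for
structural checks; permutation counts are 1,000 where a p ≤ 0.01 claim is
made and 50–300 where only direction or determinism is asserted. These
sizes were chosen so the whole suite re-runs in well under two minutes of
compute per module.

Other numerical choices: the running-sum extremum takes the first position
of maximal |deviation| (two opposite-sign extremes tied to float precision
are an unstable edge, and only the magnitude is meaningful there); BH is
computed on defined p-values only; table output rounds to 6 significant
digits by default (configurable to full precision); and every pipeline
stage writes a manifest with its parameter snapshot and input hashes so a
changed threshold is attributable to exactly one field.

## Known limitations

The Wald test relies on a normal approximation that is honest only because
dispersions are moderated; it will be anticonservative for very low counts
with unmoderated dispersion. The engine supports exactly two groups and no
covariates. Phenotype permutation at 3-vs-3 resolution cannot certify
p < 0.05 and exists for fidelity, not power. Peak merging and gene
assignment are parameterized conventions, not inferences; published peak
and target counts depend on raw accession data and unpublished tool
internals, and are not reproduced here — the acceptance checks are
property-based (recovery, calibration, exactness, determinism) instead.
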