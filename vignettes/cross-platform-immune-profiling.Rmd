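---
title: "Methods: cross-platform immune expression concordance"
author: "immunoConcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-platform immune expression concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

`immunoConcord` compares two bulk measurements of the same tumors: a
targeted hybridization panel (endogenous immune genes plus housekeeping,
negative-control and positive-control probes; no amplification) and
gene-level RNA-seq counts produced upstream by alignment and
quantification. The package starts from count matrices; read processing,
mixture deconvolution by support-vector regression, and clinical
interpretation are out of scope.

The analysis makes three modelling commitments, stated here because every
downstream number depends on them.

1. **Detection is a background-exceedance call on raw counts.** Negative
   control probes measure non-specific hybridization; the per-sample
   threshold `mean + 2 * SD` (sample SD, n − 1 denominator, matching the
   vendor convention) is computed from raw counts before any
   normalization, and a count must *strictly* exceed it. Equality is
   undetected — "below the limit" is read conservatively. On the
   sequencing side, where no spike-in background exists, detection is raw
   count ≥ 1. For positive normalization factors this is equivalent to
   geTMM > 0, but the rule is defined on raw counts so detection tallies
   cannot move when normalization parameters do. Detection tallies are
   sensitive to this rule; it is deliberately prominent.

2. **Normalization is relative, not absolute.** The panel is scaled per
   sample by stable housekeeping genes (geNorm selection, geometric-mean
   factors); RNA-seq by geTMM — TMM factors estimated on reads-per-kilobase
   so that gene length cancels within and between samples. Both yield
   relative expression: cross-platform comparisons are therefore made on
   `log2(x + offset)` scales and through correlations, never as absolute
   copy numbers.

3. **Cell scoring is marker-gene averaging.** The abundance of an immune
   cell type is the mean transformed expression of co-expressed marker
   genes. It is a *relative* score across samples; it cannot say what
   fraction of cells a type occupies.

## Parameters that matter

| parameter | default | units / scale | rationale |
|---|---|---|---|
| detection SD multiplier | 2 | SDs of negative controls | vendor convention; fixed, not tunable |
| geNorm V cutoff | 0.15 | SD of log2 factor ratio | the value published with the geNorm method |
| TMM trims | 0.30 / 0.05 | fraction of M / A values | the original TMM publication's defaults |
| bin boundaries, panel | 50, 200 | normalized counts | conventional low/intermediate/high split for panel data |
| bin boundaries, seq | 1, 3 | geTMM (per-million) | the analogous split on the per-million scale |
| similarity threshold | 0.6 | correlation | strict `> 0.6`, per the marker-selection rule the package implements |
| detection prevalence | 0.5 | fraction of samples | "at least half", with `ceiling` at odd n |
| log offset | 1 | counts | keeps zeros finite; offset 0 available where exact scale-invariance is wanted |

All are exposed through the YAML run configuration (`defaultRunConfig()`),
and every stage records what it used.

## The synthetic cohort generator

The generator (`simulateCohort()`) emulates a small paired cohort: 6
samples measured on a 730 + 40 gene panel (8 negative, 6 positive probes)
and by RNA-seq. Its defaults are the study conditions of the package's
acceptance checks, chosen once:

* **Baseline expression** per gene from a low/intermediate/high mixture
  (log2 means 3.5 / 6.6 / 9.0, weights 0.37 / 0.17 / 0.46), so both the
  detection limit and the expression bins are populated.
* **Shared biological variation**: non-marker endogenous genes get a per
  sample log2 effect of SD 0.8 seen identically by both platforms. This is
  the signal that platform noise attenuates; without it, cross-platform
  per-gene correlation would be identically zero and the bin-wise
  concordance gradient would have no mechanism at all.
* **Infiltration**: per-sample cell-type fractions from a symmetric
  Dirichlet (concentration 1 over 11 cell types). Marker genes of a cell
  type receive `markerEffect × (fraction − mean fraction)` log2 units.
  The default `markerEffect = 20` makes within-type marker correlation
  near unity at typical infiltration spreads — the regime curated marker
  panels are built for; markers' biological variance *is* the
  infiltration signal, so they carry no independent biological term.
* **Decoy candidates** (2 per cell type, against 3 planted markers each;
  55 candidates in all) represent markers of non-infiltrating
  populations. Their baseline is drawn low (log2 mean 1.5, SD 1.5):
  in an immune-cold tissue such transcripts sit at or below the
  hybridization background. Note the threshold arithmetic: with Poisson
  background of mean 10 added to every probe, a gene needs a *signal* of
  roughly two background SDs (~6 counts) to clear `mean + 2 SD`; "at
  background" must be measured against the background SD, not its mean.
  Decoys that do pass detection face the small-sample reality that a null
  correlation at n = 6 exceeds 0.6 with probability
  `pt(1.5, df = 4, lower = FALSE) ≈ 0.104` per pair — an irreducible
  false-positive floor of the strict-threshold selection rule that the
  acceptance suite documents explicitly.
* **Housekeeping genes**: high baseline (log2 mean 9); a planted subset of
  24 has zero biological variance, the other 16 get per-sample effects of
  SD 0.8 — a failed housekeeping gene varies like an ordinary gene, which
  is exactly why it fails. With 6 samples a planted-unstable gene whose
  realized effects happen to be nearly constant is *correctly* ranked
  stable by geNorm; the recovery rate of the planted labels is therefore
  below 1 by construction, not by defect.
* **Observation model**: panel counts are negative binomial around
  `2^trueLog2` with expression-dependent size
  `dispersionPanel × mu / (mu + noiseKnee)` (default 50 and 50 counts —
  low-expression genes are noisier beyond the Poisson effect), plus
  Poisson background (mean 10); negative controls are pure background;
  positive controls follow a fixed geometric ladder (ratio 4 from 4096).
  Setting a platform's dispersion to 0 switches it to an exact noise-free
  mode (`counts = round(2^trueLog2)`), used by tests that need the
  observation to equal the truth. RNA-seq counts are negative binomial
  (size 30) with mean proportional to gene length × depth × expression,
  plus extra dropout (probability 0.3) for low-component genes, and a
  15,000-gene transcriptome background present only on the sequencing
  side so that library composition and per-million values behave like
  whole-transcriptome data.

**What the generator does not emulate**: FFPE degradation chemistry
(fragment-length effects beyond a dropout knob), batch and lane effects,
probe cross-hybridization, amplification bias along transcripts, and any
attempt to fit the marginal distributions of a real deposited cohort.
Passing tests therefore demonstrate that the pipeline recovers planted
structure under a plausible noise model — not that any particular clinical
dataset will show the same tallies.

## Numerical choices and degenerate inputs

* geNorm requires strictly positive values; candidates with a zero in any
  sample are pre-filtered (log-ratios are undefined at zero), and the
  implementation refuses rather than imputes. Ties in the stability
  ranking break alphabetically; the final two genes share the last rank.
* The geNorm selection takes the smallest n with `V(n/n+1) < 0.15`; if no
  n qualifies, all candidates are used and the fallback is flagged in the
  result and the report.
* Housekeeping normalization errors out if a selected gene has a zero
  count; positive-control normalization is available (`posctrl = TRUE`,
  applied first) but off by default, since only housekeeping scaling is
  part of the core scheme.
* TMM reference selection: the sample whose library-scaled upper quartile
  is closest to the mean; ties break by sample order. The factor
  computation is delegated to edgeR and cross-checked in the test suite
  against an independent implementation of the published trim-and-weight
  formula (tolerance 1e-6). Doubling all counts of a sample changes
  factors only through the precision weights (which see absolute counts),
  so scale-invariance of geTMM holds to ~1e-3 relative, and the tests
  assert exactly that.
* Bins: medians at a boundary go downward (`≤ 50` low, `≤ 200`
  intermediate), because the conventional interval labels overlap at the
  boundaries; the high bin is unambiguous.
* The per-sample linear model regresses sequencing on panel expression by
  default; r and R² are direction-invariant, residual signs are not, and
  the output records the direction.
* The bin comparison uses a Mann–Whitney test with an exact
  enumeration-based p-value for small bins. The exact path enumerates
  group assignments of pooled *midranks*, which stays valid under ties —
  `wilcox.test` abandons exactness there; for large samples the normal
  approximation with tie correction is used, and the suite checks
  agreement with `wilcox.test` on both paths.
* Gene matching compares symbols case-insensitively and reports them in
  upper case; two probes resolving to one symbol keep the higher mean raw
  count (deterministic, mirrors panel practice). A gene missing from one
  platform is kept in the matched set only if present on both; detection
  masks, not matching, decide whether it contributes to any statistic.
* The detection cross-tabulation needs six categories to partition genes:
  both-in-all, discordant, only-A-in-all, only-B-in-all, never-detected,
  and *concordantly partial* — detected by both platforms wherever
  detected, but not in every sample. The last class is forced by
  arithmetic: a gene can agree sample-by-sample without being detected
  everywhere, and conservation (categories summing to the matched total)
  fails without it.

## Problem sizes in the checks

The unit suites run on purpose-built micro-fixtures and a reduced cohort
(120 endogenous genes, 600 background genes) so the whole suite stays
fast; the acceptance suite runs the full default generator (730 + 40
genes, 15,000 background genes, 6 samples) for 100 seeded cohorts per
property, and the acceptance script reports recovery rates over 50
cohorts. These sizes are the package's chosen trade-off between
statistical resolution of the rates being estimated and keeping a full
verification run in the minutes range on one core.

## Known limitations

* With 6 samples, rank correlations take only a handful of values and a
  strict `r > 0.6` co-expression rule has a ~10% per-pair null
  false-positive rate; marker selection on cohorts this small should be
  read as descriptive, not inferential. The acceptance suite contains a
  deliberate red-line check quantifying this floor.
* The geNorm pairwise-variation rule with the 0.15 cutoff typically
  selects very small housekeeping sets on clean synthetic data (often the
  minimum of two); real degraded-tissue data select more because no pair
  is that stable.
* Cross-platform matching trusts HGNC symbols plus a user-supplied alias
  table; probes whose target cannot be expressed as a current symbol are
  dropped and logged rather than guessed.
* The fixed-signature scorer averages whatever signature genes are
  present; it does not re-derive or validate the signatures themselves.
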