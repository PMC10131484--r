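---
title: "Scoring and interpreting a glucokinase variant activity map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and interpreting a glucokinase variant activity map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gckmap)
```

`gckmap` turns variant counts from a growth-selection deep mutational scan
of human glucokinase into rescaled activity scores with regularized errors,
classification thresholds, and a conformational-mechanism readout. This
vignette explains the models behind each stage, the tunable parameters, and
the choices made where the design was genuinely open.

## The measurement model

A codon-randomized *GCK* library (three separately mutagenized regions
covering residues 2–171, 172–337 and 338–465, the initiator methionine
immutable) is selected for glucokinase activity in yeast on low glucose.
Each region is sequenced in short tiles before and after selection, in two
biological replicates, together with a wild-type control library that
measures the sequencing-error background. The complete single-substitution
space is 20 variants per mutable position (19 missense + 1 nonsense), 9280
variants for the 464 mutable positions.

Scoring proceeds in four steps:

1. **Frequencies.** Counts are pseudocounted (default 0.5) and normalized
   by tile depth. The control library's frequency is averaged across
   control replicates and subtracted from each pre/post replicate, floored
   at `pseudocount/depth`. A variant whose *pre-selection* frequency is
   within twofold of the control background is flagged
   `background_dominated`; post-selection depletion to background level is
   *not* flagged, because complete loss of function genuinely drives a
   variant into the background. Variants with fewer than 10 raw
   pre-selection reads are flagged `low_count`.
2. **Enrichment.** φ = log2(f_post / f_pre) per replicate. The log scale
   treats enrichment and depletion symmetrically; nonpositive adjusted
   frequencies yield `NA`, never silent infinities.
3. **Rescaling.** Within each normalization group — one per region ×
   replicate, because each region is a separate library and selection —
   scores are the affine map sending the unflagged synonymous median to 1
   and the unflagged nonsense median to 0. The map requires at least five
   unflagged anchors of each kind and a synonymous median strictly above
   the nonsense median (anything else means the selection failed).
   Rescaling is invariant to any positive affine transform of φ.
4. **Replicates.** Scores are averaged; the unbiased sample standard
   deviation s and replicate count n are retained.

## Error regularization

With n = 2 replicates, s is a poor estimate of measurement error. A prior
σ₀ is predicted for every variant from the linear regression
`s ~ score + log10(pre_count)` (floored at 0.01), and combined with s as

σ² = (v₀σ₀² + (n−1)s²) / (v₀ + n − 2)

with prior degrees of freedom v₀ = 3 by default — a modest prior weight
comparable to the replicate count, configurable and echoed in all outputs.
The regression is on s rather than s², with the log10 pre-selection count
as covariate; the functional form is a package choice. Note a property of
the formula worth knowing: at s = σ₀ it returns σ = σ₀·√((v₀+n−1)/(v₀+n−2)),
slightly above σ₀, reflecting the −2 in the posterior degrees of freedom.
Confidence intervals are percentile bootstrap over replicate scores
(resample counts configurable; the generic `bootstrap_ci()` uses 10,000
resamples by default and is seeded).

## Classification

`roc_auc()` computes the empirical ROC curve over all distinct cutoffs; the
AUC is the trapezoidal area, identical to the all-pairs concordance
probability with ties counted 1/2 (verified in the tests against a
brute-force oracle and an external implementation). `select_threshold()`
maximizes Youden's J over midpoints between adjacent distinct scores,
breaking ties toward higher specificity; a closest-to-(0,1) criterion is
selectable. Two independent one-vs-rest analyses mirror the two clinical
boundaries: loss-of-function variants are called below the low threshold,
hyperactive variants above the high threshold, with strict inequalities
(`assign_class()` defaults to the published 0.66/1.18). Variants common in
the population (allele frequency above 1e-4) are expected to be
wild-type-like; `af_consistency()` flags exceptions as QC discordances.

## Conformational mechanism

Glucokinase equilibrates between a catalytically active closed conformation
and an inactive super-open conformation. A variant that destabilizes the
super-open state more than the closed state shifts the ensemble toward
activity. From per-conformation stability predictions (converted from
internal energy units by division by 2.9 where declared — units must be
declared per table, never auto-detected), `delta_ddg()` computes
Δ(ΔΔG) = ΔΔG_super-open − ΔΔG_closed, antisymmetric under exchange of the
conformations. Positions 157–179 are disordered in the super-open structure
and carry no Δ(ΔΔG) (`no-data`). The candidate filter keeps variants with
activity score > 1.18, ΔΔG_closed < 2 kcal/mol and Δ(ΔΔG) > 0.25 kcal/mol,
all strict and configurable. Verdict bands (`destabilized` when both
conformations are ≥ 2 kcal/mol above wild type; shift verdicts when
|Δ(ΔΔG)| > 0.25) are package assumptions, reported as such. Per-position
summaries use the median over the 19 missense substitutions only,
everywhere, for consistency with the stability convention.

## Conservation comparison

`filter_msa()` applies two rules in order: columns where the reference
sequence has a gap are removed, then sequences with more than 50% gaps
(over the remaining columns) are removed; the reference row is always kept
and the operation is idempotent. `naive_deltaE()` is a deliberately simple
frequency-log-ratio stand-in for tree-aware conservation predictors — it is
used for testing and synthetic work and is *not* equivalent to such
predictors; real analyses should ingest an external ΔE matrix.
`correlate_profiles()` computes Pearson or Spearman (average ranks)
correlations with pair-resampling percentile-bootstrap CIs, dropping
missing values pairwise.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
tested.

**Ground truth.** Activity follows a Boltzmann occupancy model over three
states (unfolded reference at 0, closed at −2.0 kcal/mol, super-open at
−3.0 kcal/mol, RT = 0.593 kcal/mol): the enzyme is active only when folded
and closed, so

`true_activity = cat_factor × P_closed(mut) / P_closed(wt)`

with `P_closed = exp(−G_C/RT) / (1 + exp(−G_C/RT) + exp(−G_SO/RT))`.
Nonsense variants have activity 0; synonymous variants exactly 1. Missense
variants draw a mechanistic class (30% neutral, 35% globally destabilizing,
10% shift-to-open, 10% shift-to-closed, 15% catalytically impaired). The
effect scales are deliberately modest (e.g. neutral ΔΔG noise sd
0.15 kcal/mol, shift-to-closed ΔΔG_super-open 0.1 + Gamma(2, 0.3)): the
occupancy model amplifies free energies — 0.3 kcal/mol of differential
stability already shifts occupancy roughly twofold, because the wild type
occupies the closed state only ~16% of the time — and the measured map
spans scores ~0 to ~1.5 with little mass beyond. Larger scales would pile
probability into regimes the assay cannot resolve.

**Screen.** Per region, 2×10⁵ clones receive Poisson(0.35) mutations
(positions uniform, alternate codon uniform over the non-reference NNK
codons, matching the estimated 0.3–0.4 mutations per mutagenized region and
giving each codon variant on the order of ten independent clones). Growth
is deterministic: a clone doubles `generations_wt × min(activity, 1.5)`
times (default 10 wild-type doublings; the activity cap keeps hyperactive
variants detectable but bounded, and multi-mutant clones grow by the
product of their variants' activities). Sequencing is a multinomial draw of
2×10⁶ reads per tile, condition and replicate; replicates share the clone
library and differ by sampling. Reads whose tile carries ≥ 2 amino-acid
changes are generated but excluded from per-variant counting, as a
tile-based caller would. The error background assumes tiles are read on
both strands with duplex agreement required for a call, so a specific false
single-base call occurs at (e/3)² with e = 1e-3 per base; the wild-type
control contains only this background.

**What it does not emulate.** PCR jackpots, tile-boundary chimeras,
position- or context-dependent error rates, stop-codon readthrough,
clone-level growth noise, and epistasis between co-occurring mutations are
all absent. Passing tests therefore demonstrate correctness of the
estimator under a clean version of the experimental design, not robustness
to every artifact of real libraries.

**Stability tables and MSAs.** `simulate_ddg_tables()` adds Gaussian
observation noise (0.25 kcal/mol in the standard checks) to the true
per-conformation perturbations, omits 157–179 from the super-open table,
and can emit internal energy units to exercise the converter.
`simulate_msa()` draws alignment columns i.i.d. from per-position
preference weights; `activity_preferences()` couples those weights to the
truth (`exp(β(activity − 1))`, β = 3) so that conservation and activity are
correlated by construction — which is what lets the tests reproduce the
qualitative observation that residue-median profiles correlate more
strongly than variant-level ones, since averaging cancels independent noise
in both measurements.

## Numerical and design choices

- Pseudocount 0.5, minimum pre-count 10, anchor minimum 5 per group.
- One-letter amino-acid codes are canonical in memory (stop `*`,
  synonymous records `p.X99=`); scoresets on disk use three-letter codes
  with `Ter`, the deposition convention, with conversion centralized in the
  writer/reader pair.
- The enrichment statistic (log2), the control-subtraction scheme, and the
  Youden criterion are declared package conventions; published analyses do
  not print theirs, so bit-for-bit agreement with any specific external
  pipeline is not claimed.
- Degenerate inputs fail loudly: zero-depth tiles, missing conditions,
  degenerate anchors, one-class ROC inputs, all-identical scores,
  undeclared energy units and reference/variant mismatches are all errors,
  not warnings.
- Test and check problem sizes: unit tests run a 60-residue protein at
  5×10⁵ reads per tile and 5×10⁴ clones per region; the end-to-end
  recovery check runs the full 465-residue design at default depth. These
  sizes were chosen so the whole suite exercises every stage at
  comfortable resolution.

## Limitations

The synthetic screen is the package's test bed, not evidence about any
particular wet-lab dataset; real data bring the artifacts listed above plus
batch structure the simulator does not model. The naive conservation score
is a stand-in. With very few benign variants in real clinical sets, ROC
thresholds are coarse — the package reports them with their operating
points rather than asserting clinical validity, and functional evidence
alone cannot classify a variant as pathogenic.
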