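---
title: "Guilt-by-association correlation analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guilt-by-association correlation analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbacor)
```

## The problem

Guilt-by-association (GBA) infers shared function from co-varying abundance.
Given a wide proteome matrix — thousands of proteins quantified across
hundreds of cancer cell lines or patient samples — proteins acting in a
common pathway tend to rise and fall together, so ranking every protein by
its correlation to a bait protein surfaces functional partners without any
physical-interaction assay. `gbacor` implements that pipeline: missing-value
handling, an all-vs-all Spearman co-abundance matrix, ranked bait queries,
two validation statistics (GO-term coherence and synthetic-lethal pair
enrichment), protein-panel summaries for sparse proteins such as centromere
components, and a replicate depletion contrast.

## The correlation model

Missing cells are imputed as **zero** before correlating
(`impute_missing_as_zero()`). In label-free proteomics a missing value is
usually a below-detection-limit observation, not an unknown: treating
absence as zero intensity keeps every sample in every pairwise comparison
and lets broadly-absent proteins correlate through their shared detection
pattern. The cost is that zero-imputation creates long runs of tied zeros;
Spearman with **average ranks** (the standard tie convention) handles these
gracefully, and because Spearman depends only on ranks the analysis is
invariant to any strictly increasing transform of fully observed rows — so
it does not matter whether intensities arrive raw or log-scaled. For rows
with missing values the imputed zeros interact with that invariance (the
tie block is placed at the bottom of the ranking); we compute on the
imputed values as given and make no further correction.

`spearman_matrix()` rank-transforms each protein row, centres and scales,
and obtains the full matrix as one crossproduct. The result is therefore
independent of any chunking of the pairs and bitwise reproducible for a
fixed input order. A correlation is **undefined** when a rank vector is
constant (e.g. a fully missing protein); undefined entries are stored as 0
— the same zero-imputation convention applied to the correlation matrix
itself — with a `defined` mask preserving the distinction for diagnostics.
No p-values are attached: the method ranks correlations rather than
thresholding them, and the rank out of the full pool (e.g. "position
729/15,312") is the reported quantity.

`rank_partners()` sorts descending from positive to negative, breaking ties
by partner identifier so results are deterministic and invariant to input
order. `include_self = TRUE` (default) matches the published table
convention in which the bait heads its own list at rank 1 and denominators
count the whole pool; both conventions are exposed because reported ranks
can differ by one between them.

## Validation statistics

Two summaries ask whether functionally related proteins correlate above the
bulk:

* **Term coherence** (`term_median_distribution()`): for each annotation
  term, the median of all within-term pair correlations, excluding values
  exactly equal to 1 (equality tested after rounding to 12 decimals, which
  absorbs the floating-point images of perfectly monotone duplicate rows —
  the values that exclusion is meant to remove). The statistic is the
  median of these per-term medians minus the **background median**, the
  median over all off-diagonal pairs of the matrix.
* **Pair enrichment** (`pair_median_shift()`): the median correlation over
  an externally curated pair list (e.g. high-confidence synthetic-lethal
  pairs restricted to low-throughput/CRISPR evidence) minus the same
  background.

Design choices, both configurable and always auditable through the
`excluded` report: the background median does **not** apply the "= 1"
exclusion (it belongs to within-term sets, where a duplicated protein would
otherwise dominate a tiny term, and is negligible among all ~n²/2 pairs);
the minimum number of surviving pair correlations per term defaults to 1
(no term-size floor is imposed). Terms are flat sets — no GO-graph ancestor
propagation — and proteins in the map but absent from the matrix are
dropped at use time.

## Panel summaries and sparsity

`subset_panel()` extracts a user-ordered submatrix (absent members
reported), `correlation_range_stats()` and `abundance_range_stats()` give
per-protein boxplot statistics, and `panel_sparsity()` reports the mean
number of samples lacking detection. All quartiles use linear interpolation
between order statistics (R's default type-7 rule), fixed so printed
numbers are reproducible. "Detected" means unmasked and strictly above the
detection threshold (default 0).

With zero imputation, a protein detected in fewer than half the samples
necessarily has abundance median 0 (and Q1 = 0); Q3 additionally collapses
to 0 once roughly three quarters of the samples are undetected (exactly:
when the number of zeros reaches `0.75 * (n - 1) + 1` under the type-7
rule). Centromere proteins in large patient cohorts sit deep inside that
regime — on the order of 69 detections out of 1172 samples — which is why
their abundance boxplots degenerate to zero while the well-detected members
(a CENP-B/-C-like minority) do not.

## The depletion contrast

`differential_abundance()` compares two replicate conditions (at least two
replicates each; the motivating design is four vs four): intensities are
transformed as `log2(value + pseudo)` (pseudo-count 1 intensity unit by
default, negligible for well-quantified proteins), the log2 fold change is
the mean difference, and significance comes from a two-sided Welch
(unequal-variance) t test with Benjamini–Hochberg adjustment across
proteins. The underlying published analysis does not name its test; the
Welch-plus-BH combination is the simplest defensible volcano standard and
is isolated in one function so a moderated-variance variant could be
slotted in. `set_fold_change()` aggregates a protein set as 2 to the mean
of the members' log2 fold changes — the geometric mean, appropriate on a
multiplicative scale; the set membership is always an input list, never a
constant. Degenerate rows (zero variance in both groups) take p = 1 when
the means agree and p = 0 otherwise.

## The synthetic cohort generator

Because the motivating datasets are external multi-gigabyte resources, all
calibration and testing runs on synthetic cohorts with the statistical
structure the analysis assumes (`generate_cohort()`):

* **Correlation structure** via a Gaussian-copula latent-factor model: each
  sample draws one standard-normal factor per module, and a module protein
  mixes it with private noise using weight `w`. Spearman correlation
  depends only on the copula, and for a bivariate normal
  `rho_S = (6 / pi) * asin(rho_P / 2)`, so `w = 2 sin(pi rho_S / 6)` hits
  any target rank correlation exactly in expectation (verified to ±0.03 at
  2,000 samples in the tests).
* **Intensities** are log-normal: `exp(location + scale * latent)` with
  per-protein location drawn from `[4, 8]` and scale from `[0.5, 1.5]` on
  the natural-log scale — a spread of a few orders of magnitude, typical of
  label-free proteomes.
* **Missingness** is abundance-dependent by default (detection probability
  `plogis((log intensity - floor) / steepness)`, floor 4, steepness 1.5),
  because real proteomic sparsity is intensity-driven; a uniform mode
  exists for null experiments and a `none` mode for calibration.
* **Annotation** emits one term per module plus random decoy terms, and a
  pair list with a planted within-module fraction, alongside the full
  ground truth (module membership, per-pair labels, realized mask), all
  re-readable from the emitted files.

The default cohort is 10 modules of 8 proteins at target within-module
Spearman 0.7, 200 background proteins, 300 samples — large enough that
module signal dominates noise (a null Spearman at n = 300 has sd ≈ 0.058)
yet runs in well under a second. The term-validation experiments use a
GO-like variant: 25 modules of 8 at rho 0.6, 120 background proteins, 50
decoy terms of 8. The module share matters for the median-of-medians
statistic: when coherent terms are a small minority of the map, the median
of the combined term medians sits inside the decoy noise and the shift,
while positive in expectation, is of the same order as its own sampling
error; with half the terms coherent, the combined median lands at roughly
the 75th percentile of the decoy-median distribution and the shift is
reliably positive. Real GO maps are intermediate, but a map in which a
substantial fraction of terms is genuinely coherent is the regime the
published validation figure illustrates. Depletion experiments use
baseline log2 intensities in `[8, 14]` (so the pseudo-count is negligible),
four replicates per condition and log2-scale replicate noise of sd 0.2.

All generators take an explicit integer seed, use R's Mersenne-Twister with
inversion sampling, and save/restore the caller's RNG state, so no global
generator state leaks.

### What the generator does and does not emulate

It reproduces log-normal intensity spreads, block correlation, intensity
driven missingness up to the extreme-sparsity regime, module-aligned
annotation with decoys, enrichment of curated pairs within modules, and
planted multiplicative depletion effects. It does **not** emulate
batch effects, ratio compression, peptide-level roll-up artifacts,
correlated missingness across samples, or overlapping/hierarchical GO
structure. Passing tests therefore demonstrate that the pipeline's
statistics behave as designed under the assumed generative model — not that
any particular biological correlation in real data is causal or even
reproducible across cohorts.

## Numerical choices and degenerate inputs

* Ranks: average ranks for ties everywhere, via `rank()`.
* Rounding: all emitted TSVs carry 12 significant digits so diffs are
  meaningful; abundance round trips are written at 17 digits (exact for
  doubles).
* Correlations are clamped to `[-1, 1]` after the crossproduct to absorb
  last-bit overshoot.
* Undefined correlations: zero rank variance, detected exactly; stored 0,
  flagged in `defined`.
* Equality-to-1 exclusion: after rounding to 12 decimals.
* Tie-break in rankings: partner identifier, ascending, radix order.
* Degenerate depletion rows: p = 1 (equal means) or 0 (unequal) when both
  groups have zero variance.
* Errors are raised before any output is written: ragged tables name the
  offending line, duplicate protein ids are rejected, unknown baits suggest
  near matches, pipeline configs are validated (paths, keys, stage
  prerequisites) before any computation.

## Problem sizes used in the shipped experiments

The test and acceptance experiments run at desk scale, chosen so the
relevant asymptotics already hold: 30 x 60 matrices for oracle equivalence
(20 replicates), 280-protein x 300-sample cohorts for the query-recall
study (20 seeds), 320 x 300 for the term/pair validation (20 seeds, plus
20 null cohorts at 300 x 500), 200 simulated depletion experiments of 500
proteins plus one 2,000-protein null, and a 16-protein x 1,172-sample
sparsity panel. A full pan-cancer matrix (roughly 15,000 x 1,200) is ~100x
more work in the correlation step and remains tractable with the same
crossproduct formulation.

## Known limitations

* Zero imputation biases correlations among proteins with correlated
  detection patterns; the defined mask and detection counts make the
  affected rows visible but no correction is applied.
* Welch-plus-BH without variance moderation loses power at very small
  replicate numbers compared with empirical-Bayes approaches.
* Flat term sets ignore the GO hierarchy; a parent and child term count as
  independent groups.
* The ranking reports association, not mechanism: a high rank is a
  hypothesis generator, nothing more.
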