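---
title: "The Disease State Index: model, pipeline, and synthetic-cohort design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Disease State Index: model, pipeline, and synthetic-cohort design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

The Disease State Index (DSI) is a supervised, distribution-based
classifier for cohort data with mixed-type predictors, a binary outcome,
and missing values. It was designed for clinical decision support in
dementia research, where predictors range from integer test scores (MMSE,
SPMSQ) through continuous laboratory values to categorical genotypes, and
where imposing parametric assumptions or pre-specified cutoffs is
undesirable.

**Fitness.** For a single factor with observed training values, the
fitness function at measurement value $x$ is

$$f(x) = \frac{\mathrm{FNR}(x)}{\mathrm{FNR}(x) + \mathrm{FPR}(x)},$$

the share of false-negative error among total error when $x$ is used as
the classification threshold. The curve is evaluated at every distinct
observed value. With the cases-high orientation we take
$\mathrm{FNR}(x) = P_\text{case}(X \le x)$ and
$\mathrm{FPR}(x) = P_\text{control}(X \ge x)$: the threshold value itself
is counted on both error sides, so the denominator is positive at every
observed point, and the curve still reaches exactly 0 at values below the
case range and exactly 1 at values above the control range. Between
support points the curve is interpolated linearly and clamped constant
beyond the extremes — the training distribution defines the curve only at
observed values, and test subjects routinely fall between them. No
smoothing is applied.

**Relevance.** Each factor's weight is the maximum Youden index

$$J = \max_t \big(\text{sensitivity}(t) + \text{specificity}(t) - 1\big)$$

over all observed thresholds and both orientations (case iff value
$\ge t$, ties on the case side; or the mirror rule). The maximum over the
sweep is the only operating-point choice that yields exactly 0 for
completely overlapping distributions and exactly 1 for disjoint ones,
for every distribution shape. The winning orientation is stored in the
fitted factor. Both fitness and relevance depend on the data only through
ranks, so any strictly increasing transform of a continuous factor leaves
the fitted model equivalent — a property the test suite checks directly.

**Categorical factors.** Unordered categories (APOE genotype) have no
threshold sweep. Fitness of category $c$ is
$p_\text{case}(c) / (p_\text{case}(c) + p_\text{control}(c))$ from
within-class frequencies — the direct transcription of the error-share
formula — and relevance is the Youden index of the induced rule "predict
case when fitness > 1/2". Binary factors are handled as two-category
categoricals. A category never seen in training is treated as missing (and
logged) by default, so it drops out of the aggregation rather than
contaminating the score.

**Hierarchy and missing data.** Conceptually related factors form groups
(all cognition tests, all cholesterol fractions, ...), which filters noise
and prevents strongly correlated factors from being counted repeatedly. A
group's score is the relevance-weighted average of its members' fitness
values; the group in turn receives its own relevance, computed from its
training scores against the outcome exactly as a continuous factor would
be, and the total index is the relevance-weighted average of group scores.
Missing values are ignored wherever they occur: every average is taken
over the available children only, and a subject's index is missing only
when every leaf is missing. If all available children of a node have
relevance 0, the unweighted mean is used (avoiding 0/0 while preserving
the averaging contract). The index is always in $[0,1]$: values near 0
resemble controls, values near 1 resemble cases.

## The analysis pipeline

**Inclusion filters.** The dementia model drops subjects with baseline
dementia and subjects who died within the first two years of follow-up
(removing mortality-driven differences); the pathology models drop
baseline dementia and subjects without autopsy data. The drivers log the
subject accounting at each stage.

**Screening.** Before model building, each factor is tested univariately:
Mann–Whitney U for continuous and ordinal factors (ordinal scales are
reported as means with the quantitative test), Pearson χ² without
continuity correction for binary and categorical ones. Only factors with
p < 0.05 (strict) enter the model; groups left empty are pruned. The
APOE carrier binaries inherit the genotype table's single χ² test via the
`screen_with` mechanism, so the allele family is covered by one test. The
exact Mann–Whitney p-value is computed by enumeration of all rank
assignments when the combined sample size is at most 10 (valid under
ties, using midranks); larger samples use the tie-corrected normal
approximation. No multiple-testing correction is applied. Screening once
on the full analysis population matches the original design and leaks
information into the subsequent cross-validation; `nested_screening =
TRUE` repeats screening inside every training fold for a leak-free
estimate.

**Cross-validation.** Model performance is evaluated by repeated k-fold
cross-validation (default 10 × 10): per repetition, a fresh uniformly
random partition into k near-equal subgroups (unstratified by default —
stratification is available by flag), a full model fit on k−1 subgroups,
and scoring of the held-out one. AUC is the rank-based (Mann–Whitney)
statistic, ties counting one half; sensitivity and specificity use the
fixed cutoff index = 0.5 with ties on the case side, matching the factor
threshold convention. All three metrics are computed per fold for the
entire model, every group, and every factor, then averaged over the
k × repeats folds; the default 95% interval is the 2.5th–97.5th percentile
of the fold-level values, which needs no normality assumption (a
normal-approximation option exists). Folds whose test part contains a
single class are excluded with a warning. Fold-level sensitivity and
specificity are averaged, not pooled, symmetric with the AUC aggregation.

**Pathology outcomes.** Quantitative loads and counts (amyloid load,
tangle count, CAA percentage, macro-/cortical/white-matter/microinfarct
counts) are dichotomized strictly at > 0; α-synuclein is present for
brainstem, limbic, or diffuse neocortical pathology; hippocampal sclerosis
for severe marked/total neuronal loss; TDP-43 as its immunopositivity
flag. Neuropathological AD is the NIA-AA likelihood dichotomy (present =
intermediate or high) from a configurable Braak-group × CERAD matrix: the
default encodes high = Braak V–VI with moderate/frequent plaques,
intermediate = Braak III–IV with moderate/frequent or Braak V–VI with
sparse, all else low. The matrix is data, not code, so a different
reading of the criteria is a one-argument change.

**PCA stage.** The pathology matrix (quantitative values where available,
binary indicators otherwise) is column-centered but not scaled — variables
keep their natural variances, as in the original analysis — and decomposed
on complete cases only (the dropped-row count is reported). Component
signs follow a fixed convention (largest-magnitude loading positive) for
reproducibility. Each component's subject scores are then assessed as
dementia predictors by rank AUC, with components discriminating in the
opposite direction flagged.

## The synthetic-cohort generator

The generator exists so that every stage has realistic input without any
subject-level data; its defaults are the published population structure,
not tuning knobs. The dementia defaults encode 97 incident-dementia cases
and 148 controls (245 analysis subjects) plus 94 early-death subjects that
the inclusion filter removes; per-group means and SDs for every baseline
factor; APOE genotype probability vectors from the printed genotype
counts; and the printed missing-data counts (3 education, 3 APOE),
injected exactly and reproducibly. The pathology defaults describe the
163-subject autopsy population with the printed outcome prevalences.

Continuous variables are truncated normals on the instruments' hard ranges
(MMSE 0–30, SPMSQ 0–10, BMI 12–60, education ≥ 0, ...); the published
tables give only means and SDs, so the distributional shape is an explicit
modeling choice. Because truncation shifts the mean, the underlying
location is calibrated per group (by uniroot on the truncated-mean
equation) so that the *truncated* mean equals the target; the nominal SD
is used as the underlying scale. Ordinal scores are rounded onto their
discrete support. Class counts are exact, never sampled.

Predictors are drawn independently between variables by default — the real
cohort's joint covariance is unavailable. A Gaussian-copula option imposes
rank correlation between chosen normal-family variables. Independence has
a visible consequence: the synthetic entire-model AUC (≈ 0.9 on defaults)
exceeds the published 0.73, because independent moderately-separated
factors jointly separate classes better than correlated real ones.
Passing tests on synthetic data therefore demonstrate correctness of the
machinery and recoverability of planted structure, not the real cohort's
performance levels, and no test asserts the published AUCs.

The pathology generator links amyloid load, tangle count, and CAA through
a shared latent severity factor (correlation 0.6 by default), draws
Braak × CERAD jointly so the derived NIA-AA dichotomy hits its configured
prevalence, and couples APOE ε4 carriage (r = 0.4) and dementia at death
(r = 0.5) to the same latent. Present pathologies get lognormal
magnitudes driven by the same latents; absent ones are exactly 0. This
reproduces the qualitative published pattern — an AD-/amyloid-type first
principal component that is the best dementia-predicting component — and
the test suite checks exactly that, over repeated seeds. The α-synuclein
prevalence is not printed in the source tables; 0.30 was chosen once as a
realistic Lewy-pathology rate in an 85+ autopsy series. One printed
inconsistency is resolved in favor of the explicit footnote: the
microinfarct missing count is 4, although the table denominator would
imply 7.

## Numerical choices and degenerate inputs

* Threshold ties sit on the case side everywhere (relevance sweep, index
  cutoff), making the brute-force oracle comparison exact.
* Orientation is chosen per factor by maximizing the Youden index; the
  tie-break (equal maxima) prefers cases-high, which only occurs in
  symmetric degenerate cases where both orientations are equivalent.
* A factor with zero variance in both classes gets relevance 0; a factor
  with an entirely missing class is an error at fit time and a recorded
  "unselected, with reason" at screening time.
* A group whose training scores exist in only one class gets relevance 0
  with a warning rather than an error, so one pathological group cannot
  abort a full model fit.
* Degenerate contingency tables (a single non-empty row or column) give
  p = 1 with a warning — an uninformative factor, not a failure.
* PCA drops incomplete rows (reported), and reconstruction holds to 1e-8
  with all components retained.

## Problem sizes used by the test suite

The packaged tests run the full dementia pipeline at the study's size
(245 subjects, 10 × 10-fold where the check needs it, 5 × 2-fold where
only structure is tested), 1000-replicate null calibration of the
screening rate at n = 60, 20-seed null cross-validation at n = 80, and
10-seed parameter-recovery runs at the published group sizes. These sizes
were chosen to make Monte-Carlo error small relative to the asserted
tolerances while keeping a full test run comfortable on a laptop.

## Known limitations

* Fitness curves are unsmoothed empirical step/interpolation curves; with
  very small training sets they are coarse, and relevance is an optimistic
  in-sample maximum (the cross-validation, not the training relevance, is
  the performance estimate).
* Default screening before cross-validation reproduces the original
  design's optimism; use `nested_screening = TRUE` for honest estimates.
* The generator matches marginal structure, not the real joint covariance;
  absolute synthetic AUCs are not comparable to published ones.
* The index is a similarity score, not a calibrated probability; no
  calibration layer is provided.
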