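---
title: "Hippocampal degeneration scores: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hippocampal degeneration scores: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hidscore)
```

## The problem and the score

In case-control studies of the Alzheimer's disease spectrum (ADS:
amyloid-positive participants with amnestic MCI or probable AD), atrophy of
the hippocampal formation is not uniform: CA1, the dentate gyrus (DG) and
the subiculum (SUB) shrink while CA2 and CA3 are comparatively spared. A
single per-patient summary of this multivariate atrophy pattern is useful
for relating neurodegeneration to cognition.

The hippocampal degeneration score (HiDs) implemented here is built in
three steps:

1. **ICV residualization.** Each raw subfield volume (and each
   whole-hippocampus volume) is regressed on intracranial volume (ICV) by
   OLS, and the residual replaces the raw value. This removes head-size
   scaling. Residuals are *not* re-centered, so adjusted volumes live in
   mm^3 residual units and can be negative.
2. **Profile vectorization and distances.** Each subject's ICV-adjusted
   bilateral subfield volumes are stacked into an ordered profile vector
   (canonically CA1-L, CA1-R, CA2-L, ..., SUB-R; length 10 for the whole
   profile, length 2 for a single subfield). For N patients and M controls
   the N x M Euclidean distance matrix
   $d_{nm} = \lVert x_n - y_m \rVert_2$ quantifies each patient-control
   dissimilarity, capturing hemispheric asymmetry rather than averaging it
   away.
3. **Averaging over controls.** A patient's HiDs is the mean of their M
   distances to the controls. Per-subfield scores repeat the procedure on
   the length-2 (L, R) profile of one subfield.

Because the distance operates on volumes in their native units, large
subfields (CA1) dominate the whole-profile score by construction. An
optional variant z-scales each profile feature to the control mean/SD
before the distance (`compute_hids(..., scale = TRUE)`); it is off by
default because the score is defined on ICV-adjusted volumes as such.

Downstream, group differences in adjusted volumes are tested with ANCOVAs
guarded by covariate selection and a residual-normality gate, and HiDs are
related to cognition with partial correlations under Benjamini-Hochberg
(BH) false-discovery-rate control, one BH family per analysis block.

## Inferential toolkit and its defaults

**Welch t.** Two-group comparisons of demographics and summary measures use
the unequal-variance t-test; `welch_t_summary()` works from printed
means/SDs/ns so published tables can be recomputed directly.

**Covariate ladder.** Candidate covariates are offered strictly in the
order age, then sex, then education. Starting from `outcome ~ group`, each
step is kept only when the nested-model F-test against the current
accepted model has p < 0.05, and the ladder *stops at the first
non-significant step*, so the accepted covariates are always a prefix of
the ladder. We chose the stop-at-first-failure rule over testing all three
steps unconditionally because successive unconditional tests at alpha =
0.05 would abandon the base model for ~14% of pure-noise outcomes, whereas
the hierarchical rule retains it at the nominal ~95% and matches the
spirit of successive inclusion of a fixed model order. Constant or
collinear candidates are skipped with a warning rather than aborting.

**Normality gate and fallbacks.** The accepted model's residuals are tested
with Shapiro-Wilk at alpha = 0.05. Normal residuals route to the
parametric engine (ANCOVA / partial F). Non-normal residuals route to the
Wilcoxon rank-sum test when the model has no covariates (exact enumeration
when both groups have n <= 10 and there are no ties, otherwise the
tie-corrected normal approximation), and to permutation regression when
covariates are present.

**Permutation regression.** The outcome vector is randomly permuted against
the fixed design (simple permutation, not Freedman-Lane; simple
permutation is exact under the global null of no association, which is the
hypothesis at stake in these fallbacks), with
$p = (1 + \#\{|t_b| \ge |t_{obs}|\})/(B + 1)$, a default budget of
B = 5000 and a mandatory seed. An exhaustive mode enumerates all n!
permutations for n <= 8 and is used as its own oracle in the tests.

**Partial correlations.** The residual method (correlate the residuals of
x and y each regressed on the covariates) with
$t = r\sqrt{(n-k-2)/(1-r^2)}$. The default CI is Fisher z; a seeded
percentile bootstrap (2000 resamples) is available because analytic
intervals can be optimistic at n ~ 29, and published intervals for such
designs are often wider than Fisher z implies.

**BH families.** Adjusted p-values are computed within blocks: the 2
whole-hippocampus models; the 10 subfield models; the subgroup post-hocs;
the 4 whole-profile HiDs correlations; the per-subfield HiDs correlation
grid; and each specificity block. Block-wise families match how such
analyses are reported; the family map is an interpretation, and membership
is visible in the `family` column of every results table.

## The synthetic cohort generator

No subject-level data are bundled; every stage is exercised on cohorts
drawn from `generate_cohort()`. The generator's defaults *are* the study
conditions encoded in `reference_group_summaries()`: 29 ADS (12 aMCI, 17
AD) vs 17 controls, control bilateral whole-hippocampus volume 1455 mm^3
(SD 257) against an ADS target of 922 (SD 395), MMSE 29.18 (1.13) vs 23.66
(4.30), and so on.

The generative model ties everything to one per-subject latent severity
$s_i \ge 0$ (0 for controls, half-normal for ADS):

* volume: $v_{ifh} = m_f \cdot \max(1 - a_f s_i, 0.02) \cdot
  (1 + u_i + \beta \delta_i + e_{ifh})$, floored at 0.1 mm^3 so raw
  volumes stay positive;
* cognition: intercept (the control mean) minus loading times $s_i$ plus
  Gaussian noise; MMSE/MoCA are rounded and clamped to [0, 30], composite
  domains stay continuous z-scores;
* whole-hippocampus volumes are the per-hemisphere subfield sums.

Engineering constants chosen once (they are not published values):
per-hemisphere subfield shares CA1 0.40, CA2 0.03, CA3 0.07, DG 0.30,
SUB 0.20 of 1455/2 mm^3, reflecting the usual size ordering; per-subject
common scale SD 0.151, ICV elasticity $\beta = 0.5$ with ICV 1.5e6
(SD 1.5e5) mm^3, and per-cell noise SD 0.20, jointly solved so the control
bilateral sum has SD ~257 mm^3. The atrophy fraction on CA1/DG/SUB
(a = 0.51 per unit severity) is solved from the 1455 - 922 = 533 mm^3
group gap given the half-normal severity mean $\sqrt{2/\pi}$; CA2/CA3 get
zero. Cognitive loadings are solved the same way from each domain's group
mean gap, with residual noise set to the control-arm SDs.

Demographic covariate effects default to zero: the composite scores are
demographically normed upstream by construction, and the reference groups
are matched. Slopes can be injected through `covariate_effects` to
exercise the ladder. Subgroup labels (aMCI/AD), cortical thickness
(group-shifted only) and amyloid SUVr (ADS only) are drawn independently
of severity, so subgroup moderation, thickness substitution and SUVr
blocks are null by design — matching the negative findings such designs
report. A missing-at-random switch (`missing_rate`, `missing_fields`)
exercises the complete-case accounting paths.

What the generator does *not* emulate: segmentation error and its spatial
correlation structure, floor/ceiling-induced skew in real
neuropsychological scores, site or scanner effects, and longitudinal
change. One structural consequence of the single half-normal latent is
that the ADS-arm spread of strongly loaded cognitive scores exceeds the
reference SDs (the half-normal shape fixes SD(loading * s) at ~0.76 of
the group mean shift); group means are matched exactly. Passing tests
therefore certify the statistical machinery under a faithful effect-size
regime, not distributional realism of every margin.

## Numerical choices and degenerate inputs

* ICV adjustment requires >= 3 subjects in the fit scope and non-zero ICV
  variance; the default scope is all subjects, with `controls_only`
  available because disease-related ICV-volume coupling can bias a pooled
  fit. Whether to add back a mean is moot here: pure residuals are used.
* Cross-distances are computed via the Gram-matrix identity with negative
  roundoff clamped at zero; tests pin it to a brute-force double loop at
  1e-12 relative.
* Profile label order is enforced, never assumed; a label mismatch is an
  error rather than a silent reorder, and subjects missing any requested
  volume are excluded with a logged reason rather than imputed.
* Zero-variance residual vectors are reported non-normal with undefined W;
  both-zero-variance group comparisons, zero residual variance in partial
  correlations and singular ANCOVA/moderation designs raise typed errors.
* Permutation p-values use the add-one estimator and refuse B < 99;
  tie comparison uses a 1e-12 guard.
* MMSE/MoCA discretization is round-then-clamp; clamping slightly shrinks
  the simulated control means (< 0.1 points at the defaults).

## Problem sizes used by the test suite

The bundled checks run at sizes chosen to make Monte-Carlo error small
relative to the tolerances: 2000 replicates for each type-I-error
calibration (binomial SE ~0.005 around 0.05), 1000 replicates for CI
coverage, 100-150 replicate cohorts for parameter-recovery and
flagging-rate properties, and n = 10,000 subjects for distributional
means. The per-model correct-call criterion for subfield flagging is
evaluated per model rather than jointly: with four true nulls in a
ten-model BH family at alpha = 0.05, the joint all-correct event is capped
near ~86% by construction, while each individual call is correct in well
over 90% of cohorts.

## Known limitations

* The score inherits the units of ICV residuals; comparisons across
  segmentation pipelines or atlases are not meaningful without
  harmonization.
* Whole-profile HiDs is dominated by CA1/DG; a subfield-specific question
  needs the per-subfield scores.
* The Wilcoxon fallback tests a location shift, not the ANCOVA estimand;
  engine tags in the results make the switch visible.
* The generator's single-latent structure cannot represent dissociations
  (e.g. memory impairment without atrophy); specificity conclusions from
  synthetic data are therefore about calibration, not about biology.
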