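---
title: "Decomposing longitudinal symptom heterogeneity with three-mode PCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing longitudinal symptom heterogeneity with three-mode PCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threemode)
```

## The problem

Repeated questionnaire assessments of a patient cohort form a three-way
array: persons × symptom items × assessment times, with entries
$x_{ijk}$ (for instance 21 depression items scored 0–3, administered every
three months for two years). Heterogeneity lives on all three modes at
once — patients differ, symptom domains differ, and trajectories differ —
and the clinically interesting signal is their *interaction*: which symptom
domains follow which temporal course in which kind of patient. Classical
person-level (latent class) or item-level (factor/PCA) analyses each
flatten one of these modes away.

Three-mode principal component analysis (the Tucker3 decomposition)
summarizes all three modes simultaneously:

$$x_{ijk} \approx \sum_{p=1}^{P}\sum_{q=1}^{Q}\sum_{r=1}^{R}
  a_{ip}\, b_{jq}\, c_{kr}\, g_{pqr},$$

with orthonormal component matrices $A$ (I × P, person scores), $B$ (J × Q,
symptom scores), $C$ (K × R, time scores), and a small core array $G$
(P × Q × R) whose entry $g_{pqr}$ weights the triple interaction of person
component $p$, symptom component $q$ and time component $r$. Squared core
entries partition the model's explained sum of squares, which is what makes
the core directly interpretable as a table of interaction strengths.

## The pipeline

`run_pipeline()` orchestrates the full analysis; every stage is exported on
its own. The stages, with their assumptions and the parameters that matter:

1. **Sample selection** (`select_sample`). Persons must provide at least
   `min_timepoints` assessments (default 5 of 9). A time point counts as
   provided when at least `timepoint_rule` (default 0.5) of that person's
   items are observed then; a strict reading uses 1.0. The default reflects
   the common practice of accepting half-complete questionnaires as
   administered.
2. **Multiple imputation** (`em_bootstrap_impute`). Missing item scores are
   imputed `m` times (study convention: 20) with a bootstrap-EM
   multivariate-normal imputer on the persons × (items·times [+ covariates])
   flattening: each imputation bootstrap-resamples persons, estimates
   (μ, Σ) by EM, and draws every person's missing block from its
   conditional normal given that person's observed entries. Because the
   flattening has roughly as many columns (e.g. 189) as persons (e.g. 219),
   Σ is shrunk toward its diagonal with `ridge` prior observations
   (default 0.5% of the sample). EM stops when relative parameter change
   drops below `tol = 1e-3`; draw quality is insensitive to tighter
   tolerances while iteration counts triple. The normal model is an
   approximation for bounded integer item scores — standard for this class
   of imputer, and adequate here because all downstream quantities are
   second-moment functionals.
3. **Three-way ANOVA** (`three_way_anova`, `pool_anova`). A fixed-effects
   decomposition of the grand-mean-centered completed cube into three main
   effects, three pairwise interactions, and a three-way-plus-error
   remainder (one observation per cell makes those inseparable). Its
   purpose is diagnostic: a sizeable three-way term justifies a three-mode
   model. It is computed on the raw (not preprocessed) scale, since
   person-mode centering would annihilate the persons main effect.
4. **Preprocessing** (`preprocess_cube`). Each imputed cube is centered
   across persons — removing the *general trend*, the J × K matrix of mean
   item trajectories — and then each item slab is rescaled to mean square 1
   (slab SS = I·K), so items contribute equally. The slab-RMS convention is
   used rather than SS = 1; the two yield identical components and fit
   percentages and differ only by a constant in the stored scales, but
   RMS = 1 keeps the scales invariant to I and K. After preprocessing the
   total SS is exactly I·J·K, which the explained-variance accounting
   relies on. Both steps are invertible via the stored
   `preprocessing_state`.
5. **Complexity selection** (`scree_grid`, `select_complexity`). Every
   admissible rank triple up to `max_ranks` is fitted on every imputed
   cube. On the (total components S = P+Q+R, mean fit) plane the convex
   hull marks efficient complexities; the elbow is the hull point with the
   largest ratio of per-component fit gain before versus after it.
   Candidates whose symptom/time components are unstable across imputations
   (smallest cross-imputation congruence < 0.85) are screened out first,
   and ties resolve toward fewer components. The 0.85 floor sits just above
   the 0.84 congruence conventionally read as "fair similarity".
6. **Fitting and rotation** (`tucker3_als`, `joint_orthomax`). ALS
   (TUCKALS-type): each mode's matrix is set to the leading left singular
   vectors of the cube matricized against the other modes' projections;
   HOSVD initialization, `tol = 1e-8` relative fit change, `max_iter =
   1000`, optional seeded random restarts. The loss is non-increasing by
   construction and asserted in tests. Joint Orthomax then rotates the
   solution to simple structure: it maximizes a weighted sum of orthomax
   (γ = 1, varimax flavor) simplicity of the core along all three
   matricizations and of the component matrices, by Jacobi plane rotations
   with the core counter-rotated, so the reconstruction — and hence the fit
   — is unchanged. For any plane rotation the criterion is exactly
   $a + b\cos 4\theta + c\sin 4\theta$, so each optimal angle comes from
   four criterion evaluations; sweeps run over modes in the order symptom,
   time, person for determinism. The standard weight preset weighs each
   mode matrix by (core elements)/(matrix elements) and sets the
   person-mode weight to zero: person scores are not directly interpreted,
   so simplicity there is not traded against core simplicity.
7. **Pooling** (`generalized_procrustes`). The m rotated solutions are
   iteratively rotated toward their running mean (orthogonal Procrustes per
   mode, cores counter-rotated) and averaged. The averaged matrices are
   re-orthonormalized by polar decomposition with the polar factor absorbed
   into the core, so the pooled model is again a valid Tucker3 model.
   Element-wise standard deviations across imputations quantify imputation
   uncertainty of every reported score.
8. **Fit accounting** (`total_fit_with_trend`). Two fit percentages: the
   *heterogeneity fit* of the model against the preprocessed cube, and the
   *total fit* of trend-plus-model against the trend-retained cube on the
   symptom-normalized scale, where the prediction for cell (i,j,k) is
   $M_{jk}/s_j + \hat{x}_{ijk}$. On that common scale the trend and model
   sums of squares are additive (centering makes them orthogonal), which is
   the accounting under which both percentages are comparable.
9. **Interpretation** (`core_explained_variance`,
   `component_trajectories`, `external_correlations`). Each core element's
   $100\,g_{pqr}^2/\mathrm{SS}$ is its explained-variance share; these add
   up to the model fit. Trajectory curves $\sum_r g_{pqr} c_{kr}$ show how
   person component p expresses symptom component q over time, next to the
   trend's own projection. Person component scores are correlated with
   baseline external variables: Pearson, or Spearman when Shapiro–Wilk
   rejects normality of the variable at α = 0.05; coefficients are pooled
   across imputations by Fisher-z averaging with a Rubin-style total
   variance for the p-value. No multiplicity correction is applied by
   default (a Benjamini–Hochberg option exists), mirroring the usual
   reporting of such exploratory tables.

Split-half stability (`split_half_stability`) complements selection:
persons are halved at random, each half is preprocessed and fitted
*independently* (centering is part of the estimator, so it must be redone
per half), rotated, and the halves' symptom and time components compared by
Tucker congruence after alignment. Person components are excluded — the
halves share no persons. The number of splits (default 10) is a
convention, not a fitted quantity.

## Alignment and sign conventions

A Tucker3 solution is identified only up to orthogonal rotations within
each mode (compensated in the core). Three devices make solutions
comparable and outputs deterministic:

* every fitted column is sign-flipped so its largest-magnitude entry is
  positive, compensated in the core;
* `align_solution(method = "permutation")` finds the signed column
  permutation maximizing absolute congruence with a reference (exhaustive,
  exact at these ranks) — right for comparing rotated solutions that should
  agree column-by-column;
* `align_solution(method = "procrustes")` allows a full orthogonal rotation
  — required when comparing against a *planted truth*, whose
  within-subspace orientation is arbitrary relative to the fitted one.

When comparing with a generator's truth, the truth must first be mapped
through preprocessing (`truth_model_preprocessed`): centering shifts the
person scores and slab normalization rescales the symptom rows, so raw
planted matrices are not the right reference.

## The synthetic-data generator

`generate_tucker3_dataset` builds cohorts with known ground truth:
orthonormal component matrices drawn as QR factors of Gaussians, a planted
sparse core, a shared declining trend (`default_trend`: item levels
0.5–1.4 times a profile decaying to a stable floor with time constant 2.2
assessments — the shape of a treated cohort that improves and then
plateaus), i.i.d. Gaussian noise, MCAR or dropout-like MAR-by-time
missingness (odds × 1.5 per later assessment), optional rounding/clipping
to the item range, and external covariates constructed as
`loadings × standardized person scores + independent noise`, so the
loadings are the implied correlations.

Two calibrations make the generator reproduce stated study conditions
rather than approximate them. With `target_share`, the noise variance is
solved per realization so the planted structure carries exactly that share
of the post-preprocessing SS — a global formula is biased because slab
normalization downweights items that happen to carry more structure, so
the generator solves the mean per-item share equation by root-finding.
With `target_total_share`, the trend is rescaled so trend-plus-structure
explain the requested share on the normalized scale.
`study_like_spec()` packages the emulated cohort: 219 × 21 × 9, planted
(3,2,2) structure with a realistic coupling pattern (one person component
improving on both symptom domains, one dominated by the somatic/persisting
pair, one by the cognitive/persisting pair), structure share 0.28, total
share 0.65, 7.8% missing cells, and three covariates with implied
correlations 0.6, −0.45 and 0.38 on the three person components.

The default planted core assigns each person component a *distinct*
(symptom, time) component pair covering all components of both modes;
shared pairs would silently collapse the multilinear person-rank (two
person components coupling to the same (b, c) pair merge into one), making
the planted complexity unrecoverable in principle.

What the generator does **not** emulate: ordinal measurement (graded
response), person-severity main effects (the synthetic ANOVA table is
dominated by the three-way term, unlike a real cohort's), informative
dropout beyond the geometric time weighting, and treatment-arm effects.
Passing tests therefore demonstrate correctness of the machinery and
recoverability under the stated conditions — not that any particular
clinical dataset meets those conditions.

## Numerical choices and degenerate inputs

* ALS convergence is declared at relative fit change < 1e-8; the fit of a
  larger model can land below a smaller one's only through local optima,
  which seeded random restarts (`n_starts`) resolve; tests use 15 restarts
  on deliberately hard tiny cubes.
* Integer clipping is OFF in all recovery tests (it breaks exactness) and
  available for realism experiments.
* Zero-variance item slabs, all-zero cubes, constant external variables,
  unimputable columns, persons with no observations, inadmissible rank
  triples (`P > Q·R` and permutations), and masked cells reaching a
  consumer that requires complete data all raise immediate, named errors
  rather than propagating NaNs. A constant cube's ANOVA reports zero
  shares with an explicit `zero_total` flag.
* Stage seeds in `run_pipeline` are derived deterministically from one
  master seed; a run is reproducible from its config alone, and the
  manifest records every derived seed.

## Problem sizes used by the test-suite

Unit tests run on cubes from 2 × 2 × 2 up to 80 × 10 × 6; the
cohort-scale experiments (recovery of a planted (3,2,2) structure through
8% missingness, 5 imputations and scree selection over 20 seeds, and the
acceptance script's full 20-imputation pipeline) use the emulated
219 × 21 × 9 shape. These sizes keep the whole suite in the minutes range
while exercising every code path at the study's true dimensionality.

## Known limitations

* Rotations are orthogonal only; correlated components (oblique rotation
  of core and components simultaneously) are out of scope.
* The imputer is multivariate-normal with a single EM point estimate per
  bootstrap replicate (no posterior draws of (μ, Σ) beyond the bootstrap);
  chained equations and ordinal-aware imputation are out of scope.
* Missing-data-aware ALS is deliberately absent: missingness is handled
  upstream by imputation, and the decomposition always sees complete
  cubes.
* The trend-inclusive fit accounting is one principled convention (common
  normalized scale, orthogonal trend/model split); other accountings exist
  and would shift the total-fit number, not the model.
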