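---
title: "Joint meta-analysis of correlated binary outcomes: models, assumptions and design choices"
author: "mvbmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint meta-analysis of correlated binary outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvbmeta)
```

## The problem

Systematic reviews of interventions — obstetric reviews are the motivating
case — routinely report several binary outcomes per trial: caesarean birth
and instrumental vaginal birth, perinatal death and a composite of death or
serious morbidity, intra- and post-operative nausea and vomiting. Because
the same patients contribute to every outcome, the trial-level effect
estimates are correlated. Standard practice pools each outcome separately
(univariate meta-analysis, UVMA), discarding that correlation. Multivariate
meta-analysis (MVMA) pools the outcomes jointly, which lets an outcome
borrow strength from studies that reported only its correlated companions —
potentially tightening intervals and partially correcting selective
outcome-reporting bias — at the price of a harder estimation problem that
may fail to converge.

This package implements the full pipeline for comparing the two approaches
on multi-outcome 2×2-table data: effect derivation, analytic within-study
correlations for structurally related outcomes, REML estimation of the
univariate, fully hierarchical multivariate and Riley overall-correlation
models, comparison reporting with funnel diagnostics, and a synthetic-data
generator that reproduces the statistical structure of such reviews.

## Effect derivation and sparse-data rules

For a 2×2 table with `a` events among `n_t` treated and `c` events among
`n_c` controls, the log odds ratio is
`y = log[(a/(n_t−a)) / (c/(n_c−c))]` with variance
`s² = 1/a + 1/(n_t−a) + 1/c + 1/(n_c−c)`.

Two sparse-data rules apply, in this order:

* **Double-zero studies.** If no events occurred in either arm, the study
  carries no information about the odds ratio for that outcome; the outcome
  is treated as missing in that study (the study receives zero weight).
  The same table with all events in *both* arms is not excluded — it falls
  through to the continuity correction below, which is the only reading
  under which every remaining table yields a finite estimate.
* **Continuity correction.** If any of the four cells is zero (0% or 100%
  events in one arm), 0.5 is added to all four cells before computing `y`
  and `s²`, and the estimate is flagged `correction_applied`.

## Analytic within-study correlations

The fully hierarchical model needs the within-study correlation ρ_W between
two outcomes' log ORs. With only published aggregate data this is available
exactly when the outcomes are structurally related:

* **Mutually exclusive outcomes** (no patient can have both, e.g. vaginal
  birth vs caesarean): per arm the two event counts and the remainder are
  multinomial, which by the delta method induces covariance
  `−n / ((n−a)(n−b))` between the two log odds. Summing the two arms and
  standardising gives ρ_W ≤ 0.
* **Subset outcomes** (every subset event is a superset event, e.g.
  caesarean within operative birth): nested sampling gives per-arm
  covariance `n / (a_sup (n − a_sub))`, hence ρ_W ≥ 0, and ρ_W = 1 exactly
  when the two outcomes have identical event counts in both arms — they are
  then observationally indistinguishable.

Both formulas are validated in the test suite against Monte-Carlo oracles
that draw ≥10⁵ per-arm multinomial (or nested binomial) replicates and
correlate the resulting log ORs; agreement is required within 0.02
absolute over a 20-point grid of count configurations.

Three numerical conventions, chosen where the published record is silent:

* When a table triggered the 0.5 correction, its correlations are computed
  from the *corrected* counts, so the diagonal and off-diagonal of the
  assembled within-study covariance matrix S are mutually consistent.
  Tables are corrected independently of their partner in the pair; the
  per-arm effective total is the geometric mean of the two tables'
  effective totals, which preserves the exact ρ_W = 1 identity for
  identical subset counts even under correction.
* Correlations are clamped to ±0.999999 before matrix assembly so S is
  never exactly singular; the raw value is preserved in the correlation
  export.
* A user-supplied fixed correlation matrix (used for sensitivity analyses
  on structurally unrelated pairs) can make an assembled S indefinite for
  3+ outcomes; the off-diagonals are then shrunk toward zero by the
  smallest uniform factor restoring positive semi-definiteness
  (eigenvalue floor 10⁻⁸), with a warning.

## The three models

All models work on the log OR scale and are estimated by restricted
maximum likelihood (REML) by default; ML is available for testing.

**Univariate:** `y_i ~ N(μ, s_i² + τ²)` per outcome. τ² maximises the
profiled restricted likelihood, searched on the log-variance scale with an
explicit boundary comparison at τ² = 0 (objective tolerance 10⁻⁸); μ is the
inverse-variance-weighted mean at the fitted τ².

**Fully hierarchical multivariate:** `y_i ~ N(μ, S_i + Σ)` with S_i the
within-study covariance (variances plus analytic or fixed ρ_W) and Σ the
between-study covariance. Studies missing some outcomes contribute their
observed sub-vector and the matching sub-matrix of S_i + Σ. Σ is
parameterized by its Cholesky factor with log-transformed diagonal, which
keeps it positive semi-definite without constraints and lets between-study
correlations reach ±1 (boundary solutions are common and are reported at
the boundary with a flag, not treated as errors).

**Riley overall-correlation model:** when ρ_W is not calculable, the
marginal model gives outcome j of study i variance `s_ij² + ψ_j²` and each
within-study pair (j,k) covariance `ρ_jk √((s_ij²+ψ_j²)(s_ik²+ψ_k²))`,
with one overall correlation ρ_jk per outcome pair amalgamating within- and
between-study correlation (an option shares a single ρ across pairs; the
per-pair default matches how fixed-correlation sensitivity analyses are
specified). ρ is optimized on the Fisher-z scale, boxed at |ρ| = 1 − 10⁻⁶.
A complete fixed-correlation matrix gives the `riley_fixed` variant in
which only (μ, ψ) are estimated — the form used to approximate a
trivariate model when one bivariate correlation cannot be estimated.

In every model the summary effects μ are profiled out by generalized least
squares inside the objective, so the optimizer only searches the variance
parameters (3 for a free bivariate Σ). Model choice in `fit_all_pairs()`
follows the data: hierarchical wherever a complete S is available for every
study reporting the pair, Riley otherwise.

## Standard errors

Standard errors of the summary effects come, by default, from the observed
information of the joint restricted objective in (μ, variance parameters)
at the optimum, so they carry the uncertainty of the estimated
between-study variances and covariances; the plain GLS covariance
`(Σ XᵢᵀVᵢ⁻¹Xᵢ)⁻¹` is exposed behind a flag for comparison. Parameters
pinned at a boundary are excluded from the information computation (their
uncertainty is not quadratic); if the information matrix is not positive
definite the GLS covariance is used and the fit records that fallback.
95% intervals use the normal quantile 1.96 throughout — no small-sample
(Knapp–Hartung type) adjustment — matching how such comparisons are
conventionally reported.

## Convergence policy

Multivariate REML surfaces are notoriously prone to flat ridges and
boundary solutions, so non-convergence is a first-class, reportable state
(`failed_convergence`, rendered `FC` in comparison tables), never an
exception. A fit is declared converged when:

1. the optimizer (bounded quasi-Newton, central-difference gradients with
   step 10⁻⁶) stopped under the objective tolerance rather than the
   iteration cap;
2. the gradient on the unconstrained parameter scale is numerically zero
   (norm < 10⁻⁵ relative to the objective magnitude) in all directions not
   pinned at a boundary — a correlation counts as pinned when its estimate
   is within 10⁻⁴ of ±1; where ill-conditioning makes the raw gradient
   norm unattainable, the Newton decrement gᵀH⁻¹g/2 (the attainable
   objective improvement) must be below 10⁻⁶ relative;
3. the Hessian over the non-pinned parameters is positive semi-definite to
   relative tolerance 10⁻⁶.

Failing runs are retried: the second start warm-restarts from the best
solution (resetting the quasi-Newton state, which rescues most
boundary-region stalls), later starts add seeded random jitter, up to
`n_random_starts` (default 10). When an estimate sits near a correlation
boundary, the remaining parameters are re-polished with the correlation
held exactly at the boundary before the criteria are evaluated. Two
structural situations short-circuit to `failed_convergence` immediately:
no study reports two outcomes jointly (correlations are unidentifiable),
and — as an error, since it violates the model's preconditions — an
outcome with fewer than two reporting studies.

## The synthetic-data generator

The generator emulates what a multi-outcome intervention review provides:
per study, a per-arm size drawn uniformly from `n_range` (same size in
both arms, as in a balanced trial); study-level true log ORs drawn from
`N(μ, D ρ_B D)` with `D = diag(τ)` — the random effect acts on the
contrast, applied on the logit scale to a fixed control-arm baseline risk,
matching the contrast-level random-effects models being fitted; and event
counts drawn respecting the declared structure (multinomial cells for
mutually exclusive groups, nested binomials for subset chains, independent
binomials otherwise). Degenerate arms are kept generable: if random
effects push a mutually exclusive group's probabilities to sum ≥ 1 they
are rescaled to 0.99, and a subset's conditional probability is capped at
1; both events are essentially impossible under the shipped scenarios.

Missing outcomes arise three ways: not at all; completely at random
(each designated outcome-study cell deleted with probability p); or by
**significance-driven selective reporting** — a designated outcome's
result is deleted with probability `prob` when its two-sided Wald p-value
exceeds `threshold` (default 0.05) *and* its per-arm size is below the
dataset's median study size. Small null results go unreported; small
significant ones survive; the reported evidence acquires exactly the
funnel-plot asymmetry that flags small-study effects.

The packaged `review7_scenario()` reproduces the reporting pattern of a
four-outcome review (outcomes structurally reported by 8/8/4/5 of 10
studies, the second thinned further by selective reporting), with
between-study SD 0.8 and between-study correlation 0.9. Those two values
are deliberately at the strong end: the review this scenario emulates
itself exhibited between-study SDs of 0.7–1.2 and estimated cross-outcome
correlations up to ~0.95, and high heterogeneity is what equalizes study
weights enough for the withheld small studies to move the pooled estimate
(with τ ≈ 0.3 the same mechanism produces a bias of only ≈ −0.04 on the
log OR scale — a regime in which univariate and multivariate results are
practically indistinguishable). Deletion severity is 1 (small
non-significant results always withheld), the strongest form of the
mechanism. Under this scenario the univariate summary for the selectively
reported outcome is biased away from the null by ≈ 0.07–0.13 on the log
OR scale, and a bivariate Riley fit with the fully reported first outcome
lands closer to the generating truth in roughly 60–66% of replicates —
the borrowing-of-strength attenuation the comparison is designed to
surface. Because the selection rule is two-sided, survivors extreme in
either direction partially cancel; a one-sided (direction-favouring)
rule would bias harder, but the two-sided rule is the cleaner mechanism
to test against.

What the generator does *not* emulate: unbalanced arms, covariate-driven
(MNAR beyond the significance rule) reporting, baseline-risk
heterogeneity across studies (the random effect is on the contrast only),
and arm-level rather than contrast-level correlation structure. Passing
tests therefore demonstrate correctness of the estimation machinery under
the stated generating mechanism, not robustness of MVMA on arbitrary real
reviews.

## Problem sizes and numerical checks

The shipped property suites use: a 20-point count-configuration grid with
10⁵ Monte-Carlo replicates per configuration for the correlation
formulas; 500 simulated bivariate meta-analyses of k = 20 studies
(μ = (−0.7, −0.4), τ = 0.3, ρ_B = 0.7, subset structure, baseline risks
0.15/0.35, per-arm sizes 50–500) for parameter recovery; 40 replicates
for the fixed-parameter missing-data efficiency property; and 200
replicates of the selective-reporting scenario. Optimizer agreement is
checked against brute-force grid searches (τ and ρ in steps of 10⁻⁴) of
independently coded restricted-likelihood surfaces, and against an
independent multivariate REML implementation (`metafor::rma.mv`) on
matched datasets.

## Known limitations

* **Wald under-coverage with sparse outcomes.** With a rare subset outcome
  (baseline risk 0.15, per-arm sizes from 50), 95% Wald intervals from the
  hierarchical model cover the true summary log OR at ≈ 0.90 rather than
  0.95 at k = 20; the companion outcome with baseline 0.35 covers at
  ≈ 0.93. This is a property of plug-in within-study variances and REML
  τ̂ shrinkage on sparse binary data, not of this implementation — an
  independent multivariate REML implementation produces essentially
  identical standard errors and no better coverage on the same
  replicates.
* The hierarchical fitter requires a complete within-study covariance for
  every study reporting ≥ 2 outcomes; it does not mix analytic and
  "assume zero" entries silently — route such datasets to the Riley model
  or supply fixed correlations explicitly.
* Fixed within-study correlations are applied uniformly across studies;
  per-study externally supplied correlations are not supported.
* The Riley model's likelihood can be unbounded as ρ → ±1 when one
  outcome's effects are an exact affine copy of another's (zero residual
  variance in the difference direction); the Fisher-z box at
  |ρ| = 1 − 10⁻⁶ makes the fit well-defined, and such fits report the
  boundary flag.
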