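---
title: "Methods: cytoarchitectonic gray-matter density and its longitudinal statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cytoarchitectonic gray-matter density and its longitudinal statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytogmd)
```

## Regional density extraction

A modulated gray-matter map assigns every voxel a nonnegative density
`g_v`; a cytoarchitectonic probabilistic map assigns every voxel the
probability `w_v` (0–1) that it belongs to a microscopically defined region.
The regional density is the `w`-weighted mean of `g`, with numerator and
denominator pooled across the two hemispheres *before* division:

$$\mathrm{GMD} = \frac{\sum_v g_v w_v^L + \sum_v g_v w_v^R}
                      {\sum_v w_v^L + \sum_v w_v^R}.$$

Pooling-then-dividing weights each hemisphere by its total probability mass;
a `per_hemisphere` option divides each hemisphere separately for users who
want lateralised values. Because the estimator is a weighted mean it is (i)
linear in `g`, (ii) invariant to rescaling all weights of a region by a
positive constant, and (iii) bounded by the extremes of `g` on the region's
support. The test suite checks all three properties against a brute-force
triple-loop oracle at 1e-12 relative tolerance.

Design choices that were genuinely open:

* **Probability scale.** Atlas files are distributed both on a 0–1 and a
  0–100 scale. The loader normalises to 0–1; `scale_hint = "auto"` divides
  by 100 whenever the maximum exceeds 1. The quotient above is invariant to
  this, but the type invariants need a fixed internal scale.
* **Atlas placement.** Cytoarchitectonic maps conventionally need a small
  rigid correction when moved into standard MNI space;
  `apply_atlas_translation()` applies +4 mm along y and +5 mm along z *to
  the atlas affine* (atlas moved toward the data). The direction is not
  fixed by convention everywhere, so the signs are plain arguments and the
  shift is exactly invertible.
* **Grid mismatch.** A shape mismatch between data and atlas is a hard
  error by default. Nearest-neighbour resampling through the two affines is
  available (`resample = TRUE`) but deliberately opt-in: silent resampling
  hides registration bugs.
* **Field of view.** Voxels with `w > 0` that fall outside the gray-matter
  volume contribute `g = 0` — modulated maps are defined everywhere, so a
  zero there is a statement about tissue, not missingness.

## The synthetic cohort generator

`simulate_cohort()` emulates a two-group longitudinal MRI study of the
MIRIAD design: AD and HC subjects scanned at 0, 0.5, 1.5, 3.5, 6.5, 9.5, 12,
18 and 24 months, with duplicate same-session scans at 0, 1.5 and 9.5
months. (Study descriptions of this design disagree between 1.5 and 2.5
months for the second replicate session; the subject-protocol description is
taken as primary and 1.5 is the default, overridable via
`replicate_months`.) For subject *i*, region *r* at month *t*:

$$\mu_{ir}(t) = \bigl(b_r\,\delta_{g(i)} + u_{0i}\bigr) +
               \bigl(s_{r,g(i)} + u_{1i}\bigr)\,t,
  \qquad y = \mu_{ir}(t) + \varepsilon,$$

with \((u_0, u_1)\) bivariate normal across subjects and
\(\varepsilon \sim N(0, (\tau b_r)^2)\) independent per scan. MMSE follows a
group-specific linear trend with a subject-level baseline, clamped to
[0, 30] and kept continuous (no integer rounding) so that recovery tests are
exact in the noise-free limit.

Parameters anchored to the emulated study design: group sizes 41/21; the
visit schedule above; AD baseline deficit 19.1% (`ad_baseline_deficit =
0.191`); AD decline 81.6% faster than HC (`ad_slope_multiplier = 0.816`);
MMSE slopes −0.23 points/month in AD and 0 in HC; age 69.1 ± 6.7 years.
Parameters the design does not fix are package choices, set once to
plausible values for modulated VBM and documented here rather than tuned:

| parameter | default | rationale |
|---|---|---|
| region baselines `b_r` | 0.39–0.56 (unitless GMD) | typical modulated-VBM regional means; subcortical regions slightly denser |
| `hc_slope` | −5e-4 · b_r /month | small "healthy-aging" decline; real HC rates are not published per region, so this is explicitly a stand-in |
| `random_intercept_sd` | 0.03 GMD | ≈6% between-subject baseline spread |
| `random_slope_sd` | 3e-4 GMD/month | subject slope heterogeneity of the order of the mean slope |
| `intercept_slope_corr` | 0.3 | lower-baseline subjects decline a little faster |
| `within_session_noise_sd` | 0.01 · b_r | calibrated so within-session ICC lands in ≈0.96–0.99, the regime reported for this measurement technique |
| MMSE baselines | AD 22, HC 29 | inclusion-criteria midpoints (AD 12–26, HC > 26) |

Noise is multiplicative in the region baseline so percent-change statistics
are comparable across regions of different magnitude. Dropout is off by
default (`dropout_prob`). What the generator does *not* emulate: scanner
drift and bias fields, nonlinear (accelerating) atrophy, floor effects in
severe disease, and MMSE's integer scoring. Passing recovery tests therefore
demonstrate that the estimators are correct for linear mixed trajectories
with Gaussian noise — not that real MRI meets those assumptions.

## Reliability statistics

**Percent change** is `100·(2nd − 1st)/1st` per same-session pair. The
within-session model has a fixed intercept (HC mean % change), a fixed
AD−HC difference, and a per-subject random intercept, since a subject
contributes up to three replicate sessions; inference is Wald with a normal
reference (small-sample df corrections are out of scope).

**ICC.** Replicate scans within a session are exchangeable and there is no
rater or occasion effect, so the one-way random-effects ICC(1) is the
default variant: `ICC = (MSB − MSW)/(MSB + MSW)` at k = 2. The exact
interval is Searle's construction from `F0 = MSB/MSW` with
(n−1, n) degrees of freedom, mapping the F limits through
`(F−1)/(F+1)`. Each subject-session pair is treated as one exchangeable
entity when pooling sessions; at k = 2 the estimator is bounded below by −1,
and a zero-variance input is an error, never `NaN`.

**I2C2** extends the ICC to the vector of all regions per scan: a
trace-ratio `1 − tr(Σ̂_U)/tr(Σ̂_W)`, with the within-subject trace estimated
from replicate deviations around subject means and the total trace from all
scans around the grand mean. It reduces exactly to the univariate variance
ratio for one region. The confidence interval resamples *subjects* with
replacement (percentile interval, default B = 1000; percentile rather than
BCa for simplicity and reproducibility), counting and skipping degenerate
resamples.

**Bland–Altman** works on log-ratios: geometric mean ratio `exp(mean l)`,
limits of agreement `exp(mean l ± 1.96 sd l)` (the conventional 1.96 rather
than an exact t multiplier; the multiplier is an argument), and a one-sample
t-test of `mean l = 0`.

## Random-coefficient regression

`fit_rcr_region()` fits, per region,

$$y_{ij} = \beta_0 + \beta_g\,\mathrm{AD}_i + \beta_t\,t_{ij}
         + \beta_{gt}\,\mathrm{AD}_i t_{ij} + \beta_a\,\mathrm{age}_i
         + \beta_s\,\mathrm{male}_i + u_{0i} + u_{1i} t_{ij}
         + \varepsilon_{ij}$$

with an unstructured 2×2 random-effect covariance, REML estimation and Wald
inference. Conventions: HC and female are reference levels; age enters
uncentred (the intercept is the adjusted mean at age 0 — recentring is a
one-liner and changes only the intercept, which the tests verify); only the
first scan of each session is used, because same-session replicates would
understate the residual variance unless a session effect were modelled. The
headline percentages are `100·(−β_g)/β_0` (baseline deficit) and
`100·β_{gt}/β_t` (percent-faster decline, reported as `NA` when the HC
slope is within a configurable floor of zero, where the ratio is
meaningless).

Numerical choices: the optimizer is bobyqa with `rhoend = 1e-10`, chosen
because the default optimizer stops early enough on these strongly scaled
problems (slopes of order 1e-4 against intercepts of order 0.5) to break
the algebraic invariance of slope estimates under time-origin shifts;
with the tighter setting the invariance holds to ~1e-9. Exactly
deterministic inputs (noise-free simulations) would put REML on the
boundary, so a zero-residual OLS fit short-circuits the mixed model and
returns exact coefficients with zero covariance. Singular random-effect
fits are refit with a diagonal covariance and flagged
(`refit_diagonal = TRUE`); non-convergence is reported on the fit object and
downstream consumers (`detection_table()`, `run_pipeline()`) propagate `NA`
rather than failing.

**MMSE models.** `mmse_trend()` uses cell-means coding (per-group intercepts
and slopes) with random intercept + slope, and Wald F-tests (1 df) for each
group's slope and the between-group contrasts. `change_change_rcr()`
regresses per-subject changes-from-baseline of MMSE on changes of GMD with
group-specific slopes and a random intercept; a constant ΔGMD is a
degenerate error. The dependent variable is ΔMMSE and the regressor ΔGMD —
the only reading under which a "change as a function of change" model is
well-posed.

## Detection interval

From the AD-only fit, `Q(t) = 0.005·β0 + β1·t` is the expected density
change at follow-up `t` plus 0.5% of baseline; a 0.5% loss is established
when the upper confidence limit of `Q(t)` is negative. The variance is the
delta-method form including the β0–β1 covariance (a diagonal-only option
reproduces implementations that drop it), the multiplier is the normal
z = 1.96 (configurable — the exact reference distribution is a matter of
taste at these df), and the scan runs over 0.5–24 months in 0.5 steps. The
0.005 threshold is an argument, so 1% sensitivity analyses are one call.
The grid scan is validated against an independent bisection root of
`Q(t) + z·SE(t) = 0` on random parameter draws: the reported month is always
the first grid point at or after the analytic crossing.

## Multiple testing

The per-rank threshold table for a 27-test family at α = 0.05 that this
package reproduces follows the Holm-type step-down sequence `α/(m−k+1)` —
rank 1 gets α/27 ≈ 0.00185, rank 27 gets α — even though such tables are
often labelled "Benjamini–Hochberg". Both are provided:
`paper_stepdown` (default, with the step-down prefix rejection rule) for
fidelity to the published threshold columns, and `bh_classic` (`αk/m`, with
the usual step-up rule). They coincide at rank m and for m = 1. Ties in the
p-values keep input order (stable sort), and flags are reported against the
original region labels.

## Test scale and runtime choices

The simulation-based tests use sizes chosen to make Monte-Carlo noise small
relative to the assertion bands while keeping the default suite around two
minutes on one core: 200 replicate cohorts of 60 subjects for the RCR bias,
coverage and type-I checks; 200/200 subjects for MMSE slope recovery;
n = 200 subjects × 27 regions for I2C2 trace-ratio recovery (±0.05 band);
50 random voxel scenes up to 16³ for the extraction oracle. Pipeline
determinism is checked byte-for-byte on a reduced four-region cohort.

## Known limitations

* Wald/normal inference throughout; no Satterthwaite or Kenward–Roger df.
* The detection statistic assumes linear decline over the full two years.
* The generator shares one random-intercept scale across regions (additive,
  not proportional), which mildly overstates relative heterogeneity in
  low-density regions.
* Nearest-neighbour atlas resampling is adequate for the toy scenes used in
  tests; real cross-grid work should resample with proper interpolation
  upstream.
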