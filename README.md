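# cytogmd

Regional gray-matter density (GMD) from cytoarchitectonic probabilistic
atlases, and the statistics needed to trust it longitudinally.

## The problem

Voxel-based morphometry turns a T1-weighted MRI into a modulated gray-matter
density field `g`. A cytoarchitectonic probabilistic atlas supplies, for each
brain region and hemisphere, a map `w` giving the probability that a voxel
belongs to the region (derived from stained post-mortem tissue rather than
macroanatomical landmarks). The regional density is the probability-weighted
mean, pooled bilaterally before standardization:

```
GMD_region = ( Σ_v g_v w_v^L + Σ_v g_v w_v^R ) / ( Σ_v w_v^L + Σ_v w_v^R )
```

In studies of Alzheimer's disease (AD) against healthy controls (HC) —
the MIRIAD design, with visits at 0, 0.5, 1.5, 3.5, 6.5, 9.5, 12, 18 and 24
months and duplicate same-session scans at three visits — four statistical
questions follow, and this package implements all of them:

1. **Test–retest reliability** of the regional measurements: a within-session
   percent-change mixed model, the one-way intraclass correlation ICC(1) with
   Searle's exact F-based confidence interval, the multivariate image
   intraclass correlation (I2C2, a trace-ratio extension of ICC across all
   regions) with a subject-level bootstrap interval, and Bland–Altman ratio
   analysis on the log scale.
2. **Random-coefficient regression (RCR)**: GMD modelled as
   `intercept + group + time + group×time + age + gender` with per-subject
   random intercepts and slopes (REML, Wald inference), yielding the adjusted
   baseline deficit and the percent-faster decline in AD; plus MMSE trends
   and change–change (ΔMMSE on ΔGMD) models.
3. **Minimum detectable atrophy interval**: from the AD-only fit
   (β₀ = baseline GMD, β₁ = GMD/month), the smallest follow-up time `t` on a
   0.5-month grid at which the 95% CI upper limit of
   `Q(t) = 0.005·β₀ + β₁·t` falls below zero — i.e. a 0.5% loss of baseline
   density is statistically established.
4. **Multiplicity control** across the 27-region family: the step-down
   per-rank threshold sequence `α/(m−k+1)` (with classic Benjamini–Hochberg
   `αk/m` selectable).

A synthetic MIRIAD-like cohort generator (`default_params()`,
`simulate_cohort()`) with known ground truth makes the full pipeline testable
without any imaging download, and `simulate_voxel_scene()` builds toy
NIfTI-scale voxel scenes with exact oracle truth for the extraction code.

## Worked example

```r
library(cytogmd)

params <- default_params(n_ad = 20, n_hc = 12, seed = 42)
sim    <- simulate_cohort(params)

# reliability of the two same-session scans in CA2
pairs <- replicate_pairs(sim$cohort, "CA2")
icc   <- icc_oneway(pairs$first, pairs$second)

# two-group random-coefficient regression, then the AD-only detection fit
fit <- fit_rcr_region(sim$cohort, "CA2")
pct <- group_percent_difference(fit)
det <- minimum_detectable_time(fit_rcr_region(sim$cohort, "CA2",
                                              groups = "ad_only"))
```

Output (seed 42):

```
CA2 within-session ICC: 0.990 (95% CI 0.985-0.993)
AD baseline deficit: 15.8%; AD decline 97.3% faster
0.5% loss detectable after 11.0 months
```

The ICC near 0.99 reflects the generator's calibration of within-session
noise to about 1% of the regional baseline. The deficit and percent-faster
estimates recover the generator's inputs (19.1% and 81.6%) up to sampling
noise at this small n; the detection interval is long here because a cohort
of 20 AD subjects pins down β₁ far less precisely than the full design.
`run_pipeline(pipeline_config(out_dir))` chains all stages and writes the
per-region CSV tables plus a JSON manifest; reruns with the same config are
byte-identical.

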