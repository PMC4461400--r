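# burstfit

Transcriptional burst kinetics from single-cell mRNA count distributions.

Gene expression in clonal mammalian cell populations is noisy, and much of
that noise is transcriptional: promoters flip stochastically between a
silent *Off* state and a productive *On* state, releasing mRNA in bursts.
When the same reporter is integrated at many different genomic positions,
both the mean and the width of the per-cell expression distribution vary
from clone to clone, and the question becomes *which kinetic parameter the
genomic environment tunes*. `burstfit` is an R toolkit for answering that
question from per-cell mRNA counts (e.g. smFISH), flow-cytometry readouts
and DNase-qPCR chromatin accessibility panels. It is aimed at groups
running integration-site / reporter-clone studies of expression noise.

## The model and the statistics at its core

Under the two-state (telegraph) model with Off→On rate `k_on`, On→Off rate
`k_off`, transcription rate `k_m` (On only) and mRNA degradation rate `δ`,
the stationary mRNA copy number is beta-Poisson:

    p(n) = ∫₀¹ Pois(n; λx) · Beta(x; α, β) dx,
    α = k_on/δ,  β = k_off/δ,  λ = k_m/δ

with mean `λα/(α+β)` and variance `mean + λ²αβ/[(α+β)²(α+β+1)]`. The
package works in the effective burst parameterization — burst size
`b = k_m/k_off`, burst frequency (normalized On rate) `f = k_on/δ` — and
provides:

* exact stationary pmf/moments/sampling plus a Gillespie SSA oracle
  (`stationary_pmf`, `analytic_moments`, `sample_stationary`,
  `gillespie_simulate`);
* per-clone maximum-likelihood estimates of `(b, f)` at fixed `λ`, with 95%
  profile-likelihood CIs at the 1.92 log-likelihood-ratio offset
  (`fit_clone`, `profile_ci`, `fit_cohort`);
* bootstrap moment summaries and log-log scaling regressions with Spearman
  statistics, slope t-tests against the Poisson null and subset-vs-full
  F-tests (`bootstrap_moments`, `loglog_regression`, `slope_test`,
  `compare_regressions_ftest`);
* flow-cytometry density-mode scatter gating, Ward clustering of clone
  distributions on (log mean, log CV), matched-mean noise-pair selection
  and Poisson MOI inversion (`density_mode_gate`,
  `cluster_clone_distributions`, `select_noise_pairs`, `infer_moi`);
* DNase-qPCR chromatin inaccessibility (`I = 2^-ΔCt` normalized to a
  reference locus), kinetics–accessibility regressions and PCA
  (`inaccessibility_from_ct`, `kinetics_accessibility_regression`,
  `chromatin_pca`);
* a fully seeded synthetic-cohort generator encoding the study's
  statistical structure — independent burst-size/burst-frequency variation,
  buffered GFP readout, chromatin–kinetics coupling, qPCR decay time
  courses — with recorded ground truth (`cohort_config`,
  `generate_cohort`).

## Worked example

```r
library(burstfit)

## one clone: simulate 600 cells from known kinetics, then refit them
tp <- telegraph_params(k_on = 0.5, k_off = 100, k_m = 1000, delta = 1)
d  <- sample_stationary(tp, n_cells = 600, seed = 11)
fit_clone(d, delta = 1, lam = 1000)
#> Burst-parameter fit 'clone' (600 cells)
#>   burst size  b = 9.27  [7.78, 11.2]
#>   burst freq  f = 0.523  [0.455, 0.6]
#>   NLL = 1559.5133, converged = TRUE, boundary = FALSE
```

The true burst size (10) and burst frequency (0.5) fall inside the profile
CIs. At cohort scale:

```r
cfg <- cohort_config(n_clones = 40, cells_per_clone = 300, seed = 7)
coh <- generate_cohort(cfg)

mom <- cohort_moments(coh$counts)
loglog_regression(mom$mean, mom$variance)
#> log-log OLS: slope 1.693 +/- 0.062 (95% CI 1.566..1.819), R2 = 0.951
#>   Spearman rs = 0.965, p_slope = 1.8e-26, p_spearman = 1.25e-23, n = 40

cf <- fit_cohort(coh$counts_df, delta = 1, lam = 1000)
cf$regressions$f_vs_cv
#> log-log OLS: slope -0.526 +/- 0.025 (95% CI -0.576..-0.476), R2 = 0.922
#>   Spearman rs = -0.941, p_slope = 1.23e-22, p_spearman = 1.74e-19, n = 40

prof <- chromatin_profiles(generate_chromatin_panel(coh$truth, cfg))
kinetics_accessibility_regression(prof, cf$fits, "Nuc-1")$fit
#> log-log OLS: slope -0.763 +/- 0.150 (95% CI -1.067..-0.458), R2 = 0.403
#>   Spearman rs = -0.626, p_slope = 1.07e-05, p_spearman = 1.55e-05, n = 40
```

Reading the numbers: the variance–mean slope (1.69) sits between Poisson
scaling (1) and pure burst-size modulation (2), the signature of bursty
transcription with most clone-to-clone variation in burst size; expression
noise falls with fitted burst frequency at the −1/2 power, so promoter
activation rate, not burst size, sets the noise; and burst frequency
declines with Nuc-1 chromatin inaccessibility — clones with more closed
promoter-proximal chromatin burst less often.

See `vignettes/burst-kinetics.Rmd` for the model, the numerical strategy,
the generator calibration and its limitations.

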