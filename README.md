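# occuband

Bayesian joint modelling of detection/non-detection surveys and banding
(capture–recapture) data for estimating abundance, apparent survival and
recruitment — plus the monitoring-design side of the question: what does the
second data type cost, and how much estimator precision does it buy?

The package is aimed at population ecologists designing or extending
multi-year monitoring programs, in settings like a post-wildfire songbird
study: cheap point-count surveys across a whole landscape, and expensive
banding at a subset of nest-box sites.

## The models

**Dynamic N-occupancy (point-count) model.** Site abundance follows a
demographic state process

    N_j1 ~ Poisson(lambda_j)
    S_jt ~ Binomial(N_j,t-1, phi_jt)      (survivors)
    G_jt ~ Poisson(gamma_jt)              (gains: births + immigration)
    N_jt = S_jt + G_jt

with log/logit-linear regressions of `lambda`, `phi`, `gamma` on burn
severity (dNBR), a nest-box indicator, time since fire, live and snag basal
area, and a transect random effect. Binary detections follow the
Royle–Nichols observation law `Y ~ Bern(1 - (1 - p)^N)` with an observer
random effect in `p`.

**State-space Cormack–Jolly–Seber model.** Banding histories, conditional
on first capture: latent alive states `Z_it ~ Bern(Z_i,t-1 * phi_jt)` and
resightings `Y_it ~ Bern(Z_it * p_Bi)` with a sex effect in `p_B`.

**Joint model.** Both likelihoods share the same survival regression (the
`b` block); everything else is as in the single models. Fitting is by a
Metropolis-within-Gibbs sampler (Rcpp) with integer random-walk updates for
the latent abundances, full-conditional updates for the alive states, and
optional Kuo–Mallick indicator variable selection on every slope
coefficient. See the methods vignette (`vignettes/occuband-methods.Rmd`)
for the full model, priors, sampler and design choices.

## A worked example

```r
library(occuband)

design <- study_design(n_sites = 75, n_transects = 8, n_sessions = 3,
                       n_years = 5, nbox_fraction = 0.48, n_observers = 5,
                       seed = 1)
truth <- sim_occuband(design, seed = 42)   # covariates, population, data
truth
#> Synthetic study (seed 42)
#> Study design: 75 sites on 8 transects, 3 sessions x 5 years
#>   nest boxes at 36 sites; 5 observers; 0 unsurveyed site-session-years
#> Detection/non-detection data: 75 sites x 3 sessions x 5 years; 408 detections, 0 unsurveyed cells
#> Banding data: 71 individuals over 5 years; 113 detections (incl. first captures)

fit <- fit_occuband(truth$detections, truth$bandings, truth$covariates,
                    model = "joint", seed = 7)
fit
#> occuband fit: joint model
#>   75 sites x 5 years; 71 banded individuals
#>   3 chains x 20000 iterations (burn-in 10000, thin 5); 6000 retained draws
#>   max R-hat = 1.024

s <- summary(fit)
s[s$parameter %in% c("a0", "b0", "b4", "c0", "d0", "d1", "e0", "e1"), ]
#>  parameter median  lower  upper  rhat
#>         a0  0.266 -0.170  0.719 1.002
#>         b0  0.035 -0.733  0.701 1.001
#>         b4 -0.587 -0.970 -0.252 1.008
#>         c0 -0.425 -0.868 -0.009 1.000
#>         d0 -0.995 -1.655 -0.360 1.018
#>         d1  0.227 -0.149  0.596 1.014
#>         e0  0.314 -0.349  1.073 1.000
#>         e1  0.138 -0.403  0.695 1.000

bayes_pvalue(fit)
#> [1] 0.309
```

Reading the output: `exp(a0)` is the expected initial abundance per station
(posterior median ≈ 1.3 birds, shrunk from the generating 2.0 by the tight
coefficient priors), `plogis(b0)` the baseline annual apparent survival,
`b4` the snag-basal-area effect on survival (clearly negative here — its
generating value was −1), `plogis(d0)` the per-session detection
probability away from nest boxes, and `plogis(e0)` the banding resight
probability for sex code 0. The Bayesian p-value near the middle of (0, 1)
shows no evidence of lack of fit. Credible intervals are equal-tailed 95%
intervals; `rhat` below 1.1 indicates convergence.

Single-data fits use `model = "point"` or `model = "band"`; precision
comparisons and survey costs come from

```r
relative_bci(fit_point, fit_joint)   # (single - joint)/joint BCI lengths
cost_detection(study_cost_spec("point"))   # 69179
cost_banding(study_cost_spec("band"))      # 143232
cost_joint(study_cost_spec("joint"))       # 171431
```

`run_pipeline()` wires the whole simulate → fit × 3 → compare → cost
workflow from a YAML scenario into an output directory, with CSV tables, a
violin plot of the precision gains, and a provenance log.

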