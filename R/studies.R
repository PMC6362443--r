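#' Draw generating parameters from the prior distribution
#'
#' Samples a parameter set from the model priors, for use as simulation truth
#' in calibration experiments: when data are generated from parameters drawn
#' from the prior and the sampler is correct, posterior 95% credible
#' intervals cover the generating values at their nominal rate
#' (simulation-based calibration). Regression coefficients are drawn from
#' their normal priors and the baseline banding detection from its uniform
#' prior; random-effect scales are drawn from `sigma_range` - a realistic
#' subrange of their Uniform(0, 5) prior, since scales near the upper bound
#' produce ecologically absurd between-transect heterogeneity and are kept
#' out of the generating distribution on purpose.
#'
#' @param priors an `ob_priors`.
#' @param sigma_range range for the random-effect scales.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return An `ob_params` with `NULL` random-effect vectors (completed at
#'   simulation time).
#' @export
draw_params_from_priors <- function(priors = occuband_priors(),
                                    sigma_range = c(0.1, 0.5), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  co <- as.list(rnorm(length(priors$mean), priors$mean, priors$sd))
  names(co) <- names(priors$mean)
  e0 <- if (priors$e0_prior == "probability") qlogis(runif(1))
        else runif(1)
  do.call(occuband_params,
          c(co, list(e0 = e0, sigma_a = runif(1, sigma_range[1], sigma_range[2]),
                     sigma_d = runif(1, sigma_range[1], sigma_range[2]))))
}

#' Parameter-recovery (calibration) study for the joint model
#'
#' Repeatedly draws generating parameters from the priors, simulates a
#' synthetic study, fits the joint model, and records whether each 95%
#' credible interval covers its generating value, together with the
#' goodness-of-fit Bayesian p-value of the self-simulated fit. The default
#' problem size (75 sites, 5 years, 3 sessions, a marking rate giving a few
#' dozen banded individuals) is the smallest scale at which the
#' abundance-from-detection model is considered reliable.
#'
#' @param n_rep number of replicates.
#' @param design an `ob_design` shared by all replicates.
#' @param marking_rule banding intensity per year at nest-box sites.
#' @param priors an `ob_priors` (also the truth-generating distribution).
#' @param control an `ob_control`.
#' @param params_check names of parameters whose coverage is recorded.
#' @param seed integer seed.
#' @param verbose print one line per replicate.
#' @return List with `coverage` (logical matrix, replicate x parameter),
#'   `pvalues` (per-replicate GOF p-values), `truth` and `estimates`
#'   (medians) matrices.
#' @export
recovery_study <- function(n_rep = 20,
                           design = study_design(75, 8, 3, 5,
                                                 nbox_fraction = 0.48,
                                                 n_observers = 5, seed = 1),
                           marking_rule = 0.05,
                           priors = occuband_priors(),
                           control = mcmc_control(),
                           params_check = c("a0", "b0", "c0", "d0",
                                            "e0", "e1"),
                           seed = 1, verbose = FALSE) {
  cov <- est <- tru <- matrix(NA, n_rep, length(params_check),
                              dimnames = list(NULL, params_check))
  pval <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    sr <- seed + 1000 * r
    pars <- draw_params_from_priors(priors, seed = sr)
    truth <- sim_occuband(design, params = pars, marking_rule = marking_rule,
                          seed = sr + 1)
    fit <- fit_occuband(truth$detections, truth$bandings, truth$covariates,
                        "joint", priors = priors, control = control,
                        seed = sr + 2)
    s <- fit$summary
    rows <- match(params_check, s$parameter)
    tru[r, ] <- unlist(truth$params[params_check])
    est[r, ] <- s$median[rows]
    cov[r, ] <- tru[r, ] >= s$lower[rows] & tru[r, ] <= s$upper[rows]
    pval[r] <- bayes_pvalue(fit)
    if (verbose)
      message(sprintf("replicate %d: %d/%d covered, p = %.2f, max rhat %.2f",
                      r, sum(cov[r, ]), ncol(cov), pval[r], max(fit$rhat)))
  }
  list(coverage = cov, pvalues = pval, truth = tru, estimates = est)
}

#' Precision-gain study: single-data versus joint fits
#'
#' Simulates replicate studies at the generator's default (case-study-like)
#' conditions, fits the point-only, band-only and joint models to each, and
#' summarizes the relative credible-interval-length differences
#' (single - joint)/joint for apparent survival, abundance and recruitment
#' across all site-years. This reproduces the design of the published
#' precision comparison: survival is expected to gain most (it is the shared
#' parameter), then abundance, then recruitment, and adding banding to
#' detection data should help survival more than the reverse.
#'
#' @param n_rep number of replicate studies.
#' @param design an `ob_design`.
#' @param params generating `ob_params` (defaults are the package's
#'   case-study-like values).
#' @param marking_rule banding intensity.
#' @param priors,control fitting settings.
#' @param seed integer seed.
#' @param verbose print one line per replicate.
#' @return List with `per_rep` (data frame of per-replicate mean relative
#'   differences: `phi_point`, `N_point`, `G_point`, `phi_band`) and `means`
#'   (their averages over replicates).
#' @export
precision_study <- function(n_rep = 10,
                            design = study_design(75, 8, 3, 5,
                                                  nbox_fraction = 0.48,
                                                  n_observers = 5, seed = 1),
                            params = occuband_params(),
                            marking_rule = 0.3,
                            priors = occuband_priors(select = TRUE),
                            control = mcmc_control(), seed = 1,
                            verbose = FALSE) {
  per <- data.frame(phi_point = numeric(n_rep), N_point = numeric(n_rep),
                    G_point = numeric(n_rep), phi_band = numeric(n_rep))
  for (r in seq_len(n_rep)) {
    sr <- seed + 1000 * r
    truth <- sim_occuband(design, params = params,
                          marking_rule = marking_rule, seed = sr)
    fj <- fit_occuband(truth$detections, truth$bandings, truth$covariates,
                       "joint", priors = priors, control = control,
                       seed = sr + 1)
    fp <- fit_occuband(truth$detections, NULL, truth$covariates, "point",
                       priors = priors, control = control, seed = sr + 2)
    fb <- fit_occuband(NULL, truth$bandings, truth$covariates, "band",
                       priors = priors, control = control, seed = sr + 3)
    ap <- relative_bci(fp, fj)$aggregate
    ab <- relative_bci(fb, fj)$aggregate
    per$phi_point[r] <- ap$mean[ap$parameter == "phi"]
    per$N_point[r] <- ap$mean[ap$parameter == "N"]
    per$G_point[r] <- ap$mean[ap$parameter == "G"]
    per$phi_band[r] <- ab$mean[ab$parameter == "phi"]
    if (verbose)
      message(sprintf(
        "replicate %d: phi %.2f > N %.2f > G %.2f; phi (band) %.2f",
        r, per$phi_point[r], per$N_point[r], per$G_point[r], per$phi_band[r]))
  }
  list(per_rep = per, means = colMeans(per))
}

#' Indicator-selection calibration experiment
#'
#' Simulates one study in which one covariate has a strong effect and
#' another has none, fits the joint model with indicator variable selection,
#' and returns the posterior support (indicator posterior means). A
#' calibrated selection scheme gives the strong covariate support above 0.5
#' and the null covariate support below 0.5.
#'
#' @param design an `ob_design`.
#' @param strong named value of the strong coefficient (default: nest-box
#'   effect on detection, 1.5 on the logit scale).
#' @param null_coef name of the coefficient set to zero (default: nest-box
#'   effect on recruitment).
#' @param marking_rule,control,seed as elsewhere.
#' @return List with `support` (named indicator posterior means), and the
#'   names checked (`strong`, `null`).
#' @export
selection_study <- function(design = study_design(75, 8, 3, 5,
                                                  nbox_fraction = 0.48,
                                                  n_observers = 5, seed = 1),
                            strong = c(d1 = 1.5), null_coef = "c1",
                            marking_rule = 0.3,
                            control = mcmc_control(), seed = 1) {
  pars <- occuband_params()
  pars[[names(strong)]] <- unname(strong)
  pars[[null_coef]] <- 0
  truth <- sim_occuband(design, params = pars, marking_rule = marking_rule,
                        seed = seed)
  priors <- occuband_priors(select = TRUE)
  fit <- fit_occuband(truth$detections, truth$bandings, truth$covariates,
                      "joint", priors = priors, control = control,
                      seed = seed + 1)
  list(support = fit$vmeans, strong = names(strong), null = null_coef)
}
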