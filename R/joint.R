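#' Log posterior densities of the single and joint models
#'
#' Unnormalized log posterior (likelihood at the current latent states plus
#' log priors) for the three model variants. The joint posterior factors into
#' the occupancy state and observation terms, the CJS alive-transition and
#' resighting terms, and the priors - with the shared survival (`b`) block
#' counted exactly once. Consequently, for any parameter value,
#'
#' `joint = point + band - log prior(b block)`
#'
#' when the banding model keeps the full survival regression
#' (`include_nbox = TRUE`), an identity the test suite checks numerically.
#'
#' @param detections an `ob_detections` (may have zero surveyed cells).
#' @param bandings an `ob_bandings` (may have zero individuals).
#' @param covariates an `ob_covariates`.
#' @param pop an `ob_population` (latent N, S, G).
#' @param z latent alive matrix for the banded individuals.
#' @param params an `ob_params` with random effects materialized.
#' @param priors an `ob_priors`.
#' @param include_nbox see [cjs_marginal_loglik()].
#' @return Scalar unnormalized log posterior density (`-Inf` if any component
#'   is impossible).
#' @export
joint_log_posterior <- function(detections, bandings, covariates, pop, z,
                                params, priors = occuband_priors()) {
  occu_loglik_all(detections, covariates, pop, params) +
    cjs_loglik_all(bandings, covariates, z, params) +
    log_prior(params, priors, "joint")
}

#' @rdname joint_log_posterior
#' @export
occu_log_posterior <- function(detections, covariates, pop, params,
                               priors = occuband_priors()) {
  occu_loglik_all(detections, covariates, pop, params) +
    log_prior(params, priors, "point")
}

#' @rdname joint_log_posterior
#' @export
cjs_log_posterior <- function(bandings, covariates, z, params,
                              priors = occuband_priors(),
                              include_nbox = TRUE) {
  if (!include_nbox) params$b1 <- 0
  cjs_loglik_all(bandings, covariates, z, params) +
    log_prior(params, priors, "band", drop_b1 = !include_nbox)
}

# full occupancy-data log-likelihood at the latent states
occu_loglik_all <- function(detections, covariates, pop, params) {
  if (is.null(detections)) return(0)
  des <- detections$design
  ll <- state_loglik(pop, covariates, params)
  for (t in seq_len(des$n_years)) for (k in seq_len(des$n_sessions)) {
    on <- which(des$sampled[, k, t] & !is.na(detections$y[, k, t]))
    if (!length(on)) next
    p <- det_prob(covariates, params, on, k, t)
    ll <- ll + obs_loglik(detections$y[on, k, t], pop$N[on, t], p)
  }
  ll
}

cjs_loglik_all <- function(bandings, covariates, z, params) {
  if (is.null(bandings) || length(bandings$f) == 0) return(0)
  cjs_alive_loglik(z, bandings, covariates, params) +
    cjs_obs_loglik(bandings, z, params)
}
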