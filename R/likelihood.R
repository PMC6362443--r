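#' Observation log-likelihood of the N-occupancy detection layer
#'
#' Log Bernoulli mass of a binary detection given local abundance:
#' success probability `1 - (1 - p)^N` (zero when `N = 0`). Vectorized;
#' missing `y` cells contribute 0 (an unsurveyed session carries no
#' information).
#'
#' @param y 0/1/`NA` detection indicator(s).
#' @param N nonnegative integer abundance(s).
#' @param p per-individual detection probability(ies) in `[0, 1]`.
#' @return Sum of the log masses over all non-missing cells.
#' @examples
#' obs_loglik(1, 2, 0.5)  # log(0.75)
#' obs_loglik(0, 3, 0.2)  # 3 * log(0.8)
#' @export
obs_loglik <- function(y, N, p) {
  stopifnot(all(y %in% c(0, 1) | is.na(y)), all(N >= 0),
            all(p >= 0 & p <= 1))
  keep <- !is.na(y)
  if (!any(keep)) return(0)
  df <- cbind(y = y, N = N, p = p)[keep, , drop = FALSE]
  q <- df[, "N"] * log1p(-df[, "p"])        # log P(no detection)
  q[df[, "N"] == 0] <- 0
  ll <- ifelse(df[, "y"] == 1, log1mexp(q), q)
  sum(ll)
}

# log(1 - exp(q)) for q <= 0, stable near both ends
log1mexp <- function(q) {
  out <- ifelse(q > -0.693147180559945, log(-expm1(q)), log1p(-exp(q)))
  out[q == 0] <- -Inf
  out
}

#' State-process log-likelihood of the population model
#'
#' Sum over sites and years of the latent demographic masses:
#' `Poisson(N_j1; lambda_j)` plus, for `t > 1`,
#' `Binomial(S_jt; N_j,t-1, phi_jt)` and `Poisson(G_jt; gamma_jt)`.
#' Any state with `S_jt > N_j,t-1` (more survivors than animals available)
#' has probability zero and returns `-Inf`.
#'
#' @param pop an `ob_population`.
#' @param covariates an `ob_covariates`.
#' @param params an `ob_params`.
#' @return Scalar log-likelihood.
#' @export
state_loglik <- function(pop, covariates, params) {
  T <- ncol(pop$N)
  lam <- initial_intensity(covariates, params)
  ll <- sum(dpois(pop$N[, 1], lam, log = TRUE))
  for (t in seq_len(T)[-1]) {
    if (any(pop$S[, t] > pop$N[, t - 1])) return(-Inf)
    phi <- survival_prob(covariates, params, year = t)
    gam <- recruitment_rate(covariates, params, year = t)
    ll <- ll + sum(dbinom(pop$S[, t], pop$N[, t - 1], phi, log = TRUE)) +
      sum(dpois(pop$G[, t], gam, log = TRUE))
  }
  ll
}

#' Exact marginal log-likelihood of the N-occupancy model (tiny instances)
#'
#' Marginalizes the latent (N, S, G) trajectories exactly by forward
#' summation over abundance states `0..N_max`, site by site (sites are
#' conditionally independent given the parameters). Intended as an oracle for
#' validating samplers on small problems; it refuses instances larger than 3
#' sites x 3 years (the state enumeration grows combinatorially).
#'
#' The truncation error is bounded by the Poisson tails; increasing `N_max`
#' beyond the effective support changes the result only at machine-precision
#' level.
#'
#' @param detections an `ob_detections`.
#' @param covariates an `ob_covariates`.
#' @param params an `ob_params`.
#' @param N_max abundance truncation bound (<= 100).
#' @return Scalar exact (truncated) marginal log-likelihood.
#' @export
occu_marginal_loglik <- function(detections, covariates, params, N_max = 8) {
  des <- detections$design
  J <- des$n_sites; T <- des$n_years; K <- des$n_sessions
  if (J > 3 || T > 3 || N_max > 100)
    stop("instance too large for exact marginalization (<= 3 sites, ",
         "<= 3 years, N_max <= 100)")
  ns <- 0:N_max

  obs_lik_year <- function(j, t, n) {
    # P(y_jt | N_jt = n) over surveyed sessions, for all n at once
    out <- rep(1, length(n))
    for (k in seq_len(K)) {
      yv <- detections$y[j, k, t]
      if (is.na(yv)) next
      p <- det_prob(covariates, params, j, k, t)
      pe <- 1 - (1 - p)^n
      out <- out * if (yv == 1) pe else (1 - pe)
    }
    out
  }

  ll <- 0
  for (j in seq_len(J)) {
    lam <- initial_intensity(covariates, params, j)
    fwd <- dpois(ns, lam) * obs_lik_year(j, 1, ns)
    for (t in seq_len(T)[-1]) {
      phi <- survival_prob(covariates, params, j, t)
      gam <- recruitment_rate(covariates, params, j, t)
      # transition matrix P(N_t = m | N_{t-1} = n), truncated at N_max
      trans <- outer(ns, ns, function(n, m) {
        vapply(seq_along(n), function(i) {
          s <- 0:min(n[i], m[i])
          sum(dbinom(s, n[i], phi) * dpois(m[i] - s, gam))
        }, numeric(1))
      })
      fwd <- as.vector(fwd %*% trans) * obs_lik_year(j, t, ns)
    }
    ll <- ll + log(sum(fwd))
  }
  ll
}
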