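#' Cormack-Jolly-Seber state-space log-likelihood components
#'
#' `cjs_alive_loglik()` scores the latent alive process: conditional on first
#' capture (`z_i,f_i = 1`), each later year is
#' `Z_it ~ Bernoulli(Z_i,t-1 * phi_jt)` with the same site-year apparent
#' survival regression as the population model. A "resurrection"
#' (0 followed by 1) has probability zero and returns `-Inf`.
#'
#' `cjs_obs_loglik()` scores the resighting layer
#' `Y_it ~ Bernoulli(Z_it * p_Bi)` over years after first capture; a
#' detection of a dead individual returns `-Inf`.
#'
#' @param z integer matrix (individuals x years) of alive states; entries
#'   before first capture are ignored (`NA` allowed there).
#' @param bandings an `ob_bandings` (supplies `y`, `f`, `site`, `sex`).
#' @param covariates an `ob_covariates`.
#' @param params an `ob_params` (uses the `b` block; `e` block for the
#'   observation layer).
#' @return Scalar log-likelihood.
#' @export
cjs_alive_loglik <- function(z, bandings, covariates, params) {
  T <- bandings$n_years
  I <- nrow(z)
  ll <- 0
  for (i in seq_len(I)) {
    fi <- bandings$f[i]
    if (fi >= T) next
    for (t in (fi + 1):T) {
      phi <- survival_prob(covariates, params, bandings$site[i], t)
      pr1 <- z[i, t - 1] * phi
      ll <- ll + if (z[i, t] == 1) log(pr1) else log1p(-pr1)
      if (!is.finite(ll)) return(-Inf)
    }
  }
  ll
}

#' @rdname cjs_alive_loglik
#' @export
cjs_obs_loglik <- function(bandings, z, params) {
  T <- bandings$n_years
  I <- nrow(z)
  pB <- band_det_prob(params, bandings$sex)
  ll <- 0
  for (i in seq_len(I)) {
    fi <- bandings$f[i]
    if (fi >= T) next
    for (t in (fi + 1):T) {
      yv <- bandings$y[i, t]
      pr <- z[i, t] * pB[i]
      ll <- ll + if (yv == 1) log(pr) else log1p(-pr)
      if (!is.finite(ll)) return(-Inf)
    }
  }
  ll
}

#' Marginal CJS log-likelihood (alive states summed out)
#'
#' Exact conditional-on-first-capture likelihood with the latent alive
#' history integrated out by the standard alive/dead forward recursion: at
#' each year after first capture the individual either survived (and was
#' resighted with probability `p_Bi`) or has died (in which case any later
#' detection is impossible). Equals the explicit enumeration over all
#' monotone alive histories.
#'
#' Individuals first captured in the final year contribute probability one.
#'
#' @param bandings an `ob_bandings`.
#' @param covariates an `ob_covariates`.
#' @param params an `ob_params`.
#' @param include_nbox logical; the banding-only model drops the nest-box
#'   term from the survival regression (every banded individual is at a
#'   nest-box site, so the term is confounded with the intercept). Default
#'   `TRUE` keeps the full shared regression as used by the joint model.
#' @return Scalar log-likelihood.
#' @examples
#' # one individual, history (1, 0), phi = p_B = 0.5:
#' # (1 - phi) + phi (1 - p_B) = 0.75
#' @export
cjs_marginal_loglik <- function(bandings, covariates, params,
                                include_nbox = TRUE) {
  T <- bandings$n_years
  I <- length(bandings$f)
  if (!include_nbox) params$b1 <- 0
  ll <- 0
  for (i in seq_len(I)) {
    fi <- bandings$f[i]
    if (fi >= T) next
    pB <- band_det_prob(params, bandings$sex[i])
    alive <- 1; dead <- 0
    for (t in (fi + 1):T) {
      phi <- survival_prob(covariates, params, bandings$site[i], t)
      yv <- bandings$y[i, t]
      if (yv == 1) {
        alive <- alive * phi * pB
        dead <- 0
      } else {
        dead <- dead + alive * (1 - phi)
        alive <- alive * phi * (1 - pB)
      }
    }
    ll <- ll + log(alive + dead)
  }
  ll
}
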