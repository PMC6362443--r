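#' Link-scale demographic rates
#'
#' The four regressions of the hierarchical model, evaluated at given
#' covariates and parameters. All are vectorized over `site` (and `year`
#' where applicable). Random effects that are `NULL` in `params` contribute
#' zero.
#'
#' * `initial_intensity()`: expected initial abundance
#'   `lambda_j = exp(a0 + a1 dnbr_j + a2 nbox_j + a3 tfire_j1 + a4[R_j])`.
#' * `survival_prob()`: apparent survival for the transition into `year`
#'   (`year >= 2`),
#'   `logit(phi_jt) = b0 + b1 nbox_j + b2 tfire_jt + b3 live_jt + b4 snag_jt`.
#' * `recruitment_rate()`: expected gains
#'   `log(gamma_jt) = c0 + c1 nbox_j + c2 tfire_jt + c3 live_jt + c4 snag_jt`.
#' * `det_prob()`: per-session detection of one individual,
#'   `logit(p_jkt) = d0 + d1 nbox_j + d2[o_jkt]`; errors on unsurveyed cells.
#'
#' @param covariates an `ob_covariates`.
#' @param params an `ob_params`.
#' @param site site index or vector of indices.
#' @param year year index (target year of the transition for survival and
#'   recruitment; must be `> 1`).
#' @param session session index for `det_prob`.
#' @return Numeric vector of rates (`lambda`, `gamma`) or probabilities
#'   (`phi`, `p`).
#' @examples
#' d <- study_design(10, 2, 3, 3, seed = 1)
#' cv <- sim_covariates(d, seed = 1)
#' p0 <- occuband_params(a0 = 0, a1 = 0, a2 = 0, a3 = 0)
#' initial_intensity(cv, p0, 1) # = 1 when the whole a block is zero
#' @export
initial_intensity <- function(covariates, params, site = NULL) {
  des <- covariates$design
  if (is.null(site)) site <- seq_len(des$n_sites)
  stopifnot(all(site >= 1 & site <= des$n_sites))
  a4 <- re_or_zero(params$a4, des$n_transects)
  eta <- params$a0 + params$a1 * covariates$dnbr[site] +
    params$a2 * covariates$nbox[site] +
    params$a3 * covariates$tfire[site, 1] +
    a4[des$transect[site]]
  exp(eta)
}

#' @rdname initial_intensity
#' @export
survival_prob <- function(covariates, params, site = NULL, year) {
  des <- covariates$design
  if (is.null(site)) site <- seq_len(des$n_sites)
  stopifnot(all(year > 1 & year <= des$n_years))
  idx <- cbind(site, year)
  eta <- params$b0 + params$b1 * covariates$nbox[site] +
    params$b2 * covariates$tfire[idx] +
    params$b3 * covariates$live[idx] +
    params$b4 * covariates$snag[idx]
  plogis(eta)
}

#' @rdname initial_intensity
#' @export
recruitment_rate <- function(covariates, params, site = NULL, year) {
  des <- covariates$design
  if (is.null(site)) site <- seq_len(des$n_sites)
  stopifnot(all(year > 1 & year <= des$n_years))
  idx <- cbind(site, year)
  eta <- params$c0 + params$c1 * covariates$nbox[site] +
    params$c2 * covariates$tfire[idx] +
    params$c3 * covariates$live[idx] +
    params$c4 * covariates$snag[idx]
  exp(eta)
}

#' @rdname initial_intensity
#' @export
det_prob <- function(covariates, params, site, session, year) {
  des <- covariates$design
  cells <- cbind(site, session, year)
  if (!all(des$sampled[cells]))
    stop("det_prob requested for an unsurveyed site-session-year")
  d2 <- re_or_zero(params$d2, des$n_observers)
  eta <- params$d0 + params$d1 * covariates$nbox[cells[, 1]] +
    d2[des$observer[cells]]
  plogis(eta)
}

#' Banding (resight) detection probability
#'
#' `logit(p_Bi) = e0 + e1 sex_i` for banded individual sex codes (0 = female,
#' 1 = male by the generator's convention).
#'
#' @param params an `ob_params`.
#' @param sex 0/1 vector.
#' @return Probability vector.
#' @export
band_det_prob <- function(params, sex) {
  plogis(params$e0 + params$e1 * sex)
}

re_or_zero <- function(re, n) {
  if (is.null(re)) rep(0, n) else re
}
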