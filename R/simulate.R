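#' Simulate latent population trajectories
#'
#' Draws the biological state process: initial abundance
#' `N_j1 ~ Poisson(lambda_j)`, survivors
#' `S_jt ~ Binomial(N_j,t-1, phi_jt)` and gains `G_jt ~ Poisson(gamma_jt)`
#' with `N_jt = S_jt + G_jt` for `t > 1`. Gains pool births and immigration;
#' there is no separate immigration stream.
#'
#' @param design an `ob_design`.
#' @param covariates an `ob_covariates` dimensioned to `design`.
#' @param params an `ob_params` (random effects `NULL` are treated as zero).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return Object of class `ob_population`: list of integer `n_sites x
#'   n_years` matrices `N`, `S`, `G` (`S`, `G` are `NA` in year 1).
#' @examples
#' d <- study_design(5, 1, 3, 4, seed = 1)
#' cv <- sim_covariates(d, seed = 1)
#' pop <- sim_population(d, cv, occuband_params(), seed = 1)
#' all(pop$N[, -1] == pop$S[, -1] + pop$G[, -1])
#' @export
sim_population <- function(design, covariates, params, seed = NULL) {
  validate_design(design)
  stopifnot(identical(covariates$design$n_sites, design$n_sites),
            identical(covariates$design$n_years, design$n_years))
  if (!is.null(seed)) set.seed(seed)
  J <- design$n_sites
  T <- design$n_years

  lam <- initial_intensity(covariates, params)
  if (any(!is.finite(lam)))
    stop("non-finite initial intensity: check the a-block coefficients")
  N <- S <- G <- matrix(NA_integer_, J, T)
  N[, 1] <- rpois(J, lam)
  for (t in seq_len(T)[-1]) {
    phi <- survival_prob(covariates, params, year = t)
    gam <- recruitment_rate(covariates, params, year = t)
    if (any(!is.finite(phi)))
      stop("non-finite survival probability: check the b-block coefficients")
    if (any(!is.finite(gam)))
      stop("non-finite recruitment rate: check the c-block coefficients")
    S[, t] <- rbinom(J, N[, t - 1], phi)
    G[, t] <- rpois(J, gam)
    N[, t] <- S[, t] + G[, t]
  }
  structure(list(N = N, S = S, G = G), class = "ob_population")
}

#' Simulate detection/non-detection survey data
#'
#' Draws the observation layer of the dynamic N-occupancy model: for every
#' surveyed site-session-year,
#' `Y_jkt ~ Bernoulli(1 - (1 - p_jkt)^N_jt)`, i.e. the site is recorded as
#' occupied if at least one of the `N_jt` individuals present is detected,
#' each independently with the per-individual session detection probability
#' `p_jkt`. Unsurveyed cells (per the design's `sampled` mask) are `NA`.
#'
#' @param design an `ob_design`.
#' @param pop an `ob_population` defined on `design`.
#' @param params an `ob_params`.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return Object of class `ob_detections`: list with binary array `y`
#'   (site x session x year, `NA` = unsurveyed) and the `design`.
#' @export
sim_detections <- function(design, pop, params, seed = NULL) {
  validate_design(design)
  stopifnot(nrow(pop$N) == design$n_sites, ncol(pop$N) == design$n_years)
  if (!is.null(seed)) set.seed(seed)
  J <- design$n_sites; K <- design$n_sessions; T <- design$n_years
  d2 <- re_or_zero(params$d2, design$n_observers)
  nbox <- integer(J); nbox[design$nbox_sites] <- 1L

  y <- array(NA_integer_, dim = c(J, K, T))
  for (t in seq_len(T)) for (k in seq_len(K)) {
    on <- design$sampled[, k, t]
    if (!any(on)) next
    p <- plogis(params$d0 + params$d1 * nbox[on] + d2[design$observer[on, k, t]])
    peff <- 1 - (1 - p)^pop$N[on, t]
    y[on, k, t] <- rbinom(sum(on), 1L, peff)
  }
  structure(list(y = y, design = design), class = "ob_detections")
}

#' @export
print.ob_detections <- function(x, ...) {
  cat("Detection/non-detection data:", dim(x$y)[1], "sites x", dim(x$y)[2],
      "sessions x", dim(x$y)[3], "years;",
      sum(x$y == 1, na.rm = TRUE), "detections,",
      sum(is.na(x$y)), "unsurveyed cells\n")
  invisible(x)
}

#' Simulate banding (capture-recapture) data
#'
#' Marks individuals at nest-box sites and follows them with the same
#' apparent-survival regression that governs the population process (the
#' shared-parameter contract of the joint model). Each year, every unmarked
#' resident at a nest-box site is newly banded with probability
#' `marking_rule`; a banded individual `i` first captured in year `f_i` stays
#' alive via `Z_it ~ Bernoulli(Z_i,t-1 * phi_jt)` and is resighted via
#' `Y_it ~ Bernoulli(Z_it * p_Bi)` with `logit(p_Bi) = e0 + e1 sex_i`. Sex is
#' assigned Bernoulli(0.5); individuals do not move between sites.
#'
#' @param design an `ob_design`.
#' @param covariates an `ob_covariates`.
#' @param pop an `ob_population`.
#' @param params an `ob_params`.
#' @param marking_rule per-year probability that an unmarked resident of a
#'   nest-box site is banded; either a scalar or a list `list(prob =, sites =)`
#'   restricting marking to a subset of nest-box sites.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return Object of class `ob_bandings`: binary matrix `y` (individuals x
#'   years, `NA` before first capture), `f` (first-capture year), `site`,
#'   `sex`, and the latent alive matrix `z` (kept for testing; a real data
#'   set would not have it).
#' @export
sim_bandings <- function(design, covariates, pop, params, marking_rule = 0.3,
                         seed = NULL) {
  validate_design(design)
  if (!is.null(seed)) set.seed(seed)
  if (is.list(marking_rule)) {
    mark_sites <- marking_rule$sites
    mark_p <- marking_rule$prob
    if (!all(mark_sites %in% design$nbox_sites))
      stop("marking_rule targets a site without nest boxes")
  } else {
    mark_sites <- design$nbox_sites
    mark_p <- marking_rule
  }
  stopifnot(is.numeric(mark_p), mark_p >= 0, mark_p <= 1)
  J <- design$n_sites; T <- design$n_years

  site <- integer(0); sex <- integer(0); f <- integer(0)
  z <- matrix(integer(0), 0, T)
  alive_at <- function(j, t) if (nrow(z) == 0) 0L else
    sum(z[site == j, t, drop = TRUE] == 1L, na.rm = TRUE)

  for (t in seq_len(T)) {
    # survival transition for previously marked individuals
    if (t > 1 && nrow(z) > 0) {
      phi <- survival_prob(covariates, params, site, t)
      prev <- z[, t - 1]
      z[, t] <- ifelse(is.na(prev), NA_integer_,
                       rbinom(nrow(z), 1L, prev * phi))
    }
    # new markings: unmarked residents of marking sites
    for (j in mark_sites) {
      unmarked <- max(0L, pop$N[j, t] - alive_at(j, t))
      nnew <- rbinom(1L, unmarked, mark_p)
      if (nnew == 0) next
      znew <- matrix(NA_integer_, nnew, T)
      znew[, t] <- 1L
      z <- rbind(z, znew)
      site <- c(site, rep.int(j, nnew))
      sex <- c(sex, rbinom(nnew, 1L, 0.5))
      f <- c(f, rep.int(t, nnew))
    }
  }

  I <- nrow(z)
  y <- matrix(NA_integer_, I, T)
  if (I > 0) {
    pB <- band_det_prob(params, sex)
    for (i in seq_len(I)) {
      y[i, f[i]] <- 1L  # first capture, by definition
      tt <- seq_len(T)[seq_len(T) > f[i]]
      if (length(tt))
        y[i, tt] <- rbinom(length(tt), 1L, z[i, tt] * pB[i])
    }
  }
  structure(list(y = y, f = f, site = site, sex = sex, z = z,
                 n_years = T, design = design),
            class = "ob_bandings")
}

#' @export
print.ob_bandings <- function(x, ...) {
  cat("Banding data:", nrow(x$y), "individuals over", x$n_years, "years;",
      sum(x$y == 1, na.rm = TRUE), "detections (incl. first captures)\n")
  invisible(x)
}

#' Simulate a complete study (truth record)
#'
#' Convenience wrapper that completes the random effects, then simulates the
#' population, the detection/non-detection surveys and the banding histories
#' from one seed. The returned truth record carries everything needed for
#' parameter-recovery experiments.
#'
#' @param design an `ob_design`.
#' @param covariates optional `ob_covariates`; generated from `design` if
#'   `NULL`.
#' @param params an `ob_params`; `NULL` random effects are drawn from their
#'   scales and returned completed.
#' @param marking_rule passed to [sim_bandings()].
#' @param seed integer seed (required: the truth record must be reproducible).
#' @return Object of class `ob_truth`: list with `design`, `covariates`,
#'   completed `params`, `pop`, `detections`, `bandings`, `seed`.
#' @examples
#' tr <- sim_occuband(study_design(20, 4, 3, 3, seed = 1), seed = 1)
#' tr$detections
#' @export
sim_occuband <- function(design, covariates = NULL,
                         params = occuband_params(), marking_rule = 0.3,
                         seed) {
  set.seed(seed)
  if (is.null(covariates)) covariates <- sim_covariates(design)
  params <- complete_params(params, design)
  pop <- sim_population(design, covariates, params)
  detections <- sim_detections(design, pop, params)
  bandings <- sim_bandings(design, covariates, pop, params, marking_rule)
  structure(list(design = design, covariates = covariates, params = params,
                 pop = pop, detections = detections, bandings = bandings,
                 seed = seed),
            class = "ob_truth")
}

#' @export
print.ob_truth <- function(x, ...) {
  cat("Synthetic study (seed ", x$seed, ")\n", sep = "")
  print(x$design); print(x$detections); print(x$bandings)
  invisible(x)
}
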