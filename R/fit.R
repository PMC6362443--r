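#' MCMC configuration
#'
#' Desk-scale defaults: 3 chains of 20,000 iterations, 10,000 burn-in,
#' thinning 5 (2,000 retained draws per chain). The original case-study runs
#' used chains an order of magnitude longer; those remain available by
#' raising `n_iter`/`burn_in`.
#'
#' @param n_chains number of independent chains.
#' @param n_iter total iterations per chain.
#' @param burn_in iterations discarded (also the adaptation window for the
#'   random-walk proposal scales, which are frozen afterwards so the retained
#'   chain is a valid Markov chain).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param adapt tune proposal scales during burn-in (target acceptance
#'   0.2-0.5).
#' @return Object of class `ob_control`.
#' @export
mcmc_control <- function(n_chains = 3, n_iter = 20000, burn_in = 10000,
                         thin = 5, adapt = TRUE) {
  stopifnot(n_chains >= 1, burn_in < n_iter, thin >= 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 adapt = isTRUE(adapt)),
            class = "ob_control")
}

#' Fit a single-data or joint population model
#'
#' Fits one of three Bayesian hierarchical models by Metropolis-within-Gibbs:
#' `"point"` (dynamic N-occupancy, detection/non-detection data only),
#' `"band"` (state-space Cormack-Jolly-Seber, banding data only) or
#' `"joint"` (both likelihoods sharing the apparent-survival regression).
#' Latent abundances are updated with integer random-walk proposals, alive
#' states by their full conditionals, coefficients by adaptive scalar
#' random-walk Metropolis, and (if `priors$select`) Kuo-Mallick indicator
#' variables by Gibbs steps.
#'
#' The banding-only model drops the nest-box survival term (all banded
#' individuals live at nest-box sites, so it is confounded with the
#' intercept); survival is nonetheless predicted at every site from the
#' fitted regression, which is what the precision comparison uses.
#'
#' @param detections an `ob_detections` (required unless `model = "band"`).
#' @param bandings an `ob_bandings` (required unless `model = "point"`).
#' @param covariates an `ob_covariates`.
#' @param model `"joint"`, `"point"` or `"band"`.
#' @param priors an `ob_priors`.
#' @param control an `ob_control`.
#' @param seed integer seed; chains receive derived sub-seeds.
#' @return An object of class `occuband_fit`; see [summary.occuband_fit()],
#'   [coef.occuband_fit()], [bayes_pvalue()], [relative_bci()].
#' @examples
#' \donttest{
#' tr <- sim_occuband(study_design(25, 5, 3, 3, seed = 1), seed = 1)
#' f <- fit_occuband(tr$detections, tr$bandings, tr$covariates,
#'                   control = mcmc_control(2, 2000, 1000), seed = 1)
#' summary(f)
#' }
#' @export
fit_occuband <- function(detections = NULL, bandings = NULL, covariates,
                         model = c("joint", "point", "band"),
                         priors = occuband_priors(),
                         control = mcmc_control(), seed = 1) {
  model <- match.arg(model)
  stopifnot(inherits(covariates, "ob_covariates"),
            inherits(priors, "ob_priors"), inherits(control, "ob_control"))
  if (!all(is.finite(priors$mean)) || !all(is.finite(priors$sd)))
    stop("initialization error: non-finite prior specification")
  use_occ <- model %in% c("joint", "point")
  use_band <- model %in% c("joint", "band")
  if (use_occ && is.null(detections))
    stop("model '", model, "' needs detection/non-detection data")
  if (use_band && is.null(bandings))
    stop("model '", model, "' needs banding data")
  design <- covariates$design
  J <- design$n_sites; K <- design$n_sessions; T <- design$n_years
  R <- design$n_transects; O <- design$n_observers

  # --- pack data for the sampler ---
  if (use_occ) {
    stopifnot(identical(dim(detections$y), c(J, K, T)))
    yP <- as.integer(detections$y)
    yP[is.na(yP)] <- -1L
    obsv <- as.integer(design$observer) - 1L
    obsv[yP == -1L] <- -1L
  } else {
    yP <- rep(-1L, J * K * T)
    obsv <- rep(-1L, J * K * T)
  }
  if (use_band && length(bandings$f) > 0) {
    I <- length(bandings$f)
    yB <- bandings$y
    yB[is.na(yB)] <- -1L
    storage.mode(yB) <- "integer"
    fv <- as.integer(bandings$f) - 1L
    bs <- as.integer(bandings$site) - 1L
    sexv <- as.numeric(bandings$sex)
  } else {
    I <- 0L
    yB <- matrix(integer(0), 0, T)
    fv <- integer(0); bs <- integer(0); sexv <- numeric(0)
  }
  dat <- list(J = J, K = K, T = T, R = R, O = O, I = I,
              use_occ = use_occ, use_band = use_band,
              yP = yP, obs = obsv,
              dnbr = covariates$dnbr, nbox = as.numeric(covariates$nbox),
              tfire = covariates$tfire, live = covariates$live,
              snag = covariates$snag,
              transect = as.integer(design$transect) - 1L,
              yB = yB, f = fv, bsite = bs, sex = sexv)

  pn <- param_names(R, O)
  P <- length(pn)
  prm <- numeric(P); prs <- rep(1, P)
  cn <- names(priors$mean)
  prm[match(cn, pn)] <- priors$mean
  prs[match(cn, pn)] <- priors$sd
  prior_cpp <- list(mean = prm, sd = prs, sigma_upper = priors$sigma_upper,
                    e0_logistic = priors$e0_prior == "probability")

  upd <- update_flags(model, pn)
  sel <- sel_active_flags(model)
  v0 <- rep(1L, 15)
  if (model == "band") v0[5] <- 0L  # b1 excluded: nbox confounded
  cfg <- list(n_iter = control$n_iter, burn_in = control$burn_in,
              thin = control$thin, adapt = control$adapt,
              select = priors$select,
              sel_active = as.integer(sel & priors$select),
              update = as.integer(upd))

  # --- run chains ---
  stopifnot(seed == floor(seed), abs(seed) < 2^30)
  set.seed(seed)
  chain_seeds <- sample.int(2^30, control$n_chains)
  chains <- vector("list", control$n_chains)
  t0 <- proc.time()[["elapsed"]]
  for (ch in seq_len(control$n_chains)) {
    set.seed(chain_seeds[ch])
    init <- make_inits(dat, priors, v0, pn)
    chains[[ch]] <- ob_mcmc_chain(dat, prior_cpp, cfg, init)
  }
  runtime <- proc.time()[["elapsed"]] - t0

  assemble_fit(chains, model, pn, design, covariates, detections, bandings,
               priors, control, seed, runtime, v0)
}

param_names <- function(R, O) {
  c("a0", "a1", "a2", "a3", paste0("a4[", seq_len(R), "]"), "sigma_a",
    "b0", "b1", "b2", "b3", "b4", "c0", "c1", "c2", "c3", "c4",
    "d0", "d1", paste0("d2[", seq_len(O), "]"), "sigma_d", "e0", "e1")
}

selectable_names <- c("a1", "a2", "a3", "a4", "b1", "b2", "b3", "b4",
                      "c1", "c2", "c3", "c4", "d1", "d2", "e1")

update_flags <- function(model, pn) {
  blk <- substr(sub("\\[.*", "", pn), 1, 1)
  sig <- pn %in% c("sigma_a", "sigma_d")
  f <- switch(model,
    joint = rep(TRUE, length(pn)),
    point = blk %in% c("a", "b", "c", "d") | sig,
    band  = (blk %in% c("b", "e")) & !(pn == "b1"))
  f
}

sel_active_flags <- function(model) {
  switch(model,
    joint = rep(TRUE, 15),
    point = c(rep(TRUE, 14), FALSE),
    band  = c(rep(FALSE, 5), TRUE, TRUE, TRUE, rep(FALSE, 6), TRUE))
}

make_inits <- function(dat, priors, v0, pn) {
  J <- dat$J; K <- dat$K; T <- dat$T
  P <- length(pn)
  # start each chain at an independent draw near the prior centre
  theta <- rnorm(P, 0, 0.2)
  cn <- names(priors$mean)
  theta[match(cn, pn)] <- rnorm(length(cn), priors$mean,
                                pmin(priors$sd, 0.3))
  su <- priors$sigma_upper
  theta[pn == "sigma_a"] <- runif(1, 0.1, 0.9) * min(1, su)
  theta[pn == "sigma_d"] <- runif(1, 0.1, 0.9) * min(1, su)
  theta[grepl("^(a4|d2)\\[", pn)] <- rnorm(sum(grepl("^(a4|d2)\\[", pn)),
                                           0, 0.1 * min(1, su))
  if (priors$e0_prior == "logit")
    theta[pn == "e0"] <- runif(1, 0.2, 0.8)

  # latent abundance envelope: one more than the largest session count seen
  y <- array(dat$yP, dim = c(J, K, T))
  y[y < 0] <- 0L
  maxdet <- apply(y, c(1, 3), max)
  N <- maxdet + 1L
  S <- G <- matrix(0L, J, T)
  if (T > 1) for (t in 2:T) {
    S[, t] <- pmin(N[, t], N[, t - 1])
    G[, t] <- N[, t] - S[, t]
  }
  # alive until last detection, dead afterwards
  I <- dat$I
  z <- matrix(0L, I, T)
  if (I > 0) for (i in seq_len(I)) {
    yi <- dat$yB[i, ]
    last <- max(which(yi == 1L))
    z[i, (dat$f[i] + 1L):last] <- 1L  # f is 0-based here
  }
  list(theta = theta, v = as.integer(v0), N = N, S = S, G = G, z = z)
}

assemble_fit <- function(chains, model, pn, design, covariates, detections,
                         bandings, priors, control, seed, runtime, v0) {
  nch <- length(chains)
  P <- length(pn)
  kept <- nrow(chains[[1]]$theta)

  # effective coefficients: indicator times raw value
  beta_list <- lapply(chains, function(ch) {
    th <- ch$theta
    colnames(th) <- pn
    vm <- matrix(1, kept, P)
    for (si in seq_along(selectable_names)) {
      nm <- selectable_names[si]
      cols <- if (nm %in% c("a4", "d2")) grep(paste0("^", nm, "\\["), pn)
              else which(pn == nm)
      vm[, cols] <- ch$v[, si]
    }
    th * vm
  })
  beta_all <- do.call(rbind, beta_list)
  colnames(beta_all) <- pn

  keep_par <- update_flags(model, pn)

  rh <- vapply(which(keep_par), function(ip) {
    if (nch < 2) return(NA_real_)  # diagnostic needs parallel chains
    m <- vapply(beta_list, function(b) b[, ip], numeric(kept))
    rhat(m)
  }, numeric(1))

  q <- apply(beta_all[, keep_par, drop = FALSE], 2, quantile,
             probs = c(0.025, 0.5, 0.975), names = FALSE)
  summ <- data.frame(parameter = pn[keep_par],
                     median = q[2, ], lower = q[1, ], upper = q[3, ],
                     rhat = rh, row.names = NULL)

  v_all <- do.call(rbind, lapply(chains, `[[`, "v"))
  colnames(v_all) <- selectable_names
  vmeans <- if (priors$select)
    colMeans(v_all)[sel_active_flags(model)] else NULL

  pool <- function(nm) do.call(rbind, lapply(chains, `[[`, nm))
  disc <- pool("disc")
  colnames(disc) <- c("T_obs_point", "T_rep_point", "T_obs_band", "T_rep_band")

  structure(list(model = model, param_names = pn, keep_par = keep_par,
                 beta = beta_all, beta_chains = beta_list,
                 v = if (priors$select) v_all else NULL, vmeans = vmeans,
                 summary = summ, rhat = setNames(rh, pn[keep_par]),
                 phi = pool("phi"),
                 N = if (model != "band") pool("N") else NULL,
                 G = if (model != "band") pool("G") else NULL,
                 z = if (model != "point") pool("z") else NULL,
                 disc = disc,
                 loglik = unlist(lapply(chains, `[[`, "loglik")),
                 accept = lapply(chains, `[[`, "accept"),
                 design = design, covariates = covariates,
                 detections = detections, bandings = bandings,
                 priors = priors, control = control, seed = seed,
                 runtime = runtime),
            class = "occuband_fit")
}
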