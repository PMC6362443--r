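# Shared fixtures and independent oracles for the test suite.
# The enumeration oracles below are deliberately written from the model
# definitions (explicit sums over latent trajectories) and share no code with
# the package's marginalization routines.

tiny_design <- function(J = 2, R = 1, K = 2, T = 2, nbox = 0.5, O = 2,
                        seed = 1) {
  study_design(J, R, K, T, nbox_fraction = nbox, n_observers = O, seed = seed)
}

# covariates with fully controlled values (defaults: everything zero except
# the nest-box indicator, which follows the design)
flat_covariates <- function(design, dnbr = 0, nbox = NULL, tfire = 0,
                            snag = 0, live = 0) {
  J <- design$n_sites; T <- design$n_years
  if (is.null(nbox)) {
    nbox <- integer(J); nbox[design$nbox_sites] <- 1L
  }
  mat <- function(x) if (is.matrix(x)) x else matrix(x, J, T)
  structure(list(dnbr = rep_len(dnbr, J), nbox = rep_len(nbox, J),
                 burned = rep_len(0L, J), tfire = mat(tfire),
                 snag = mat(snag), live = mat(live), design = design),
            class = "ob_covariates")
}

# all-zero coefficients, with overrides
zero_params <- function(...) {
  p <- occuband_params(a0 = 0, a1 = 0, a2 = 0, a3 = 0, sigma_a = 0,
                       b0 = 0, b1 = 0, b2 = 0, b3 = 0, b4 = 0,
                       c0 = 0, c1 = 0, c2 = 0, c3 = 0, c4 = 0,
                       d0 = 0, d1 = 0, sigma_d = 0, e0 = 0, e1 = 0)
  ov <- list(...)
  for (nm in names(ov)) p[[nm]] <- ov[[nm]]
  p
}

const_pop <- function(design, N) {
  J <- design$n_sites; T <- design$n_years
  structure(list(N = matrix(as.integer(N), J, T),
                 S = matrix(NA_integer_, J, T),
                 G = matrix(NA_integer_, J, T)),
            class = "ob_population")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# explicit enumeration of all (N1, S, G) trajectories of one site, truncated
# at N_max; returns per-trajectory log masses and the N_j1 of each trajectory
enum_site_trajectories <- function(detections, covariates, params, j, N_max) {
  des <- detections$design
  T <- des$n_years; K <- des$n_sessions
  obsll <- function(t, n) {
    ll <- 0
    for (k in seq_len(K)) {
      y <- detections$y[j, k, t]
      if (is.na(y)) next
      ll <- ll + obs_loglik(y, n, det_prob(covariates, params, j, k, t))
    }
    ll
  }
  out_ll <- numeric(0)
  out_n1 <- integer(0)
  recurse <- function(t, prevN, ll) {
    if (t > T) {
      out_ll <<- c(out_ll, ll)
      return(invisible(NULL))
    }
    phi <- survival_prob(covariates, params, j, t)
    gam <- recruitment_rate(covariates, params, j, t)
    for (s in 0:prevN) for (g in 0:(N_max - s)) {
      n <- s + g
      recurse(t + 1, n,
              ll + dbinom(s, prevN, phi, log = TRUE) +
                dpois(g, gam, log = TRUE) + obsll(t, n))
    }
  }
  lam <- initial_intensity(covariates, params, j)
  for (n1 in 0:N_max) {
    before <- length(out_ll)
    ll1 <- dpois(n1, lam, log = TRUE) + obsll(1, n1)
    if (T >= 2) recurse(2, n1, ll1) else out_ll <- c(out_ll, ll1)
    out_n1 <- c(out_n1, rep.int(n1, length(out_ll) - before))
  }
  list(ll = out_ll, n1 = out_n1)
}

enum_occu_loglik <- function(detections, covariates, params, N_max) {
  sum(vapply(seq_len(detections$design$n_sites), function(j)
    logsumexp(enum_site_trajectories(detections, covariates, params,
                                     j, N_max)$ll), numeric(1)))
}

# brute-force CJS likelihood of one capture history: sum over death years
# (the alive history is monotone, so the death year indexes all of them)
enum_cjs_lik <- function(y, f, phis, pB) {
  T <- length(y)
  tot <- 0
  for (d in f:T) {
    pr <- 1
    if (d > f) for (t in (f + 1):d)
      pr <- pr * phis[t] * (if (y[t] == 1) pB else 1 - pB)
    if (d < T) {
      pr <- pr * (1 - phis[d + 1])
      if (any(y[(d + 1):T] == 1)) pr <- 0
    }
    tot <- tot + pr
  }
  tot
}

# minimal stand-in fit objects for precision-report arithmetic tests
fake_fit <- function(model, phi, N = NULL, G = NULL, J = 1, T = 2) {
  structure(list(model = model, phi = phi, N = N, G = G,
                 design = list(n_sites = J, n_years = T)),
            class = "occuband_fit")
}
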