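# helper: bandings object with fully specified histories
make_bandings <- function(y, f, site, sex, design) {
  structure(list(y = y, f = f, site = site, sex = sex, z = NULL,
                 n_years = ncol(y), design = design),
            class = "ob_bandings")
}

test_that("alive-transition and resighting masses match hand arithmetic", {
  d <- study_design(1, 1, 1, 4, nbox_fraction = 1, seed = 1)
  cv <- flat_covariates(d, nbox = 0)
  pars <- zero_params(b0 = qlogis(0.8), e0 = qlogis(0.7))
  b <- make_bandings(matrix(c(1L, 1L, 0L, 1L), 1, 4), 1L, 1L, 0L, d)

  # alive throughout: three survival transitions at phi = 0.8
  z_alive <- matrix(1L, 1, 4)
  expect_equal(cjs_alive_loglik(z_alive, b, cv, pars), 3 * log(0.8))
  # death at the first transition
  z_dead <- matrix(c(1L, 0L, 0L, 0L), 1, 4)
  expect_equal(cjs_alive_loglik(z_dead, b, cv, pars), log(0.2))
  # resurrection is impossible
  z_res <- matrix(c(1L, 0L, 1L, 1L), 1, 4)
  expect_equal(cjs_alive_loglik(z_res, b, cv, pars), -Inf)

  # resighting layer
  b2 <- make_bandings(matrix(c(1L, 1L), 1, 2), 1L, 1L, 0L,
                      study_design(1, 1, 1, 2, nbox_fraction = 1, seed = 1))
  expect_equal(cjs_obs_loglik(b2, matrix(1L, 1, 2), pars), log(0.7))
  b3 <- make_bandings(matrix(c(1L, 0L), 1, 2), 1L, 1L, 0L, b2$design)
  expect_equal(cjs_obs_loglik(b3, matrix(c(1L, 0L), 1, 2), pars), 0)
  expect_equal(cjs_obs_loglik(b2, matrix(c(1L, 0L), 1, 2), pars), -Inf)
})

test_that("the forward recursion reproduces the worked two-year values", {
  d <- study_design(1, 1, 1, 2, nbox_fraction = 1, seed = 1)
  cv <- flat_covariates(d, nbox = 0)
  pars <- zero_params()  # phi = p_B = 0.5
  h10 <- make_bandings(matrix(c(1L, 0L), 1, 2), 1L, 1L, 0L, d)
  h11 <- make_bandings(matrix(c(1L, 1L), 1, 2), 1L, 1L, 0L, d)
  expect_equal(cjs_marginal_loglik(h10, cv, pars), log(0.75),
               tolerance = 1e-10)
  expect_equal(cjs_marginal_loglik(h11, cv, pars), log(0.25),
               tolerance = 1e-10)
  # perfect detection: history (1,0) can only mean death
  pars1 <- zero_params(b0 = qlogis(0.3), e0 = 40)
  expect_equal(cjs_marginal_loglik(h10, cv, pars1), log(0.7),
               tolerance = 1e-8)
})

test_that("forward marginalization equals enumeration over alive histories", {
  set.seed(42)
  T <- 8
  d <- study_design(3, 1, 1, T, nbox_fraction = 1, seed = 2)
  snag <- matrix(rnorm(3 * T), 3, T)
  cv <- flat_covariates(d, snag = snag, nbox = 0)
  pars <- zero_params(b0 = 0.4, b4 = -0.6, e0 = -0.2, e1 = 0.5)
  for (rep in 1:20) {
    f <- sample(1:(T - 1), 1)
    site <- sample(1:3, 1)
    sex <- sample(0:1, 1)
    y <- rep(0L, T)
    y[f] <- 1L
    later <- (f + 1):T
    y[later] <- rbinom(length(later), 1, 0.4)
    b <- make_bandings(matrix(y, 1), f, site, sex, d)
    phis <- c(NA, survival_prob(cv, pars, rep(site, T - 1), 2:T))
    pB <- band_det_prob(pars, sex)
    expect_equal(cjs_marginal_loglik(b, cv, pars),
                 log(enum_cjs_lik(y, f, phis, pB)), tolerance = 1e-10)
  }
})

test_that("individuals first captured in the final year contribute nothing", {
  d <- study_design(2, 1, 1, 3, nbox_fraction = 1, seed = 3)
  cv <- flat_covariates(d, nbox = 0)
  pars <- zero_params(b0 = 0.3, e0 = 0.1)
  b1 <- make_bandings(matrix(c(1L, 0L, 1L), 1, 3), 1L, 1L, 1L, d)
  ll1 <- cjs_marginal_loglik(b1, cv, pars)
  b2 <- make_bandings(rbind(c(1L, 0L, 1L), c(NA, NA, 1L)),
                      c(1L, 3L), c(1L, 2L), c(1L, 0L), d)
  expect_equal(cjs_marginal_loglik(b2, cv, pars), ll1)
})

test_that("the banding-only variant drops the nest-box survival term", {
  d <- study_design(2, 1, 1, 3, nbox_fraction = 1, seed = 4)
  cv <- flat_covariates(d, nbox = 1)
  pars <- zero_params(b0 = 0.2, b1 = 0.9, e0 = 0.1)
  b <- make_bandings(matrix(c(1L, 1L, 0L), 1, 3), 1L, 1L, 0L, d)
  with_b1 <- cjs_marginal_loglik(b, cv, pars)
  without <- cjs_marginal_loglik(b, cv, pars, include_nbox = FALSE)
  pars0 <- pars; pars0$b1 <- 0
  expect_equal(without, cjs_marginal_loglik(b, cv, pars0))
  expect_false(isTRUE(all.equal(with_b1, without)))
})
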