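test_that("R-hat behaves on identical, stationary and separated chains", {
  set.seed(1)
  same <- matrix(rnorm(1000), 1000, 3)
  same[, 2] <- same[, 1]; same[, 3] <- same[, 1]
  expect_equal(rhat(same), 1, tolerance = 0.01)
  stat <- matrix(rnorm(3000), 1000, 3)
  expect_lt(rhat(stat), 1.1)
  apart <- stat + rep(c(0, 10, 20), each = 1000)
  expect_gt(rhat(apart), 2)
  expect_error(rhat(matrix(rnorm(100), 100, 1)), "2 chains")
  # agrees with the reference implementation in coda
  m <- matrix(rnorm(4000, sd = 2), 1000, 4)
  cd <- coda::gelman.diag(coda::as.mcmc.list(
    lapply(1:4, function(i) coda::mcmc(m[, i]))), autoburnin = FALSE)
  expect_equal(rhat(m), unname(cd$psrf[1, 1]), tolerance = 0.02)
})

test_that("posterior summaries are equal-tailed quantile summaries", {
  s <- posterior_summary(matrix(1:100, 100, 1, dimnames = list(NULL, "x")))
  expect_equal(s$median, 50.5)
  expect_equal(s$lower, 3.475)
  expect_equal(s$upper, 97.525)
  cz <- posterior_summary(matrix(2, 50, 1))
  expect_equal(cz$upper - cz$lower, 0)
  set.seed(3)
  sym <- posterior_summary(matrix(rnorm(1e4), ncol = 1))
  expect_lt(abs(sym$median), 0.05)
  expect_error(posterior_summary(matrix(numeric(0), 0, 1)), "no draws")
})

test_that("with no surveyed data the sampler reproduces the prior", {
  # every session missing: the posterior of every coefficient is its prior
  d <- study_design(6, 2, 2, 2, nbox_fraction = 0.5, n_observers = 2,
                    seed = 2)
  cv <- sim_covariates(d, seed = 2)
  det <- structure(list(y = array(NA_integer_, c(6, 2, 2)), design = d),
                   class = "ob_detections")
  f <- fit_occuband(det, NULL, cv, "point",
                    control = mcmc_control(3, 6000, 2000, thin = 2),
                    seed = 3)
  a0 <- f$beta[, "a0"]
  expect_lt(abs(mean(a0)), 0.08)            # prior mean 0
  expect_lt(abs(sd(a0) - sqrt(0.1)), 0.08)  # prior sd ~ 0.316
  b0 <- f$beta[, "b0"]
  expect_lt(abs(sd(b0) - 1), 0.25)          # wide intercept prior
  # the replicate discrepancy ties the observed one -> p-value ~ 1/2
  expect_equal(bayes_pvalue(f), 0.5, tolerance = 0.05)
})

test_that("latent abundance matches the enumeration posterior when pinned", {
  # pin all coefficients with near-degenerate priors centred at the truth,
  # then compare the N posterior with the exact trajectory enumeration
  d <- study_design(2, 1, 3, 2, nbox_fraction = 0.5, n_observers = 1,
                    seed = 4)
  cv <- flat_covariates(d)
  pars <- zero_params(a0 = log(2), b0 = 0.4, c0 = -0.3, d0 = -0.4)
  pars$a4 <- 0; pars$d2 <- 0
  pop <- sim_population(d, cv, pars, seed = 5)
  det <- sim_detections(d, pop, pars, seed = 6)

  pin_mean <- unlist(pars[c("a0", "a1", "a2", "a3", "b0", "b1", "b2", "b3",
                            "b4", "c0", "c1", "c2", "c3", "c4", "d0", "d1",
                            "e1")])
  priors <- occuband_priors(mean = pin_mean,
                            sd = setNames(rep(1e-6, 17), names(pin_mean)),
                            sigma_upper = 1e-6)
  f <- fit_occuband(det, NULL, cv, "point", priors = priors,
                    control = mcmc_control(3, 8000, 3000), seed = 7)

  # exact conditional posterior of N_11 by enumeration
  tr <- enum_site_trajectories(det, cv, pars, 1, N_max = 12)
  w <- exp(tr$ll - logsumexp(tr$ll))
  exact <- vapply(0:12, function(n) sum(w[tr$n1 == n]), numeric(1))
  draws <- f$N[, 1]  # site 1, year 1
  mcmc_dist <- vapply(0:12, function(n) mean(draws == n), numeric(1))
  expect_lt(max(abs(mcmc_dist - exact)), 0.05)
  expect_lt(abs(mean(draws) - sum(0:12 * exact)), 0.15)
})

test_that("independent seeds agree in distribution but not draw-by-draw", {
  d <- tiny_design(J = 15, R = 3, K = 3, T = 3, seed = 8)
  truth <- sim_occuband(d, seed = 9)
  ctl <- mcmc_control(2, 5000, 2500)
  f1 <- fit_occuband(truth$detections, truth$bandings, truth$covariates,
                     "joint", control = ctl, seed = 10)
  f2 <- fit_occuband(truth$detections, truth$bandings, truth$covariates,
                     "joint", control = ctl, seed = 11)
  expect_false(identical(f1$beta[, "a0"], f2$beta[, "a0"]))
  for (p in c("a0", "b0", "d0"))
    expect_lt(abs(median(f1$beta[, p]) - median(f2$beta[, p])), 0.15)
  # and the same seed is exactly reproducible
  f3 <- fit_occuband(truth$detections, truth$bandings, truth$covariates,
                     "joint", control = ctl, seed = 10)
  expect_identical(f1$beta, f3$beta)
})

test_that("switched-off indicators zero the effective coefficient", {
  d <- tiny_design(J = 20, R = 2, K = 3, T = 3, seed = 12)
  truth <- sim_occuband(d, seed = 13)
  f <- fit_occuband(truth$detections, truth$bandings, truth$covariates,
                    "joint", priors = occuband_priors(select = TRUE),
                    control = mcmc_control(2, 3000, 1500), seed = 14)
  expect_true(all(f$beta[f$v[, "c1"] == 0, "c1"] == 0))
  expect_true(all(f$beta[f$v[, "d1"] == 0, "d1"] == 0))
  expect_true(all(f$vmeans >= 0 & f$vmeans <= 1))
  s <- summary(f)
  expect_true("support" %in% names(s))
})

test_that("initialization failures are reported, not silently absorbed", {
  d <- tiny_design(J = 4, R = 1, K = 2, T = 2, seed = 15)
  truth <- sim_occuband(d, seed = 16)
  bad <- occuband_priors(mean = c(a0 = Inf))
  expect_error(fit_occuband(truth$detections, NULL, truth$covariates,
                            "point", priors = bad, seed = 1))
})
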