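test_that("link functions evaluate their regressions exactly", {
  d <- tiny_design(J = 3, R = 1, K = 2, T = 3, O = 2, seed = 1)
  cv <- flat_covariates(d, nbox = 0)

  # initial intensity
  expect_equal(initial_intensity(cv, zero_params(), 1), 1)
  expect_equal(initial_intensity(cv, zero_params(a0 = 1), 1), exp(1))
  cv2 <- flat_covariates(d, dnbr = 2, nbox = 0)
  expect_equal(initial_intensity(cv2, zero_params(a1 = 0.5), 1), exp(1))
  # transect random effect enters through the site's transect
  p4 <- zero_params(); p4$a4 <- 0.7
  expect_equal(initial_intensity(cv, p4, 2), exp(0.7))

  # survival
  expect_equal(survival_prob(cv, zero_params(), 1, 2), 0.5)
  expect_equal(survival_prob(cv, zero_params(b0 = qlogis(0.9)), 1, 2), 0.9)
  cv3 <- flat_covariates(d, snag = 1, nbox = 0)
  expect_equal(survival_prob(cv3, zero_params(b4 = -1), 1, 2), 1 / (1 + exp(1)),
               tolerance = 1e-12)
  expect_error(survival_prob(cv, zero_params(), 1, 1))

  # recruitment
  expect_equal(recruitment_rate(cv, zero_params(), 1, 2), 1)
  expect_equal(recruitment_rate(cv, zero_params(c0 = log(0.5)), 1, 2), 0.5)
  cv4 <- flat_covariates(d, tfire = 3, nbox = 0)
  expect_equal(recruitment_rate(cv4, zero_params(c2 = 0.092), 1, 2),
               exp(0.276))

  # detection
  expect_equal(det_prob(cv, zero_params(), 1, 1, 1), 0.5)
  cv5 <- flat_covariates(d, nbox = 1)
  expect_equal(det_prob(cv5, zero_params(d1 = 1), 1, 1, 1),
               plogis(1), tolerance = 1e-12)
  pobs <- zero_params(d0 = -2)
  pobs$d2 <- rep(-0.3, d$n_observers)
  expect_equal(det_prob(cv, pobs, 1, 1, 1), 1 / (1 + exp(2.3)),
               tolerance = 1e-12)
  d$sampled[1, 1, 1] <- FALSE
  cvm <- flat_covariates(d)
  expect_error(det_prob(cvm, zero_params(), 1, 1, 1), "unsurveyed")
})

test_that("the observation mass handles impossible and closed-form cases", {
  expect_equal(obs_loglik(1, 0, 0.5), -Inf)
  expect_equal(obs_loglik(1, 2, 0.5), log(0.75))
  expect_equal(obs_loglik(0, 3, 0.2), 3 * log(0.8))
  expect_equal(obs_loglik(0, 0, 0.9), 0)
  expect_equal(obs_loglik(NA, 5, 0.5), 0)   # unsurveyed cells are skipped
  expect_equal(obs_loglik(c(1, NA, 0), c(2, 2, 2), 0.5),
               log(0.75) + 2 * log(0.5))
  # success probability is nondecreasing in N and in p
  grid <- expand.grid(N = 0:6, p = seq(0, 1, 0.1))
  succ <- matrix(1 - (1 - grid$p)^grid$N, nrow = 7)
  expect_true(all(diff(succ) >= 0))           # in N
  expect_true(all(t(diff(t(succ))) >= -1e-12))  # in p
})

test_that("the state mass matches hand arithmetic and rejects bad states", {
  d <- study_design(1, 1, 1, 1, nbox_fraction = 1, seed = 1)
  cv <- flat_covariates(d, nbox = 0)
  pop <- structure(list(N = matrix(2L, 1, 1), S = matrix(NA_integer_, 1, 1),
                        G = matrix(NA_integer_, 1, 1)),
                   class = "ob_population")
  expect_equal(state_loglik(pop, cv, zero_params(a0 = log(2))),
               dpois(2, 2, log = TRUE))

  d2 <- study_design(1, 1, 1, 2, nbox_fraction = 1, seed = 1)
  cv2 <- flat_covariates(d2, nbox = 0)
  pop2 <- structure(list(N = matrix(c(1L, 1L), 1, 2),
                         S = matrix(c(NA, 1L), 1, 2),
                         G = matrix(c(NA, 0L), 1, 2)),
                    class = "ob_population")
  pars <- zero_params(a0 = 0.3)  # phi = 0.5, gamma = 1
  expect_equal(state_loglik(pop2, cv2, pars),
               dpois(1, exp(0.3), log = TRUE) + log(0.5) + (-1))
  # more survivors than animals available is impossible
  pop3 <- pop2
  pop3$S[1, 2] <- 2L
  pop3$G[1, 2] <- 0L
  pop3$N[1, 2] <- 2L
  expect_equal(state_loglik(pop3, cv2, pars), -Inf)
})

test_that("forward marginalization equals explicit trajectory enumeration", {
  for (seed in 1:3) {
    set.seed(seed)
    d <- tiny_design(J = 2, R = 1, K = 2, T = 3, O = 2, seed = seed)
    cv <- sim_covariates(d, seed = seed)
    pars <- occuband_params(a0 = runif(1, -0.5, 0.5), a1 = 0.2, a3 = 0.1,
                            b4 = -0.4, c0 = runif(1, -1, 0),
                            d0 = runif(1, -1, 0),
                            a4 = rep(0.1, 1), d2 = c(-0.2, 0.3))
    det <- sim_detections(d, sim_population(d, cv, pars, seed = seed),
                          pars, seed = seed + 10)
    expect_equal(occu_marginal_loglik(det, cv, pars, N_max = 8),
                 enum_occu_loglik(det, cv, pars, N_max = 8),
                 tolerance = 1e-8)
  }
})

test_that("marginal likelihood is insensitive to the truncation bound", {
  d <- tiny_design(J = 1, R = 1, K = 3, T = 2, O = 1, seed = 5)
  cv <- flat_covariates(d)
  pars <- zero_params(a0 = log(1.5), d0 = -0.5, c0 = -0.5)
  pars$a4 <- 0; pars$d2 <- 0
  det <- sim_detections(d, sim_population(d, cv, pars, seed = 6), pars,
                        seed = 7)
  l20 <- occu_marginal_loglik(det, cv, pars, N_max = 20)
  l40 <- occu_marginal_loglik(det, cv, pars, N_max = 40)
  expect_lt(abs(l40 - l20), 1e-10)
})

test_that("undetectable animals leave the marginal free of the state blocks", {
  # p ~ 0: the data carry no information about abundance parameters
  d <- tiny_design(J = 2, R = 1, K = 2, T = 2, O = 1, seed = 8)
  cv <- flat_covariates(d)
  base <- zero_params(d0 = -50)
  base$a4 <- 0; base$d2 <- 0
  det <- structure(list(y = array(0L, c(2, 2, 2)), design = d),
                   class = "ob_detections")
  alt <- base; alt$a0 <- 0.8; alt$c0 <- 0.5
  expect_lt(abs(occu_marginal_loglik(det, cv, base, 30) -
                  occu_marginal_loglik(det, cv, alt, 30)), 1e-8)
})

test_that("exact marginalization refuses combinatorially large instances", {
  d <- study_design(10, 2, 3, 4, seed = 9)
  cv <- sim_covariates(d, seed = 9)
  pars <- occuband_params(a4 = rep(0, 2), d2 = rep(0, 9))
  det <- sim_detections(d, sim_population(d, cv, pars, seed = 9), pars,
                        seed = 9)
  expect_error(occu_marginal_loglik(det, cv, pars), "too large")
})
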