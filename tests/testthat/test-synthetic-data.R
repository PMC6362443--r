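test_that("study designs partition sites and respect their invariants", {
  d <- study_design(20, 4, 3, 5, nbox_fraction = 0.4, n_observers = 3,
                    seed = 1)
  expect_length(d$transect, 20)
  expect_setequal(unique(d$transect), 1:4)
  expect_true(all(d$nbox_sites %in% 1:20))
  expect_length(d$nbox_sites, 8)
  expect_true(all(d$observer >= 1 & d$observer <= 3))
  expect_error(study_design(5, 10), "more transects")
  expect_error(study_design(10, 2, nbox_fraction = 0), "nbox_fraction")
  # smallest valid design
  d1 <- study_design(1, 1, 1, 1, nbox_fraction = 1, n_observers = 1)
  expect_equal(d1$n_sites, 1L)
  # determinism
  expect_identical(study_design(30, 5, seed = 7), study_design(30, 5, seed = 7))
})

test_that("generated covariates are standardized and fire-structured", {
  d <- study_design(150, 10, 3, 6, seed = 2)
  cv <- sim_covariates(d, seed = 3)
  expect_lt(abs(mean(cv$dnbr)), 0.1)
  expect_lt(abs(var(cv$dnbr) - 1), 0.1)
  expect_lt(abs(mean(cv$snag)), 0.1)
  expect_lt(abs(var(as.vector(cv$snag)) - 1), 0.1)
  expect_lt(abs(var(as.vector(cv$live)) - 1), 0.1)
  # tfire is zero at unburned sites and grows linearly at burned ones
  expect_true(all(cv$tfire[cv$burned == 0, ] == 0))
  burned1 <- which(cv$burned == 1)[1]
  expect_equal(cv$tfire[burned1, ], 1:6)
  # yearly-index coding applies to every site
  cv2 <- sim_covariates(d, tfire_site_specific = FALSE, seed = 3)
  expect_equal(cv2$tfire[1, ], 1:6)
  # burn severity is higher at burned sites
  expect_gt(mean(cv$dnbr[cv$burned == 1]), mean(cv$dnbr[cv$burned == 0]))
})

test_that("population trajectories satisfy N = S + G and limiting cases", {
  d <- tiny_design(J = 40, R = 4, T = 5, seed = 4)
  cv <- flat_covariates(d)
  pop <- sim_population(d, cv, occuband_params(), seed = 5)
  expect_true(all(pop$N[, -1] == pop$S[, -1] + pop$G[, -1]))
  expect_true(all(pop$S[, -1] <= pop$N[, -5]))
  # closed population: survival ~ 1, recruitment ~ 0
  closed <- sim_population(d, cv, zero_params(a0 = 1, b0 = 40, c0 = -40),
                           seed = 6)
  expect_true(all(closed$N == closed$N[, 1]))
  # extinction: survival 0, recruitment 0
  ext <- sim_population(d, cv, zero_params(a0 = 1, b0 = -40, c0 = -40),
                        seed = 7)
  expect_true(all(ext$N[, -1] == 0))
  # non-finite rate names the offending block
  expect_error(sim_population(d, cv, zero_params(a0 = Inf), seed = 1),
               "a-block")
  expect_error(sim_population(d, cv, zero_params(c0 = Inf), seed = 1),
               "c-block")
})

test_that("Monte-Carlo mean of initial abundance matches exp(a0)", {
  d <- study_design(10000, 1, 1, 1, nbox_fraction = 0.5, n_observers = 1,
                    seed = 8)
  cv <- flat_covariates(d)
  pop <- sim_population(d, cv, zero_params(a0 = log(2)), seed = 9)
  se <- sqrt(2 / 10000)  # Poisson(2) mean over 1e4 sites
  expect_lt(abs(mean(pop$N[, 1]) - 2), 3 * se)
})

test_that("detection data follow the abundance-dependent Bernoulli law", {
  d <- study_design(10000, 1, 1, 1, nbox_fraction = 0.5, n_observers = 1,
                    seed = 10)
  pars <- zero_params()  # d block zero: p = 0.5
  # no animals, no detections
  y0 <- sim_detections(d, const_pop(d, 0), pars, seed = 11)
  expect_true(all(y0$y == 0))
  # N = 1, p = 0.5
  y1 <- sim_detections(d, const_pop(d, 1), pars, seed = 12)
  expect_lt(abs(mean(y1$y) - 0.5), 3 * sqrt(0.25 / 10000))
  # N = 2, p = 0.5: 1 - 0.5^2 = 0.75
  y2 <- sim_detections(d, const_pop(d, 2), pars, seed = 13)
  expect_lt(abs(mean(y2$y) - 0.75), 3 * sqrt(0.75 * 0.25 / 10000))
})

test_that("marginal session occupancy matches 1 - exp(-lambda p)", {
  # with N ~ Poisson(lambda), P(Y = 1) = 1 - E[(1-p)^N] = 1 - exp(-lambda p)
  d <- study_design(20000, 1, 1, 1, nbox_fraction = 0.5, n_observers = 1,
                    seed = 14)
  cv <- flat_covariates(d)
  pars <- zero_params(a0 = log(2))
  pop <- sim_population(d, cv, pars, seed = 15)
  y <- sim_detections(d, pop, pars, seed = 16)
  pocc <- 1 - exp(-2 * 0.5)
  expect_lt(abs(mean(y$y) - pocc), 3 * sqrt(pocc * (1 - pocc) / 20000))
})

test_that("banding data respect the marking rule and shared survival", {
  d <- tiny_design(J = 60, R = 3, K = 2, T = 6, nbox = 0.5, seed = 17)
  cv <- flat_covariates(d)
  # perfect world: phi = 1, p_B = 1 -> detected every year from first capture
  pars <- zero_params(a0 = 1.2, b0 = 40, c0 = -1, e0 = 40)
  b <- sim_bandings(d, cv, sim_population(d, cv, pars, seed = 18), pars,
                    marking_rule = 0.5, seed = 19)
  expect_gt(nrow(b$y), 10)
  for (i in seq_len(nrow(b$y)))
    expect_true(all(b$y[i, b$f[i]:d$n_years] == 1))
  expect_true(all(b$site %in% d$nbox_sites))
  # immediate death: phi = 0 -> never detected after the banding year
  pars0 <- zero_params(a0 = 1.2, b0 = -40, c0 = 1, e0 = 40)
  b0 <- sim_bandings(d, cv, sim_population(d, cv, pars0, seed = 20), pars0,
                     marking_rule = 0.5, seed = 21)
  after <- unlist(lapply(seq_len(nrow(b0$y)), function(i)
    if (b0$f[i] < d$n_years) b0$y[i, (b0$f[i] + 1):d$n_years] else NULL))
  expect_true(all(after == 0))
  # marking at a non-nest-box site is a configuration error
  bad <- setdiff(seq_len(d$n_sites), d$nbox_sites)[1]
  expect_error(
    sim_bandings(d, cv, sim_population(d, cv, pars, seed = 1), pars,
                 marking_rule = list(prob = 0.3, sites = bad), seed = 1),
    "without nest boxes")
})

test_that("a zero sex effect gives equal detection rates by sex", {
  d <- study_design(400, 4, 1, 6, nbox_fraction = 0.9, n_observers = 2,
                    seed = 22)
  cv <- flat_covariates(d)
  pars <- zero_params(a0 = 1.5, b0 = 40, c0 = -1, e0 = 0, e1 = 0)
  pop <- sim_population(d, cv, pars, seed = 23)
  b <- sim_bandings(d, cv, pop, pars, marking_rule = 0.6, seed = 24)
  post <- lapply(seq_len(nrow(b$y)), function(i)
    if (b$f[i] < d$n_years) cbind(b$y[i, (b$f[i] + 1):d$n_years], b$sex[i]))
  post <- do.call(rbind, post)
  expect_gt(nrow(post), 1000)
  p1 <- mean(post[post[, 2] == 1, 1])
  p0 <- mean(post[post[, 2] == 0, 1])
  se <- sqrt(0.25 / sum(post[, 2] == 1) + 0.25 / sum(post[, 2] == 0))
  expect_lt(abs(p1 - p0), 3 * se)
})

test_that("marked individuals experience the population's survival rate", {
  d <- study_design(300, 3, 1, 2, nbox_fraction = 1, n_observers = 1,
                    seed = 25)
  cv <- flat_covariates(d)
  pars <- zero_params(a0 = 1.5, b0 = qlogis(0.7), c0 = -1, e0 = 40)
  pop <- sim_population(d, cv, pars, seed = 26)
  b <- sim_bandings(d, cv, pop, pars, marking_rule = 1, seed = 27)
  surv <- b$z[b$f == 1, 2]
  expect_gt(length(surv), 300)
  expect_lt(abs(mean(surv) - 0.7), 3 * sqrt(0.21 / length(surv)))
})

test_that("the full generator is reproducible from its seed", {
  d <- tiny_design(J = 25, R = 5, T = 4, seed = 28)
  t1 <- sim_occuband(d, seed = 99)
  t2 <- sim_occuband(d, seed = 99)
  expect_identical(t1$detections$y, t2$detections$y)
  expect_identical(t1$bandings$y, t2$bandings$y)
  expect_identical(t1$params, t2$params)
  t3 <- sim_occuband(d, seed = 100)
  expect_false(identical(t1$detections$y, t3$detections$y))
})
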