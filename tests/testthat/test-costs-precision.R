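test_that("cost functions reproduce hand arithmetic on the case-study specs", {
  expect_equal(cost_detection(study_cost_spec("point")), 69179)
  expect_equal(cost_banding(study_cost_spec("band")), 143232)
  expect_equal(cost_joint(study_cost_spec("joint")), 171431)
})

test_that("cost functions handle degenerate designs exactly", {
  zero <- cost_spec(c0 = 0, c1 = 0, c2 = 0, c3 = 0, c4 = 0, c5 = 0, c6 = 0,
                    s_points = 10, s_boxes = 10, k = 3, t = 5)
  expect_equal(cost_detection(zero), 0)
  expect_equal(cost_banding(zero), 0)
  expect_equal(cost_joint(zero), 0)
  # no sampling years: establishment only
  est <- cost_spec(c0 = 100, c1 = 7, c2 = 3, c3 = 2, s_points = 10, k = 3,
                   t = 0)
  expect_equal(cost_detection(est), 100 + 7 * 10)
  # no boxes: startup plus yearly overhead
  nb <- cost_spec(c0 = 50, c4 = 9, c5 = 4, c6 = 11, s_boxes = 0, t = 3)
  expect_equal(cost_banding(nb), 50 + 11 * 3)
  # one box, one year
  one <- cost_spec(c0 = 5, c4 = 4, c5 = 3, c6 = 2, s_boxes = 1, t = 1)
  expect_equal(cost_banding(one), 5 + 4 + 3 + 2)
  # joint with banding terms zeroed reduces to the detection form
  jp <- cost_spec(c0 = 21900, c1 = 19, c2 = 12, c3 = 64, c4 = 0, c5 = 0,
                  c6 = 0, s_points = 149, s_boxes = 216, k = 3, t = 8)
  expect_equal(cost_joint(jp), cost_detection(jp))
  # and with point terms zeroed reduces to the banding form
  jb <- cost_spec(c0 = 23400, c1 = 0, c2 = 0, c3 = 0, c4 = 105, c5 = 55,
                  c6 = 264, s_points = 149, s_boxes = 216, k = 3, t = 8)
  expect_equal(cost_joint(jb), cost_banding(jb))
  # missing components are loud configuration errors
  expect_error(cost_detection(cost_spec(c0 = 1)), "needs")
  expect_error(cost_joint(cost_spec(c0 = 1, c1 = 1, c2 = 1, c3 = 1,
                                    s_points = 5, k = 3, t = 2)), "needs")
  expect_error(cost_spec(c0 = -1), ">= 0")
  expect_error(cost_spec(c0 = 1, t = 2.5), "integers")
})

test_that("costs are nondecreasing in every component and size", {
  base <- cost_spec(c0 = 100, c1 = 5, c2 = 2, c3 = 4, c4 = 7, c5 = 3,
                    c6 = 6, s_points = 20, s_establish = 10, s_boxes = 30,
                    k = 3, t = 4)
  for (fld in c("c0", "c1", "c2", "c3", "c4", "c5", "c6", "s_points",
                "s_boxes", "k", "t")) {
    more <- base
    more[[fld]] <- base[[fld]] + 1
    expect_gte(cost_joint(more), cost_joint(base))
  }
})

test_that("session probabilities annualize by the complement product", {
  expect_equal(annualize_detection(c(0, 0, 0)), 0)
  expect_equal(annualize_detection(c(1, 0.2, 0.9)), 1)
  expect_equal(annualize_detection(c(0.5, 0.5, 0.5)), 0.875)
  expect_equal(annualize_detection(0.3), 0.3)
  expect_error(annualize_detection(c(0.5, 1.2)))
})

test_that("relative BCI differences follow the defining arithmetic", {
  # engineered draws with known 95% interval lengths (J = 1 site, T = 2
  # years: phi and G have one site-year column, N has two)
  ramp <- function(len, k = 1) {
    matrix(seq(0, len / 0.95, length.out = 2001), 2001, k)
  }
  single <- fake_fit("point", phi = ramp(2), N = ramp(1.5, 2), G = ramp(1))
  joint <- fake_fit("joint", phi = ramp(1), N = ramp(1.2, 2), G = ramp(1))
  pr <- relative_bci(single, joint)
  agg <- pr$aggregate
  expect_equal(agg$mean[agg$parameter == "phi"], 1, tolerance = 1e-10)
  expect_equal(agg$mean[agg$parameter == "N"], 0.25, tolerance = 1e-10)
  expect_equal(agg$mean[agg$parameter == "G"], 0, tolerance = 1e-10)
  # zero-length joint interval: undefined, dropped with a warning
  degen <- fake_fit("joint", phi = matrix(1, 2001, 1), N = ramp(1.2, 2),
                    G = ramp(1))
  expect_warning(pr2 <- relative_bci(single, degen), "zero-length")
  expect_true(is.nan(pr2$aggregate$mean[pr2$aggregate$parameter == "phi"]) ||
                is.na(pr2$aggregate$mean[pr2$aggregate$parameter == "phi"]))
  # band fits compare survival only
  bandf <- fake_fit("band", phi = ramp(1.5))
  pr3 <- relative_bci(bandf, joint)
  expect_setequal(unique(pr3$cells$parameter), "phi")
  expect_equal(pr3$aggregate$mean, 0.5, tolerance = 1e-10)
  # mismatched designs are rejected
  expect_error(relative_bci(fake_fit("point", ramp(1), J = 2), joint),
               "matching")
  expect_error(relative_bci(single, bandf), "joint-model")
})
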