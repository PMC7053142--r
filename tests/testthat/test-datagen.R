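test_that("Beta moment equations are inverted in closed form", {
  # symmetric case: a + b = 1 forces a = b = 1/2
  bp <- solve_beta_params(0.5, 0.5)
  expect_equal(bp$a, 0.5)
  expect_equal(bp$b, 0.5)

  # frozen values checked against the moment equations directly
  bp <- solve_beta_params(0.1, 0.3)
  expect_equal(bp$a, 7 / 30)
  expect_equal(bp$b, 2.1)
  bp <- solve_beta_params(0.5, 0.7)
  expect_equal(bp$a, 3 / 14)
  expect_equal(bp$b, 3 / 14)

  # round trip over a grid: mean and correlation reproduce the inputs
  for (prev in c(0.05, 0.1, 0.3, 0.5, 0.9)) {
    for (rho in c(0.05, 0.3, 0.7, 0.95)) {
      bp <- solve_beta_params(prev, rho)
      expect_gt(bp$a, 0)
      expect_gt(bp$b, 0)
      expect_equal(bp$a / (bp$a + bp$b), prev, tolerance = 1e-12)
      expect_equal(1 / (1 + bp$a + bp$b), rho, tolerance = 1e-12)
    }
  }

  expect_error(solve_beta_params(0.1, 1), "between 0 and 1")
  expect_error(solve_beta_params(0.1, 0), "between 0 and 1")
  expect_error(solve_beta_params(1.2, 0.3), "between 0 and 1")
})

test_that("two-proportion sample size reproduces the design sizes", {
  expect_identical(required_sample_size(0.1, 0.2, 0.80, 0.05), 398L)
  expect_identical(required_sample_size(0.5, 0.6, 0.80, 0.05), 776L)
  # symmetric in the two arms
  expect_identical(required_sample_size(0.2, 0.1, 0.80, 0.05), 398L)
  expect_error(required_sample_size(0.3, 0.3), "must differ")
})

test_that("scenario defaults derive the sample size from the design", {
  expect_identical(scenario_config(0.1, 0.3)$n_total, 398L)
  expect_identical(scenario_config(0.5, 0.7)$n_total, 776L)
  expect_error(scenario_config(0.1, 0.3, n_total = 399), "even")
  expect_error(scenario_config(0.95, 0.3, n_total = 100, delta = 0.05),
               "exceeds 1")
})

test_that("complete replicates have the stated structure", {
  cfg <- tiny_config(n_total = 100L)
  set.seed(3)
  td <- generate_complete_replicate(cfg)
  expect_identical(nrow(td), 300L)
  expect_identical(sort(unique(td$visit)), 1:3)
  # equal allocation, first half treatment
  expect_identical(sum(td$arm == 1L) , 150L)
  expect_true(all(td$arm[td$subject <= 50] == 1L))
  expect_true(all(td$arm[td$subject > 50] == 0L))
  expect_false(any(td$missing))
  expect_true(all(td$p >= 0 & td$p <= 1))
  expect_true(all(td$y %in% 0:1))
  # treatment-arm probabilities nondecreasing in visit, control constant
  wide <- matrix(td$p, nrow = 3)
  trt <- wide[, td$arm[seq(1, 300, 3)] == 1L]
  ctl <- wide[, td$arm[seq(1, 300, 3)] == 0L]
  expect_true(all(diff(trt) >= 0))
  expect_true(all(abs(diff(ctl)) == 0))
})

test_that("delta = 0 alternative coincides with the null generation", {
  cfg_a <- tiny_config(delta = 0)
  cfg_n <- tiny_config(hypothesis = "null")
  set.seed(9)
  td_a <- generate_complete_replicate(cfg_a)
  set.seed(9)
  td_n <- generate_complete_replicate(cfg_n)
  expect_equal(td_a$p, td_n$p)
  expect_equal(td_a$y, td_n$y)
})

test_that("marginal event probabilities follow the design trajectories", {
  # large single replicate: treatment mean rises by delta per visit,
  # control stays at prevalence, all within Monte Carlo error
  cfg <- scenario_config(0.1, 0.3, n_total = 40000L, n_reps = 1L)
  set.seed(11)
  td <- generate_complete_replicate(cfg)
  tol <- 3.5 * sqrt(0.2 * 0.8 / 20000)
  for (j in 1:3) {
    m_t <- mean(td$y[td$visit == j & td$arm == 1L])
    m_c <- mean(td$y[td$visit == j & td$arm == 0L])
    expect_lt(abs(m_t - (0.1 + 0.05 * (j - 1))), tol)
    expect_lt(abs(m_c - 0.1), tol)
  }
  # baseline capping touches ~0.1% of subjects at prevalence 0.1 and the
  # induced loss of marginal probability is below 1e-3
  expect_lt(attr(td, "clipped_frac"), 5e-3)
  bp <- solve_beta_params(0.1, 0.3)
  loss <- integrate(function(p) (p - 0.9) * dbeta(p, bp$a, bp$b), 0.9, 1)$value
  expect_lt(loss, 1e-3)
})

test_that("null generation keeps all arm-by-visit proportions at prevalence", {
  cfg <- scenario_config(0.5, 0.7, n_total = 40000L, hypothesis = "null",
                         n_reps = 1L)
  set.seed(12)
  td <- generate_complete_replicate(cfg)
  props <- tapply(td$y, list(td$arm, td$visit), mean)
  expect_true(all(abs(props - 0.5) < 3.5 * sqrt(0.25 / 20000)))
  # no capping under the null: trajectories are flat so p_i1 keeps support
  expect_identical(attr(td, "clipped_frac"), 0)
})

test_that("within-subject outcome correlation equals rho", {
  # for a constant-probability subject, corr(y1, y2) = Var(p)/(p(1-p)) = rho
  # exactly; check by simulation in the control arm
  n <- 4e5
  for (rho in c(0.3, 0.7)) {
    bp <- solve_beta_params(0.1, rho)
    set.seed(100 + round(10 * rho))
    p <- rbeta(n, bp$a, bp$b)
    y1 <- rbinom(n, 1L, p)
    y2 <- rbinom(n, 1L, p)
    # MC standard error of a correlation estimate
    expect_lt(abs(cor(y1, y2) - rho), 3 * (1 - rho^2) / sqrt(n))
  }
})
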