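test_that("scenario runs are deterministic and mechanism-free runs complete", {
  cfg <- tiny_config(n_total = 100L, n_reps = 3L, seed = 5L)
  r1 <- run_scenario(cfg)
  r2 <- run_scenario(cfg)
  attr(r1, "config") <- attr(r2, "config") <- NULL
  expect_identical(r1, r2)
  expect_identical(unique(r1$dataset), "complete")
  expect_identical(nrow(r1), 6L)  # 3 replicates x 2 methods
})

test_that("dropout scenarios carry both datasets and the calibrated model", {
  cfg <- tiny_config(n_total = 100L, n_reps = 2L, mechanism = "MAR1",
                     dropout_pattern = "unequal1", seed = 6L)
  res <- run_scenario(cfg)
  expect_setequal(unique(res$dataset), c("complete", "incomplete"))
  m <- attr(res, "mar_model")
  expect_s3_class(m, "missingness_model")
  expect_identical(m$gamma2, 1.5)
  r <- expected_mar_rates(m)
  expect_equal(unname(r), c(0.2, 0.4), tolerance = 1e-8)

  # MCAR scenario: incomplete chi-squared totals reflect exact deletion
  cfg2 <- tiny_config(n_total = 398L, n_reps = 2L, mechanism = "MCAR",
                      dropout_pattern = "equal", seed = 7L,
                      rho = 0.3)
  res2 <- run_scenario(cfg2, methods = "chisq")
  expect_true(all(!res2$degenerate))
})

test_that("summary measures follow their defining formulas", {
  # hand-built results: known estimates, ses and p-values
  res <- data.frame(
    replicate = rep(1:4, each = 2),
    dataset = rep(c("complete", "incomplete"), 4),
    method = "chisq",
    estimate = c(0.8, 0.9, 0.8, 0.7, 0.8, 1.1, 0.8, 0.9),
    se = c(0.3, 0.4, 0.3, 0.4, 0.3, 0.2, 0.3, 0.4),
    statistic = 1, p_value = c(0.01, 0.2, 0.01, 0.01, 0.01, 0.04, 0.01, 0.6),
    ci_low = -10, ci_high = 10, converged = TRUE, degenerate = FALSE,
    sigma_b2 = NA_real_, residual_scale = NA_real_, n_iterations = NA_integer_,
    clipped_frac = 0)
  attr(res, "config") <- tiny_config()
  s <- summarize_scenario(res)
  comp <- s[s$dataset == "complete", ]
  inc <- s[s$dataset == "incomplete", ]
  # theta_T is the complete-data mean of the same method
  expect_equal(comp$theta_T, 0.8)
  expect_equal(inc$mean_log_or, 0.9)
  expect_equal(inc$relative_bias_pct, 100 * (0.9 - 0.8) / 0.8)
  expect_equal(inc$power_pct, 50)           # 2 of 4 p-values below 0.05
  expect_equal(comp$power_pct, 100)
  expect_equal(inc$coverage_pct, 100)       # intervals are (-10, 10)
  expect_equal(inc$model_se, sqrt(mean(c(0.4, 0.4, 0.2, 0.4)^2)))
  expect_equal(inc$empirical_se, sd(c(0.9, 0.7, 1.1, 0.9)))
  expect_equal(inc$mcse_power, 100 * sqrt(0.5 * 0.5 / 4))
  expect_equal(inc$mcse_empirical_se, inc$empirical_se / sqrt(2 * 3))
  expect_identical(inc$n_used + inc$n_degenerate, inc$n_reps)
})

test_that("degenerate replicates are excluded from estimate measures only", {
  res <- data.frame(
    replicate = 1:3, dataset = "complete", method = "glmm",
    estimate = c(0.5, NA, 0.7), se = c(0.1, NA, 0.1), statistic = 1,
    p_value = c(0.01, 0.2, NA), ci_low = 0, ci_high = 1,
    converged = c(TRUE, TRUE, TRUE), degenerate = c(FALSE, TRUE, FALSE),
    sigma_b2 = 1, residual_scale = 1, n_iterations = 5L, clipped_frac = 0)
  attr(res, "config") <- tiny_config()
  s <- summarize_scenario(res, theta_T = c(glmm = 0.6))
  expect_identical(s$n_used, 2L)
  expect_identical(s$n_degenerate, 1L)
  expect_identical(s$n_tested, 2L)     # p-value exists for replicates 1-2
  expect_equal(s$mean_log_or, 0.6)
  expect_equal(s$power_pct, 50)
})

test_that("config files round-trip through the DCF reader", {
  path <- tempfile(fileext = ".dcf")
  writeLines(c(
    "prevalence: 0.1", "rho: 0.3", "mechanism: MCAR",
    "dropout_pattern: unequal2", "n_reps: 10", "seed: 3",
    "",
    "prevalence: 0.5", "rho: 0.7", "hypothesis: null",
    "mechanism: MAR1", "n_reps: 5", "seed: 4"), path)
  grid <- read_scenario_grid(path)
  expect_length(grid, 2)
  expect_identical(grid[[1]]$n_total, 398L)
  expect_identical(grid[[1]]$dropout_pattern, "unequal2")
  expect_identical(grid[[2]]$n_total, 776L)
  expect_identical(grid[[2]]$hypothesis, "null")
  expect_identical(grid[[2]]$n_reps, 5L)

  example <- system.file("extdata", "example_scenarios.dcf",
                         package = "dropoutsim")
  expect_gt(length(read_scenario_grid(example)), 0)
})

test_that("the full factorial grid has the expected structure", {
  grid <- full_scenario_grid(n_reps = 2L)
  expect_length(grid, 80)
  key <- sapply(grid, function(g)
    paste(g$prevalence, g$rho, g$hypothesis, g$mechanism, g$dropout_pattern))
  expect_identical(anyDuplicated(key), 0L)
  # 2 prevalence x 2 rho x 2 hypotheses x (1 + 3 + 3 + 3) cells
  expect_identical(sum(grepl("none", key)), 8L)
  expect_identical(sum(grepl("MAR1", key)), 24L)
})

test_that("rendered tables mirror the summary layout", {
  cfg <- tiny_config(n_total = 100L, n_reps = 4L, mechanism = "MCAR",
                     seed = 9L)
  s1 <- summarize_scenario(run_scenario(cfg, methods = "chisq"))
  cfg0 <- tiny_config(n_total = 100L, n_reps = 4L, seed = 9L)
  s0 <- summarize_scenario(run_scenario(cfg0, methods = "chisq"))
  dir <- tempfile()
  paths <- suppressWarnings(render_tables(rbind(s0, s1), dir))
  expect_true(all(file.exists(paths)))
  tab <- read.delim(paths[1])
  expect_identical(tab$scenario, c("Complete", "MCAR.equal"))
  expect_true(all(c("log_odds", "power_pct", "model_se") %in% names(tab)))
  # type-1 file exists even with no null-hypothesis rows
  expect_true(any(grepl("type1_error", paths)))
})
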