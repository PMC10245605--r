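test_that("rejection rate under the null matches the significance level", {
  cal <- calibrate_scenario(trial_scenario(theta = 1, Lambda_target = 0.9,
                                           C_target = 0.65, d = 0.01))
  res <- estimate_power(cal, n = 200, reps = 600, adjust = FALSE, seed = 21)
  expect_lt(abs(res$power - 0.05), 3 * sqrt(0.05 * 0.95 / 600))
})

test_that("power is non-decreasing in sample size up to Monte-Carlo error", {
  cal <- cal_for(0.65, 0.9)
  pc <- power_curve(cal, n_grid = c(150, 250, 350, 450), reps = 500,
                    seed = 22)
  for (adj in c(FALSE, TRUE)) {
    p <- pc$power[pc$adjusted == adj]
    se <- pc$se[pc$adjusted == adj]
    expect_true(all(diff(p) > -2 * sqrt(se[-1]^2 + se[-length(se)]^2)))
  }
})

test_that("adjusted power dominates unadjusted power on the reference power curve", {
  # C = 0.65, Lambda = 0.9, w = 1.5, d = 0, theta = 0.7; paired simulation
  cal <- cal_for(0.65, 0.9, d = 0)
  pc <- power_curve(cal, n_grid = seq(200, 400, by = 100), reps = 800,
                    seed = 23)
  for (n in unique(pc$n)) {
    sub <- pc[pc$n == n, ]
    d <- sub$power[sub$adjusted] - sub$power[!sub$adjusted]
    expect_gt(d, -2 * sqrt(sum(sub$se^2)))
  }
})

test_that("reduction arithmetic matches its definition", {
  expect_equal(sample_size_reduction(759, 671), 1 - 671 / 759)
  expect_equal(round(sample_size_reduction(759, 671), 3), 0.116)
  expect_equal(sample_size_reduction(500, 500), 0)
  expect_equal(sample_size_reduction(1000, 500), 0.5)
  expect_lt(sample_size_reduction(500, 600), 0) # not clipped
  expect_error(sample_size_reduction(0, 10))
})

test_that("Fleiss prediction reproduces the correlation-0.5 worked example", {
  expect_identical(fleiss_predict(1000, 0.25), 750L)
  expect_identical(fleiss_predict(1000, 0), 1000L)
  expect_error(fleiss_predict(1000, 1))
  expect_error(fleiss_predict(1000, -0.1))
})

test_that("sample-size search agrees with an exhaustive-grid oracle", {
  cal <- cal_for(0.65, 0.9)
  res <- run_reduction(cal, reps = 1000, seed = 24)
  expect_lte(res$Nadj, res$N0) # adjustment cannot hurt here
  expect_true(res$N0 %% 2 == 0 && res$Nadj %% 2 == 0)

  # oracle: estimate power at every even n across a bracket around Nadj
  # with fresh seeds, then take the first isotonic crossing of 0.80
  grid <- seq(res$Nadj - 60, res$Nadj + 80, by = 8)
  pow <- vapply(grid, function(n)
    estimate_power(cal, n, reps = 1000, adjust = TRUE,
                   seed = 1e6 + n)$power, 0)
  iso <- isoreg(grid, pow)$yf
  first <- which(iso >= 0.8)[1]
  expect_false(is.na(first)) # search result must sit below the crossing + 80
  oracle_n <- grid[first]
  expect_lt(abs(res$Nadj - oracle_n) / oracle_n, 0.05)
})

test_that("reduction runs are reproducible given the seed", {
  cal <- cal_for(0.75, 0.9)
  a <- run_reduction(cal, reps = 300, seed = 5)
  b <- run_reduction(cal, reps = 300, seed = 5)
  expect_identical(a$N0, b$N0)
  expect_identical(a$Nadj, b$Nadj)
  expect_identical(a$probes, b$probes)
})
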