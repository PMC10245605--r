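test_that("no censoring means every patient has an event", {
  cal <- cal_for(0.75, 0.5, d = 0)
  set.seed(1)
  co <- simulate_cohort(cal, 500, followup = Inf)
  expect_true(all(co$event == 1))
  expect_true(all(co$time == co$t_event))
})

test_that("cohort structure invariants hold", {
  cal <- cal_for(0.65, 0.9)
  set.seed(2)
  co <- simulate_cohort(cal, 501)
  expect_equal(sum(co$z == 0), 251) # odd n: extra patient in control
  expect_true(all(co$time <= 5))
  expect_true(all(co$time > 0))
  expect_true(all(co$event %in% 0:1))
  expect_true(all(co$time[co$event == 1] == co$t_event[co$event == 1]))
  expect_error(simulate_cohort(cal, 2))
})

test_that("a cohort calibrated to Lambda = 0.5 shows that event fraction", {
  cal <- cal_for(0.75, 0.5, d = 0)
  set.seed(4)
  co <- simulate_cohort(cal, 2e5)
  ctrl <- co$z == 0
  frac <- mean(co$t_event[ctrl] <= 5)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / sum(ctrl)))
  # treated arm is protected (theta = 0.7): fewer events
  expect_lt(mean(co$t_event[!ctrl] <= 5), frac)
})

test_that("a non-prognostic covariate shows Harrell C of 0.5", {
  cal <- calibrate_scenario(trial_scenario(Lambda_target = 0.5,
                                           C_target = 0.5, d = 0))
  set.seed(5)
  co <- simulate_cohort(cal, 2e4)
  ctrl <- co$z == 0
  hc <- survival::concordance(
    survival::Surv(co$time[ctrl], co$event[ctrl]) ~ co$x[ctrl, 1],
    reverse = TRUE)$concordance
  expect_lt(abs(hc - 0.5), 0.02)
})

test_that("simulation is bit-identical under the same seed", {
  cal <- cal_for(0.65, 0.9)
  set.seed(99); a <- simulate_cohort(cal, 1000)
  set.seed(99); b <- simulate_cohort(cal, 1000)
  expect_identical(a, b)
})

test_that("control-arm event times follow the analytic mixture distribution", {
  cal <- cal_for(0.75, 0.5, d = 0)
  set.seed(6)
  co <- simulate_cohort(cal, 2e5)
  te <- co$t_event[co$z == 0]
  ks <- suppressWarnings(stats::ks.test(te, mixture_event_cdf(cal)))
  expect_gt(ks$p.value, 0.001)
})

test_that("restricted enrollment truncates the covariate at the population quantile", {
  cal <- cal_for(0.65, 0.9, d = 0)
  set.seed(7)
  co <- simulate_cohort(cal, 5e4, restrict_quantile = 0.8)
  expect_true(all(co$x[, 1] < qnorm(0.8)))
  # truncated-normal mean, verified against a quadrature oracle
  oracle <- stats::integrate(function(v) v * dnorm(v), -Inf,
                             qnorm(0.8))$value / 0.8
  expect_equal(oracle, -dnorm(qnorm(0.8)) / 0.8, tolerance = 1e-8)
  expect_lt(abs(mean(co$x[, 1]) - oracle), 3 * sd(co$x[, 1]) / sqrt(co$n))
})

test_that("restrict_parametric filters an existing cohort and tracks screening", {
  cal <- cal_for(0.65, 0.9, d = 0)
  set.seed(8)
  co <- simulate_cohort(cal, 2e4)
  expect_identical(restrict_parametric(co, 1)$n, co$n)
  r <- restrict_parametric(co, 0.8)
  expect_true(all(r$x[, 1] < qnorm(0.8)))
  expect_equal(attr(r, "screened"), co$n)
  expect_lt(abs(r$n / co$n - 0.8), 3 * sqrt(0.8 * 0.2 / co$n))
  # lower-risk selection lowers cumulative incidence
  expect_lt(mean(r$t_event <= 5), mean(co$t_event <= 5))
  expect_error(restrict_parametric(co, 0))
})

test_that("screened-population accounting is exact", {
  expect_identical(screened_population(100, 1), 100L)
  expect_identical(screened_population(100, 0.5), 200L)
  expect_identical(screened_population(101, 0.52), as.integer(ceiling(101 / 0.52)))
  expect_error(screened_population(100, 0))
})
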