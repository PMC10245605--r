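test_that("cumulative incidence matches the closed form when beta = 0", {
  for (kappa in c(-3, -1, 0.5)) {
    for (w in c(1, 1.5, 2.5)) {
      expect_equal(control_cumulative_incidence(kappa, 0, w, followup = 5),
                   1 - exp(-exp(kappa) * 5^w), tolerance = 1e-10)
    }
  }
  # vanishing hazard
  expect_lt(control_cumulative_incidence(-50, 0.5, 1.5, 5), 1e-15)
})

test_that("cumulative incidence quadrature matches a Monte-Carlo oracle", {
  # brute-force oracle: exact Weibull survival averaged over Gaussian draws
  set.seed(42)
  x <- rnorm(1e6)
  surv <- exp(-exp(-2.0 + 0.5 * x) * 5^1.5)
  mc <- 1 - mean(surv)
  mc_se <- sd(surv) / sqrt(length(x))
  quad <- control_cumulative_incidence(-2.0, 0.5, 1.5, 5)
  expect_lt(abs(quad - mc), 3 * mc_se)
})

test_that("censoring-free concordance has the exchangeable/monotone limits", {
  expect_equal(control_concordance(0), 0.5, tolerance = 1e-12)
  expect_gt(control_concordance(10), 0.95)
  b <- seq(0, 3, by = 0.25)
  cc <- vapply(b, control_concordance, 0)
  expect_true(all(diff(cc) > 0))
  expect_equal(control_concordance(-1.3), control_concordance(1.3),
               tolerance = 1e-12)
})

test_that("concordance quadrature matches a pairwise Monte-Carlo oracle", {
  # oracle: simulate exponential pairs with hazards e^{beta x}, count which
  # member fails first
  set.seed(7)
  n <- 1e6
  x1 <- rnorm(n); x2 <- rnorm(n)
  t1 <- rexp(n, exp(1.0 * x1)); t2 <- rexp(n, exp(1.0 * x2))
  conc <- (x1 > x2) == (t1 < t2)
  mc <- mean(conc)
  mc_se <- sqrt(mc * (1 - mc) / n)
  expect_lt(abs(control_concordance(1.0) - mc), 3 * mc_se)
})

test_that("analytic Harrell C under censoring matches a simulated control arm", {
  cal <- cal_for(0.85, 0.1)
  sc <- cal$scenario
  set.seed(11)
  n <- 2e5
  x <- rnorm(n)
  h <- exp(cal$kappa + cal$beta * x)
  te <- (-log(runif(n)) / h)^(1 / sc$w)
  td <- rexp(n, sc$d)
  tt <- pmin(te, td, sc$followup)
  ev <- as.integer(te <= pmin(td, sc$followup))
  hc <- survival::concordance(survival::Surv(tt, ev) ~ x,
                              reverse = TRUE)$concordance
  expect_lt(abs(hc - sc$C_target), 0.01)
})

test_that("calibration hits a non-prognostic target and round-trips", {
  cal0 <- calibrate_scenario(trial_scenario(Lambda_target = 0.6,
                                            C_target = 0.5))
  expect_lt(abs(cal0$beta), 1e-6)
  expect_equal(cal0$kappa, log(-log(1 - 0.6) / 5^1.5), tolerance = 1e-6)

  for (cm in c("harrell", "concordance")) {
    cal <- calibrate_scenario(trial_scenario(Lambda_target = 0.9,
                                             C_target = 0.75, d = 0.01),
                              c_method = cm)
    expect_lt(abs(cal$achieved_Lambda - 0.9), 1e-4)
    expect_lt(abs(cal$achieved_C - 0.75), 1e-3)
    expect_equal(
      control_cumulative_incidence(cal$kappa, cal$beta, 1.5, 5), 0.9,
      tolerance = 1e-4)
  }
})

test_that("a calibrated control arm reproduces the target incidence by forward simulation", {
  cal <- cal_for(0.65, 0.9, d = 0)
  set.seed(3)
  n <- 4e5
  co <- simulate_cohort(cal, n)
  frac <- mean(co$t_event[co$z == 0] <= 5)
  se <- sqrt(0.9 * 0.1 / sum(co$z == 0))
  expect_lt(abs(frac - 0.9), 3 * se)
})

test_that("incidence is increasing in kappa and calibration is deterministic", {
  ks <- seq(-4, 1, by = 0.5)
  lam <- vapply(ks, function(k)
    control_cumulative_incidence(k, 0.7, 1.5, 5), 0)
  expect_true(all(diff(lam) > 0))

  sc <- trial_scenario(Lambda_target = 0.5, C_target = 0.75, d = 0.01)
  a <- calibrate_scenario(sc)
  b <- calibrate_scenario(sc)
  expect_identical(a$kappa, b$kappa)
  expect_identical(a$beta, b$beta)
})

test_that("unattainable targets raise calibration errors", {
  expect_error(trial_scenario(C_target = 1.0))
  expect_error(trial_scenario(Lambda_target = 0))
})
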