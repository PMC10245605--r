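test_that("Cox-Snell formula evaluates its defining expression", {
  expect_equal(r2_cox_snell(-100, -100, 50), 0)
  expect_equal(r2_cox_snell(-200, -200 + 500, 1000), 1 - exp(-1))
  expect_error(r2_cox_snell(-100, -101, 50))
})

test_that("panel R2_CS equals the formula applied to independent coxph fits", {
  cal <- cal_for(0.75, 0.9)
  set.seed(31)
  co <- simulate_control(cal, 1000)
  p <- r2_panel(co$time, co$event, co$x)

  # independent route: two survival::coxph fits and the closed formula
  fit <- survival::coxph(survival::Surv(co$time, co$event) ~ co$x[, 1],
                         ties = "efron")
  ref <- 1 - exp(-2 / co$n * (fit$loglik[2] - fit$loglik[1]))
  expect_equal(p$r2_cs, ref, tolerance = 1e-6)
  expect_equal(p$l1 - p$l0, fit$loglik[2] - fit$loglik[1],
               tolerance = 1e-6)
})

test_that("all measures are near zero for a non-prognostic covariate", {
  cal <- calibrate_scenario(trial_scenario(Lambda_target = 0.9,
                                           C_target = 0.5, d = 0.01))
  m <- average_r2(cal, reps = 200, n = 1000, seed = 32)
  sds <- attr(m, "sd") / sqrt(200)
  for (k in names(m)) {
    expect_lt(m[[k]], 0.01 + 3 * sds[[k]])
  }
})

test_that("event-normalized rho2_k dominates R2_CS under censoring", {
  cal <- cal_for(0.75, 0.5)
  set.seed(33)
  co <- simulate_control(cal, 800)
  expect_lt(sum(co$event), co$n)
  p <- r2_panel(co$time, co$event, co$x)
  expect_gte(p$rho2_k, p$r2_cs)
})

test_that("measures are invariant to affine rescaling of the covariate", {
  cal <- cal_for(0.85, 0.9)
  set.seed(34)
  co <- simulate_control(cal, 600)
  keys <- c("r2_cs", "rho2_k", "r2_d", "r2_i", "r2_pm", "r2_r",
            "rho2_wa", "rho2_xoq")
  a <- r2_panel(co$time, co$event, co$x)
  b <- r2_panel(co$time, co$event, 3.7 * co$x + 2)
  expect_equal(unlist(a[keys]), unlist(b[keys]), tolerance = 1e-5)
})

test_that("R2_CS tracks cumulative incidence while EV measures stay flat", {
  m_lo <- average_r2(cal_for(0.75, 0.3), reps = 60, n = 1000, seed = 35)
  m_hi <- average_r2(cal_for(0.75, 0.9), reps = 60, n = 1000, seed = 36)
  cs_shift <- m_hi[["r2_cs"]] - m_lo[["r2_cs"]]
  expect_gt(cs_shift, 0.08)
  # EV measures move far less than the Cox-Snell measure (they are not
  # exactly flat: the C-index calibration under censoring shifts beta a
  # little across incidence levels)
  for (k in c("r2_d", "r2_pm", "r2_r", "r2_i", "rho2_wa")) {
    expect_lt(abs(m_hi[[k]] - m_lo[[k]]), 0.5 * cs_shift)
  }
})

test_that("panel rejects eventless data", {
  expect_error(r2_panel(c(1, 2, 3), c(0, 0, 0), matrix(rnorm(3))))
})
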