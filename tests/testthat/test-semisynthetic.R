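test_that("surrogate cohort has the documented shape and no missing values", {
  tab <- generate_surrogate_cohort(seed = 5)
  expect_s3_class(tab, "cohort_table")
  expect_identical(nrow(tab), 328L)
  expect_false(anyNA(tab))
  expect_true(all(tab$tumor_staging %in% 1:3))
  expect_true(all(tab$ecog %in% 0:2))
  expect_true(all(tab$child_pugh %in% c("A", "B")))
  expect_true(all(tab$observed_time > 0))
  expect_gt(sum(tab$event), 2)
})

test_that("surrogate generator meets its summary targets at large n", {
  tab <- generate_surrogate_cohort(1e5, seed = 7)
  km <- survival::survfit(survival::Surv(observed_time, event) ~ 1,
                          data = tab)
  inc5 <- 1 - summary(km, times = 5)$surv
  expect_lt(abs(inc5 - 0.49), 0.02)

  cidx <- function(covs) {
    X <- semisynthetic_design(tab, covs)
    fit <- cox_fit(tab$observed_time, tab$event, X)
    survival::concordance(
      survival::Surv(tab$observed_time, tab$event) ~
        I(drop(X %*% fit$coef)), reverse = TRUE)$concordance
  }
  expect_lt(abs(cidx(c("tumor_staging", "ecog")) - 0.65), 0.02)
  expect_lt(abs(cidx(c("tumor_staging", "ecog", "risk_score")) - 0.70),
            0.02)

  lev <- hcc_eligibility_levels()
  expect_lt(abs(mean(lev$mild(tab)) - 0.82), 0.02)
  expect_lt(abs(mean(lev$most(tab)) - 0.52), 0.02)
})

test_that("zeroing the score coefficient equalizes the two C-indices", {
  cfg <- surrogate_config(s_score = 0)
  tab <- generate_surrogate_cohort(3e4, config = cfg, seed = 8)
  cidx <- function(covs) {
    X <- semisynthetic_design(tab, covs)
    fit <- cox_fit(tab$observed_time, tab$event, X)
    survival::concordance(
      survival::Surv(tab$observed_time, tab$event) ~
        I(drop(X %*% fit$coef)), reverse = TRUE)$concordance
  }
  expect_lt(abs(cidx(c("tumor_staging", "ecog", "risk_score")) -
                  cidx(c("tumor_staging", "ecog"))), 0.01)
})

test_that("Breslow baseline matches hand-computed increments and survival::basehaz", {
  tab <- data.frame(tumor_staging = c(1, 2, 1, 3, 2, 1),
                    ecog = c(0, 1, 1, 0, 0, 1),
                    child_pugh = c("A", "A", "B", "A", "B", "A"),
                    macrovascular_invasion = c(0, 1, 0, 0, 1, 0),
                    hbv = c(0, 0, 1, 0, 0, 0), hcv = c(0, 0, 0, 1, 0, 0),
                    risk_score = c(0.5, -0.3, 0.1, -0.9, 0.8, -0.2),
                    observed_time = 1:6, event = c(1, 1, 0, 1, 1, 0))
  m <- fit_cox_with_baseline(tab, c("tumor_staging", "risk_score"))
  lp <- drop(semisynthetic_design(tab, m$covariates) %*% m$coef)
  w <- exp(lp)
  # hand enumeration: increment at each event time = 1 / sum(risk-set w)
  hand <- c(1 / sum(w), 1 / sum(w[2:6]), 1 / sum(w[4:6]), 1 / sum(w[5:6]))
  expect_equal(m$baseline$hazard, hand, tolerance = 1e-8)
  expect_equal(m$baseline$time, c(1, 2, 4, 5))
  bh <- survival::basehaz(
    survival::coxph(survival::Surv(observed_time, event) ~
                      tumor_staging + risk_score, data = tab,
                    ties = "efron"), centered = FALSE)
  expect_equal(m$baseline$cumhaz, bh$hazard[bh$time %in% c(1, 2, 4, 5)],
               tolerance = 1e-6)
})

test_that("baseline survival is a proper non-increasing step function", {
  tab <- generate_surrogate_cohort(500, seed = 9)
  m <- fit_cox_with_baseline(tab, c("tumor_staging", "ecog", "risk_score"))
  expect_true(all(diff(m$baseline$surv) <= 0))
  expect_true(all(m$baseline$surv > 0 & m$baseline$surv <= 1))
  expect_error(fit_cox_with_baseline(
    within(tab, risk_score2 <- 2 * risk_score),
    c("risk_score", "risk_score2")))
})

test_that("simulation from a fitted model round-trips the coefficients", {
  tab <- generate_surrogate_cohort(2000, seed = 10)
  m <- fit_cox_with_baseline(tab, c("tumor_staging", "ecog", "risk_score"))
  co <- simulate_from_fitted(m, tab, theta = 0.7, n = 5000, seed = 11)
  fit <- cox_fit(co$time, co$event, cbind(z = co$z, co$x))
  expect_true(fit$converged)
  est <- fit$coef[-1]
  ses <- fit$se[-1]
  expect_true(all(abs(est - unname(m$coef)) < 3 * ses))
  expect_lt(abs(fit$coef[1] - log(0.7)), 3 * fit$se[1])
})

test_that("simulated survival obeys the fitted power transform per risk profile", {
  tab <- generate_surrogate_cohort(2000, seed = 12)
  m <- fit_cox_with_baseline(tab, c("tumor_staging", "ecog", "risk_score"))
  # degenerate pool: one covariate row replicated -> every patient shares h
  for (row_id in c(which.min(tab$risk_score), which.max(tab$risk_score))) {
    one <- tab[rep(row_id, 50), ]
    co <- simulate_from_fitted(m, one, theta = 1, n = 3e4, seed = 13,
                               stratify_on = NULL)
    h <- exp(sum(semisynthetic_design(one[1, ], m$covariates) * m$coef))
    km <- survival::survfit(survival::Surv(co$time, co$event) ~ 1)
    ref <- stats::approx(c(0, m$baseline$time), c(1, m$baseline$surv^h),
                         xout = km$time, method = "constant",
                         rule = 2)$y
    expect_lt(max(abs(km$surv - ref)), 0.02)
    expect_true(all(co$time <= 5))
    expect_true(all(is.finite(co$t_event) |
                      co$event == 0)) # censored when U exceeds every step
  }
})

test_that("randomization is balanced within staging strata", {
  tab <- generate_surrogate_cohort(1000, seed = 14)
  m <- fit_cox_with_baseline(tab, c("tumor_staging", "risk_score"))
  co <- simulate_from_fitted(m, tab, theta = 0.72, n = 761, seed = 15)
  stg <- co$x[, "tumor_staging"]
  for (s in unique(stg)) {
    expect_lte(abs(sum(co$z[stg == s] == 1) - sum(co$z[stg == s] == 0)), 1)
  }
  expect_true(all(co$t_event[co$event == 1] %in% m$baseline$time))
})

test_that("a valueless score yields no material sample-size reduction", {
  cfg <- surrogate_config(s_score = 0)
  tab <- generate_surrogate_cohort(328, config = cfg, seed = 16)
  res <- run_semisynthetic_reduction(tab, theta = 0.72, reps = 600,
                                     seed = 17)
  expect_lt(abs(res$reduction), 0.08)
})
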