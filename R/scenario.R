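#' Define a parametric trial scenario
#'
#' A trial scenario collects the design parameters of a simulated two-arm
#' randomized time-to-event trial with a single standard-Gaussian prognostic
#' covariate. Event times follow a Weibull proportional-hazards model with
#' hazard multiplier \eqn{\theta^z \exp(\kappa + \beta x)}; the auxiliary
#' parameters \eqn{(\kappa, \beta)} are not part of the scenario but are
#' solved by [calibrate_scenario()] so that the control arm attains the
#' requested cumulative incidence and C-index.
#'
#' @param theta Treatment hazard ratio (> 0); values below 1 are protective.
#' @param Lambda_target Control-arm cumulative incidence at `followup`,
#'   i.e. the Kaplan-Meier probability of an event by end of follow-up,
#'   in (0, 1).
#' @param C_target Control-arm concordance index of the covariate, in
#'   \[0.5, 1).
#' @param w Weibull shape of the baseline hazard (> 0); 1 gives constant
#'   hazard, > 1 increasing.
#' @param d Drop-out rate of the exponential censoring process, events per
#'   year (>= 0).
#' @param followup Administrative censoring horizon in years; all patients
#'   still at risk are censored at this time.
#' @param alpha Two-sided significance level of the Wald test.
#' @param power_target Target statistical power.
#'
#' @return An object of class `trial_scenario`.
#' @examples
#' trial_scenario(theta = 0.7, Lambda_target = 0.9, C_target = 0.65)
#' @export
trial_scenario <- function(theta = 0.7, Lambda_target = 0.5, C_target = 0.65,
                           w = 1.5, d = 0, followup = 5,
                           alpha = 0.05, power_target = 0.8) {
  stopifnot(is.numeric(theta), length(theta) == 1, theta > 0,
            is.numeric(w), w > 0,
            is.numeric(d), d >= 0,
            is.numeric(followup), followup > 0,
            Lambda_target > 0, Lambda_target < 1,
            C_target >= 0.5, C_target < 1,
            alpha > 0, alpha < 1,
            power_target > 0, power_target < 1)
  structure(
    list(theta = theta, Lambda_target = Lambda_target, C_target = C_target,
         w = w, d = d, followup = followup, alpha = alpha,
         power_target = power_target, allocation = c(1, 1)),
    class = "trial_scenario")
}

#' @export
print.trial_scenario <- function(x, ...) {
  cat("Trial scenario (Weibull PH, 1:1 allocation)\n")
  cat(sprintf("  theta = %g, w = %g, d = %g /yr, follow-up = %g yr\n",
              x$theta, x$w, x$d, x$followup))
  cat(sprintf("  targets: Lambda = %g, C-index = %g\n",
              x$Lambda_target, x$C_target))
  cat(sprintf("  test: two-sided alpha = %g, target power = %g\n",
              x$alpha, x$power_target))
  invisible(x)
}

#' @export
print.calibrated_scenario <- function(x, ...) {
  print(x$scenario)
  cat(sprintf("Calibrated: kappa = %.6f, beta = %.6f\n", x$kappa, x$beta))
  cat(sprintf("  achieved Lambda = %.6f (gap %.2e), C = %.6f (gap %.2e)\n",
              x$achieved_Lambda, x$residuals[["Lambda"]],
              x$achieved_C, x$residuals[["C"]]))
  invisible(x)
}
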