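#' Fit a Cox model by Newton-Raphson (compiled inner-loop fitter)
#'
#' Maximizes the Cox partial likelihood with Efron tie handling. This is the
#' fitter used inside the Monte-Carlo loops, where hundreds of thousands of
#' small fits are needed; it is validated against [survival::coxph()] in the
#' test suite. For exploratory single fits prefer `coxph`, which offers
#' richer diagnostics.
#'
#' @param time Observed times (> 0).
#' @param event Event indicator, 0/1.
#' @param X Numeric covariate matrix (may have zero columns for the null
#'   model).
#' @return List with `coef`, `se`, `var`, `loglik`, `loglik_null` (log
#'   partial likelihood of the covariate-free model), `score0` (score vector
#'   at zero), `iter`, `converged`, `n`, `nevent`.
#' @export
cox_fit <- function(time, event, X) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  storage.mode(X) <- "double"
  fit <- .cox_fit_cpp(as.double(time), as.integer(event), X)
  fit$coef <- drop(fit$coef)
  fit$se <- drop(fit$se)
  fit$score0 <- drop(fit$score0)
  fit
}

#' Wald test for the treatment coefficient in a Cox regression
#'
#' Fits the Cox proportional-hazards model with the treatment indicator
#' alone (`adjust = FALSE`) or with the baseline covariate(s) added
#' (`adjust = TRUE`), and returns the two-sided Wald test for the treatment
#' coefficient. Non-convergent or degenerate fits are flagged, not raised:
#' during power simulation they are counted as non-rejections.
#'
#' @param cohort A `cohort` (from [simulate_cohort()] or
#'   [simulate_from_fitted()]).
#' @param adjust Include the covariate matrix `cohort$x` in the model?
#' @return A `cox_fit_result`: `coef`, `se`, `wald_z`, `p` for the treatment
#'   coefficient, `loglik`, `loglik_null`, `converged`, `ties = "efron"`.
#' @examples
#' cal <- calibrate_scenario(trial_scenario(Lambda_target = 0.9,
#'                                          C_target = 0.75))
#' set.seed(1)
#' cox_wald_test(simulate_cohort(cal, 300), adjust = TRUE)
#' @export
cox_wald_test <- function(cohort, adjust = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  if (sum(cohort$event) < 2) {
    return(structure(list(coef = NA_real_, se = NA_real_, wald_z = NA_real_,
                          p = NA_real_, loglik = NA_real_,
                          loglik_null = NA_real_, converged = FALSE,
                          ties = "efron"), class = "cox_fit_result"))
  }
  X <- if (adjust) cbind(z = cohort$z, cohort$x) else
    cbind(z = cohort$z)
  fit <- cox_fit(cohort$time, cohort$event, X)
  zstat <- fit$coef[1] / fit$se[1]
  structure(list(coef = fit$coef[1], se = fit$se[1], wald_z = zstat,
                 p = 2 * pnorm(-abs(zstat)), loglik = fit$loglik,
                 loglik_null = fit$loglik_null,
                 converged = isTRUE(fit$converged), ties = "efron"),
            class = "cox_fit_result")
}

#' @export
print.cox_fit_result <- function(x, ...) {
  cat(sprintf("Cox Wald test (treatment): coef = %.4f (se %.4f), z = %.3f, p = %.4g%s\n",
              x$coef, x$se, x$wald_z, x$p,
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}
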