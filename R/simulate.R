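#' Simulate a two-arm trial cohort from a calibrated scenario
#'
#' Generates `n` patients from the calibrated Weibull proportional-hazards
#' model: covariate `x` iid standard Gaussian (optionally truncated for
#' restricted eligibility), treatment `z` assigned as an exact half split
#' independent of `x`, latent event time by inverse transform
#' \eqn{T = (-\log U / h)^{1/w}} with hazard multiplier
#' \eqn{h = \theta^z e^{\kappa + \beta x}}, exponential drop-out at rate `d`,
#' and administrative censoring at `followup`.
#'
#' @param calibrated A `calibrated_scenario` from [calibrate_scenario()].
#' @param n Number of patients (>= 4). For odd `n` the control arm receives
#'   the extra patient.
#' @param restrict_quantile If not `NULL`, enrollment is restricted to
#'   patients with `x` below the population quantile
#'   \eqn{\Phi^{-1}(q)}; enrollment continues until `n` eligible
#'   patients are randomized, so the cohort has full size but a truncated
#'   covariate distribution. `1` means no restriction.
#' @param followup Override of the scenario's follow-up horizon (e.g. `Inf`
#'   to disable administrative censoring).
#' @return A `cohort`: list with covariate matrix `x` (n x 1), arm indicator
#'   `z`, latent `t_event` and `t_drop`, observed `time`, `event` flag and
#'   `n`.
#' @examples
#' cal <- calibrate_scenario(trial_scenario(Lambda_target = 0.9,
#'                                          C_target = 0.65))
#' set.seed(1)
#' coh <- simulate_cohort(cal, 200)
#' mean(coh$event[coh$z == 0])
#' @export
simulate_cohort <- function(calibrated, n, restrict_quantile = NULL,
                            followup = NULL) {
  stopifnot(inherits(calibrated, "calibrated_scenario"))
  if (n < 4) stop("n must be at least 4")
  sc <- calibrated$scenario
  if (is.null(followup)) followup <- sc$followup

  if (is.null(restrict_quantile) || restrict_quantile >= 1) {
    x <- rnorm(n)
  } else {
    if (restrict_quantile <= 0) stop("restrict_quantile must be in (0, 1]")
    # inverse-CDF draw from the Gaussian truncated above at the population
    # quantile: screened patients beyond the threshold are never enrolled
    x <- qnorm(runif(n) * restrict_quantile)
  }
  z <- sample(rep(c(0L, 1L), c(ceiling(n / 2), floor(n / 2))))
  h <- sc$theta^z * .clip_exp(calibrated$kappa + calibrated$beta * x)
  t_event <- (-log(runif(n)) / h)^(1 / sc$w)
  t_drop <- if (sc$d > 0) rexp(n, sc$d) else rep(Inf, n)
  time <- pmin(t_event, t_drop, followup)
  event <- as.integer(t_event <= pmin(t_drop, followup))

  structure(list(x = matrix(x, ncol = 1, dimnames = list(NULL, "x")),
                 z = z, t_event = t_event, t_drop = t_drop,
                 time = time, event = event, n = as.integer(n)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort: %d patients (%d control / %d treated), %d events\n",
              x$n, sum(x$z == 0), sum(x$z == 1), sum(x$event)))
  invisible(x)
}

#' @export
as.data.frame.cohort <- function(x, ...) {
  data.frame(x$x, z = x$z, time = x$time, event = x$event)
}

#' Restrict an existing cohort to low-risk patients
#'
#' Applies the restricted-eligibility rule of the parametric experiments:
#' keep patients with covariate value below the population quantile
#' \eqn{\Phi^{-1}(q)} of the standard Gaussian (the design-stage threshold,
#' not the empirical sample quantile). The returned cohort is smaller; the
#' `screened` attribute records the original size.
#'
#' @param cohort A `cohort`.
#' @param quantile Inclusion quantile in (0, 1\]; `1` keeps everyone.
#' @return The restricted `cohort` with attribute `screened`.
#' @export
restrict_parametric <- function(cohort, quantile = 0.8) {
  stopifnot(inherits(cohort, "cohort"))
  if (quantile <= 0 || quantile > 1) stop("quantile must be in (0, 1]")
  if (quantile == 1) {
    attr(cohort, "screened") <- cohort$n
    return(cohort)
  }
  keep <- cohort$x[, 1] < qnorm(quantile)
  out <- structure(list(x = cohort$x[keep, , drop = FALSE],
                        z = cohort$z[keep],
                        t_event = cohort$t_event[keep],
                        t_drop = cohort$t_drop[keep],
                        time = cohort$time[keep],
                        event = cohort$event[keep],
                        n = sum(keep)),
                   class = "cohort")
  attr(out, "screened") <- cohort$n
  out
}

#' Screened-population size for a required enrollment
#'
#' Expected number of patients whose eligibility must be evaluated to
#' randomize `n_required` patients when a fraction `inclusion_fraction` of
#' the screened population is eligible.
#'
#' @param n_required Randomized patients needed.
#' @param inclusion_fraction Probability a screened patient is eligible,
#'   in (0, 1\].
#' @return Integer screened count, `ceiling(n_required / inclusion_fraction)`.
#' @examples
#' screened_population(100, 0.5)
#' @export
screened_population <- function(n_required, inclusion_fraction) {
  if (inclusion_fraction <= 0 || inclusion_fraction > 1)
    stop("inclusion_fraction must be in (0, 1]")
  stopifnot(n_required > 0)
  as.integer(ceiling(n_required / inclusion_fraction))
}
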