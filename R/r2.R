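#' Cox-Snell R-squared from nested model log-likelihoods
#'
#' \deqn{R^2_{CS} = 1 - \exp\left[-\tfrac{2}{n}(l_1 - l_0)\right]}
#' where \eqn{l_0} and \eqn{l_1} are the log-likelihoods of a base model and
#' of a model adjusting for additional covariates, and \eqn{n} the number of
#' patients. For a Cox model the log partial likelihoods are used and the
#' base model is the covariate-free (null) model.
#'
#' @param l0,l1 Log-likelihoods of the nested base and full models
#'   (`l1 >= l0`).
#' @param n Number of patients.
#' @return A proportion in \[0, 1).
#' @examples
#' r2_cox_snell(-500, -450, n = 1000)
#' @export
r2_cox_snell <- function(l0, l1, n) {
  stopifnot(n >= 1)
  if (l1 < l0 - 1e-8 * max(1, abs(l0)))
    stop("l1 < l0: models are not nested or fits did not converge")
  1 - exp(-2 / n * max(l1 - l0, 0))
}

# expected standard-normal order statistics (Blom rankits)
.rankits <- function(n) qnorm((seq_len(n) - 0.375) / (n + 0.25))

#' Panel of eight survival R-squared measures
#'
#' Computes, from one dataset, the explained-variation (EV) measures
#' \eqn{R^2_D, R^2_I, R^2_{PM}, R^2_R} and explained-randomness (ER)
#' measures \eqn{\rho^2_k, \rho^2_{WA}, \rho^2_{XOQ}, R^2_{CS}} for the Cox
#' model of `time`/`event` on covariates `X` against the covariate-free
#' null model.
#'
#' Formulations (with \eqn{v} the sample variance of the fitted prognostic
#' index \eqn{\hat\beta^T X}, \eqn{\sigma^2 = \pi^2/6} the extreme-value
#' error variance of the PH model on the log-time scale, and
#' \eqn{\kappa_D = \sqrt{8/\pi}}):
#' \itemize{
#'   \item \eqn{R^2_{CS} = 1 - e^{-2(l_1 - l_0)/n}}; \eqn{\rho^2_k} is the
#'     same expression with \eqn{n} replaced by the event count \eqn{k}.
#'   \item \eqn{R^2_{PM} = v / (v + \sigma^2)} (prognostic-index variance
#'     ratio); \eqn{\rho^2_{WA} = v / (v + 1)} is the Weibull-approximation
#'     variant with unit error scale.
#'   \item \eqn{D} is the Royston-Sauerbrei prognostic separation: the Cox
#'     coefficient of the scaled normal order statistics
#'     (rankits / \eqn{\kappa_D}) ordered by the prognostic index;
#'     \eqn{R^2_D = (D^2/\kappa_D^2) / (D^2/\kappa_D^2 + \sigma^2)}, and
#'     \eqn{R^2_I} is its unit-error-scale variant
#'     \eqn{(D^2/\kappa_D^2) / (D^2/\kappa_D^2 + 1)}.
#'   \item \eqn{\rho^2_{XOQ} = 1 - e^{-\hat\Gamma}} with \eqn{\hat\Gamma}
#'     the Kaplan-Meier-weighted average over event times of twice the
#'     conditional log-likelihood gain of the fitted model over the null in
#'     the risk-set (conditional) distribution.
#' }
#' \eqn{R^2_R} is the robust-scale variant of \eqn{R^2_{PM}}, using the
#' squared normalized MAD of the prognostic index in place of its variance.
#'
#' @param time Observed times.
#' @param event Event indicators (0/1); at least one event required.
#' @param X Covariate matrix.
#' @return An `r2_panel` list: the eight measures plus `n`, `k`, `l0`,
#'   `l1`, `v` and the fit convergence flag.
#' @examples
#' cal <- calibrate_scenario(trial_scenario(Lambda_target = 0.9,
#'                                          C_target = 0.75))
#' set.seed(1)
#' co <- simulate_control(cal, 500)
#' r2_panel(co$time, co$event, co$x)
#' @export
r2_panel <- function(time, event, X) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  n <- length(time)
  k <- sum(event)
  if (k == 0) stop("no events: R2 measures undefined")
  fit <- cox_fit(time, event, X)
  l0 <- fit$loglik_null
  l1 <- fit$loglik
  lrgain <- max(l1 - l0, 0)

  pi2_6 <- pi^2 / 6
  PI <- drop(X %*% fit$coef)
  v <- var(PI)
  v_mad <- (mad(PI))^2

  # Royston-Sauerbrei D: Cox regression on scaled rankits ordered by PI
  kap <- sqrt(8 / pi)
  zr <- numeric(n)
  zr[order(PI)] <- .rankits(n) / kap
  dfit <- cox_fit(time, event, matrix(zr, ncol = 1))
  D <- dfit$coef[1]
  d2 <- D^2 / kap^2

  structure(list(
    r2_cs = 1 - exp(-2 * lrgain / n),
    rho2_k = 1 - exp(-2 * lrgain / k),
    r2_d = d2 / (d2 + pi2_6),
    r2_i = d2 / (d2 + 1),
    r2_pm = v / (v + pi2_6),
    r2_r = v_mad / (v_mad + pi2_6),
    rho2_wa = v / (v + 1),
    rho2_xoq = .rho2_xoq(time, event, PI),
    n = n, k = k, l0 = l0, l1 = l1, v = v,
    converged = isTRUE(fit$converged)), class = "r2_panel")
}

# Explained randomness of Xu & O'Quigley type: average over event times,
# weighted by the Kaplan-Meier increments, of twice the gain in conditional
# log-likelihood (risk-set distribution) of the fitted over the null model.
.rho2_xoq <- function(time, event, PI) {
  o <- order(time)
  t_s <- time[o]; e_s <- event[o]; eta <- pmin(pmax(PI[o], -700), 700)
  w <- exp(eta)
  # risk-set sums at each position, constant within tied-time groups
  grp_first <- match(t_s, t_s)               # first index of each tie group
  csum_w <- rev(cumsum(rev(w)))
  csum_1 <- rev(cumsum(rev(rep(1, length(w)))))
  S_w <- csum_w[grp_first]
  S_1 <- csum_1[grp_first]
  ev <- which(e_s == 1)
  if (length(ev) == 0) return(0)

  # Kaplan-Meier mass at each event (product-limit over tied-time groups;
  # the jump at a tied time is split evenly across its events)
  uniq <- !duplicated(t_s)
  grp_id <- cumsum(uniq)               # group index per row, in time order
  d_j <- as.vector(rowsum(e_s, grp_id))
  n_j <- S_1[uniq]
  s_prev <- cumprod(c(1, utils::head(1 - d_j / n_j, -1)))
  wt <- (s_prev / n_j)[grp_id[ev]]
  if (sum(wt) <= 0) wt <- rep(1, length(ev))

  gain <- 2 * ((eta[ev] - log(S_w[ev])) - (-log(S_1[ev])))
  Gamma <- sum(wt * gain) / sum(wt)
  1 - exp(-Gamma)
}

#' @export
print.r2_panel <- function(x, ...) {
  m <- unlist(x[c("r2_cs", "rho2_k", "r2_d", "r2_i", "r2_pm", "r2_r",
                  "rho2_wa", "rho2_xoq")])
  cat(sprintf("R2 panel (n = %d, events = %d):\n", x$n, x$k))
  print(round(m, 4))
  invisible(x)
}

#' Simulate a control-only cohort
#'
#' Control-arm patients from the calibrated model (no treatment), with
#' drop-out and administrative censoring applied; the sampling protocol for
#' R-squared estimation uses datasets of control patients only.
#'
#' @inheritParams simulate_cohort
#' @return A `cohort` with all `z = 0`.
#' @export
simulate_control <- function(calibrated, n, followup = NULL) {
  stopifnot(inherits(calibrated, "calibrated_scenario"))
  sc <- calibrated$scenario
  if (is.null(followup)) followup <- sc$followup
  x <- rnorm(n)
  h <- .clip_exp(calibrated$kappa + calibrated$beta * x)
  t_event <- (-log(runif(n)) / h)^(1 / sc$w)
  t_drop <- if (sc$d > 0) rexp(n, sc$d) else rep(Inf, n)
  structure(list(x = matrix(x, ncol = 1, dimnames = list(NULL, "x")),
                 z = rep(0L, n), t_event = t_event, t_drop = t_drop,
                 time = pmin(t_event, t_drop, followup),
                 event = as.integer(t_event <= pmin(t_drop, followup)),
                 n = as.integer(n)),
            class = "cohort")
}

#' Replication-averaged R-squared panel for a scenario
#'
#' Estimation protocol for scenario-level R-squared values: each measure is
#' the mean over `reps` independent simulated datasets of `n` control
#' patients.
#'
#' @param calibrated A `calibrated_scenario`.
#' @param reps Number of simulated datasets (protocol default 1000; smaller
#'   values trade precision for speed).
#' @param n Control patients per dataset (protocol default 1000).
#' @param seed Seed.
#' @return Named numeric vector of the eight averaged measures, with the
#'   per-dataset standard deviations in attribute `"sd"`.
#' @export
average_r2 <- function(calibrated, reps = 1000, n = 1000, seed = 1) {
  keys <- c("r2_cs", "rho2_k", "r2_d", "r2_i", "r2_pm", "r2_r",
            "rho2_wa", "rho2_xoq")
  set.seed(seed)
  acc <- matrix(NA_real_, nrow = reps, ncol = length(keys),
                dimnames = list(NULL, keys))
  for (r in seq_len(reps)) {
    co <- simulate_control(calibrated, n)
    p <- r2_panel(co$time, co$event, co$x)
    acc[r, ] <- unlist(p[keys])
  }
  out <- colMeans(acc)
  attr(out, "sd") <- apply(acc, 2, sd)
  out
}

#' Generalized Fleiss sample-size prediction
#'
#' Predicts the adjusted-analysis sample size from the unadjusted one and a
#' proportion of explained variation: \eqn{N_{adj} = N_0 (1 - r^2)},
#' rounded up to an even total. With the Cox-Snell \eqn{R^2_{CS}} as
#' \eqn{r^2} this extends the Fleiss formula to time-to-event outcomes.
#'
#' @param n0 Unadjusted sample size (>= 1).
#' @param r2 Proportion of explained variation in \[0, 1).
#' @return Even integer predicted adjusted sample size.
#' @examples
#' fleiss_predict(1000, 0.25) # correlation 0.5 -> 25% fewer patients
#' @export
fleiss_predict <- function(n0, r2) {
  stopifnot(n0 >= 1)
  if (r2 < 0 || r2 >= 1) stop("r2 must be in [0, 1)")
  .even_up(n0 * (1 - r2))
}
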