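# Paired Monte-Carlo power for two analyses of the same simulated trials.
# `gen` draws one cohort; `covA`/`covB` map a cohort to the adjustment
# covariate matrix of each analysis (NULL = unadjusted). Using the same
# cohorts for both analyses makes power differences paired estimates.
.mc_power_pair <- function(gen, reps, alpha,
                           covA = function(co) NULL,
                           covB = function(co) co$x) {
  rejA <- rejB <- 0L
  ncA <- ncB <- 0L
  events <- 0
  for (r in seq_len(reps)) {
    co <- gen()
    events <- events + sum(co$event)
    for (side in 1:2) {
      Xextra <- if (side == 1) covA(co) else covB(co)
      X <- if (is.null(Xextra)) cbind(z = co$z) else cbind(z = co$z, Xextra)
      fit <- cox_fit(co$time, co$event, X)
      ok <- isTRUE(fit$converged) && is.finite(fit$se[1]) && fit$se[1] > 0
      rej <- ok && (2 * pnorm(-abs(fit$coef[1] / fit$se[1])) < alpha)
      if (side == 1) {
        rejA <- rejA + rej; ncA <- ncA + !ok
      } else {
        rejB <- rejB + rej; ncB <- ncB + !ok
      }
    }
  }
  pA <- rejA / reps; pB <- rejB / reps
  list(power_A = pA, power_B = pB,
       se_A = sqrt(pA * (1 - pA) / reps), se_B = sqrt(pB * (1 - pB) / reps),
       mean_events = events / reps, nonconv_A = ncA, nonconv_B = ncB,
       reps = reps)
}

#' Monte-Carlo power of the Cox Wald test
#'
#' Simulates `reps` trials of `n` patients from the calibrated scenario and
#' returns the fraction in which the two-sided Wald test for the treatment
#' coefficient rejects at level `alpha`. Non-convergent fits count as
#' non-rejections (conservative) and are reported.
#'
#' @param calibrated A `calibrated_scenario`.
#' @param n Patients per trial.
#' @param reps Replications (>= 100).
#' @param adjust Adjust for the covariate?
#' @param seed Optional seed set before simulation.
#' @param alpha Significance level; defaults to the scenario's.
#' @param restrict_quantile Optional eligibility restriction passed to
#'   [simulate_cohort()].
#' @return List with `power`, `se` (binomial Monte-Carlo SE),
#'   `mean_events`, `nonconverged`, `n`, `reps`, `adjusted`.
#' @examples
#' cal <- calibrate_scenario(trial_scenario(Lambda_target = 0.9,
#'                                          C_target = 0.65))
#' estimate_power(cal, n = 300, reps = 200, adjust = TRUE, seed = 1)
#' @export
estimate_power <- function(calibrated, n, reps = 1000, adjust = FALSE,
                           seed = NULL, alpha = NULL,
                           restrict_quantile = NULL) {
  stopifnot(inherits(calibrated, "calibrated_scenario"), reps >= 100)
  if (is.null(alpha)) alpha <- calibrated$scenario$alpha
  if (!is.null(seed)) set.seed(seed)
  gen <- function() simulate_cohort(calibrated, n, restrict_quantile)
  res <- .mc_power_pair(gen, reps, alpha)
  p <- if (adjust) res$power_B else res$power_A
  list(power = p, se = sqrt(p * (1 - p) / reps),
       mean_events = res$mean_events,
       nonconverged = if (adjust) res$nonconv_B else res$nonconv_A,
       n = n, reps = reps, adjusted = adjust)
}

#' Power over a grid of sample sizes
#'
#' @inheritParams estimate_power
#' @param n_grid Vector of sample sizes.
#' @return Data frame with one row per (n, analysis): columns `n`,
#'   `adjusted`, `power`, `se`, `mean_events`. At each `n` both analyses
#'   are evaluated on the same simulated trials.
#' @export
power_curve <- function(calibrated, n_grid, reps = 1000, seed = NULL,
                        alpha = NULL, restrict_quantile = NULL) {
  if (is.null(alpha)) alpha <- calibrated$scenario$alpha
  rows <- lapply(n_grid, function(n) {
    if (!is.null(seed)) set.seed(derive_seed(seed, n))
    gen <- function() simulate_cohort(calibrated, n, restrict_quantile)
    r <- .mc_power_pair(gen, reps, alpha)
    data.frame(n = rep(n, 2), adjusted = c(FALSE, TRUE),
               power = c(r$power_A, r$power_B), se = c(r$se_A, r$se_B),
               mean_events = r$mean_events)
  })
  do.call(rbind, rows)
}

# Analytic starting guess: Schoenfeld events formula divided by the
# per-patient event probability estimated from one quick simulation.
.n_guess <- function(calibrated, seed) {
  sc <- calibrated$scenario
  ev_needed <- 4 * (qnorm(1 - sc$alpha / 2) + qnorm(sc$power_target))^2 /
    log(sc$theta)^2
  set.seed(derive_seed(seed, 0L))
  co <- simulate_cohort(calibrated, 40000)
  p_event <- max(mean(co$event), 1e-4)
  max(2 * ceiling(ev_needed / p_event / 2), 8)
}

.even_up <- function(n) as.integer(2 * ceiling(n / 2))

# invert a probed power curve at `target`: isotonic fit over probed n,
# then linear interpolation at the first crossing, rounded up to even
.invert_power_curve <- function(ns, powers, target) {
  o <- order(ns)
  ns <- ns[o]; powers <- powers[o]
  agg_n <- sort(unique(ns))
  agg_p <- vapply(agg_n, function(v) mean(powers[ns == v]), 0)
  yf <- if (length(agg_n) > 1) isoreg(agg_n, agg_p)$yf else agg_p
  i <- which(yf >= target)[1]
  if (is.na(i)) return(NA_integer_)
  if (i == 1) return(.even_up(agg_n[1]))
  dy <- yf[i] - yf[i - 1]
  nstar <- if (dy < 1e-12) agg_n[i] else
    agg_n[i - 1] + (target - yf[i - 1]) / dy * (agg_n[i] - agg_n[i - 1])
  .even_up(nstar)
}

# Shared-probe search: every probed n evaluates both analyses on the same
# simulated trials (probe seed is a deterministic function of the master
# seed and n, so a probe reused by both searches is computed once).
.reduction_engine <- function(gen_factory, calibrated, reps, seed,
                              n_start, n_max, alpha, target,
                              covA, covB, refine = 3L) {
  cache <- new.env(parent = emptyenv())
  probe <- function(n) {
    n <- .even_up(n)
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      set.seed(derive_seed(seed, n))
      res <- .mc_power_pair(gen_factory(n), reps, alpha, covA, covB)
      cache[[key]] <- c(n = n, pA = res$power_A, pB = res$power_B,
                        events = res$mean_events)
    }
    cache[[key]]
  }
  bracket <- function(col) {
    lo <- hi <- .even_up(n_start)
    p <- probe(lo)[[col]]
    if (p < target) {
      while (p < target) {
        lo <- hi
        hi <- .even_up(hi * 1.4)
        if (hi > n_max) stop("sample-size search exceeded n_max = ", n_max)
        p <- probe(hi)[[col]]
      }
    } else {
      while (p >= target && lo > 8) {
        hi <- lo
        lo <- max(8, .even_up(lo / 1.4))
        p <- probe(lo)[[col]]
      }
    }
    for (k in seq_len(refine)) {
      mid <- .even_up((lo + hi) / 2)
      if (mid <= lo || mid >= hi) break
      if (probe(mid)[[col]] >= target) hi <- mid else lo <- mid
    }
    invisible(NULL)
  }
  bracket("pA")
  bracket("pB")
  get_tab <- function() {
    tab <- as.data.frame(do.call(rbind,
                                 lapply(ls(cache), function(k) cache[[k]])))
    tab <- tab[order(tab$n), , drop = FALSE]
    rownames(tab) <- NULL
    tab
  }
  invert <- function(col) {
    # isotonic pooling can pull the fitted curve back under the target when
    # noisy high-n probes from the other search are merged in; extend the
    # bracket until the pooled curve crosses
    for (att in 1:6) {
      tab <- get_tab()
      N <- .invert_power_curve(tab$n, tab[[col]], target)
      if (!is.na(N)) return(N)
      nn <- .even_up(max(tab$n) * 1.4)
      if (nn > n_max) stop("sample-size search exceeded n_max = ", n_max)
      probe(nn)
    }
    stop("power target not reached on the probed grid")
  }
  N_A <- invert("pA")
  N_B <- invert("pB")
  list(N_A = N_A, N_B = N_B, probes = get_tab())
}

#' Observed sample-size reduction from covariate adjustment
#'
#' Runs the full pipeline for one calibrated scenario: locates the sample
#' size at which the unadjusted analysis reaches the target power
#' (\eqn{N_0}) and the size at which the covariate-adjusted analysis does
#' (\eqn{N_{adj}}), and returns the observed relative reduction
#' \eqn{R^2_{obs} = 1 - N_{adj}/N_0}. Both analyses are evaluated on the
#' same simulated trials at every probed sample size; the final sizes come
#' from isotonic-then-linear interpolation of the probed power curves.
#'
#' @param calibrated A `calibrated_scenario`.
#' @param reps Replications per probed sample size.
#' @param seed Master seed for the search.
#' @param n_max Abort threshold for the bracket search.
#' @param refine Bisection refinement steps after bracketing.
#' @return A `sample_size_result`: `N0`, `Nadj`, `R2_obs`, and the probed
#'   power table `probes` (`n`, `pA` unadjusted, `pB` adjusted, mean
#'   events).
#' @examples
#' \donttest{
#' cal <- calibrate_scenario(trial_scenario(Lambda_target = 0.9,
#'                                          C_target = 0.75, d = 0.01))
#' run_reduction(cal, reps = 400, seed = 1)
#' }
#' @export
run_reduction <- function(calibrated, reps = 2000, seed = 1,
                          n_max = 2e5, refine = 3L) {
  sc <- calibrated$scenario
  eng <- .reduction_engine(
    gen_factory = function(n) function() simulate_cohort(calibrated, n),
    calibrated = calibrated, reps = reps, seed = seed,
    n_start = .n_guess(calibrated, seed), n_max = n_max,
    alpha = sc$alpha, target = sc$power_target,
    covA = function(co) NULL, covB = function(co) co$x, refine = refine)
  structure(list(N0 = eng$N_A, Nadj = eng$N_B,
                 R2_obs = sample_size_reduction(eng$N_A, eng$N_B),
                 probes = eng$probes, reps = reps, seed = seed),
            class = "sample_size_result")
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat(sprintf("N0 = %d, Nadj = %d, R2_obs = %.1f%% (%d reps per probe)\n",
              x$N0, x$Nadj, 100 * x$R2_obs, x$reps))
  invisible(x)
}

#' Sample size at target power for one analysis
#'
#' @inheritParams run_reduction
#' @param adjust Search for the adjusted (`TRUE`) or unadjusted analysis.
#' @return Even integer sample size at the scenario's target power.
#' @export
find_sample_size <- function(calibrated, adjust = FALSE, reps = 2000,
                             seed = 1, n_max = 2e5, refine = 3L) {
  res <- run_reduction(calibrated, reps = reps, seed = seed, n_max = n_max,
                       refine = refine)
  if (adjust) res$Nadj else res$N0
}

#' Relative sample-size reduction
#'
#' @param N0 Unadjusted sample size at target power.
#' @param Nadj Adjusted sample size at the same power.
#' @return `1 - Nadj / N0` (negative if adjustment increased the size; not
#'   clipped).
#' @examples
#' sample_size_reduction(759, 671) # 0.116
#' @export
sample_size_reduction <- function(N0, Nadj) {
  if (N0 <= 0) stop("N0 must be positive")
  if (Nadj <= 0) stop("Nadj must be positive")
  1 - Nadj / N0
}
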