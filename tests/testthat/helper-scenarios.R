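# Calibration cache shared across test files (calibration is deterministic,
# so memoizing only saves time).
.cal_cache <- new.env(parent = emptyenv())

cal_for <- function(C, L, theta = 0.7, d = 0.01, w = 1.5,
                    c_method = "harrell") {
  key <- paste(C, L, theta, d, w, c_method, sep = "_")
  if (is.null(.cal_cache[[key]])) {
    .cal_cache[[key]] <- calibrate_scenario(
      trial_scenario(theta = theta, Lambda_target = L, C_target = C,
                     w = w, d = d),
      c_method = c_method)
  }
  .cal_cache[[key]]
}

# analytic marginal CDF of the control-arm event time (Gaussian mixture of
# Weibulls), used as an independent distributional oracle
mixture_event_cdf <- function(cal, nodes = 80) {
  gh <- pracma::gaussHermite(nodes)
  xs <- sqrt(2) * gh$x
  ws <- gh$w / sqrt(pi)
  h <- exp(cal$kappa + cal$beta * xs)
  w_shape <- cal$scenario$w
  function(t) {
    tw <- outer(pmax(t, 0)^w_shape, h)
    drop(1 - exp(-tw) %*% ws)
  }
}
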