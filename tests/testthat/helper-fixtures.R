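# shared fixture builders (everything is generated in code)

ar1_series <- function(n, phi, sd = 1, seed = 1, dt = 1) {
  set.seed(seed)
  e <- rnorm(n, 0, sd * sqrt(1 - phi^2))
  UniformSeries(as.numeric(stats::filter(e, phi, method = "recursive")),
                dt = dt)
}

sinus_series <- function(n, dt, period, amp = 1, noiseSd = 0, seed = 1) {
  t <- (seq_len(n) - 1) * dt
  v <- amp * sin(2 * pi * t / period)
  if (noiseSd > 0) {
    set.seed(seed)
    v <- v + rnorm(n, 0, noiseSd)
  }
  UniformSeries(v, dt = dt)
}

# logistic edge profile over a flat background
edge_profile <- function(nPx, centre, width, plateau = 100, bg = 10,
                         noiseSd = 0, seed = NULL) {
  p <- seq_len(nPx) - 1
  prof <- bg + (plateau - bg) / (1 + exp(-(centre - p) / width))
  if (noiseSd > 0) {
    if (!is.null(seed)) set.seed(seed)
    prof <- prof + rnorm(nPx, 0, noiseSd)
  }
  prof
}

# centred (bias-corrected) root-mean-square error: precision of a tracker
# whose reference-level convention implies a constant offset
crmse <- function(est, truth) {
  e <- est - truth
  e <- e[is.finite(e)]
  sqrt(mean((e - mean(e))^2))
}

quiet_outliers <- function(us, ...) suppressWarnings(removeOutliers(us, ...))

analyze_rate <- function(trace, ...) {
  suppressWarnings(analyzeOscillations(growthRate(trace), ...))
}
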