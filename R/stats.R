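#' Case-study summary statistics
#'
#' Mixture-model summaries of period/delay distributions, growth-regime
#' classification, Welch tests with Bonferroni correction, McNemar paired
#' detection comparison, and tracking-noise quantification.
#'
#' @name stats-module
NULL

.gmm2_em <- function(x, mu, sdv, w, maxIter = 500, tol = 1e-8) {
  n <- length(x)
  sdFloor <- 1e-6 * stats::sd(x)
  ll_old <- -Inf
  for (it in seq_len(maxIter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sdv[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sdv[2])
    tot <- d1 + d2
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    g <- d1 / tot
    n1 <- sum(g); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break
    mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
    sdv <- c(sqrt(sum(g * (x - mu[1])^2) / n1),
             sqrt(sum((1 - g) * (x - mu[2])^2) / n2))
    sdv <- pmax(sdv, sdFloor)
    w <- c(n1, n2) / n
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(mu = mu, sd = sdv, w = w, loglik = ll)
}

#' Fit a two-component Gaussian mixture
#'
#' Expectation-maximization, best of \code{nStarts} seeded k-means-style
#' initializations. The reported summary of a period/delay distribution is
#' the mean and sd of the main component (the one with the larger weight;
#' ties broken by the smaller sd).
#'
#' @param values numeric sample (periods, delays, ...), \code{n >= 20}.
#' @param seed RNG seed for the initializations.
#' @param nStarts number of restarts (default 10).
#' @return a [MixtureFit-class].
#' @export
fitGmm2 <- function(values, seed = 1, nStarts = 10) {
  x <- values[is.finite(values)]
  if (length(x) < 20L) stop("need at least 20 finite values")
  if (stats::sd(x) == 0)
    stop("degenerate data (all values equal): use descriptive statistics")
  best <- NULL
  for (s in seq_len(nStarts)) {
    set.seed(seed + s - 1L)
    km <- tryCatch(stats::kmeans(x, centers = 2, nstart = 1),
                   error = function(e) NULL)
    if (is.null(km)) next
    mu <- as.numeric(km$centers)
    sdv <- vapply(1:2, function(k) {
      v <- stats::sd(x[km$cluster == k])
      if (!is.finite(v) || v == 0) stats::sd(x) / 10 else v
    }, numeric(1))
    w <- as.numeric(table(factor(km$cluster, levels = 1:2))) / length(x)
    w <- pmax(w, 0.01); w <- w / sum(w)
    fit <- .gmm2_em(x, mu, sdv, w)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) stop("EM initialization failed")
  main <- if (abs(best$w[1] - best$w[2]) < 1e-12) {
    which.min(best$sd)
  } else which.max(best$w)
  new("MixtureFit", means = best$mu, sds = best$sd, weights = best$w,
      main = as.integer(main), loglik = best$loglik, seed = as.integer(seed))
}

#' Classify growth regime from the growth-rate trend
#'
#' Per-time labels from the low-frequency growth trend (the baseline left
#' after removing fluctuations, see [bandpass()]): growing above \code{hi}
#' (default 2 um/min), non-growing below \code{lo} (default 0.5 um/min),
#' intermediate otherwise (excluded from group comparisons).
#'
#' @param trend numeric vector or [UniformSeries-class] of the growth-rate
#'   trend, um/min.
#' @param hi,lo regime thresholds, um/min.
#' @return character vector of labels \code{"growing"},
#'   \code{"non_growing"}, \code{"intermediate"}.
#' @export
classifyGrowthRegime <- function(trend, hi = 2, lo = 0.5) {
  if (is(trend, "UniformSeries")) trend <- trend@v
  if (hi <= lo) stop("'hi' must exceed 'lo'")
  ifelse(trend > hi, "growing",
         ifelse(trend < lo, "non_growing", "intermediate"))
}

#' Welch t-tests with Bonferroni correction
#'
#' Unequal-variances t-test per comparison (Welch-Satterthwaite degrees of
#' freedom), with p-values adjusted as \code{min(1, m p)} and a confidence
#' interval for the difference in means.
#'
#' @param groups list of comparisons, each a list/pair of two numeric
#'   samples.
#' @param m number of comparisons for the correction (default
#'   \code{length(groups)}).
#' @param conf confidence level (default 0.95).
#' @return data.frame: \code{t}, \code{df}, \code{p}, \code{p_adj},
#'   \code{mean_diff}, \code{ci_low}, \code{ci_high}.
#' @export
welchBonferroni <- function(groups, m = NULL, conf = 0.95) {
  if (is.null(m)) m <- length(groups)
  out <- lapply(groups, function(g) {
    x <- g[[1]]; y <- g[[2]]
    if (length(x) < 2L || length(y) < 2L) stop("each group needs n >= 2")
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (mean(x) == mean(y))
        return(data.frame(t = 0, df = NA_real_, p = 1, p_adj = 1,
                          mean_diff = 0, ci_low = 0, ci_high = 0))
      stop("zero variance in both groups with different means")
    }
    tt <- stats::t.test(x, y, var.equal = FALSE, conf.level = conf)
    data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, p_adj = min(1, m * tt$p.value),
               mean_diff = unname(diff(rev(tt$estimate))),
               ci_low = tt$conf.int[1], ci_high = tt$conf.int[2])
  })
  res <- do.call(rbind, out)
  rownames(res) <- names(groups)
  res
}

#' Build the 2x2 paired detection table
#'
#' Cross-tabulates per-time detection (at least one ridge) of two methods
#' over the time points trustworthy for both (outside both cones of
#' influence). Both ridge sets must come from spectra on the same grid.
#'
#' @param ridgesA,ridgesB [RidgeSet-class] from the two methods.
#' @return 2x2 integer matrix with dimnames A/B x detected/not.
#' @export
compareDetection <- function(ridgesA, ridgesB) {
  if (length(ridgesA@times) != length(ridgesB@times) ||
      max(abs(ridgesA@times - ridgesB@times)) > 1e-9)
    stop("ridge sets are not on the same time grid")
  common <- ridgesA@times[ridgesA@coiTimes & ridgesB@coiTimes]
  detA <- common %in% ridgesA@points$time_s
  detB <- common %in% ridgesB@points$time_s
  tab <- matrix(c(sum(detA & detB), sum(detA & !detB),
                  sum(!detA & detB), sum(!detA & !detB)),
                2, 2, byrow = TRUE,
                dimnames = list(A = c("A_det", "A_not"),
                                B = c("B_det", "B_not")))
  tab
}

#' McNemar paired proportion test
#'
#' On a 2x2 paired detection table with discordant counts b (A only) and c
#' (B only): \code{chi2 = (|b - c| - 1)^2 / (b + c)} with continuity
#' correction (default) or \code{(b - c)^2 / (b + c)} without; p from the
#' chi-squared distribution with 1 df. The exact binomial p,
#' \code{min(1, 2 P(Bin(b + c, 1/2) >= max(b, c)))}, is also reported when
#' \code{b + c < 25}. By convention \code{b + c = 0} gives chi2 = 0, p = 1.
#'
#' @param tab 2x2 matrix as from [compareDetection()], or a pair
#'   \code{c(b, c)} of discordant counts.
#' @param correction apply the continuity correction (default TRUE).
#' @return list: \code{chi2}, \code{p}, \code{b}, \code{c},
#'   \code{p_exact} (NA unless \code{b + c < 25}).
#' @export
mcnemarTest <- function(tab, correction = TRUE) {
  if (is.matrix(tab)) {
    b <- tab[1, 2]; cc <- tab[2, 1]
  } else {
    b <- tab[1]; cc <- tab[2]
  }
  n <- b + cc
  if (n == 0) return(list(chi2 = 0, p = 1, b = b, c = cc, p_exact = 1))
  chi2 <- if (correction) (abs(b - cc) - 1)^2 / n else (b - cc)^2 / n
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  p_exact <- if (n < 25)
    min(1, 2 * stats::pbinom(max(b, cc) - 1, n, 0.5,
                             lower.tail = FALSE)) else NA_real_
  list(chi2 = chi2, p = p, b = b, c = cc, p_exact = p_exact)
}

#' Tracking-noise summary from a growth-rate series
#'
#' Isolates the fastest frequencies (the finest multiresolution detail
#' level, the "noise band") and summarizes them by their standard
#' deviation and a kernel density estimate — the basis for comparing the
#' noise of tip-detection methods.
#'
#' @param rate a [UniformSeries-class] growth-rate series, \code{n >= 32}.
#' @param filter wavelet filter for the decomposition (default "la8").
#' @return list: \code{sd}, \code{density} (a [stats::density()] object),
#'   \code{noiseBand} (the D1 series).
#' @export
noiseBandDensity <- function(rate, filter = "la8") {
  stopifnot(is(rate, "UniformSeries"))
  if (length(rate@v) < 32L) stop("need at least 32 samples")
  if (anyNA(rate@v))
    stop("series has missing values: run removeOutliers() first")
  d <- mra(rate, filter = filter)
  d1 <- d@details[[1]]
  list(sd = stats::sd(d1), density = stats::density(d1), noiseBand = d1)
}
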