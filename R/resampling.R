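# Autocorrelation-aware uncertainty for time-series observables. Frames of a
# simulation are strongly correlated, so naive bootstrap CIs undercover; the
# remedy used here resamples only N/I points per replicate, where I is the
# integral of the series' autocorrelation function.

#' Integral of the autocorrelation function of a time series
#'
#' Estimates `I = 1 + 2 * sum_k rho(k)`, summing the empirical normalized
#' autocorrelation over positive lags up to (but excluding) the first
#' non-positive value (initial-positive-sequence truncation). `I` is the
#' factor by which correlation inflates the variance of the series mean;
#' `N / I` is the effective number of independent samples. The estimate is
#' clipped below at 1.
#'
#' @param series Numeric vector, length >= 10.
#' @return Autocorrelation integral `I >= 1`.
#' @export
autocorrelation_integral <- function(series) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 10L) stop("autocorrelation_integral: series must have length >= 10")
  if (stats::var(series) == 0)
    stop("autocorrelation_integral: zero-variance series")
  lag_max <- n - 1L
  rho <- stats::acf(series, lag.max = lag_max, plot = FALSE,
                    demean = TRUE)$acf[-1]
  cut <- which(rho <= 0)
  if (length(cut)) rho <- rho[seq_len(cut[1] - 1L)]
  max(1, 1 + 2 * sum(rho))
}

#' Subsampled (N/I) bootstrap confidence interval
#'
#' Bootstrap for the mean (or another statistic) of an autocorrelated
#' series: each replicate resamples only `ceil(N / I)` observations with
#' replacement, where `I` is the [autocorrelation_integral()]. For an
#' i.i.d. series (`I = 1`) this reduces to the ordinary bootstrap.
#'
#' @param series Numeric vector.
#' @param statistic Function of a numeric vector; default `mean`.
#' @param n_boot Number of bootstrap replicates (default 2000).
#' @param seed Integer seed; replicates are deterministic given the seed.
#' @param conf Confidence level (default 0.95, percentile interval).
#' @param I Optional override of the autocorrelation integral (e.g. `I = 1`
#'   forces the ordinary bootstrap).
#' @return A `resample_result`: list with `estimate`, `ci` (length-2),
#'   `n_eff`, `I`, `n_boot`, `seed`, `replicates`.
#' @export
subsampled_bootstrap <- function(series, statistic = mean, n_boot = 2000L,
                                 seed = 1L, conf = 0.95, I = NULL) {
  series <- as.numeric(series)
  N <- length(series)
  if (is.null(I))
    I <- if (stats::var(series) == 0) 1 else autocorrelation_integral(series)
  I <- max(1, I)
  n_eff <- ceiling(N / I)
  if (n_eff < 5L)
    stop("subsampled_bootstrap: fewer than 5 effective samples (N/I = ",
         round(N / I, 2), ")")
  est <- statistic(series)
  set.seed(as.integer(seed))
  reps <- vapply(seq_len(n_boot), function(b)
    statistic(series[sample.int(N, n_eff, replace = TRUE)]), numeric(1))
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha), type = 7))
  structure(list(estimate = est, ci = ci, n_eff = n_eff, I = I,
                 n_boot = n_boot, seed = seed, replicates = reps),
            class = "resample_result")
}

#' @export
print.resample_result <- function(x, ...) {
  cat(sprintf("estimate %.4g, 95%% CI [%.4g, %.4g] (N/I bootstrap, I = %.2f, n_eff = %d)\n",
              x$estimate, x$ci[1], x$ci[2], x$I, x$n_eff))
  invisible(x)
}

weighted_moments <- function(x, w) {
  sw <- sum(w)
  if (sw <= 0) stop("weighted moments: weights must have positive sum")
  m <- sum(w * x) / sw
  v <- sum(w * (x - m)^2) / (sw - 1)  # frequency-weight convention
  list(mean = m, var = v, n = sw)
}

#' Weighted Welch t-test (frequency-weight convention)
#'
#' Two-sample Welch t-test with Satterthwaite degrees of freedom in which
#' each observation carries a frequency weight: integer weights `k` are
#' exactly equivalent to replicating the observation `k` times. Used, e.g.,
#' to compare contact lifetimes with each event weighted by its own
#' lifetime.
#'
#' @param x,y Numeric value vectors.
#' @param wx,wy Positive weights (default all 1, reducing to the standard
#'   Welch test).
#' @return List with `t`, `df`, `p`, and per-group weighted means.
#' @export
weighted_welch_ttest <- function(x, y, wx = rep(1, length(x)),
                                 wy = rep(1, length(y))) {
  keep_x <- wx > 0; keep_y <- wy > 0
  x <- x[keep_x]; wx <- wx[keep_x]; y <- y[keep_y]; wy <- wy[keep_y]
  if (length(x) < 2L || length(y) < 2L)
    stop("weighted_welch_ttest: need >= 2 positively weighted values per group")
  a <- weighted_moments(x, wx); b <- weighted_moments(y, wy)
  se2a <- a$var / a$n; se2b <- b$var / b$n
  t <- (a$mean - b$mean) / sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 /
    (se2a^2 / (a$n - 1) + se2b^2 / (b$n - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, mean_x = a$mean, mean_y = b$mean)
}

#' Block sub-average t-test for autocorrelated series
#'
#' Compares the means of two time series by first averaging each over
#' non-overlapping blocks longer than the autocorrelation time (block
#' length `ceil(max(I_a, I_b))`, minimum 1) and then applying a Welch
#' t-test to the block means, which are approximately independent.
#'
#' @param a,b Numeric series.
#' @return List with `p`, `t`, `df`, `block_length`, and block counts.
#' @export
block_subaverage_ttest <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  Ia <- tryCatch(autocorrelation_integral(a), error = function(e) 1)
  Ib <- tryCatch(autocorrelation_integral(b), error = function(e) 1)
  L <- max(1L, as.integer(ceiling(max(Ia, Ib))))
  block_means <- function(x) {
    nb <- floor(length(x) / L)
    if (nb < 2L) stop("block_subaverage_ttest: fewer than 2 blocks of length ", L)
    colMeans(matrix(x[seq_len(nb * L)], nrow = L))
  }
  ma <- block_means(a); mb <- block_means(b)
  if (identical(a, b))
    return(list(p = 1, t = 0, df = length(ma) + length(mb) - 2,
                block_length = L, n_blocks_a = length(ma),
                n_blocks_b = length(mb)))
  if (stats::var(ma) == 0 && stats::var(mb) == 0) {
    eq <- isTRUE(all.equal(mean(ma), mean(mb)))
    return(list(p = if (eq) 1 else 0, t = if (eq) 0 else Inf, df = NA_real_,
                block_length = L, n_blocks_a = length(ma),
                n_blocks_b = length(mb)))
  }
  tt <- stats::t.test(ma, mb, var.equal = FALSE)
  list(p = unname(tt$p.value), t = unname(tt$statistic),
       df = unname(tt$parameter), block_length = L,
       n_blocks_a = length(ma), n_blocks_b = length(mb))
}
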