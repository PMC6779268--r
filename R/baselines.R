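#' Patel's tau with threshold integration
#'
#' Each series is rescaled to \[0, 1\] by clipping below its 10th and above
#' its 90th percentile and linearly mapping the rest. For every
#' binarization threshold on a dense grid in (0, 1) the signals are
#' thresholded into event trains and the difference of conditional
#' activation probabilities `P(Y1|X1) - P(X1|Y1)` is computed; the
#' statistic is the average over thresholds (integrating out the free
#' threshold parameter). Positive values indicate x -> y.
#'
#' @param x,y numeric vectors or [fc_ts()], length >= 20.
#' @param n_thresholds number of equally spaced thresholds in (0, 1).
#' @return an `fc_decision` (method `"patel_tau"`).
#' @export
patel_tau <- function(x, y, n_thresholds = 99) {
  xv <- ts_values(x)
  yv <- ts_values(y)
  if (length(xv) != length(yv)) stop("x and y must have equal length")
  if (length(xv) < 20) stop("need at least 20 samples")
  rescale <- function(v) {
    q <- quantile(v, c(0.1, 0.9), names = FALSE)
    if (q[2] <= q[1]) stop("degenerate series after percentile rescaling")
    pmin(pmax((v - q[1]) / (q[2] - q[1]), 0), 1)
  }
  xs <- rescale(xv)
  ys <- rescale(yv)
  thetas <- seq_len(n_thresholds) / (n_thresholds + 1)
  taus <- vapply(thetas, function(th) {
    x1 <- xs > th
    y1 <- ys > th
    nx <- sum(x1)
    ny <- sum(y1)
    if (nx == 0 || ny == 0) return(NA_real_)
    sum(x1 & y1) / nx - sum(x1 & y1) / ny
  }, numeric(1))
  taus <- taus[!is.na(taus)]
  if (length(taus) == 0) stop("no admissible binarization threshold")
  fc_decision(mean(taus), "patel_tau")
}

#' Pairwise likelihood-ratio robust skew (PW-LR r skew)
#'
#' Third-cumulant direction statistic of the pairwise likelihood-ratio
#' family with the log-cosh outlier discount, weighted by the correlation
#' of the normalized pair:
#' `R = rho * mean(g(x) * y - x * g(y))` with `g(u) = log(cosh(max(u, 0)))`.
#' The constant factors of the likelihood-ratio approximation are dropped
#' as they do not affect the sign. Positive values indicate x -> y.
#'
#' @param x,y numeric vectors or [fc_ts()], length >= 20, non-constant.
#' @return an `fc_decision` (method `"pw_lr_rskew"`).
#' @export
pw_lr_rskew <- function(x, y) {
  xv <- ts_values(x)
  yv <- ts_values(y)
  if (length(xv) != length(yv)) stop("x and y must have equal length")
  if (length(xv) < 20) stop("need at least 20 samples")
  xn <- normalize_series(xv)
  yn <- normalize_series(yv)
  rho <- mean(xn * yn)
  stat <- rho * mean(discount(xn) * yn - xn * discount(yn))
  fc_decision(stat, "pw_lr_rskew")
}

# lag-embedded OLS residual variance of y ~ lags of (y[, regressors])
ols_resid_var <- function(target, lagged) {
  fit <- stats::lm.fit(cbind(1, lagged), target)
  if (fit$rank < ncol(lagged) + 1) stop("rank-deficient regressors")
  mean(fit$residuals^2)
}

#' Bivariate Granger causality (OLS, lag 1)
#'
#' Fits restricted (own past only) and unrestricted (both pasts) lag-1
#' regressions in both directions; the directed measure is the log ratio of
#' restricted to unrestricted residual variance, and the statistic is
#' `GC(x -> y) - GC(y -> x)`. Positive values indicate x -> y.
#'
#' @param x,y numeric vectors or [fc_ts()], length > 10 * lag.
#' @param lag autoregressive order (default 1).
#' @return an `fc_decision` (method `"granger"`) with the per-direction
#'   measures in `$gc`.
#' @export
granger_bivariate <- function(x, y, lag = 1) {
  xv <- ts_values(x)
  yv <- ts_values(y)
  if (length(xv) != length(yv)) stop("x and y must have equal length")
  n <- length(xv)
  if (n <= 10 * lag) stop("series too short for lag ", lag)
  idx <- (lag + 1):n
  lags <- function(v) sapply(seq_len(lag), function(h) v[idx - h])
  lx <- lags(xv)
  ly <- lags(yv)
  gc_xy <- log(ols_resid_var(yv[idx], ly) /
               ols_resid_var(yv[idx], cbind(ly, lx)))
  gc_yx <- log(ols_resid_var(xv[idx], lx) /
               ols_resid_var(xv[idx], cbind(lx, ly)))
  dec <- fc_decision(gc_xy - gc_yx, "granger")
  dec$gc <- c(xy = gc_xy, yx = gc_yx)
  dec
}

# OLS fit of a bivariate VAR(p); returns list of 2x2 coefficient matrices
fit_var <- function(xv, yv, order) {
  n <- length(xv)
  idx <- (order + 1):n
  X <- do.call(cbind, lapply(seq_len(order), function(h)
    cbind(xv[idx - h], yv[idx - h])))
  Y <- cbind(xv[idx], yv[idx])
  fit <- stats::lm.fit(cbind(1, X), Y)
  if (fit$rank < 2 * order + 1) stop("rank-deficient regressors")
  B <- t(fit$coefficients[-1, , drop = FALSE])  # 2 x (2*order)
  lapply(seq_len(order), function(h) B[, (2 * h - 1):(2 * h), drop = FALSE])
}

var_stable <- function(A_list) {
  p <- length(A_list)
  comp <- matrix(0, 2 * p, 2 * p)
  comp[1:2, ] <- do.call(cbind, A_list)
  if (p > 1) comp[3:(2 * p), 1:(2 * (p - 1))] <- diag(2 * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values)) < 1
}

#' Partial directed coherence of a fitted VAR
#'
#' Computes the PDC spectrum
#' `PDC_ij(f) = |Abar_ij(f)| / sqrt(sum_m |Abar_mj(f)|^2)` with
#' `Abar(f) = I - sum_h A_h exp(-i 2 pi f h)` from the fitted coefficient
#' matrices (column normalization over the source column j).
#'
#' @param A_list list of 2x2 VAR coefficient matrices.
#' @param freqs normalized frequencies in \[0, 0.5\] (cycles per sample).
#' @return array (2, 2, length(freqs)) of PDC magnitudes.
#' @export
pdc_spectrum <- function(A_list, freqs) {
  out <- array(NA_real_, c(2, 2, length(freqs)))
  for (fi in seq_along(freqs)) {
    Abar <- diag(2) + 0i
    for (h in seq_along(A_list))
      Abar <- Abar - A_list[[h]] * exp(-2i * pi * freqs[fi] * h)
    for (j in 1:2)
      out[, j, fi] <- Mod(Abar[, j]) / sqrt(sum(Mod(Abar[, j])^2))
  }
  out
}

#' Bivariate partial directed coherence direction statistic
#'
#' Fits a bivariate VAR by OLS, checks stability, computes the PDC in both
#' directions and reports the band-averaged difference
#' `mean_f PDC(x -> y) - mean_f PDC(y -> x)`. Positive values indicate
#' x -> y.
#'
#' @param x,y numeric vectors or [fc_ts()].
#' @param order VAR order (default 1, matching the Granger setting).
#' @param band normalized frequency band (cycles/sample, within
#'   \[0, 0.5\]).
#' @param n_freq number of evaluation frequencies across the band.
#' @return an `fc_decision` (method `"pdc"`) with the spectrum in
#'   `$spectrum` and frequencies in `$freqs`.
#' @export
pdc_bivariate <- function(x, y, order = 1, band = c(0, 0.5), n_freq = 64) {
  xv <- ts_values(x)
  yv <- ts_values(y)
  if (length(xv) != length(yv)) stop("x and y must have equal length")
  if (length(xv) <= 10 * order) stop("series too short for order ", order)
  # PDC is not scale-invariant; z-score first (standard practice)
  xv <- normalize_series(xv)
  yv <- normalize_series(yv)
  A_list <- fit_var(xv, yv, order)
  if (!var_stable(A_list)) stop("fitted VAR is unstable")
  freqs <- seq(band[1], band[2], length.out = n_freq)
  spec <- pdc_spectrum(A_list, freqs)
  stat <- mean(spec[2, 1, ]) - mean(spec[1, 2, ])
  dec <- fc_decision(stat, "pdc")
  dec$spectrum <- spec
  dec$freqs <- freqs
  dec
}

#' Common pair-method interface
#'
#' Returns named functions `(x, y) -> fc_decision` for use with the
#' experiment harness.
#'
#' @param names subset of `"fractional_cumulants"`, `"patel_tau"`,
#'   `"pw_lr_rskew"`, `"granger"`, `"pdc"`.
#' @param classifier_cfg configuration for the fractional-cumulant
#'   classifier (`NULL`: default).
#' @param lagged_tr optional repetition time (s) at which the *lagged*
#'   methods (Granger, PDC) see the data; requires `fs`. Autoregressive
#'   fMRI methods operate at scan resolution ("lag 1" means one TR), while
#'   cumulant estimation deliberately uses the full-resolution series, so
#'   simulator-based comparisons pass the high-resolution input through
#'   [downsample_bold()] for these two methods only.
#' @param fs sampling rate of the series handed to the methods (Hz); only
#'   needed with `lagged_tr`.
#' @return named list of functions.
#' @export
pair_methods <- function(names = c("fractional_cumulants", "patel_tau",
                                   "pw_lr_rskew", "granger", "pdc"),
                         classifier_cfg = NULL, lagged_tr = NULL,
                         fs = NULL) {
  ds <- function(v) v
  if (!is.null(lagged_tr)) {
    if (is.null(fs)) stop("lagged_tr requires fs")
    ds <- function(v) downsample_bold(ts_values(v), tr = lagged_tr, fs = fs)
  }
  all <- list(
    fractional_cumulants = function(x, y)
      classify_pair(x, y, classifier_cfg),
    patel_tau = function(x, y) patel_tau(x, y),
    pw_lr_rskew = function(x, y) pw_lr_rskew(x, y),
    granger = function(x, y) granger_bivariate(ds(x), ds(y)),
    pdc = function(x, y) pdc_bivariate(ds(x), ds(y))
  )
  unknown <- setdiff(names, names(all))
  if (length(unknown) > 0)
    stop("unknown methods: ", paste(unknown, collapse = ", "))
  all[names]
}
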