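#' Moment-order grid
#'
#' Ordered grid of (possibly fractional) moment orders k shared by moment
#' curves, cumulant maps, sign maps and the classifier. The default covers
#' \[0, 5\] in steps of 0.1, a granularity fine enough that the resulting
#' cumulant maps vary smoothly with the index.
#'
#' @param k_max largest order on the grid.
#' @param step grid spacing.
#' @return numeric vector of strictly increasing orders starting at 0.
#' @export
moment_grid <- function(k_max = 5, step = 0.1) {
  stopifnot(k_max > 0, step > 0, step <= k_max)
  round(seq(0, k_max, by = step), 10)
}

#' Single-node time series
#'
#' Lightweight container for one node's sampled signal.
#'
#' @param values numeric vector of samples.
#' @param fs sampling rate in Hz.
#' @param node_id label for the node.
#' @return an object of class `fc_ts`.
#' @export
fc_ts <- function(values, fs = 1, node_id = "x") {
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("time series values must be finite")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  structure(list(values = values, fs = fs, node_id = node_id),
            class = "fc_ts")
}

ts_values <- function(x) {
  if (inherits(x, "fc_ts")) x$values else as.numeric(x)
}

#' @export
print.fc_ts <- function(x, ...) {
  cat(sprintf("<fc_ts> node '%s': %d samples at %g Hz\n",
              x$node_id, length(x$values), x$fs))
  invisible(x)
}

#' Normalize a series to zero mean and unit population variance
#'
#' Divides by the population (1/N) standard deviation so that downstream
#' 1/N moment sums satisfy M_1 = 0 and M_2 = 1 exactly.
#'
#' @param ts numeric vector or [fc_ts()].
#' @return same type as the input, normalized.
#' @export
normalize_series <- function(ts) {
  x <- ts_values(ts)
  if (length(x) < 2) stop("need at least 2 samples to normalize")
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v <= 0 || !is.finite(v)) stop("degenerate input: constant series")
  z <- (x - m) / sqrt(v)
  if (inherits(ts, "fc_ts")) {
    ts$values <- z
    ts
  } else z
}

is_normalized <- function(x, tol = 1e-6) {
  abs(mean(x)) < tol && abs(mean(x^2) - 1) < tol
}

#' Principal-branch power of a real number
#'
#' Fractional powers of negative numbers are taken on the principal branch:
#' `x^k = |x|^k * exp(i*pi*k)` for `x < 0`, so the resulting moment curves
#' are continuous in k and cross the real axis at every integer k.
#' `0^0` is defined as 1.
#'
#' @param x real vector (the base).
#' @param k scalar order, `k >= 0`.
#' @return complex vector.
#' @export
complex_power <- function(x, k) {
  stopifnot(length(k) == 1, k >= 0)
  x <- as.numeric(x)
  out <- complex(real = numeric(length(x)), imaginary = numeric(length(x)))
  if (k == 0) return(rep(1 + 0i, length(x)))
  pos <- x >= 0
  out[pos] <- x[pos]^k
  if (any(!pos)) {
    out[!pos] <- abs(x[!pos])^k * exp(1i * pi * k)
  }
  out
}

#' Fractional moment curve
#'
#' Complex moments `M_k = (1/N) sum_i x_i^k` of a normalized series over a
#' grid of fractional orders. For a normalized series the curve starts at
#' (1, 0) for k = 0, passes through (0, 0) at k = 1, returns to (1, 0) at
#' k = 2 and crosses the real axis at every integer order.
#'
#' @param ts numeric vector or [fc_ts()], already normalized
#'   (see [normalize_series()]).
#' @param grid moment-order grid from [moment_grid()].
#' @param check verify that the input is normalized (default TRUE).
#' @return object of class `fc_moments`: list with `grid`, complex `M`, `n`.
#' @export
fractional_moments <- function(ts, grid = moment_grid(), check = TRUE) {
  x <- ts_values(ts)
  if (check && !is_normalized(x))
    stop("input series is not normalized; call normalize_series() first")
  n <- length(x)
  pos <- x[x >= 0]
  neg <- abs(x[x < 0])
  # log-domain powers; 0^0 = 1 handled by the k == 0 branch
  M <- vapply(grid, function(k) {
    if (k == 0) return(1 + 0i)
    sp <- sum(pos^k)
    sn <- sum(neg^k)
    (sp + sn * exp(1i * pi * k)) / n
  }, complex(1))
  structure(list(grid = grid, M = M, n = n), class = "fc_moments")
}

#' @export
print.fc_moments <- function(x, ...) {
  cat(sprintf("<fc_moments> %d orders in [%g, %g], series length %d\n",
              length(x$grid), min(x$grid), max(x$grid), x$n))
  invisible(x)
}

#' Fractional cumulant map of a pair of series
#'
#' Antisymmetrized cross-moments
#' `C_kl = (1/N) sum_i (x_i^k y_i^l - x_i^l y_i^k)` over all pairs (k, l) on
#' the grid, using principal-branch powers for negative values. The map is
#' exactly antisymmetric (`C_kl = -C_lk`) with a zero diagonal; its sign
#' pattern carries the evidence about which series is upstream.
#'
#' @param x,y numeric vectors or [fc_ts()] of equal length, both normalized.
#' @param grid moment-order grid.
#' @param check verify normalization.
#' @param engine `"cpp"` (BLAS-backed, default) or `"r"` (plain vectorized).
#' @return object of class `fc_cumulants`: list with `grid` and real/imaginary
#'   component matrices `Cr`, `Ci` (rows indexed by k, columns by l).
#' @export
fractional_cumulants <- function(x, y, grid = moment_grid(), check = TRUE,
                                 engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  xv <- ts_values(x)
  yv <- ts_values(y)
  if (length(xv) != length(yv)) stop("x and y must have equal length")
  if (check) {
    if (!is_normalized(xv) || !is_normalized(yv))
      stop("both series must be normalized; call normalize_series() first")
  }
  if (engine == "cpp") {
    res <- .cumulant_map_cpp(xv, yv, grid)
    Cr <- res$Cr
    Ci <- res$Ci
  } else {
    K <- length(grid)
    PX <- vapply(grid, function(k) complex_power(xv, k), complex(length(xv)))
    PY <- vapply(grid, function(k) complex_power(yv, k), complex(length(yv)))
    T1 <- crossprod(PX, PY) # t(PX) %*% PY, no conjugation for complex
    C <- (T1 - t(T1)) / length(xv)
    Cr <- Re(C)
    Ci <- Im(C)
  }
  dimnames(Cr) <- dimnames(Ci) <- list(k = grid, l = grid)
  structure(list(grid = grid, Cr = Cr, Ci = Ci,
                 labels = c(label_of(x, "x"), label_of(y, "y"))),
            class = "fc_cumulants")
}

label_of <- function(ts, default) {
  if (inherits(ts, "fc_ts") && !is.null(ts$node_id)) ts$node_id else default
}

#' @export
print.fc_cumulants <- function(x, ...) {
  cat(sprintf("<fc_cumulants> %s vs %s, %dx%d grid in [%g, %g]\n",
              x$labels[1], x$labels[2], length(x$grid), length(x$grid),
              min(x$grid), max(x$grid)))
  invisible(x)
}
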