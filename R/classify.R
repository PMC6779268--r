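#' Log-cosh discount nonlinearity
#'
#' `f(x) = log(cosh(max(x, 0)))`: zero for non-positive arguments, about
#' `x^2 / 2` for small positive x and asymptotically `x - log 2` for large
#' x. Used to discount the contribution of poorly estimated high-index
#' cumulants (and, in the pairwise likelihood-ratio family, to discount
#' outliers).
#'
#' @param x numeric vector.
#' @return numeric vector, `>= 0`.
#' @export
discount <- function(x) {
  z <- pmax(x, 0)
  out <- numeric(length(z))
  big <- z > 20  # log(cosh(z)) overflows; use z - log(2) + log1p(exp(-2z))
  out[big] <- z[big] - log(2) + log1p(exp(-2 * z[big]))
  out[!big] <- log(cosh(z[!big]))
  out
}

#' Classifier configuration
#'
#' Bundles the trained sign maps with the voting window: cumulants with
#' `min_index <= k, l` and `k + l <= Ind_max` vote (component-wise windows
#' `ind_r_max`, `ind_i_max` for the real and imaginary part), optionally
#' restricted to cells whose discriminability exceeds a cutoff. Pure
#' moments (k = 0 or l = 0) never vote. Defaults are the tuned windows:
#' (2.1, 3.7) weighted, (2.4, 1.7) unweighted.
#'
#' @param sign_maps an `fc_signmaps` object ([train_sign_maps()] or
#'   [default_sign_maps()]).
#' @param ind_r_max,ind_i_max window maxima for the triangle constraint
#'   `k + l <= Ind_max`; `NULL` picks the tuned default for the chosen
#'   voting scheme.
#' @param weighted apply the log-cosh [discount()] to cumulant values.
#' @param cov_weighted multiply the final statistic by the covariance of
#'   the normalized pair (the construction used when mirroring the
#'   pairwise likelihood-ratio benchmark setting).
#' @param min_index smallest index allowed to vote (default 0.1).
#' @param disc_map optional [discriminability()] map.
#' @param disc_cutoff cells below this discriminability abstain.
#' @param window `"triangle"` (default, `k + l <= Ind_max`) or `"max"`
#'   (`max(k, l) <= Ind_max`).
#' @return object of class `fc_classifier`.
#' @export
classifier_config <- function(sign_maps, ind_r_max = NULL, ind_i_max = NULL,
                              weighted = TRUE, cov_weighted = FALSE,
                              min_index = 0.1, disc_map = NULL,
                              disc_cutoff = 0,
                              window = c("triangle", "max")) {
  stopifnot(inherits(sign_maps, "fc_signmaps"))
  window <- match.arg(window)
  if (is.null(ind_r_max)) ind_r_max <- if (weighted) 2.1 else 2.4
  if (is.null(ind_i_max)) ind_i_max <- if (weighted) 3.7 else 1.7
  g <- sign_maps$grid
  lim <- if (window == "triangle") 2 * max(g) else max(g)
  if (ind_r_max <= 0 || ind_i_max <= 0 || ind_r_max > lim || ind_i_max > lim)
    stop("index windows must lie within the grid range")
  mask <- function(ind_max) {
    kk <- outer(g, g, function(k, l) {
      if (window == "triangle") k + l else pmax(k, l)
    })
    admissible <- outer(g >= min_index, g >= min_index, "&")
    admissible & (kk <= ind_max + 1e-9)
  }
  mr <- mask(ind_r_max)
  mi <- mask(ind_i_max)
  if (disc_cutoff > 0) {
    if (is.null(disc_map)) stop("disc_cutoff > 0 requires disc_map")
    stopifnot(identical(disc_map$grid, g))
    mr <- mr & (disc_map$dr >= disc_cutoff)
    mi <- mi & (disc_map$di >= disc_cutoff)
  }
  structure(list(sign_maps = sign_maps, ind_r_max = ind_r_max,
                 ind_i_max = ind_i_max, weighted = weighted,
                 cov_weighted = cov_weighted, min_index = min_index,
                 mask_r = mr, mask_i = mi, window = window,
                 disc_cutoff = disc_cutoff),
            class = "fc_classifier")
}

fc_decision <- function(statistic, method, tie = FALSE) {
  structure(list(statistic = statistic,
                 verdict = if (statistic >= 0) "x->y" else "y->x",
                 tie = tie, method = method),
            class = "fc_decision")
}

#' @export
print.fc_decision <- function(x, ...) {
  cat(sprintf("<fc_decision> %s: %s (statistic %.6g%s)\n", x$method,
              x$verdict, x$statistic, if (x$tie) ", tie" else ""))
  invisible(x)
}

#' Classify the direction of a pair of time series
#'
#' Normalizes both series, computes the fractional cumulant map, and sums
#' the sign-map-weighted (optionally log-cosh discounted) contributions of
#' all cumulants inside the voting window. A non-negative statistic is
#' evidence for x -> y, a negative one for y -> x; an exact zero resolves
#' to x -> y with a tie warning.
#'
#' @param x,y numeric vectors or [fc_ts()] of equal length (>= `min_len`).
#' @param cfg an [classifier_config()]; `NULL` uses [default_classifier()].
#' @param min_len minimal accepted series length.
#' @return an `fc_decision` with fields `statistic`, `verdict`
#'   (`"x->y"` / `"y->x"`), `tie` and `method`.
#' @export
classify_pair <- function(x, y, cfg = NULL, min_len = 50) {
  if (is.null(cfg)) cfg <- default_classifier()
  stopifnot(inherits(cfg, "fc_classifier"))
  xv <- ts_values(x)
  yv <- ts_values(y)
  if (length(xv) != length(yv)) stop("x and y must have equal length")
  if (length(xv) < min_len)
    stop("series too short: need at least ", min_len, " samples")
  xn <- normalize_series(xv)
  yn <- normalize_series(yv)
  cm <- fractional_cumulants(xn, yn, cfg$sign_maps$grid, check = FALSE)
  w <- if (cfg$weighted) discount else identity
  stat <- sum(cfg$sign_maps$Sr[cfg$mask_r] * w(cm$Cr[cfg$mask_r])) +
    sum(cfg$sign_maps$Si[cfg$mask_i] * w(cm$Ci[cfg$mask_i]))
  if (cfg$cov_weighted) stat <- stat * mean(xn * yn)
  tie <- stat == 0
  if (tie) warning("voting statistic is exactly zero; resolving to x->y")
  fc_decision(stat, "fractional_cumulants", tie = tie)
}

#' Shipped default sign maps
#'
#' Ternary sign maps trained at reduced scale (see the package vignette)
#' and shipped as versioned JSON; regenerable with the `train` CLI
#' subcommand or [train_sign_maps()].
#'
#' @return an `fc_signmaps` object.
#' @export
default_sign_maps <- function() {
  path <- system.file("extdata", "signmaps_default.json", package = "fraccum")
  if (path == "") stop("shipped sign maps not found")
  read_signmaps(path)
}

#' Default classifier configuration
#'
#' @param weighted use the log-cosh discounted voting scheme (default) with
#'   its tuned window (2.1, 3.7); unweighted uses (2.4, 1.7).
#' @param ... further arguments passed to [classifier_config()].
#' @return an `fc_classifier`.
#' @export
default_classifier <- function(weighted = TRUE, ...) {
  classifier_config(default_sign_maps(), weighted = weighted, ...)
}
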