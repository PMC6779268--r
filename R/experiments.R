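#' Fraction of correct direction verdicts
#'
#' @param decisions list of `fc_decision` objects (or character verdicts).
#' @param truths character vector of true directions (`"x->y"` / `"y->x"`).
#' @return fraction in \[0, 1\].
#' @export
success_rate <- function(decisions, truths) {
  if (length(decisions) == 0) stop("empty decision list")
  if (length(decisions) != length(truths)) stop("length mismatch")
  verdicts <- vapply(decisions, function(d) {
    if (inherits(d, "fc_decision")) d$verdict else as.character(d)
  }, character(1))
  mean(verdicts == truths)
}

#' Per-cumulant single-cell success rates
#'
#' Classifies every pair with one cumulant cell at a time: the cell's vote
#' is `S_kl * C_kl` and the non-negative tie rule applies. Returns one
#' success-rate grid per component.
#'
#' @param pairs list of `list(x, y)` raw series pairs.
#' @param truths true directions, one per pair.
#' @param sign_maps trained [train_sign_maps()] object.
#' @return list with matrices `real` and `imag` of per-cell success rates.
#' @export
per_cumulant_success <- function(pairs, truths, sign_maps) {
  stopifnot(length(pairs) == length(truths), length(pairs) >= 1)
  g <- sign_maps$grid
  K <- length(g)
  accR <- accI <- matrix(0, K, K)
  for (p in seq_along(pairs)) {
    cm <- fractional_cumulants(normalize_series(pairs[[p]]$x),
                               normalize_series(pairs[[p]]$y), g)
    want_xy <- truths[p] == "x->y"
    verdictR <- (sign_maps$Sr * cm$Cr) >= 0   # TRUE = x->y
    verdictI <- (sign_maps$Si * cm$Ci) >= 0
    accR <- accR + (verdictR == want_xy)
    accI <- accI + (verdictI == want_xy)
  }
  list(real = accR / length(pairs), imag = accI / length(pairs),
       grid = g)
}

# one grid cell: n_real two-node simulations with balanced truths
run_grid_cell <- function(mode, up_level, down_level, n_real, methods,
                          weight, fs, duration) {
  correct <- setNames(numeric(length(methods)), names(methods))
  n_eval <- setNames(numeric(length(methods)), names(methods))
  for (r in seq_len(n_real)) {
    # validation realizations fix the input process at its prior mean
    # (amplitude 1 or the grid level, switching rates 1/s); only training
    # marginalizes over input parameters
    cfg <- if (mode == "noise") {
      two_node_config(weight, fs = fs, duration = duration,
                      input_magnitude = 1,
                      input_rates = 1,
                      noise_variance = c(up_level, down_level),
                      noise_kind = "pink")
    } else {
      two_node_config(weight, fs = fs, duration = duration,
                      input_magnitude = c(up_level, down_level),
                      input_rates = 1,
                      noise_kind = "none")
    }
    sim_pair <- nondegenerate_pair(function(i) {
      s <- simulate_network(cfg)
      list(x = s$bold[, 1], y = s$bold[, 2])
    }, r)
    flip <- r %% 2 == 0  # balanced truths: chance is exactly 0.5
    a <- if (flip) sim_pair$y else sim_pair$x
    b <- if (flip) sim_pair$x else sim_pair$y
    truth <- if (flip) "y->x" else "x->y"
    for (m in names(methods)) {
      dec <- tryCatch(suppressWarnings(methods[[m]](a, b)),
                      error = function(e) NULL)
      if (!is.null(dec)) {
        n_eval[m] <- n_eval[m] + 1
        correct[m] <- correct[m] + (dec$verdict == truth)
      }
    }
  }
  list(correct = correct, n = n_eval)
}

run_two_node_grid <- function(mode, levels, n_real, methods, weight,
                              fs, duration) {
  stopifnot(n_real >= 1, length(levels) >= 1)
  if (is.function(methods)) methods <- list(method = methods)
  cells <- expand.grid(up_level = levels, down_level = levels)
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    res <- run_grid_cell(mode, cells$up_level[ci], cells$down_level[ci],
                         n_real, methods, weight, fs, duration)
    rows[[ci]] <- data.frame(
      method = names(methods), up_level = cells$up_level[ci],
      down_level = cells$down_level[ci],
      success = unname(res$correct / pmax(res$n, 1)),
      n = unname(res$n), row.names = NULL)
  }
  out <- do.call(rbind, rows)
  structure(list(results = out, mode = mode, levels = levels,
                 n_real = n_real, weight = weight, fs = fs,
                 duration = duration),
            class = "fc_grid")
}

#' @export
print.fc_grid <- function(x, ...) {
  cat(sprintf("<fc_grid> %s grid, %d levels x %d levels, n_real = %d\n",
              x$mode, length(x$levels), length(x$levels), x$n_real))
  invisible(x)
}

#' Robustness grid against scale-free background noise
#'
#' Two-node simulations with input amplitude fixed at 1.0 and pink-noise
#' variance varied independently for the upstream and downstream node over
#' the level grid. In each cell, half the realizations present the pair in
#' upstream-first order and half swapped, so chance success is exactly 0.5.
#'
#' @param levels noise-variance levels (default covers \[0.2, 5.0\]).
#' @param n_real realizations per cell (paper-scale: 500; the reduced
#'   default keeps test runtimes practical).
#' @param methods named list of pair methods from [pair_methods()] (or a
#'   single function).
#' @param weight connection weight.
#' @param fs,duration simulation rate and length per realization.
#' @return object of class `fc_grid` whose `$results` data.frame has one
#'   row per (method, cell) with the per-cell success rate and n.
#' @export
noise_robustness_grid <- function(levels = seq(0.2, 5.0, length.out = 5),
                                  n_real = 50, methods = pair_methods(),
                                  weight = 0.9, fs = 200, duration = 600) {
  run_two_node_grid("noise", levels, n_real, methods, weight, fs, duration)
}

#' Robustness grid against asymmetric input strengths
#'
#' Noiseless two-node simulations with the input magnitudes of the
#' upstream and downstream node fixed to each combination of levels
#' (switching rates still sampled). Truths are balanced as in
#' [noise_robustness_grid()].
#'
#' @inheritParams noise_robustness_grid
#' @param levels input-magnitude levels (default covers \[0.2, 5.0\]).
#' @return an `fc_grid`.
#' @export
signal_strength_grid <- function(levels = seq(0.2, 5.0, length.out = 5),
                                 n_real = 50, methods = pair_methods(),
                                 weight = 0.9, fs = 200, duration = 600) {
  run_two_node_grid("signal", levels, n_real, methods, weight, fs, duration)
}

#' Z-scores of edge statistics against a permutation null
#'
#' @param statistics numeric vector of per-edge statistics.
#' @param null_statistics numeric null sample (>= 30 values, non-constant).
#' @return numeric vector `(statistics - mean(null)) / sd(null)`.
#' @export
zscore_vs_null <- function(statistics, null_statistics) {
  if (length(null_statistics) < 30) stop("need at least 30 null samples")
  s <- sd(null_statistics)
  if (s == 0) stop("degenerate null distribution (zero standard deviation)")
  (statistics - mean(null_statistics)) / s
}
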