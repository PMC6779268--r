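#' Default two-node training simulation factory
#'
#' Returns a closure producing one training realization of the canonical
#' two-node system: connection weight `weight` from upstream to downstream
#' (0 for the null condition), noiseless, input magnitudes and switching
#' rates drawn per node from Gamma(mean 1, var 1), hemodynamic parameters
#' drawn per node from the empirical priors.
#'
#' @param weight connection weight (0.9 for the connection condition,
#'   0 for the null condition).
#' @param fs sampling rate in Hz.
#' @param duration seconds per realization.
#' @return function(i) returning `list(x = , y = )` of raw BOLD vectors
#'   (upstream first).
#' @export
training_sim_factory <- function(weight = 0.9, fs = 200, duration = 600) {
  force(weight); force(fs); force(duration)
  function(i) {
    A <- matrix(c(-1, weight, 0, -1), 2, 2)
    cfg <- dcm_config(A, fs = fs, duration = duration,
                      input_magnitude = NA, input_rates = NA,
                      noise_kind = "none")
    sim <- simulate_network(cfg)
    list(x = sim$bold[, 1], y = sim$bold[, 2])
  }
}

#' Canonical validation simulation factory
#'
#' Fresh two-node realizations of the validation world: connection weight
#' `weight`, input process fixed at its prior mean (amplitude 1, switching
#' rates 1/s), hemodynamics sampled per node from the priors, optional
#' background noise. Training marginalizes over input parameters; the
#' validation experiments hold them fixed (see the vignette).
#'
#' @inheritParams training_sim_factory
#' @param noise_variance per-node noise variance (length 2).
#' @param noise_kind `"none"`, `"white"` or `"pink"`.
#' @return function(i) returning `list(x = upstream, y = downstream)`.
#' @export
validation_sim_factory <- function(weight = 0.9, fs = 200, duration = 600,
                                   noise_variance = 0,
                                   noise_kind = "none") {
  force(weight); force(fs); force(duration)
  force(noise_variance); force(noise_kind)
  function(i) {
    cfg <- two_node_config(weight, fs = fs, duration = duration,
                           input_magnitude = 1, input_rates = 1,
                           noise_variance = noise_variance,
                           noise_kind = noise_kind)
    sim <- simulate_network(cfg)
    list(x = sim$bold[, 1], y = sim$bold[, 2])
  }
}

# A realization whose input train never switches on yields constant BOLD
# and carries no directional information; such silent draws are resampled.
nondegenerate_pair <- function(sim_factory, i, max_try = 50) {
  for (try in seq_len(max_try)) {
    pair <- tryCatch(sim_factory(i), error = function(e)
      stop("simulation ", i, " failed: ", conditionMessage(e)))
    if (sd(pair$x) > 1e-12 && sd(pair$y) > 1e-12) return(pair)
  }
  stop("simulation ", i, " produced only degenerate (constant) series")
}

#' Collect per-cell cumulant samples over repeated simulations
#'
#' @param sim_factory function(i) returning `list(x, y)` of raw series.
#' @param n_sims number of realizations.
#' @param grid moment-order grid.
#' @return list with arrays `Cr`, `Ci` of dimension (K, K, n_sims) and
#'   the `grid`.
#' @export
collect_cumulant_samples <- function(sim_factory, n_sims,
                                     grid = moment_grid()) {
  stopifnot(is.function(sim_factory), n_sims >= 1)
  K <- length(grid)
  Cr <- array(NA_real_, c(K, K, n_sims))
  Ci <- array(NA_real_, c(K, K, n_sims))
  for (i in seq_len(n_sims)) {
    pair <- nondegenerate_pair(sim_factory, i)
    cm <- fractional_cumulants(normalize_series(pair$x),
                               normalize_series(pair$y), grid)
    Cr[, , i] <- cm$Cr
    Ci[, , i] <- cm$Ci
  }
  list(Cr = Cr, Ci = Ci, grid = grid)
}

#' Train majority-sign maps from repeated directed simulations
#'
#' For each cell (k, l) of the cumulant grid, the trained sign is the sign
#' held by the majority of the simulations' real (imaginary) cumulant
#' component; exact ties and the diagonal give 0 (abstaining cells). The
#' resulting ternary maps are the classifier state.
#'
#' @param sim_factory function(i) returning `list(x, y)`; defaults to
#'   [training_sim_factory()] with the given weight.
#' @param n_sims number of training simulations (paper-scale: 1000).
#' @param weight connection weight used by the default factory.
#' @param grid moment-order grid.
#' @param fs,duration forwarded to the default factory.
#' @param samples optional precomputed output of
#'   [collect_cumulant_samples()]; when given, `sim_factory` is ignored.
#' @return object of class `fc_signmaps`: list with ternary matrices
#'   `Sr`, `Si`, the `grid`, `n_sims` and `weight`.
#' @export
train_sign_maps <- function(sim_factory = NULL, n_sims = 1000, weight = 0.9,
                            grid = moment_grid(), fs = 200, duration = 600,
                            samples = NULL) {
  if (is.null(samples)) {
    if (is.null(sim_factory))
      sim_factory <- training_sim_factory(weight, fs = fs,
                                          duration = duration)
    samples <- collect_cumulant_samples(sim_factory, n_sims, grid)
  } else {
    n_sims <- dim(samples$Cr)[3]
    grid <- samples$grid
  }
  majority <- function(a) {
    pos <- apply(a > 0, c(1, 2), sum)
    neg <- apply(a < 0, c(1, 2), sum)
    sign(pos - neg)
  }
  Sr <- majority(samples$Cr)
  Si <- majority(samples$Ci)
  dimnames(Sr) <- dimnames(Si) <- list(k = grid, l = grid)
  structure(list(Sr = Sr, Si = Si, grid = grid, n_sims = n_sims,
                 weight = weight, version = .fc_version()),
            class = "fc_signmaps")
}

#' @export
print.fc_signmaps <- function(x, ...) {
  cat(sprintf(
    "<fc_signmaps> %dx%d grid, trained on %d simulations (weight %g)\n",
    length(x$grid), length(x$grid), x$n_sims, x$weight))
  invisible(x)
}

# Smoothed empirical CDF evaluated at t: Gaussian kernel, Silverman
# bandwidth. Falls back to the step CDF for degenerate samples.
smoothed_cdf <- function(samples, t) {
  bw <- tryCatch(stats::bw.nrd0(samples), error = function(e) 0)
  if (!is.finite(bw) || bw <= 0) return(mean(samples <= t))
  mean(pnorm(t, mean = samples, sd = bw))
}

smoothed_quantile <- function(samples, p) {
  bw <- tryCatch(stats::bw.nrd0(samples), error = function(e) 0)
  if (!is.finite(bw) || bw <= 0) return(unname(quantile(samples, p)))
  lo <- min(samples) - 10 * bw
  hi <- max(samples) + 10 * bw
  stats::uniroot(function(t) mean(pnorm(t, samples, bw)) - p, c(lo, hi),
                 tol = 1e-10)$root
}

#' Discriminability of each cumulant between connection and null
#'
#' Per grid cell and component, both empirical distributions (across
#' simulations) are smoothed with a Gaussian kernel (Silverman bandwidth);
#' discriminability is the fraction of connection-condition samples falling
#' beyond the null distribution's 95th percentile, or below its 5th
#' percentile when the connection-condition mean is negative.
#'
#' @param null_samples,conn_samples outputs of [collect_cumulant_samples()]
#'   for the null (no connection) and connection condition; at least 50
#'   samples per cell each.
#' @return object of class `fc_discmap`: list with matrices `dr`, `di` in
#'   \[0, 1\] and the `grid`.
#' @export
discriminability <- function(null_samples, conn_samples) {
  if (dim(null_samples$Cr)[3] < 50 || dim(conn_samples$Cr)[3] < 50)
    stop("insufficient samples: need at least 50 per condition")
  if (!identical(null_samples$grid, conn_samples$grid))
    stop("sample collections use different grids")
  grid <- null_samples$grid
  K <- length(grid)
  one_cell <- function(nu, co) {
    if (sd(nu) == 0 && sd(co) == 0) return(0)
    if (mean(co) < 0) {
      smoothed_cdf(co, smoothed_quantile(nu, 0.05))
    } else {
      1 - smoothed_cdf(co, smoothed_quantile(nu, 0.95))
    }
  }
  dr <- di <- matrix(0, K, K, dimnames = list(k = grid, l = grid))
  for (i in seq_len(K - 1)) {
    for (j in seq(i + 1, K)) {
      dr[i, j] <- one_cell(null_samples$Cr[i, j, ], conn_samples$Cr[i, j, ])
      di[i, j] <- one_cell(null_samples$Ci[i, j, ], conn_samples$Ci[i, j, ])
      # antisymmetric samples: the mirrored cell sees negated values, the
      # percentile rule mirrors with them, so discriminability is equal
      dr[j, i] <- dr[i, j]
      di[j, i] <- di[i, j]
    }
  }
  structure(list(dr = dr, di = di, grid = grid), class = "fc_discmap")
}

#' Grid search over index windows and discriminability cutoffs
#'
#' Exhaustive search over the discriminability cutoff and the component-wise
#' index windows (IndR_max, IndI_max), separately for the weighted
#' (log-cosh discounted) and unweighted voting scheme. The evaluator is any
#' function mapping a classifier configuration to a grand-mean success rate
#' over a dataset collection.
#'
#' @param sign_maps trained [train_sign_maps()] object.
#' @param disc_map [discriminability()] map, or NULL when all cutoffs are 0.
#' @param evaluator function(cfg) -> numeric success rate in \[0, 1\].
#' @param cutoffs discriminability cutoffs to scan.
#' @param ind_r,ind_i candidate window maxima for the real and imaginary
#'   component (triangle constraint k + l <= Ind_max with k, l >= 0.1).
#' @param weighted logical vector of voting schemes to scan.
#' @return list with `best` (row of the surface with maximal score; ties
#'   resolved to the first in scan order) and `surface` (data.frame of all
#'   evaluated configurations).
#' @export
tune_window <- function(sign_maps, disc_map = NULL, evaluator,
                        cutoffs = 0, ind_r = seq(1, 5, 0.5),
                        ind_i = seq(1, 5, 0.5),
                        weighted = c(TRUE, FALSE)) {
  stopifnot(is.function(evaluator))
  combos <- expand.grid(cutoff = cutoffs, ind_r_max = ind_r,
                        ind_i_max = ind_i, weighted = weighted)
  if (nrow(combos) == 0) stop("empty search grid")
  if (any(combos$cutoff > 0) && is.null(disc_map))
    stop("positive cutoffs require a discriminability map")
  score <- vapply(seq_len(nrow(combos)), function(r) {
    cfg <- classifier_config(
      sign_maps, ind_r_max = combos$ind_r_max[r],
      ind_i_max = combos$ind_i_max[r], weighted = combos$weighted[r],
      disc_map = disc_map, disc_cutoff = combos$cutoff[r])
    val <- evaluator(cfg)
    if (!is.finite(val)) stop("evaluator returned a non-finite score")
    val
  }, numeric(1))
  combos$score <- score
  list(best = combos[which.max(score), , drop = FALSE], surface = combos)
}
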