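#' Hemodynamic parameter priors
#'
#' Empirical prior means and variances of the Balloon-Windkessel parameters
#' (signal decay kappa, autoregulation gamma, transit time tau, vessel
#' stiffness alpha, resting oxygen extraction E0, resting blood volume V0).
#' Defaults follow the canonical bilinear DCM formulation; they are stored
#' in one editable JSON file (`inst/extdata/hemo_priors.json`) so corrected
#' hemodynamic variants can be swapped in without touching code.
#'
#' @param path optional path to an alternative priors JSON file.
#' @return data.frame with columns `mean` and `var`, rownames the parameter
#'   names `kappa`, `gamma`, `tau`, `alpha`, `e0`, `v0`.
#' @export
hemo_priors <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hemo_priors.json", package = "fraccum")
  pr <- jsonlite::fromJSON(path)
  out <- data.frame(mean = unlist(pr$mean), var = unlist(pr$var))
  required <- c("kappa", "gamma", "tau", "alpha", "e0", "v0")
  if (!all(required %in% rownames(out)))
    stop("priors file must define: ", paste(required, collapse = ", "))
  out[required, , drop = FALSE]
}

hemo_domain <- list(
  kappa = c(1e-6, Inf), gamma = c(1e-6, Inf), tau = c(1e-6, Inf),
  alpha = c(1e-6, 1 - 1e-6), e0 = c(1e-6, 1 - 1e-6), v0 = c(1e-6, Inf)
)

#' Sample per-node hemodynamic parameters
#'
#' Independent Gaussian draws per node from the empirical priors, truncated
#' (by rejection) to the valid domain: all parameters positive, alpha and E0
#' in (0, 1). Zero prior variance returns the prior mean.
#'
#' @param n_nodes number of nodes.
#' @param priors priors table as returned by [hemo_priors()].
#' @return data.frame with one row per node and columns
#'   `kappa`, `gamma`, `tau`, `alpha`, `e0`, `v0`.
#' @export
sample_hemo_params <- function(n_nodes, priors = hemo_priors()) {
  stopifnot(n_nodes >= 1)
  if (any(priors$var < 0) || any(!is.finite(priors$mean)))
    stop("invalid prior configuration: negative variance or non-finite mean")
  out <- matrix(NA_real_, n_nodes, nrow(priors),
                dimnames = list(NULL, rownames(priors)))
  for (p in rownames(priors)) {
    mu <- priors[p, "mean"]
    sdv <- sqrt(priors[p, "var"])
    dom <- hemo_domain[[p]]
    if (mu < dom[1] || mu > dom[2])
      stop("invalid prior configuration: mean of ", p, " outside its domain")
    if (sdv == 0) {
      out[, p] <- mu
    } else {
      draw <- rnorm(n_nodes, mu, sdv)
      bad <- draw < dom[1] | draw > dom[2]
      while (any(bad)) {
        draw[bad] <- rnorm(sum(bad), mu, sdv)
        bad <- draw < dom[1] | draw > dom[2]
      }
      out[, p] <- draw
    }
  }
  as.data.frame(out)
}

#' Simulation configuration for the DCM forward model
#'
#' @param adjacency square matrix; off-diagonal entries are connection
#'   weights (entry `[i, j]` is the weight of the connection j -> i),
#'   diagonal entries are negative self-inhibition terms.
#' @param fs sampling (integration) rate in Hz.
#' @param duration simulated time in seconds.
#' @param input_magnitude per-node input amplitude; `NA` means "draw from
#'   Gamma(mean 1, var 1) at simulation time" (the training regime).
#' @param input_rates per-node switching rates per second, a matrix with
#'   columns `on_off` and `off_on` (or a vector recycled to both); `NA`
#'   entries are drawn from Gamma(mean 1, var 1) at simulation time.
#' @param noise_variance per-node variance of the background neuronal noise.
#' @param noise_kind `"none"`, `"white"` or `"pink"` (scale-free).
#' @param speed neuronal rate constant sigma (1/s): the neuronal ODE is
#'   `zdot = speed * (A z + s(t) + sigma(t))`, so `1/speed` is the neuronal
#'   time constant. The default 20 reproduces the ~50 ms neuronal lag of
#'   the benchmark generative model; steady-state node mixing depends only
#'   on `adjacency`.
#' @param seed optional integer seed applied by [simulate_network()].
#' @return object of class `fc_dcm_config`.
#' @export
dcm_config <- function(adjacency, fs = 200, duration = 600,
                       input_magnitude = NA_real_, input_rates = NA_real_,
                       noise_variance = 0,
                       noise_kind = c("none", "white", "pink"),
                       speed = 20, seed = NULL) {
  noise_kind <- match.arg(noise_kind)
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (ncol(adjacency) != n) stop("adjacency must be square")
  if (any(diag(adjacency) >= 0))
    stop("diagonal of adjacency must be negative (stable self-decay)")
  if (fs <= 0) stop("fs must be positive")
  if (duration <= 0) stop("duration must be positive")
  input_magnitude <- rep_len(as.numeric(input_magnitude), n)
  if (is.null(dim(input_rates))) {
    input_rates <- matrix(rep_len(as.numeric(input_rates), 2 * n), n, 2)
  } else {
    input_rates <- as.matrix(input_rates)
    stopifnot(nrow(input_rates) == n, ncol(input_rates) == 2)
  }
  colnames(input_rates) <- c("on_off", "off_on")
  noise_variance <- rep_len(as.numeric(noise_variance), n)
  if (any(noise_variance < 0, na.rm = TRUE))
    stop("noise_variance must be >= 0")
  if (speed <= 0) stop("speed must be positive")
  structure(list(adjacency = adjacency, fs = fs, duration = duration,
                 speed = speed,
                 input_magnitude = input_magnitude,
                 input_rates = input_rates,
                 noise_variance = noise_variance, noise_kind = noise_kind,
                 seed = seed, n_nodes = n),
            class = "fc_dcm_config")
}

#' Binary Poisson-switching input process
#'
#' Piecewise-constant signal alternating between 0 and a drawn magnitude.
#' Switching between the on- and off-state is a two-state Markov process
#' discretized per step with probability `rate / fs`, giving (approximately)
#' exponential dwell times with the requested per-second rates. Magnitude
#' and rates left `NULL` are drawn from a Gamma distribution with mean and
#' variance 1 (shape 1, scale 1, i.e. exponential).
#'
#' @param fs sampling rate (Hz); `duration` in seconds.
#' @param duration duration in seconds.
#' @param magnitude on-state amplitude (`NULL`: draw Gamma(1, 1)).
#' @param rate_on_off,rate_off_on per-second switching rates
#'   (`NULL`: draw Gamma(1, 1)).
#' @param initial_state `"off"` or `"on"`.
#' @param node_id label for the returned series.
#' @return [fc_ts()] with values in `{0, magnitude}` and attributes
#'   `magnitude`, `rate_on_off`, `rate_off_on`.
#' @export
sample_input_process <- function(fs, duration, magnitude = NULL,
                                 rate_on_off = NULL, rate_off_on = NULL,
                                 initial_state = c("off", "on"),
                                 node_id = "u") {
  stopifnot(fs > 0, duration > 0)
  initial_state <- match.arg(initial_state)
  if (is.null(magnitude) || is.na(magnitude)) magnitude <- rgamma(1, 1, 1)
  if (is.null(rate_on_off) || is.na(rate_on_off)) rate_on_off <- rgamma(1, 1, 1)
  if (is.null(rate_off_on) || is.na(rate_off_on)) rate_off_on <- rgamma(1, 1, 1)
  n <- round(duration * fs)
  p <- pmin(c(rate_on_off, rate_off_on) / fs, 1)  # [on->off, off->on]
  state <- initial_state == "on"
  u <- numeric(n)
  i <- 1L
  while (i <= n) {
    psw <- if (state) p[1] else p[2]
    dwell <- if (psw <= 0) n else rgeom(1L, psw) + 1L
    j <- min(n, i + dwell - 1L)
    if (state) u[i:j] <- magnitude
    state <- !state
    i <- j + 1L
  }
  out <- fc_ts(u, fs = fs, node_id = node_id)
  attr(out, "magnitude") <- magnitude
  attr(out, "rate_on_off") <- rate_on_off
  attr(out, "rate_off_on") <- rate_off_on
  out
}

#' Scale-free (pink) background noise
#'
#' Zero-mean noise with power spectral density proportional to 1/f over the
#' resolvable band, generated by spectral shaping: the Fourier coefficients
#' of Gaussian white noise are multiplied by `f^(-1/2)` (DC set to 0) and
#' transformed back, then the series is rescaled so its population variance
#' equals the requested value exactly.
#'
#' @param n number of samples (`n >= 16`).
#' @param variance target variance (`>= 0`); 0 yields an all-zero series.
#' @param fs sampling rate, metadata only.
#' @param node_id label.
#' @return [fc_ts()] of length `n`.
#' @export
generate_pink_noise <- function(n, variance, fs = 1, node_id = "noise") {
  if (n < 16) stop("n too small for spectral shaping (need n >= 16)")
  if (variance < 0) stop("variance must be >= 0")
  if (variance == 0) return(fc_ts(numeric(n), fs = fs, node_id = node_id))
  w <- rnorm(n)
  z <- fft(w)
  # frequency index of each fft bin (0, 1, ..., n/2, ..., 1)
  idx <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1)))
  h <- c(0, idx[-1]^(-0.5))
  x <- Re(fft(z * h, inverse = TRUE)) / n
  x <- x - mean(x)
  x <- x * sqrt(variance / mean(x^2))
  fc_ts(x, fs = fs, node_id = node_id)
}

#' Simulate BOLD dynamics of a directed network
#'
#' Integrates the bilinear neuronal model `zdot = A z + s(t) + sigma(t)`
#' together with per-node Balloon-Windkessel hemodynamics using explicit
#' Euler steps of `1/fs`. Inputs `s(t)` are binary Poisson-switching trains
#' (see [sample_input_process()]); `sigma(t)` is optional white or pink
#' background neuronal noise. Fully reproducible given `(config, seed)`.
#'
#' @param config an [dcm_config()] object.
#' @param hemo per-node hemodynamic parameters (data.frame as returned by
#'   [sample_hemo_params()]); `NULL` samples them from [hemo_priors()].
#' @param inputs optional list of per-node input [fc_ts()] overriding the
#'   sampled Poisson trains (recycled zeros for magnitude 0).
#' @return object of class `fc_sim`: list with `bold`, `neuronal`, `inputs`,
#'   `noise` (time x node matrices), `fs`, `hemo` and `config`.
#' @export
simulate_network <- function(config, hemo = NULL, inputs = NULL) {
  stopifnot(inherits(config, "fc_dcm_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_nodes
  nT <- round(config$duration * config$fs)
  if (is.null(hemo)) hemo <- sample_hemo_params(n)
  stopifnot(nrow(hemo) == n)

  U <- matrix(0, nT, n)
  if (is.null(inputs)) {
    for (i in seq_len(n)) {
      u <- sample_input_process(
        config$fs, config$duration,
        magnitude = config$input_magnitude[i],
        rate_on_off = config$input_rates[i, "on_off"],
        rate_off_on = config$input_rates[i, "off_on"],
        node_id = paste0("u", i))
      U[, i] <- u$values
    }
  } else {
    stopifnot(length(inputs) == n)
    for (i in seq_len(n)) U[, i] <- rep_len(ts_values(inputs[[i]]), nT)
  }

  S <- matrix(0, nT, n)
  if (config$noise_kind != "none") {
    for (i in seq_len(n)) {
      v <- config$noise_variance[i]
      if (v > 0) {
        S[, i] <- if (config$noise_kind == "pink") {
          generate_pink_noise(nT, v, fs = config$fs)$values
        } else {
          rnorm(nT, sd = sqrt(v))
        }
      }
    }
  }

  res <- .dcm_integrate_cpp(config$speed * config$adjacency,
                            config$speed * (U + S), 1 / config$fs,
                            hemo$kappa, hemo$gamma, hemo$tau, hemo$alpha,
                            hemo$e0, hemo$v0)
  colnames(res$bold) <- colnames(res$neuronal) <-
    paste0("node", seq_len(n))
  structure(list(bold = res$bold, neuronal = res$neuronal, inputs = U,
                 noise = S, fs = config$fs, hemo = hemo, config = config),
            class = "fc_sim")
}

#' @export
print.fc_sim <- function(x, ...) {
  cat(sprintf("<fc_sim> %d nodes, %d samples at %g Hz (%gs)\n",
              ncol(x$bold), nrow(x$bold), x$fs, nrow(x$bold) / x$fs))
  invisible(x)
}

#' Downsample simulated BOLD to an fMRI repetition time
#'
#' Training and robustness simulations use the full-resolution series; this
#' helper decimates to a benchmark-style TR for evaluations that emulate
#' scanner sampling.
#'
#' @param x numeric vector, [fc_ts()] or time x nodes matrix at rate `fs`.
#' @param fs source sampling rate (Hz); taken from `x` when it is an
#'   `fc_ts`.
#' @param tr target repetition time in seconds (e.g. 3).
#' @return same shape as the input, decimated to one sample per `tr`.
#' @export
downsample_bold <- function(x, tr, fs = NULL) {
  if (inherits(x, "fc_ts")) {
    fs <- x$fs
    step <- max(1L, round(tr * fs))
    out <- x
    out$values <- x$values[seq(1, length(x$values), by = step)]
    out$fs <- fs / step
    return(out)
  }
  if (is.null(fs)) stop("fs is required for plain inputs")
  step <- max(1L, round(tr * fs))
  if (is.matrix(x)) x[seq(1, nrow(x), by = step), , drop = FALSE]
  else x[seq(1, length(x), by = step)]
}

#' Two-node training configuration
#'
#' Convenience constructor of the canonical two-node system used for
#' supervised training and the robustness experiments: node 1 (upstream)
#' projects to node 2 (downstream) with the given weight, self-inhibition
#' -1 on the diagonal.
#'
#' @param weight connection weight upstream -> downstream (0.9 by default).
#' @param ... passed to [dcm_config()].
#' @return an `fc_dcm_config`.
#' @export
two_node_config <- function(weight = 0.9, ...) {
  A <- matrix(c(-1, weight, 0, -1), 2, 2)
  dcm_config(adjacency = A, ...)
}
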