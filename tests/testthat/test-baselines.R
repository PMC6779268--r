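test_that("Patel's tau: symmetry, antisymmetry and the counting oracle", {
  set.seed(70)
  x <- rnorm(200)
  expect_equal(patel_tau(x, x)$statistic, 0)
  y <- 0.5 * x + rnorm(200)
  expect_equal(patel_tau(x, y)$statistic, -patel_tau(y, x)$statistic,
               tolerance = 1e-12)
  expect_error(patel_tau(rnorm(10), rnorm(10)), "at least 20")
  expect_error(patel_tau(rep(1, 30), rnorm(30)), "degenerate")

  # printed 20-sample toy pair: x's on-events contain y's
  xt <- c(5, 5, 5, 5, 0, 0, 0, 0, 5, 5, 5, 0, 0, 0, 0, 5, 5, 0, 0, 0)
  yt <- c(0, 4, 4, 0, 0, 0, 0, 0, 0, 4, 4, 0, 0, 0, 0, 0, 4, 0, 0, 0)
  got <- patel_tau(xt, yt, n_thresholds = 9)
  # exhaustive counting oracle over the same threshold grid
  rescale <- function(v) {
    q <- quantile(v, c(0.1, 0.9), names = FALSE)
    pmin(pmax((v - q[1]) / (q[2] - q[1]), 0), 1)
  }
  xs <- rescale(xt); ys <- rescale(yt)
  vals <- c()
  for (th in (1:9) / 10) {
    x1 <- xs > th; y1 <- ys > th
    if (sum(x1) == 0 || sum(y1) == 0) next
    p_y_given_x <- sum(x1 & y1) / sum(x1)
    p_x_given_y <- sum(x1 & y1) / sum(y1)
    vals <- c(vals, p_y_given_x - p_x_given_y)
  }
  expect_equal(got$statistic, mean(vals), tolerance = 1e-12)
  # y's events are contained in x's, so P(X1|Y1) = 1 > P(Y1|X1) and the
  # statistic is negative under the printed decision rule
  expect_lt(got$statistic, 0)
  expect_identical(got$verdict, "y->x")
})

test_that("PW-LR r-skew: null symmetry and LiNGAM-style direction", {
  set.seed(71)
  # bivariate Gaussian, no skew: statistic within 3 SE of 0
  reps <- 40
  stats <- numeric(reps)
  for (i in seq_len(reps)) {
    x <- rnorm(2000)
    y <- 0.5 * x + rnorm(2000)
    stats[i] <- pw_lr_rskew(x, y)$statistic
  }
  expect_lt(abs(mean(stats)), 3 * sd(stats) / sqrt(reps))
  # right-skewed upstream: positive statistic in nearly all runs
  set.seed(72)
  hit <- 0
  for (i in 1:50) {
    x <- rexp(5000) - 1
    y <- 0.9 * x + (rexp(5000) - 1)
    d <- pw_lr_rskew(x, y)
    hit <- hit + (d$verdict == "x->y")
  }
  expect_gte(hit, 48)
  # antisymmetry under swap
  set.seed(73)
  x <- rexp(500); y <- 0.5 * x + rnorm(500)
  expect_equal(pw_lr_rskew(x, y)$statistic, -pw_lr_rskew(y, x)$statistic,
               tolerance = 1e-12)
  expect_error(pw_lr_rskew(rep(1, 100), rnorm(100)), "degenerate")
})

test_that("Granger causality: null behaviour and VAR(1) recovery", {
  set.seed(74)
  reps <- 30
  stats <- numeric(reps)
  for (i in seq_len(reps)) {
    stats[i] <- granger_bivariate(rnorm(2000), rnorm(2000))$statistic
  }
  expect_lt(abs(mean(stats)), 3 * sd(stats) / sqrt(reps))
  # planted VAR(1) coupling x -> y
  set.seed(75)
  hit <- 0
  for (i in 1:100) {
    n <- 2000
    x <- as.numeric(stats::arima.sim(list(ar = 0.5), n))
    e <- rnorm(n)
    y <- numeric(n)
    for (t in 2:n) y[t] <- 0.5 * x[t - 1] + 0.3 * y[t - 1] + e[t]
    d <- granger_bivariate(x, y)
    hit <- hit + (d$verdict == "x->y" && d$statistic > 0)
  }
  expect_gte(hit, 99)
  set.seed(76)
  x <- rnorm(500); y <- 0.4 * x + rnorm(500)
  expect_equal(granger_bivariate(x, y)$statistic,
               -granger_bivariate(y, x)$statistic, tolerance = 1e-10)
  expect_error(granger_bivariate(rnorm(5), rnorm(5)), "too short")
})

test_that("PDC: column normalization, zero coupling, known direction", {
  # diagonal VAR: off-diagonal PDC is zero at every frequency
  A <- list(matrix(c(0.5, 0, 0, 0.3), 2, 2))
  spec <- pdc_spectrum(A, seq(0, 0.5, length.out = 16))
  expect_lt(max(abs(spec[1, 2, ])), 1e-12)
  expect_lt(max(abs(spec[2, 1, ])), 1e-12)
  # column-normalization identity at every frequency and column
  A2 <- list(matrix(c(0.5, 0.4, -0.2, 0.3), 2, 2))
  s2 <- pdc_spectrum(A2, seq(0, 0.5, length.out = 33))
  norms <- apply(s2^2, c(2, 3), sum)
  expect_equal(as.numeric(norms), rep(1, length(norms)), tolerance = 1e-12)
  # closed-form check of a unidirectional coupling at f = 0:
  # Abar(0) = I - A, column 1 = (1 - a11, -a21)
  a <- matrix(c(0.5, 0.4, 0, 0.3), 2, 2)
  s0 <- pdc_spectrum(list(a), 0)
  expect_equal(s0[2, 1, 1], 0.4 / sqrt(0.5^2 + 0.4^2), tolerance = 1e-12)
  expect_equal(s0[1, 2, 1], 0, tolerance = 1e-12)

  # fitted VAR: planted x -> y coupling gives a positive statistic
  set.seed(77)
  hit <- 0
  for (i in 1:20) {
    n <- 2000
    x <- as.numeric(stats::arima.sim(list(ar = 0.5), n))
    y <- numeric(n)
    e <- rnorm(n)
    for (t in 2:n) y[t] <- 0.6 * x[t - 1] + 0.3 * y[t - 1] + e[t]
    d <- pdc_bivariate(x, y)
    hit <- hit + (d$statistic > 0)
  }
  expect_gte(hit, 19)
})

test_that("all pair methods are at chance on direction-free null pairs", {
  set.seed(78)
  n_seeds <- 200
  methods <- pair_methods(c("patel_tau", "pw_lr_rskew", "granger", "pdc"))
  hits <- setNames(numeric(length(methods)), names(methods))
  evals <- hits
  for (i in seq_len(n_seeds)) {
    # independent AR(2)-filtered series: no causal link either way
    x <- as.numeric(stats::arima.sim(list(ar = c(0.4, 0.2)), 300))
    y <- as.numeric(stats::arima.sim(list(ar = c(0.4, 0.2)), 300))
    truth <- if (i %% 2 == 0) "y->x" else "x->y"
    for (m in names(methods)) {
      d <- tryCatch(methods[[m]](x, y), error = function(e) NULL)
      if (!is.null(d)) {
        evals[m] <- evals[m] + 1
        hits[m] <- hits[m] + (d$verdict == truth)
      }
    }
  }
  for (m in names(methods)) {
    p <- hits[m] / evals[m]
    # binomial 99% interval around 0.5
    half <- 2.58 * sqrt(0.25 / evals[m])
    expect_gt(p, 0.5 - half)
    expect_lt(p, 0.5 + half)
  }
})

test_that("pair_methods exposes the common interface", {
  expect_error(pair_methods("nope"), "unknown")
  m <- pair_methods(c("patel_tau", "granger"))
  expect_named(m, c("patel_tau", "granger"))
  set.seed(79)
  d <- m$granger(rnorm(100), rnorm(100))
  expect_s3_class(d, "fc_decision")
})
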