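test_that("hemodynamic parameter sampling respects priors and domains", {
  pr <- hemo_priors()
  expect_identical(rownames(pr), c("kappa", "gamma", "tau", "alpha", "e0", "v0"))
  # zero prior variance: every node gets the prior mean
  pr0 <- pr
  pr0$var <- 0
  h <- sample_hemo_params(5, pr0)
  for (p in rownames(pr0)) expect_equal(h[[p]], rep(pr0[p, "mean"], 5))
  # determinism under seeding
  set.seed(10)
  h1 <- sample_hemo_params(4)
  set.seed(10)
  h2 <- sample_hemo_params(4)
  expect_identical(h1, h2)
  # Monte-Carlo: sample mean of tau within 3 SE of the prior mean
  set.seed(11)
  big <- sample_hemo_params(10000)
  se <- sqrt(pr["tau", "var"] / 10000)
  expect_lt(abs(mean(big$tau) - pr["tau", "mean"]), 3 * se)
  expect_true(all(big$alpha > 0 & big$alpha < 1))
  expect_true(all(big$e0 > 0 & big$e0 < 1))
  expect_true(all(big$kappa > 0 & big$tau > 0))
  # invalid configuration
  bad <- pr
  bad$var[1] <- -1
  expect_error(sample_hemo_params(2, bad), "invalid prior")
})

test_that("input process is a two-level signal with exponential dwell times", {
  set.seed(12)
  # rate -> 0 with initial off state: all-zero signal
  u0 <- sample_input_process(100, 5, magnitude = 2, rate_on_off = 0,
                             rate_off_on = 0)
  expect_true(all(u0$values == 0))
  # two-level: on-samples equal the magnitude exactly
  u <- sample_input_process(100, 60, magnitude = 1.7, rate_on_off = 1,
                            rate_off_on = 1)
  expect_true(all(u$values %in% c(0, 1.7)))
  expect_gt(mean(u$values > 0), 0.2)
  # mean dwell time within 3 SE of 1 s at rates 1/s over a long run
  set.seed(13)
  u2 <- sample_input_process(200, 2400, magnitude = 1, rate_on_off = 1,
                             rate_off_on = 1)
  r <- rle(u2$values > 0)
  dwell <- r$lengths[-c(1, length(r$lengths))] / 200  # drop censored ends
  expect_gt(length(dwell), 500)
  expect_lt(abs(mean(dwell) - 1), 3 * sd(dwell) / sqrt(length(dwell)))
})

test_that("pink noise has the requested variance and a 1/f spectrum", {
  expect_error(generate_pink_noise(8, 1), "too small")
  expect_equal(generate_pink_noise(64, 0)$values, numeric(64))
  set.seed(14)
  n <- 2^16
  x <- generate_pink_noise(n, variance = 2.5)$values
  expect_lt(abs(var(x) - 2.5) / 2.5, 0.01)
  expect_lt(abs(mean(x)), 1e-10)
  # log-log PSD slope about -1 in [0.01, 1] x Nyquist (Welch-style average)
  nseg <- 16
  seg <- matrix(x[1:(nseg * floor(n / nseg))], ncol = nseg)
  m <- floor(n / nseg)
  psd <- rowMeans(apply(seg, 2, function(s) Mod(fft(s * 2 / m))[1:(m / 2)]^2))
  f <- (seq_len(m / 2) - 1) / m
  band <- f >= 0.005 & f <= 0.5
  slope <- coef(lm(log(psd[band]) ~ log(f[band])))[2]
  expect_lt(abs(slope + 1), 0.15)
})

test_that("network simulation is reproducible and settles without input", {
  cfg0 <- two_node_config(0.9, duration = 10, input_magnitude = 0,
                          input_rates = 1, noise_kind = "none", seed = 20)
  sim0 <- simulate_network(cfg0)
  half <- (nrow(sim0$bold) / 2):nrow(sim0$bold)
  expect_lt(max(apply(sim0$bold[half, ], 2, var)), 1e-10)

  cfg <- two_node_config(0.9, duration = 10, seed = 21)
  s1 <- simulate_network(cfg)
  s2 <- simulate_network(cfg)
  expect_identical(s1$bold, s2$bold)
  expect_identical(dim(s1$bold), c(2000L, 2L))
})

test_that("paper-scale run length and causal ordering of responses", {
  cfg <- two_node_config(0.9, fs = 200, duration = 600, input_magnitude = 0,
                         input_rates = 1, seed = 22)
  # 10 min at 200 Hz: 120,000 samples per node
  expect_identical(round(cfg$duration * cfg$fs), 120000)
  # impulse into node 1 only: node 2's neuronal state departs later
  n <- 400
  imp <- matrix(0, n, 2)
  imp[10, 1] <- 1
  cfg2 <- two_node_config(0.9, fs = 200, duration = n / 200,
                          input_magnitude = 0, input_rates = 1, seed = 23)
  pr0 <- hemo_priors(); pr0$var <- 0
  sim <- simulate_network(cfg2, hemo = sample_hemo_params(2, pr0),
                          inputs = list(fc_ts(imp[, 1], 200),
                                        fc_ts(imp[, 2], 200)))
  t1 <- which(abs(sim$neuronal[, 1]) > 1e-9)[1]
  t2 <- which(abs(sim$neuronal[, 2]) > 1e-9)[1]
  expect_lt(t1, t2)
  expect_gt(max(abs(sim$neuronal[, 2])), 0)
})

test_that("neuronal response is linear in the input magnitude", {
  n <- 2000
  u <- numeric(n)
  u[100:300] <- 1
  pr0 <- hemo_priors(); pr0$var <- 0
  base <- two_node_config(0.9, fs = 200, duration = n / 200,
                          input_magnitude = 0, input_rates = 1, seed = 1)
  s1 <- simulate_network(base, hemo = sample_hemo_params(2, pr0),
                         inputs = list(fc_ts(u, 200), fc_ts(0 * u, 200)))
  s2 <- simulate_network(base, hemo = sample_hemo_params(2, pr0),
                         inputs = list(fc_ts(2 * u, 200), fc_ts(0 * u, 200)))
  expect_equal(s2$neuronal, 2 * s1$neuronal, tolerance = 1e-8)
})

test_that("null connection gives exchangeable node summaries", {
  # with no connection and i.i.d. node configurations, upstream and
  # downstream BOLD variances come from the same distribution
  set.seed(30)
  fac <- training_sim_factory(weight = 0, duration = 10)
  v1 <- v2 <- numeric(40)
  for (i in 1:40) {
    p <- fraccum:::nondegenerate_pair(fac, i)
    v1[i] <- var(p$x)
    v2[i] <- var(p$y)
  }
  expect_gt(suppressWarnings(ks.test(v1, v2)$p.value), 0.01)
})

test_that("downsampling decimates to the requested TR", {
  m <- matrix(seq_len(400), ncol = 2)
  d <- downsample_bold(m, tr = 2, fs = 10)
  expect_equal(nrow(d), 10)
  expect_equal(d[2, 1], 21)
  ts <- fc_ts(1:100, fs = 10)
  dt <- downsample_bold(ts, tr = 1)
  expect_equal(dt$fs, 1)
  expect_equal(dt$values[1:3], c(1, 11, 21))
  expect_error(downsample_bold(1:10, tr = 1), "fs is required")
})

test_that("configuration validation catches bad inputs", {
  expect_error(dcm_config(matrix(c(1, 0, 0, -1), 2, 2)), "diagonal")
  expect_error(dcm_config(matrix(-1, 1, 2)), "square")
  expect_error(two_node_config(0.9, fs = -1), "fs")
  expect_error(two_node_config(0.9, noise_variance = -2,
                               noise_kind = "pink"), "noise_variance")
})
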