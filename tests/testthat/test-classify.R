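test_that("discount nonlinearity matches its definition", {
  expect_identical(discount(0), 0)
  expect_identical(discount(-5), 0)
  expect_equal(discount(1), log(cosh(1)), tolerance = 1e-12)
  # monotone increasing, asymptotically x - log 2
  x <- seq(0, 30, by = 0.25)
  fx <- discount(x)
  expect_true(all(diff(fx) > 0))
  expect_lt(abs(discount(30) - (30 - log(2))), 1e-12)
  expect_equal(discount(c(-1, 0.5, 2)),
               c(0, log(cosh(0.5)), log(cosh(2))), tolerance = 1e-12)
})

test_that("classifier verdicts are antisymmetric and scale invariant", {
  set.seed(50)
  maps <- train_sign_maps(quick_training_factory(duration = 10), n_sims = 10)
  cfg <- classifier_config(maps, weighted = TRUE)
  fac <- quick_validation_factory(duration = 10)
  for (i in 1:5) {
    p <- fraccum:::nondegenerate_pair(fac, i)
    d1 <- classify_pair(p$x, p$y, cfg)
    d2 <- classify_pair(p$y, p$x, cfg)
    expect_equal(d1$statistic, -d2$statistic, tolerance = 1e-9)
    if (d1$statistic != 0) expect_false(d1$verdict == d2$verdict)
    # affine transforms with positive gain do not change the verdict
    d3 <- classify_pair(3.2 * p$x + 7, 0.4 * p$y - 2, cfg)
    expect_equal(d3$statistic, d1$statistic, tolerance = 1e-9)
  }
})

test_that("all-zero sign maps give the x->y tie verdict", {
  g <- moment_grid(1, 0.1)
  maps <- train_sign_maps(samples = list(
    Cr = array(0, c(11, 11, 1)), Ci = array(0, c(11, 11, 1)), grid = g))
  cfg <- classifier_config(maps, ind_r_max = 1, ind_i_max = 1)
  set.seed(51)
  expect_warning(d <- classify_pair(rnorm(100), rnorm(100), cfg), "zero")
  expect_identical(d$verdict, "x->y")
  expect_true(d$tie)
})

test_that("classifier input validation", {
  set.seed(52)
  maps <- train_sign_maps(samples = list(
    Cr = array(1, c(3, 3, 1)), Ci = array(1, c(3, 3, 1)),
    grid = c(0, 0.5, 1)))
  cfg <- classifier_config(maps, ind_r_max = 1, ind_i_max = 1)
  expect_error(classify_pair(rnorm(100), rnorm(50), cfg), "equal length")
  expect_error(classify_pair(rnorm(10), rnorm(10), cfg), "too short")
  expect_error(classify_pair(rep(1, 100), rnorm(100), cfg), "degenerate")
  expect_error(classifier_config(maps, ind_r_max = 99), "within the grid")
})

test_that("trained classifier orients noiseless simulations", {
  set.seed(53)
  maps <- train_sign_maps(quick_training_factory(duration = 20), n_sims = 40)
  cfg <- classifier_config(maps, weighted = TRUE)
  fac <- quick_validation_factory(duration = 20)
  set.seed(54)
  ok <- balanced_successes(fac, 30, function(a, b) classify_pair(a, b, cfg))
  expect_gte(ok, 26)  # >= ~85% at this reduced scale
})

test_that("weighted and unweighted classifiers agree on clear directions", {
  set.seed(55)
  maps <- train_sign_maps(quick_training_factory(duration = 20), n_sims = 40)
  cw <- classifier_config(maps, weighted = TRUE)
  cu <- classifier_config(maps, weighted = FALSE)
  fac <- quick_validation_factory(duration = 20)
  agree <- 0
  set.seed(56)
  for (i in 1:20) {
    p <- fraccum:::nondegenerate_pair(fac, i)
    agree <- agree + (classify_pair(p$x, p$y, cw)$verdict ==
                        classify_pair(p$x, p$y, cu)$verdict)
  }
  expect_gte(agree, 18)
})

test_that("verdict is stable across connection strengths", {
  # the voting statistic scales with the connection weight but its sign
  # should not change in the noiseless case
  cfg <- default_classifier()
  for (w in c(0.3, 0.6, 0.9)) {
    fac <- quick_validation_factory(weight = w, duration = 60)
    set.seed(58)
    ok <- balanced_successes(fac, 20, function(a, b) classify_pair(a, b, cfg))
    expect_gte(ok, 16)
  }
})

test_that("covariance weighting scales the statistic by the pair covariance", {
  set.seed(59)
  maps <- train_sign_maps(quick_training_factory(duration = 10), n_sims = 10)
  c0 <- classifier_config(maps, weighted = TRUE, cov_weighted = FALSE)
  c1 <- classifier_config(maps, weighted = TRUE, cov_weighted = TRUE)
  fac <- quick_validation_factory(duration = 10)
  p <- fraccum:::nondegenerate_pair(fac, 1)
  xn <- normalize_series(p$x)
  yn <- normalize_series(p$y)
  d0 <- classify_pair(p$x, p$y, c0)
  d1 <- classify_pair(p$x, p$y, c1)
  expect_equal(d1$statistic, d0$statistic * mean(xn * yn), tolerance = 1e-12)
})

test_that("shipped default sign maps load and drive the default classifier", {
  maps <- default_sign_maps()
  expect_s3_class(maps, "fc_signmaps")
  expect_identical(maps$grid, moment_grid())
  expect_true(all(maps$Sr %in% c(-1, 0, 1)))
  expect_true(all(maps$Sr == -t(maps$Sr)))
  cfg <- default_classifier()
  expect_equal(cfg$ind_r_max, 2.1)
  expect_equal(cfg$ind_i_max, 3.7)
  cfu <- default_classifier(weighted = FALSE)
  expect_equal(cfu$ind_r_max, 2.4)
  expect_equal(cfu$ind_i_max, 1.7)
})
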