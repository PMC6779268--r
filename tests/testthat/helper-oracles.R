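# Brute-force double-loop evaluation of the cumulant map, independent of
# the vectorized/BLAS implementation path.
brute_force_cumulants <- function(x, y, grid) {
  K <- length(grid)
  C <- matrix(0 + 0i, K, K)
  for (a in seq_len(K)) {
    for (b in seq_len(K)) {
      s <- 0 + 0i
      for (i in seq_along(x)) {
        s <- s +
          complex_power(x[i], grid[a]) * complex_power(y[i], grid[b]) -
          complex_power(x[i], grid[b]) * complex_power(y[i], grid[a])
      }
      C[a, b] <- s / length(x)
    }
  }
  C
}

# small, fast two-node simulation helpers for tests
quick_training_factory <- function(weight = 0.9, duration = 20)
  training_sim_factory(weight, fs = 200, duration = duration)

quick_validation_factory <- function(weight = 0.9, duration = 20, ...)
  validation_sim_factory(weight, fs = 200, duration = duration, ...)

# classify n pairs from a factory with balanced truths; returns successes
balanced_successes <- function(factory, n, classify_fun) {
  ok <- 0L
  for (i in seq_len(n)) {
    p <- fraccum:::nondegenerate_pair(factory, i)
    if (i %% 2 == 0) {
      d <- classify_fun(p$y, p$x)
      ok <- ok + (d$verdict == "y->x")
    } else {
      d <- classify_fun(p$x, p$y)
      ok <- ok + (d$verdict == "x->y")
    }
  }
  ok
}
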