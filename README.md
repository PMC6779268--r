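# fraccum

Pairwise effective-connectivity inference for fMRI BOLD time series using
fractional complex moments and cumulants.

## What problem this solves

Functional connectivity tells you *that* two brain regions interact;
effective connectivity asks *which way* the influence flows. Lag-based
direction methods struggle on BOLD data because regional differences in
the hemodynamic response are larger than the neuronal lags they look for.
`fraccum` implements a two-step, distribution-based alternative for
researchers working with region-of-interest BOLD time series (or
simulated benchmarks):

1. detect undirected connections by permutation-thresholded partial
   correlation (normalized inverse covariance);
2. classify each connected pair into an upstream and a downstream node
   from the *shape* of the joint signal distribution, ignoring temporal
   order entirely.

The direction classifier works on fractional complex moments. For a
series normalized to mean 0 and population variance 1,

    M_k = (1/N) * sum_i x_i^k ,        k in [0, 5] (step 0.1)

where negative values use the principal branch `x^k = |x|^k exp(i*pi*k)`,
so the moments form a curve in the complex plane. Directional asymmetry
between two series is measured by the antisymmetrized cross-moments
("fractional cumulants")

    C_kl = (1/N) * sum_i ( x_i^k y_i^l  -  x_i^l y_i^k ).

A supervised classifier compares the observed sign pattern of `C` with
ternary sign maps `Sr, Si` trained on repeated simulations of a two-node
dynamic-causal-modelling (DCM) generative model with a known connection:

    T = sum_kl [ Sr_kl * f(Re C_kl) + Si_kl * f(Im C_kl) ],
    f(x) = log(cosh(max(x, 0)))        (weighted scheme)

with `T >= 0` read as `x->y`. The package also ships the full generative
simulator (bilinear neuronal dynamics + Balloon-Windkessel hemodynamics,
Poisson-switching inputs, pink background noise), four reference
direction methods (Patel's tau with threshold integration, PW-LR r-skew,
bivariate lag-1 Granger causality, bivariate partial directed coherence),
and the robustness experiment harness (noise-variance and input-strength
grids). See the vignette in `vignettes/fractional-cumulants.Rmd` for the
model, parameter choices and limitations.

## Worked example

Simulate a two-node system in which node 1 drives node 2 with weight 0.9,
then ask the shipped classifier which way the connection points:

```r
library(fraccum)
set.seed(42)
cfg <- two_node_config(weight = 0.9, fs = 200, duration = 60,
                       input_magnitude = 1, input_rates = 1)
sim <- simulate_network(cfg)

classify_pair(sim$bold[, 1], sim$bold[, 2])   # upstream given first
#> <fc_decision> fractional_cumulants: x->y (statistic 36.594)
classify_pair(sim$bold[, 2], sim$bold[, 1])   # swapped
#> <fc_decision> fractional_cumulants: y->x (statistic -36.594)
```

The positive statistic is the voting sum `T` above: the observed cumulant
signs match the trained upstream-first pattern, so the verdict is
`x->y`; swapping the arguments negates the cumulant map and the statistic
exactly. Comparing all methods on the same pair (the lagged methods see
the series at a typical scan resolution, TR = 2 s):

```r
m <- pair_methods(lagged_tr = 2, fs = 200)
#>                 method   statistic verdict
#> 1 fractional_cumulants 36.59403754    x->y
#> 2            patel_tau  0.01194456    x->y
#> 3          pw_lr_rskew  0.01016821    x->y
#> 4              granger -0.02814872    y->x
#> 5                  pdc -0.07075695    y->x
```

On this single 60-s realization the distribution-based methods recover
the planted direction while the lagged methods (Granger, PDC) answer
essentially at random — the pattern the robustness grids
(`noise_robustness_grid()`, `signal_strength_grid()`) quantify over
hundreds of realizations.

A full two-step analysis of a multi-node matrix:

```r
res <- two_step_infer(ts_matrix, n_perm = 1000, alpha = 0.05)
res$directed   # binary adjacency, [i, j] = 1 means node i -> node j
```

## Command line

```sh
exec/fraccum simulate --duration 600 --seed 1 --out sim.csv
exec/fraccum train --n-sims 1000 --seed 1 --out maps.json
exec/fraccum classify --input sim.csv --maps maps.json
exec/fraccum grid --mode noise --n-real 50 --seed 1 --out grid.csv
```

Time-series text files use a header row of node labels and one row per
time point; a `<file>.json` sidecar carries the sampling rate and
optional ground truth.

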