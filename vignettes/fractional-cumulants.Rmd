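---
title: "Fractional cumulants for pairwise effective connectivity: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractional cumulants for pairwise effective connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Estimating *effective* (directed) connectivity from fMRI is hard: the BOLD
signal is a slow, regionally variable hemodynamic filter of neuronal
activity, sampled at low rates and contaminated by scale-free background
noise. Lag-based methods (Granger causality, partial directed coherence)
are confounded by hemodynamic timing differences between regions, which
are of the same order as — or larger than — the neuronal lags they try to
detect. This package takes the two-step pairwise route instead: detect
undirected connections from partial correlations first, then classify each
connected pair into an upstream and a downstream node using only the
*distributions* of the two signals, with no reliance on temporal order.

## Fractional moments and cumulants

For a series normalized to mean 0 and population variance 1, the moment of
(possibly fractional) order $k$ is

$$M_k = \frac{1}{N}\sum_{i=1}^N \hat x_i^{\,k},$$

where negative values are raised to fractional powers on the principal
branch, $x^k = |x|^k e^{i\pi k}$ for $x<0$. This makes $M_k$ complex; as a
function of $k$ the moments trace a continuous curve in the complex plane
that starts at $(1,0)$ for $k=0$, passes through the origin at $k=1$
(demeaned data), returns to $(1,0)$ at $k=2$ (unit variance) and crosses
the real axis at every integer $k$. The directional information for a pair
$x(t), y(t)$ sits in the antisymmetrized cross-moments — the *fractional
cumulants* —

$$C_{kl} = \frac{1}{N}\sum_i \left(\hat x_i^k \hat y_i^l -
  \hat x_i^l \hat y_i^k\right),$$

computed on a grid $k, l \in [0, 5]$ with step $\Delta k = 0.1$ (fine
enough that the maps vary smoothly with the index; finer grids add cost
but little information, since nearby cumulants are strongly correlated).
$C$ is exactly antisymmetric with a zero diagonal, and negates when the
pair is swapped.

## The generative trainer

The classifier is supervised: its state — two ternary *sign maps*
$S_r, S_i$ — is the majority sign of $\mathrm{Re}\,C_{kl}$ and
$\mathrm{Im}\,C_{kl}$ over repeated simulations of a two-node system with
a known connection (weight 0.9). The simulator is the canonical bilinear
DCM forward model:

* neuronal layer $\dot z = \sigma\,(A z + s(t) + \xi(t))$ with adjacency
  $A$ in benchmark units (diagonal $-1$, connection weight $A_{21}=0.9$)
  and rate constant $\sigma = 20\,\mathrm{s^{-1}}$, i.e. a 50 ms neuronal
  time constant as in the benchmark implementation this package follows.
  Steady-state mixing of the nodes depends only on $A$, not on $\sigma$;
  $\sigma$ matters for what lag-based methods can see (below).
* per-node Balloon–Windkessel hemodynamics (signal decay $\kappa$,
  autoregulation $\gamma$, transit time $\tau$, stiffness $\alpha$,
  resting extraction $E_0$, resting volume $V_0$) integrated by explicit
  Euler at $1/F_s$ with $F_s = 200$ Hz. Parameters are drawn per node from
  the empirical priors ($\kappa: 0.65 \pm 0.015$, $\gamma: 0.41 \pm 0.002$,
  $\tau: 0.98 \pm 0.0568$, $\alpha: 0.32 \pm 0.0015$,
  $E_0: 0.34 \pm 0.0024$ (mean ± variance), $V_0 = 0.04$ fixed), truncated
  to their valid domains. They live in one editable JSON file
  (`inst/extdata/hemo_priors.json`) so corrected hemodynamic variants can
  be swapped in.
* inputs $s_i(t)$ are binary on/off trains driven by a two-state Markov
  process (per-step switching probability $r/F_s$, i.e. exponential dwell
  times), with magnitude and both rates drawn from Gamma(mean 1, var 1) —
  the unique Gamma with that mean and variance, an Exponential(1) — in
  *training*, to marginalize input parameters out of the sign maps.
* optional background neuronal noise $\xi(t)$, white or pink. Pink noise
  is generated by spectral shaping ($f^{-1/2}$ amplitude on white-noise
  Fourier coefficients, DC removed) and rescaled to the exact target
  variance.

Training runs 10-minute simulations at 200 Hz without downsampling to an
fMRI TR, which gives precise cumulant estimates. Draws whose input train
never switches on (constant BOLD, no directional information) are
resampled; at 10 minutes this is rare, at the reduced durations used in
tests it is not.

### Training samples vs validation fixes

The input magnitude and switching rates are *sampled* only while training.
Validation and robustness experiments hold them at fixed values (amplitude
1.0 or the grid level, rates 1/s). This distinction matters: if the test
pair itself has, say, a much faster input to the downstream node, part of
the directional evidence is genuinely erased, and every pairwise method —
not just this one — degrades toward chance. The fixed-input validation
world matches the robustness experiments, which state the input amplitude
explicitly and vary one factor at a time.

## The classifier

For a new pair, both series are normalized, the cumulant map is computed,
and every cumulant inside the voting window casts a vote: its observed
sign against its trained sign. The decision statistic is

$$T = \sum_{k,l} \left[S_{r,kl}\, f(C_{r,kl}) + S_{i,kl}\, f(C_{i,kl})\right],$$

with $f(x) = \log(\cosh(\max(x, 0)))$ in the *weighted* scheme (the
discount suppresses poorly estimated high-index cumulants; note that a
cumulant agreeing with a negative trained sign contributes through its
mirrored cell, so no evidence is lost) and $f$ the identity in the
unweighted scheme. $T \ge 0$ is read as `x->y`, otherwise `y->x`; an exact
zero resolves to `x->y` with a warning, following the literal decision
rule. Optional covariance weighting multiplies $T$ by the covariance of
the normalized pair, mirroring the construction of the pairwise
likelihood-ratio family; it is exposed as a flag and off by default
outside benchmark-style comparisons.

The voting window restricts to $k, l \ge 0.1$ (pure moments, $k=0$ or
$l=0$, have lower discriminative value and never vote) and
$k + l \le \mathrm{Ind}_{max}$, with separate windows for the real and
imaginary component. The shipped defaults are the tuned windows
$(\mathrm{IndR}_{max}, \mathrm{IndI}_{max}) = (2.1, 3.7)$ for the weighted
scheme and $(2.4, 1.7)$ unweighted. A `"max"` window variant
($\max(k,l) \le \mathrm{Ind}_{max}$) is available behind a flag because
the defining text mixes both readings; the triangle reading is the
default. `tune_window()` re-runs the exhaustive search over cutoffs and
windows against any user-supplied evaluation collection.

Discriminability maps (`discriminability()`) quantify, per cumulant, the
fraction of connection-condition samples beyond the null distribution's
95th percentile (below the 5th when the connection mean is negative),
with both distributions smoothed by a Gaussian kernel using Silverman's
bandwidth — the reference text specifies kernel smoothing without
parameters, and Silverman is the conventional default. Including all
off-diagonal cumulants (cutoff 0) is the best-performing choice in the
source setting, so the cutoff defaults to 0.

## First stage and baselines

`partial_correlation()` is the normalized inverse covariance;
`permutation_threshold()` builds per-edge nulls from circular time-shift
surrogates (preserving each node's autocorrelation — essential, because
BOLD at 200 Hz has few effective degrees of freedom per sample) and keeps
edges beyond the $1-\alpha$ null quantile. Defaults $n_{perm} = 1000$,
$\alpha = 0.05$ are package choices; the source does not state its
first-stage settings.

Four reference direction methods share the pair interface: Patel's tau
(percentile rescaling to $[0,1]$, integration over a dense grid of 99
binarization thresholds, statistic $P(Y_1|X_1) - P(X_1|Y_1)$ with the
printed sign rule), PW-LR r-skew (correlation-weighted third-cumulant
asymmetry with the log-cosh outlier discount; constant factors of the
likelihood-ratio approximation are dropped as they do not affect the
sign), bivariate lag-1 OLS Granger causality (log residual-variance
ratios), and bivariate PDC (order-1 VAR, column-normalized coefficient
spectra, band-averaged over $[0, F_s/2]$). PDC inputs are z-scored before
the VAR fit: PDC is not scale-invariant, and without this step it
inherits a systematic amplitude-ratio bias in the asymmetric-input
experiments.

Two sampling regimes coexist in simulator-based comparisons. Cumulant
estimation deliberately uses the full-resolution (200 Hz) series — that
is the point of not subsampling the synthetic BOLD — and the
distribution-based baselines are insensitive to the sampling rate. The
autoregressive methods, however, are defined at scan resolution: "lag 1"
for fMRI Granger causality means one repetition time, not one 5-ms
integration step. `pair_methods(lagged_tr = 2, fs = ...)` therefore hands
GC and PDC the series decimated to a typical TR of 2 s. Run at the full
rate instead, lag-1 GC acquires genuine skill in the corner of the noise
grid where strong upstream pink noise transmits downstream — an artifact
of evaluating a seconds-scale method on millisecond-scale data that no
fMRI analysis would see.

## Numerical choices

* Powers of negative bases use the principal branch; $0^0 = 1$.
* Normalization divides by the population (1/N) standard deviation so the
  1/N moment sums hit $M_1 = 0$, $M_2 = 1$ exactly.
* The cumulant map partitions samples by the sign pattern of $(x, y)$;
  within each group the complex phase is constant, so the map reduces to
  four real matrix crossproducts (BLAS) plus phase factors — identical to
  the double-loop definition to machine precision, and fast enough to
  evaluate 120,000-sample pairs on the full 51×51 grid in tens of
  milliseconds.
* The Euler integrator clamps the hemodynamic states $f, v, q$ at a small
  positive floor; under strong noise excursions toward zero flow would
  otherwise produce complex powers. Any non-finite state aborts with the
  step index.
* `log(cosh(x))` switches to $x - \log 2 + \log(1 + e^{-2x})$ for large
  $x$ to avoid overflow.
* Majority-sign ties (including the zero diagonal) give abstaining cells;
  an exactly zero decision statistic resolves to `x->y` with a warning.

## What the synthetic world does and does not establish

The generator emulates: bilinear neuronal dynamics with a fixed
excitatory connection, empirically calibrated and regionally variable
hemodynamics, Poisson-switching inputs, and scale-free background noise
of controllable variance. It does not emulate: measurement noise and
scanner artifacts, TR-subsampled short series (a `TR` downsampling option
exists for benchmark-style evaluation), nonlinear input modulation
(bilinear terms), inhibitory connections (the trained maps cover
excitatory links only), or networks beyond the sparse graphs the user
supplies. A green robustness test therefore establishes that the method
ranks as reported *within this generative world*, not that it will do so
on empirical fMRI.

The neuronal rate constant deserves emphasis: at $\sigma = 20$ (50 ms
lags) the lagged baselines sit at chance because per-node hemodynamic
variability (~hundreds of ms) swamps the neuronal lag structure, which is
the mechanism the robustness experiments illustrate. Slowing the neuronal
layer to $\sigma = 1$ hands the lagged methods a detectable 1-second lag
and changes that conclusion; the distribution-based classifier is
indifferent to $\sigma$ because steady-state mixing is not.

## Known limitations

* Verdicts are binary net-direction calls with no calibrated confidence;
  bidirectional connections are reported as their net direction.
* The shipped sign maps are trained at a reduced scale (they stabilize
  well before 1,000 simulations, but cells near the decision boundary may
  abstain differently across retraining runs); `train_sign_maps()`
  regenerates them at any scale.
* The first-stage permutation test uses circular-shift surrogates; for
  multi-subject collections run it per subject and combine, as
  subject-label shuffling is not separately implemented.
* Exact-tie verdicts (`x->y`) are a convention, not evidence.
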