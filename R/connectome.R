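#' Partial correlation matrix (normalized inverse covariance)
#'
#' `P_ij = -Omega_ij / sqrt(Omega_ii Omega_jj)` with Omega the inverse of
#' the sample covariance; the diagonal is set to 1. This conditions each
#' pairwise association on all remaining nodes and is the usual first-stage
#' functional-connectivity estimate.
#'
#' @param ts_matrix numeric matrix, time points x nodes (more rows than
#'   columns).
#' @param ridge optional ridge term added to the covariance diagonal before
#'   inversion (default 0; use when the covariance is ill-conditioned).
#' @return symmetric matrix of partial correlations with unit diagonal.
#' @export
partial_correlation <- function(ts_matrix, ridge = 0) {
  ts_matrix <- as.matrix(ts_matrix)
  if (nrow(ts_matrix) <= ncol(ts_matrix))
    stop("need more time points than nodes")
  S <- cov(ts_matrix)
  if (ridge > 0) S <- S + diag(ridge, ncol(S))
  if (rcond(S) < 1e-12)
    stop("covariance matrix is (near-)singular; consider ridge > 0")
  if (rcond(S) < 1e-8)
    warning("covariance matrix is ill-conditioned; consider ridge > 0")
  Om <- solve(S)
  d <- sqrt(diag(Om))
  P <- -Om / tcrossprod(d)
  diag(P) <- 1
  dimnames(P) <- list(colnames(ts_matrix), colnames(ts_matrix))
  P
}

# circular time-shift surrogate: preserves each node's autocorrelation,
# destroys cross-node alignment
circular_surrogate <- function(ts_matrix) {
  n <- nrow(ts_matrix)
  apply(ts_matrix, 2, function(col) {
    s <- sample.int(n, 1)
    if (s == n) col else c(col[(s + 1):n], col[1:s])
  })
}

#' Permutation-thresholded undirected connectome
#'
#' Builds a per-edge null distribution of absolute partial correlations
#' from circularly time-shifted surrogates and keeps an edge when its
#' observed absolute partial correlation exceeds the (1 - alpha) null
#' quantile.
#'
#' @param ts_matrix time x nodes matrix.
#' @param n_perm number of surrogate permutations (>= 100).
#' @param alpha per-edge significance level.
#' @param ridge forwarded to [partial_correlation()].
#' @return object of class `fc_connectome`: list with the binary
#'   `adjacency`, the observed `pcor` matrix, the per-edge null
#'   `threshold` matrix and the per-edge null `percentile` of the observed
#'   value.
#' @export
permutation_threshold <- function(ts_matrix, n_perm = 1000, alpha = 0.05,
                                  ridge = 0) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  ts_matrix <- as.matrix(ts_matrix)
  obs <- partial_correlation(ts_matrix, ridge = ridge)
  n <- ncol(ts_matrix)
  null_abs <- array(NA_real_, c(n, n, n_perm))
  for (p in seq_len(n_perm)) {
    null_abs[, , p] <- abs(partial_correlation(circular_surrogate(ts_matrix),
                                               ridge = ridge))
  }
  thr <- apply(null_abs, c(1, 2), quantile, probs = 1 - alpha)
  pct <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    pct[i, j] <- mean(null_abs[i, j, ] <= abs(obs[i, j]))
  adj <- (abs(obs) > thr) * 1L
  diag(adj) <- 0L
  dimnames(adj) <- dimnames(thr) <- dimnames(pct) <- dimnames(obs)
  structure(list(adjacency = adj, pcor = obs, threshold = thr,
                 percentile = pct, alpha = alpha, n_perm = n_perm),
            class = "fc_connectome")
}

#' @export
print.fc_connectome <- function(x, ...) {
  n <- ncol(x$adjacency)
  cat(sprintf("<fc_connectome> %d nodes, %d/%d edges at alpha = %g\n",
              n, sum(x$adjacency[upper.tri(x$adjacency)]),
              n * (n - 1) / 2, x$alpha))
  invisible(x)
}

#' Two-step effective-connectivity inference
#'
#' First stage: sparse undirected connectome by permutation-thresholded
#' partial correlation. Second stage: each retained edge is oriented with
#' the pairwise direction classifier; edges absent from the first stage
#' stay absent.
#'
#' @param ts_matrix time x nodes matrix.
#' @param classifier_cfg an [classifier_config()] (`NULL`: default).
#' @param n_perm,alpha,ridge first-stage settings, see
#'   [permutation_threshold()].
#' @return object of class `fc_directed`: list with binary `directed`
#'   adjacency (`[i, j] = 1` means node i -> node j), the first-stage
#'   `connectome` and the per-edge `decisions`.
#' @export
two_step_infer <- function(ts_matrix, classifier_cfg = NULL, n_perm = 1000,
                           alpha = 0.05, ridge = 0) {
  ts_matrix <- as.matrix(ts_matrix)
  conn <- permutation_threshold(ts_matrix, n_perm = n_perm, alpha = alpha,
                                ridge = ridge)
  n <- ncol(ts_matrix)
  directed <- matrix(0L, n, n, dimnames = dimnames(conn$adjacency))
  decisions <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (conn$adjacency[i, j] == 1L) {
        dec <- classify_pair(ts_matrix[, i], ts_matrix[, j], classifier_cfg)
        if (dec$verdict == "x->y") directed[i, j] <- 1L
        else directed[j, i] <- 1L
        decisions[[paste0(i, "-", j)]] <- dec
      }
    }
  }
  structure(list(directed = directed, connectome = conn,
                 decisions = decisions),
            class = "fc_directed")
}
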