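# FastICA core: tanh (log-cosh) contrast, symmetric decorrelation.
#
# Operates on pre-whitened data Y (k x n, rows uncorrelated with unit
# population variance and zero mean).  Deterministic given `seed`.

# E[log cosh(z)] for z ~ N(0,1); reference point of the negentropy proxy.
LOGCOSH_GAUSS <- 0.3745672

sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps)
  e$vectors %*% diag(1 / sqrt(vals), nrow = length(vals)) %*%
    t(e$vectors) %*% W
}

fastica_core <- function(Y, seed, max_iter = 500L, tol = 1e-5) {
  k <- nrow(Y)
  n <- ncol(Y)
  W <- with_seed(seed, matrix(stats::rnorm(k * k), k, k))
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    WY <- W %*% Y
    G <- tanh(WY)
    gprime_mean <- rowMeans(1 - G^2)
    W1 <- (G %*% t(Y)) / n - gprime_mean * W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(1 - abs(rowSums(W1 * W))))
    W <- W1
    if (delta < tol) break
  }
  S <- W %*% Y
  # negentropy proxy summed over components; larger = more non-Gaussian
  contrast <- sum((rowMeans(log(cosh(S))) - LOGCOSH_GAUSS)^2)
  list(W = W, S = S, contrast = contrast, n_iter = it, converged = delta < tol)
}

# Run `n_restarts` FastICA fits from derived seeds, keep the best contrast.
fastica_restarts <- function(Y, seed, n_restarts = 1L, max_iter = 500L,
                             tol = 1e-5) {
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- fastica_core(Y, seed = derive_seed(seed, r), max_iter = max_iter,
                        tol = tol)
    if (is.null(best) || fit$contrast > best$contrast) best <- fit
  }
  best
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic derived seeds, kept within 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483647)
}
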