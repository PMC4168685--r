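# Independent oracles and small fixtures shared across tests.

# O(n^2) direct DFT one-sided periodogram; independent of stats::fft.
oracle_dft_power <- function(x, tr) {
  n <- length(x)
  xc <- x - mean(x)
  half <- n %/% 2
  idx <- 0:(n - 1)
  power <- numeric(half + 1)
  for (k in 0:half) {
    re <- sum(xc * cos(2 * pi * k * idx / n))
    im <- -sum(xc * sin(2 * pi * k * idx / n))
    p <- (re^2 + im^2) / n^2
    power[k + 1] <- if (k == 0 || (n %% 2 == 0 && k == half)) p else 2 * p
  }
  list(freq = (0:half) / (n * tr), power = power)
}

# Exhaustive optimal 1-D 2-partition by within-cluster SSE (k-means oracle).
oracle_two_partition <- function(v) {
  ord <- order(v)
  s <- v[ord]
  n <- length(s)
  best_sse <- Inf
  best_cut <- 1L
  for (cut in 1:(n - 1)) {
    a <- s[1:cut]; b <- s[(cut + 1):n]
    sse <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (sse < best_sse) {
      best_sse <- sse
      best_cut <- cut
    }
  }
  cl <- integer(n)
  cl[ord] <- rep(c(1L, 2L), c(best_cut, n - best_cut))
  cl  # cluster 2 holds the larger values
}

# Small quick phantom used by unit tests (acceptance uses spec defaults).
tiny_phantom_spec <- function(seed, ...) {
  phantom_spec(grid = c(16, 16, 8), n_volumes = 120, seed = seed, ...)
}

# Truth maps as a (sources + artifacts) x n_maskvoxels matrix.
truth_maps_matrix <- function(truth, include_artifacts = TRUE) {
  b <- which(truth$brain$data != 0)
  maps <- lapply(truth$source_maps, function(m) m[b])
  if (include_artifacts) {
    maps <- c(maps, lapply(truth$artifact_maps, function(m) m[b]))
  }
  do.call(rbind, maps)
}

# Per-voxel truth peri-event responses (n_maskvoxels x n_bins).
truth_response_field <- function(truth) {
  b <- which(truth$brain$data != 0)
  out <- matrix(0, length(b), length(truth$bin_times))
  for (i in seq_along(truth$source_maps)) {
    out <- out + truth$amplitudes[i] *
      truth$source_maps[[i]][b] %o% truth$source_responses[[i]]
  }
  out
}

truth_response_curves <- function(truth) {
  do.call(cbind, truth$source_responses)
}

# Amari separation error between recovered and true maps (rows = components).
# The gain matrix is estimated by regressing recovered maps on truth maps so
# that perfect separation gives a scaled permutation even when the truth maps
# are themselves correlated.
amari_error <- function(recovered, truth) {
  Rc <- recovered - rowMeans(recovered)
  Tc <- truth - rowMeans(truth)
  P <- abs(Rc %*% t(Tc) %*% solve(Tc %*% t(Tc)))
  k <- nrow(P)
  rowterm <- sum((rowSums(P / apply(P, 1, max)) - 1) / (k - 1))
  colterm <- sum((colSums(P / rep(apply(P, 2, max), each = k)) - 1) / (k - 1))
  (rowterm + colterm) / (2 * k)
}
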