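#' Model-order rules for PCA reduction
#'
#' Two rules select how many principal components are retained before ICA:
#' a fixed count, or the smallest count whose cumulative variance fraction
#' reaches `f`.  The default rule used by [decompose] is `order_variance(0.995)`.
#'
#' @param k integer number of components.
#' @param f variance fraction in (0, 1].
#' @return An order-rule object consumed by [pca_reduce] and [decompose].
#' @export
order_fixed <- function(k) {
  k <- as.integer(k)
  stopifnot(length(k) == 1L, k >= 1L)
  structure(list(rule = "fixed", value = k), class = "order_rule")
}

#' @rdname order_fixed
#' @export
order_variance <- function(f) {
  stopifnot(length(f) == 1L, f > 0, f <= 1)
  structure(list(rule = "variance", value = f), class = "order_rule")
}

#' PCA reduction and whitening of a masked series
#'
#' Reduces a time-by-voxel matrix to `k` whitened spatial principal
#' components.  Rows of the returned `whitened` matrix (k x n_voxels) are
#' mutually uncorrelated with zero mean and unit population variance.
#'
#' @param x numeric matrix, n_volumes x n_maskvoxels, rows already demeaned
#'   in time and space (see [decompose]).
#' @param order_rule an [order_fixed] / [order_variance] rule.
#' @return list with `whitened` (k x v), `mixing_basis` (n_volumes x k, maps
#'   whitened rows back to the time domain), `order`, `variance_fraction`,
#'   `singular_values`.
#' @export
pca_reduce <- function(x, order_rule = order_variance(0.995)) {
  stopifnot(inherits(order_rule, "order_rule"))
  nt <- nrow(x)
  nv <- ncol(x)
  if (nt < 4L) stop("need at least 4 volumes for PCA reduction", call. = FALSE)
  sv <- svd(x)
  tol <- max(dim(x)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  ev <- sv$d^2
  cum <- cumsum(ev) / sum(ev)
  k <- if (order_rule$rule == "fixed") {
    if (order_rule$value > nt - 1L) {
      stop(sprintf("requested order %d exceeds n_volumes - 1 = %d",
                   order_rule$value, nt - 1L), call. = FALSE)
    }
    if (order_rule$value > rank) {
      stop(sprintf("requested order %d exceeds achievable rank %d",
                   order_rule$value, rank), call. = FALSE)
    }
    order_rule$value
  } else {
    min(which(cum >= order_rule$value - 1e-12), rank)
  }
  # whitened spatial series: rows have unit population variance over voxels
  whitened <- sqrt(nv) * t(sv$v[, seq_len(k), drop = FALSE])
  mixing_basis <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)] / sqrt(nv), nrow = k)
  list(whitened = whitened, mixing_basis = mixing_basis, order = k,
       variance_fraction = cum[k], singular_values = sv$d)
}

#' Spatial ICA decomposition of a 4D series
#'
#' Decomposes the masked series into spatially independent component maps
#' with associated time courses and power spectra, after voxelwise temporal
#' demeaning, removal of the global (spatial-mean) time course, and PCA
#' whitening.  The ICA engine is FastICA with tanh contrast and symmetric
#' decorrelation (up to 500 iterations, tolerance 1e-5); `n_restarts` runs
#' from derived seeds are fitted and the run with the best final contrast is
#' kept.  Components are ordered by descending explained variance and each
#' component's sign is fixed so its spatial map has non-negative skewness.
#' The result is a deterministic function of the data and `seed`.
#'
#' @param vol a [volume4d].
#' @param mask a brain [mask3d] matching `vol` spatially.
#' @param order_rule model-order rule; default `order_variance(0.995)`.
#' @param seed integer seed.
#' @param n_restarts number of FastICA restarts (best contrast kept).
#' @return An object of class `ica_decomposition` with fields
#'   `spatial_maps` (k x n_maskvoxels, zero mean / unit variance per row over
#'   mask voxels), `time_courses` (n_volumes x k), `mean_map`, `global_tc`,
#'   `n_components`, `mask`, `seed`, `variance_fraction`, `power_spectra`
#'   (list with `freq` and k-column `power` matrix), `tr`.
#' @export
decompose <- function(vol, mask, order_rule = order_variance(0.995),
                      seed = 1L, n_restarts = 1L) {
  stopifnot(inherits(vol, "volume4d"), inherits(mask, "mask3d"))
  X <- masked_series(vol, mask)            # t x v
  nt <- nrow(X); nv <- ncol(X)
  mean_map <- colMeans(X)
  Xc <- sweep(X, 2L, mean_map)
  if (max(abs(Xc)) < 1e-12) {
    stop("degenerate input: series is constant in time", call. = FALSE)
  }
  global_tc <- rowMeans(Xc)
  Xcc <- Xc - global_tc                    # rows now have zero spatial mean
  red <- pca_reduce(Xcc, order_rule)
  k <- red$order
  fit <- fastica_restarts(red$whitened, seed = seed, n_restarts = n_restarts)
  S <- fit$S                               # k x v, rows unit pop. variance
  A <- red$mixing_basis %*% t(fit$W)       # t x k  (Xcc ~= A %*% S)

  # exact z-scaling with population moments (rows already ~N(0,1)-scaled)
  mu <- rowMeans(S)
  sdev <- sqrt(rowMeans((S - mu)^2))
  # rows of S have zero spatial mean by construction (V'1 = 0 after global
  # removal) so mu is ~0; fold any numerical residue into the global time
  # course to keep the reconstruction identity tight
  global_tc <- global_tc + as.vector(A %*% mu)
  S <- (S - mu) / sdev
  A <- sweep(A, 2L, sdev, `*`)

  expl <- colMeans(A^2)
  ord <- order(expl, decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  A <- A[, ord, drop = FALSE]
  sk <- apply(S, 1L, function(r) mean(r^3))
  flip <- ifelse(sk < 0, -1, 1)
  S <- S * flip
  A <- sweep(A, 2L, flip, `*`)

  freq <- periodogram_freq(nt, vol$tr)
  power <- vapply(seq_len(k), function(j) power_spectrum(A[, j], vol$tr)$power,
                  numeric(length(freq)))

  structure(
    list(spatial_maps = S, time_courses = A, mean_map = mean_map,
         global_tc = global_tc, n_components = k, mask = mask,
         seed = as.integer(seed), variance_fraction = red$variance_fraction,
         power_spectra = list(freq = freq, power = power), tr = vol$tr),
    class = "ica_decomposition"
  )
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf(
    "<ica_decomposition> %d components, %d volumes, %d mask voxels (%.1f%% variance retained)\n",
    x$n_components, nrow(x$time_courses), ncol(x$spatial_maps),
    100 * x$variance_fraction))
  invisible(x)
}

#' Reconstruct the masked series from a decomposition
#'
#' Returns `mean_map + global_tc %o% 1 + time_courses %*% spatial_maps`; the
#' residual variance fraction relative to the masked input is bounded by
#' `1 - variance_fraction` up to numerical noise.
#'
#' @param ica an `ica_decomposition`.
#' @return n_volumes x n_maskvoxels matrix.
#' @export
reconstruct <- function(ica) {
  stopifnot(inherits(ica, "ica_decomposition"))
  sweep(ica$time_courses %*% ica$spatial_maps + ica$global_tc, 2L,
        ica$mean_map, `+`)
}

periodogram_freq <- function(n, tr) {
  (0:(n %/% 2)) / (n * tr)
}

#' One-sided periodogram of a time course
#'
#' Frequency grid runs from 0 to the Nyquist frequency 1/(2 tr).  The
#' spectrum satisfies Parseval's identity: its sum equals the population
#' variance of the time course (mean removed) to within 1e-6 relative.
#'
#' @param tc numeric time course, length >= 4.
#' @param tr repetition time (s), > 0.
#' @return list with `freq` (Hz) and `power` (signal-units squared per bin).
#' @export
power_spectrum <- function(tc, tr) {
  if (tr <= 0) stop("tr must be positive", call. = FALSE)
  n <- length(tc)
  if (n < 4L) stop("time course too short for a periodogram", call. = FALSE)
  xc <- tc - mean(tc)
  f <- stats::fft(xc)
  p_full <- Mod(f)^2 / n^2
  half <- n %/% 2
  power <- p_full[1:(half + 1)]
  # fold negative frequencies; DC and (even-n) Nyquist bins are unique
  if (n %% 2 == 0) {
    if (half > 1) power[2:half] <- 2 * power[2:half]
  } else {
    power[2:(half + 1)] <- 2 * power[2:(half + 1)]
  }
  list(freq = periodogram_freq(n, tr), power = power)
}

#' Serialize a decomposition to a directory
#'
#' Writes `maps.nii` (components along the 4th axis, mask-filled with 0),
#' `mean_map.nii`, `mask.nii`, tab-separated `time_courses.tsv` and
#' `power_spectra.tsv` with header rows, and a small `info.tsv`.
#'
#' @param ica an `ica_decomposition`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_decomposition <- function(ica, dir) {
  stopifnot(inherits(ica, "ica_decomposition"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d3 <- dim(ica$mask$data)
  maps4d <- array(0, dim = c(d3, ica$n_components))
  for (j in seq_len(ica$n_components)) {
    maps4d[, , , j] <- unmask_map(ica$spatial_maps[j, ], ica$mask)
  }
  nifti_write(file.path(dir, "maps.nii"), maps4d)
  nifti_write(file.path(dir, "mean_map.nii"), unmask_map(ica$mean_map, ica$mask))
  write_mask(ica$mask, file.path(dir, "mask.nii"))
  tc <- as.data.frame(ica$time_courses)
  names(tc) <- sprintf("IC%d", seq_len(ica$n_components))
  utils::write.table(cbind(global = ica$global_tc, tc),
                     file.path(dir, "time_courses.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  sp <- as.data.frame(ica$power_spectra$power)
  names(sp) <- sprintf("IC%d", seq_len(ica$n_components))
  utils::write.table(cbind(freq_hz = ica$power_spectra$freq, sp),
                     file.path(dir, "power_spectra.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(key = c("n_components", "tr", "seed", "variance_fraction"),
               value = c(ica$n_components, ica$tr, ica$seed,
                         ica$variance_fraction)),
    file.path(dir, "info.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
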