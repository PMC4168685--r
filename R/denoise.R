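#' Aggressive regression filtering of artifact components
#'
#' Removes, per voxel, all signal variance explainable by the artifact
#' component time courses alone: the demeaned voxel signal is regressed (OLS)
#' on the demeaned artifact time courses and replaced by the residual plus
#' the voxel's temporal mean.  This reproduces "aggressive" component
#' filtering semantics.  The operation is an orthogonal projection: it is
#' idempotent, never increases per-voxel temporal variance, preserves voxel
#' means exactly, and leaves residuals orthogonal to every artifact time
#' course.
#'
#' @param vol a [volume4d].
#' @param time_courses n_volumes x n_components matrix (from [decompose]).
#' @param artifact_idx integer indices of components to remove (may be empty,
#'   in which case the input is returned unchanged).
#' @param mode only `"aggressive"` is supported.
#' @param mask optional [mask3d]; voxels outside are passed through
#'   untouched.  Default filters every voxel.
#' @return An object of class `denoised_series`: `volume` ([volume4d]),
#'   `removed_indices`, `variance_removed_fraction`.
#' @export
regression_filter <- function(vol, time_courses, artifact_idx,
                              mode = "aggressive", mask = NULL) {
  mode <- match.arg(mode, "aggressive")
  stopifnot(inherits(vol, "volume4d"))
  time_courses <- as.matrix(time_courses)
  nt <- vol$n_volumes
  if (nrow(time_courses) != nt) {
    stop("time_courses rows must equal n_volumes", call. = FALSE)
  }
  artifact_idx <- as.integer(artifact_idx)
  if (length(artifact_idx) &&
      (min(artifact_idx) < 1L || max(artifact_idx) > ncol(time_courses))) {
    stop("artifact_idx out of range", call. = FALSE)
  }
  d <- dim(vol$data)
  if (is.null(mask)) {
    mask <- mask3d(array(1L, dim = d[1:3]), "brain")
  }
  if (length(artifact_idx) == 0L) {
    return(structure(list(volume = vol, removed_indices = integer(0),
                          variance_removed_fraction = 0),
                     class = "denoised_series"))
  }
  A <- time_courses[, artifact_idx, drop = FALSE]
  A <- sweep(A, 2L, colMeans(A))
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    cc <- stats::cor(A)
    bad <- which(abs(cc) > 1 - 1e-10 & upper.tri(cc), arr.ind = TRUE)
    pairs <- apply(bad, 1L, function(r) {
      paste(artifact_idx[r[1]], artifact_idx[r[2]], sep = "~")
    })
    stop("artifact time courses are rank deficient; collinear pairs: ",
         paste(pairs, collapse = ", "), call. = FALSE)
  }
  X <- masked_series(vol, mask)          # t x v
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  resid <- Xc - A %*% qr.coef(qrA, Xc)
  out_mat <- sweep(resid, 2L, mu, `+`)
  var_in <- sum(Xc^2)
  vrf <- if (var_in > 0) max(0, min(1, 1 - sum(resid^2) / var_in)) else 0

  data_out <- vol$data
  grid <- matrix(data_out, nrow = prod(d[1:3]), ncol = nt)
  grid[which(mask$data != 0), ] <- t(out_mat)
  vol_out <- volume4d(array(grid, dim = d), tr = vol$tr,
                      voxel_size = vol$voxel_size, affine = vol$affine)
  structure(list(volume = vol_out, removed_indices = artifact_idx,
                 variance_removed_fraction = vrf),
            class = "denoised_series")
}

#' @export
print.denoised_series <- function(x, ...) {
  cat(sprintf(
    "<denoised_series> removed %d components (%.1f%% of demeaned variance)\n",
    length(x$removed_indices), 100 * x$variance_removed_fraction))
  invisible(x)
}
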