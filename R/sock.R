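# SOCK-style component features and artifact classification.
#
# Four feature families are computed per independent component:
#   - smoothness: ratio of high to low spatial-frequency power per axial
#     slice, plus the fraction of suprathreshold voxels in very small
#     26-connected clusters ("spotty" appearance);
#   - edge activity: fraction of suprathreshold voxels in an edge mask;
#   - ventricular activity: fraction in a CSF mask;
#   - temporal frequency noise (TFN): time-course power beyond 0.08 Hz.

# ---- 3D morphology helpers -------------------------------------------------

shift3d <- function(a, dx, dy, dz, fill = 0) {
  d <- dim(a)
  out <- array(fill, dim = d)
  xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
  sx <- xs - dx; sy <- ys - dy; sz <- zs - dz
  keep_x <- sx >= 1 & sx <= d[1]
  keep_y <- sy >= 1 & sy <= d[2]
  keep_z <- sz >= 1 & sz <= d[3]
  out[xs[keep_x], ys[keep_y], zs[keep_z]] <-
    a[sx[keep_x], sy[keep_y], sz[keep_z]]
  out
}

erode6 <- function(bin) {
  out <- bin
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
    out <- out & shift3d(bin, s[1], s[2], s[3], fill = 0)
  }
  array(as.integer(out), dim = dim(bin))
}

neighbor_offsets_26 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
}

# Label 26-connected components of a binary 3D array by iterative minimum
# propagation; returns an integer array (0 outside, labels not compacted).
label_components_26 <- function(bin) {
  d <- dim(bin)
  inside <- bin != 0
  lab <- array(0, dim = d)
  lab[inside] <- which(inside)
  offs <- neighbor_offsets_26()
  repeat {
    new_lab <- lab
    for (i in seq_len(nrow(offs))) {
      sh <- shift3d(lab, offs$dx[i], offs$dy[i], offs$dz[i], fill = 0)
      take <- inside & sh > 0 & (new_lab == 0 | sh < new_lab)
      new_lab[take] <- sh[take]
    }
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  lab
}

# ---- operations ------------------------------------------------------------

#' Build an edge mask from a brain mask
#'
#' The edge is the brain mask minus the brain eroded `width_voxels` times
#' with a 6-connected structuring element; it is a subset of the brain mask.
#'
#' @param brain a brain [mask3d].
#' @param width_voxels erosion depth (voxels), >= 1.
#' @return A [mask3d] of kind `"edge"`.
#' @export
make_edge_mask <- function(brain, width_voxels = 1L) {
  stopifnot(inherits(brain, "mask3d"), width_voxels >= 1L)
  core <- brain$data
  for (i in seq_len(width_voxels)) core <- erode6(core)
  if (sum(core) == 0L) {
    stop("erosion emptied the mask; use a smaller width_voxels",
         call. = FALSE)
  }
  mask3d(brain$data * (1L - core), kind = "edge")
}

#' Threshold a z-scaled spatial map
#'
#' A voxel is suprathreshold iff `|z| >= z_thr`.
#'
#' @param map numeric vector of z-scaled map values over mask voxels, or a 3D
#'   array.
#' @param z_thr threshold.
#' @return logical vector/array of the same shape, plus attribute `empty`
#'   (TRUE when no voxel survives).
#' @export
threshold_map <- function(map, z_thr = 2.3) {
  supra <- abs(map) >= z_thr
  attr(supra, "empty") <- !any(supra)
  supra
}

#' Spatial smoothness and small-cluster features
#'
#' `smoothness` is the ratio of 2D spatial-spectral power above
#' `radial_cutoff` of the spatial Nyquist frequency to the power at or below
#' it, averaged over axial slices with at least 32 in-mask voxels (NA when no
#' slice qualifies).  `small_cluster_fraction` is the fraction of
#' suprathreshold voxels lying in 26-connected clusters of size < `s_min`.
#'
#' @param map3d 3D map (z-scaled values, 0 outside mask).
#' @param mask brain [mask3d].
#' @param z_thr suprathreshold level.
#' @param s_min minimum cluster size (voxels).
#' @param radial_cutoff fraction of the spatial Nyquist splitting low/high.
#' @return list with `smoothness`, `small_cluster_fraction`, `n_suprathreshold`.
#' @export
smoothness_features <- function(map3d, mask, z_thr = 2.3, s_min = 5L,
                                radial_cutoff = 0.25) {
  d <- dim(map3d)
  stopifnot(identical(as.integer(d), as.integer(dim(mask$data))))
  ratios <- c()
  for (z in seq_len(d[3])) {
    in_mask <- mask$data[, , z] != 0
    if (sum(in_mask) < 32L) next
    sl <- map3d[, , z]
    sl[!in_mask] <- 0
    p <- Mod(stats::fft(sl))^2
    fx <- seq_len(d[1]) - 1L; fx <- ifelse(fx > d[1] / 2, fx - d[1], fx) / d[1]
    fy <- seq_len(d[2]) - 1L; fy <- ifelse(fy > d[2] / 2, fy - d[2], fy) / d[2]
    radial <- sqrt(outer(fx^2, fy^2, `+`))
    high <- radial > radial_cutoff * 0.5
    lo <- sum(p[!high]); hi <- sum(p[high])
    if (lo > 0) ratios <- c(ratios, hi / lo)
  }
  smoothness <- if (length(ratios)) mean(ratios) else NA_real_

  supra <- array(abs(map3d) >= z_thr & mask$data != 0, dim = d)
  n_supra <- sum(supra)
  scf <- if (n_supra == 0L) {
    0
  } else {
    lab <- label_components_26(array(as.integer(supra), dim = d))
    sizes <- table(lab[lab > 0])
    small <- as.numeric(names(sizes))[sizes < s_min]
    sum(lab %in% small) / n_supra
  }
  list(smoothness = smoothness, small_cluster_fraction = scf,
       n_suprathreshold = n_supra)
}

#' Fraction of suprathreshold voxels inside a region
#'
#' @param supra logical 3D array (or vector) of suprathreshold voxels.
#' @param region a [mask3d] on the same grid.
#' @return `|supra intersect region| / |supra|`; 0 when `supra` is empty.
#' @export
region_fraction <- function(supra, region) {
  n <- sum(supra)
  if (n == 0) return(0)
  sum(supra & region$data != 0) / n
}

#' Temporal-frequency-noise fraction of a time course
#'
#' Fraction of periodogram power at frequencies strictly above `cutoff`
#' (the 0 Hz bin is excluded from both numerator and denominator).
#'
#' @param tc numeric time course.
#' @param tr repetition time (s).
#' @param cutoff frequency cutoff (Hz), must be below Nyquist.
#' @return fraction in [0, 1].
#' @export
tfn_fraction <- function(tc, tr, cutoff = 0.08) {
  nyquist <- 1 / (2 * tr)
  if (cutoff >= nyquist) {
    stop(sprintf("tfn cutoff %g Hz is at or above Nyquist %g Hz",
                 cutoff, nyquist), call. = FALSE)
  }
  ps <- power_spectrum(tc, tr)
  keep <- seq_along(ps$freq)[-1]
  total <- sum(ps$power[keep])
  if (total <= 0) return(0)
  sum(ps$power[keep][ps$freq[keep] > cutoff]) / total
}

#' Compute component features for a decomposition
#'
#' @param ica an `ica_decomposition`.
#' @param edge edge [mask3d] (built with [make_edge_mask] if NULL).
#' @param csf CSF [mask3d] (may be NULL; csf_fraction is then NA).
#' @param z_thr suprathreshold level on z-scaled maps.
#' @param s_min small-cluster size (voxels).
#' @param radial_cutoff spatial-frequency split (fraction of Nyquist).
#' @param tfn_cutoff temporal cutoff (Hz), default 0.08.
#' @return data.frame with one row per component: `smoothness`,
#'   `small_cluster_fraction`, `edge_fraction`, `csf_fraction`,
#'   `tfn_fraction`, `empty`.
#' @export
sock_features <- function(ica, edge = NULL, csf = NULL, z_thr = 2.3,
                          s_min = 5L, radial_cutoff = 0.25,
                          tfn_cutoff = 0.08) {
  stopifnot(inherits(ica, "ica_decomposition"))
  mask <- ica$mask
  if (is.null(edge)) edge <- make_edge_mask(mask, 1L)
  k <- ica$n_components
  out <- data.frame(component = seq_len(k), smoothness = NA_real_,
                    small_cluster_fraction = NA_real_,
                    edge_fraction = NA_real_, csf_fraction = NA_real_,
                    tfn_fraction = NA_real_, empty = FALSE)
  for (j in seq_len(k)) {
    m3 <- unmask_map(ica$spatial_maps[j, ], mask)
    sm <- smoothness_features(m3, mask, z_thr = z_thr, s_min = s_min,
                              radial_cutoff = radial_cutoff)
    supra <- array(abs(m3) >= z_thr & mask$data != 0, dim = dim(m3))
    out$smoothness[j] <- sm$smoothness
    out$small_cluster_fraction[j] <- sm$small_cluster_fraction
    out$edge_fraction[j] <- region_fraction(supra, edge)
    out$csf_fraction[j] <- if (is.null(csf)) NA_real_ else
      region_fraction(supra, csf)
    out$tfn_fraction[j] <- tfn_fraction(ica$time_courses[, j], ica$tr,
                                        cutoff = tfn_cutoff)
    out$empty[j] <- sm$n_suprathreshold == 0L
  }
  out
}

#' Default absolute floors for artifact classification
#'
#' A k-means cluster can only be called artifact-prone when its mean feature
#' value also exceeds the family's absolute floor; this prevents the
#' clustering from manufacturing an artifact class in homogeneous data.
#'
#' @return named numeric vector of floors.
#' @export
sock_floors <- function() {
  c(edge = 0.4, csf = 0.35, tfn = 0.5, small_cluster = 0.5, smoothness = 1.0)
}

# Flag components via seed-fixed 2-means on robust-z-scored values; the
# higher-mean cluster is artifact-prone only if its raw mean exceeds `floor`.
flag_family <- function(values, floor, seed) {
  flags <- rep(FALSE, length(values))
  ok <- is.finite(values)
  v <- values[ok]
  if (length(v) < 3L) {             # fall back to absolute thresholds only
    flags[ok] <- v >= floor
    return(flags)
  }
  if (length(unique(v)) < 2L) return(flags)
  scale <- stats::mad(v)
  if (scale == 0) scale <- stats::sd(v)
  if (scale == 0) return(flags)
  z <- (v - stats::median(v)) / scale
  km <- with_seed(seed, stats::kmeans(z, centers = 2L, nstart = 10L,
                                      iter.max = 100L))
  hi <- which.max(km$centers)
  if (mean(v[km$cluster == hi]) > floor) {
    flags[ok] <- km$cluster == hi
  }
  flags
}

#' Classify components as artifact vs unlikely artifact
#'
#' Per feature family (smoothness + small-cluster, edge, csf, tfn) the family
#' scalar is robust-z-scored across components and split by seed-fixed
#' 2-means (10 restarts); the higher-mean cluster is artifact-prone only if
#' its mean exceeds that family's absolute floor.  A component is labeled
#' artifact iff it is artifact-prone in at least one family; `reasons`
#' records the triggering families.  With fewer than 3 components carrying
#' defined features the classifier falls back to the absolute floors alone.
#'
#' @param features data.frame from [sock_features].
#' @param floors named floors, see [sock_floors].
#' @param seed integer seed for the k-means restarts.
#' @return An object of class `sock_classification`: data.frame `table` with
#'   `component`, `label`, `reasons`; `rejected` (artifact indices);
#'   `rejected_fraction`.
#' @export
sock_classify <- function(features, floors = sock_floors(), seed = 1L) {
  k <- nrow(features)
  fam <- list(
    smoothness = flag_family(features$smoothness, floors[["smoothness"]],
                             derive_seed(seed, 11L)) |
      flag_family(features$small_cluster_fraction, floors[["small_cluster"]],
                  derive_seed(seed, 12L)),
    edge = flag_family(features$edge_fraction, floors[["edge"]],
                       derive_seed(seed, 13L)),
    csf = flag_family(features$csf_fraction, floors[["csf"]],
                      derive_seed(seed, 14L)),
    tfn = flag_family(features$tfn_fraction, floors[["tfn"]],
                      derive_seed(seed, 15L))
  )
  reasons <- vapply(seq_len(k), function(j) {
    paste(names(fam)[vapply(fam, `[`, logical(1), j)], collapse = ",")
  }, character(1))
  label <- ifelse(nzchar(reasons), "artifact", "unlikely_artifact")
  structure(
    list(table = data.frame(component = features$component, label = label,
                            reasons = reasons),
         rejected = features$component[label == "artifact"],
         rejected_fraction = mean(label == "artifact")),
    class = "sock_classification"
  )
}

#' @export
print.sock_classification <- function(x, ...) {
  cat(sprintf("<sock_classification> %d/%d components rejected (%.0f%%)\n",
              length(x$rejected), nrow(x$table), 100 * x$rejected_fraction))
  invisible(x)
}

#' Write a classification report
#'
#' Emits a tab-separated feature/label table and a plain-text list of
#' rejected component indices (one per line) consumable by
#' [regression_filter]'s CLI route.
#'
#' @param cls a `sock_classification`.
#' @param features the matching [sock_features] table.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_classification <- function(cls, features, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- cbind(features, label = cls$table$label, reasons = cls$table$reasons)
  utils::write.table(tab, file.path(dir, "classification.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeLines(as.character(cls$rejected), file.path(dir, "rejected.txt"))
  invisible(dir)
}
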