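#' Construct a 4D fMRI volume container
#'
#' `volume4d` is the core signal container used throughout the package: a 4D
#' real-valued grid (x, y, z, t) together with voxel sizes in millimetres, the
#' repetition time (TR, seconds) and a 4x4 voxel-to-world affine.  Voxel
#' coordinates are 0-based and all event times are seconds relative to the
#' acquisition start of the first volume.
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param tr repetition time in seconds, > 0.
#' @param voxel_size numeric length-3 vector of voxel edge lengths (mm), all > 0.
#' @param affine 4x4 voxel-to-world matrix; defaults to a scaled identity.
#' @return An object of class `volume4d` with fields `data`, `tr`,
#'   `voxel_size`, `affine`, `n_volumes`.
#' @export
volume4d <- function(data, tr, voxel_size = c(1, 1, 1), affine = NULL) {
  if (length(dim(data)) != 4L) {
    stop("not a 4D series: data must have 4 dimensions", call. = FALSE)
  }
  if (dim(data)[4] < 2L) {
    stop("a 4D series needs at least 2 volumes", call. = FALSE)
  }
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0) {
    stop("tr must be a single positive number (seconds)", call. = FALSE)
  }
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop("voxel_size must be 3 positive lengths (mm)", call. = FALSE)
  }
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  structure(
    list(data = data, tr = as.double(tr), voxel_size = as.double(voxel_size),
         affine = affine, n_volumes = dim(data)[4]),
    class = "volume4d"
  )
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume4d> %d x %d x %d voxels, %d volumes, TR = %g s\n",
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

#' Construct a 3D binary mask
#'
#' @param data 3D array; nonzero voxels are inside the mask.
#' @param kind one of `"brain"`, `"edge"`, `"csf"`.
#' @return An object of class `mask3d` with logical-like 0/1 `data` and `kind`.
#' @export
mask3d <- function(data, kind = c("brain", "edge", "csf")) {
  kind <- match.arg(kind)
  if (length(dim(data)) != 3L) {
    stop("mask must be a 3D grid", call. = FALSE)
  }
  bin <- array(as.integer(data != 0), dim = dim(data))
  if (kind == "brain" && sum(bin) == 0L) {
    stop("all-zero brain mask", call. = FALSE)
  }
  structure(list(data = bin, kind = kind), class = "mask3d")
}

#' @export
print.mask3d <- function(x, ...) {
  cat(sprintf("<mask3d kind=%s> %s, %d voxels set\n", x$kind,
              paste(dim(x$data), collapse = " x "), sum(x$data)))
  invisible(x)
}

#' Construct an event train
#'
#' Event onsets in seconds relative to the start of the series; optional
#' per-event durations (default 0, i.e. impulse events).
#'
#' @param onsets numeric vector of onset times (s), non-negative.
#' @param durations optional numeric vector of durations (s), >= 0.
#' @return An object of class `event_train`.
#' @export
event_train <- function(onsets, durations = NULL) {
  onsets <- as.double(onsets)
  if (any(!is.finite(onsets)) || any(onsets < 0)) {
    stop("event onsets must be finite and non-negative", call. = FALSE)
  }
  ord <- order(onsets)
  onsets <- onsets[ord]
  if (is.null(durations)) {
    durations <- rep(0, length(onsets))
  } else {
    if (length(durations) != length(onsets) || any(durations < 0)) {
      stop("durations must match onsets and be non-negative", call. = FALSE)
    }
    durations <- as.double(durations)[ord]
  }
  structure(list(onsets = onsets, durations = durations),
            class = "event_train")
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("<event_train> %d events, span [%g, %g] s\n",
              length(x$onsets),
              if (length(x$onsets)) min(x$onsets) else NA,
              if (length(x$onsets)) max(x$onsets) else NA))
  invisible(x)
}

#' Read a 4D NIfTI-1 series
#'
#' The repetition time is taken from the header (`pixdim[4]`) unless `tr` is
#' supplied, which always wins.  NIfTI scaling slope/intercept are applied so
#' returned values are physical.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param tr optional repetition time override (seconds).
#' @return A [volume4d].
#' @export
read_volume4d <- function(path, tr = NULL) {
  nii <- nifti_read(path)
  if (length(nii$dim) != 4L) {
    stop("not a 4D series: ", path, " has ", length(nii$dim),
         " dimensions", call. = FALSE)
  }
  header_tr <- nii$pixdim[5]
  if (is.null(tr)) {
    if (!is.finite(header_tr) || header_tr <= 0) {
      stop("non-positive tr in header and no override supplied for ", path,
           call. = FALSE)
    }
    tr <- header_tr
  }
  volume4d(nii$data, tr = tr, voxel_size = abs(nii$pixdim[2:4]),
           affine = nii$affine)
}

#' Write a 4D series as NIfTI-1
#'
#' @param vol a [volume4d].
#' @param path output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume4d <- function(vol, path) {
  stopifnot(inherits(vol, "volume4d"))
  if (!dir.exists(dirname(path))) {
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  }
  nifti_write(path, vol$data, pixdim_spatial = vol$voxel_size, tr = vol$tr,
              affine = vol$affine)
  invisible(path)
}

#' Read a 3D mask from NIfTI-1
#'
#' Nonzero voxels are inside; the grid is binarized.  If `reference` is given
#' its spatial extents must match.
#'
#' @param path path to a 3D NIfTI file.
#' @param kind mask kind, one of `"brain"`, `"edge"`, `"csf"`.
#' @param reference optional [volume4d] or [mask3d] whose spatial grid the
#'   mask must match.
#' @return A [mask3d].
#' @export
read_mask <- function(path, kind = c("brain", "edge", "csf"),
                      reference = NULL) {
  kind <- match.arg(kind)
  nii <- nifti_read(path)
  d <- nii$dim
  if (length(d) == 4L && d[4] == 1L) {
    nii$data <- array(nii$data, dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L) {
    stop("mask must be a 3D image: ", path, call. = FALSE)
  }
  if (!is.null(reference)) {
    ref_dim <- if (inherits(reference, "volume4d")) {
      dim(reference$data)[1:3]
    } else {
      dim(reference$data)
    }
    if (!identical(as.integer(d), as.integer(ref_dim))) {
      stop("mask grid ", paste(d, collapse = "x"),
           " does not match reference grid ",
           paste(ref_dim, collapse = "x"), call. = FALSE)
    }
  }
  mask3d(nii$data, kind = kind)
}

#' Write a 3D mask as NIfTI-1
#'
#' @param mask a [mask3d].
#' @param path output path.
#' @param voxel_size voxel edge lengths (mm).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, voxel_size = c(1, 1, 1)) {
  stopifnot(inherits(mask, "mask3d"))
  nifti_write(path, mask$data, pixdim_spatial = voxel_size)
  invisible(path)
}

#' Read event timings
#'
#' Two dialects: `"plain"` is one onset (seconds) per line; `"fsl3col"` is the
#' three-column onset / duration / weight layout.  Onsets are returned sorted
#' ascending; durations are 0 for the plain dialect.
#'
#' @param path text file of event timings.
#' @param dialect `"plain"` or `"fsl3col"`.
#' @return An [event_train].
#' @export
read_events <- function(path, dialect = c("plain", "fsl3col")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no events in ", path, call. = FALSE)
  onsets <- numeric(length(lines))
  durations <- numeric(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(trimws(lines[i]), "[ \t,]+")[[1]]
    want <- if (dialect == "plain") 1L else 3L
    vals <- suppressWarnings(as.numeric(fields))
    if (length(fields) < want || any(is.na(vals[seq_len(want)]))) {
      stop(sprintf("unparseable event line %d in %s: '%s'", i, path, lines[i]),
           call. = FALSE)
    }
    if (vals[1] < 0) {
      stop(sprintf("negative onset at line %d in %s", i, path), call. = FALSE)
    }
    onsets[i] <- vals[1]
    durations[i] <- if (dialect == "fsl3col") vals[2] else 0
  }
  event_train(onsets, durations)
}

#' Write event timings
#'
#' Inverse of [read_events]; `read_events` is idempotent over this
#' serialization.
#'
#' @param events an [event_train].
#' @param path output text file.
#' @param dialect `"plain"` or `"fsl3col"` (weight column written as 1).
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, dialect = c("plain", "fsl3col")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(events, "event_train"))
  lines <- if (dialect == "plain") {
    format(events$onsets, trim = TRUE, digits = 15)
  } else {
    paste(format(events$onsets, trim = TRUE, digits = 15),
          format(events$durations, trim = TRUE, digits = 15), "1")
  }
  writeLines(lines, path)
  invisible(path)
}

# Validate that an event train fits inside a series.
check_events_in_series <- function(events, n_volumes, tr) {
  t_end <- n_volumes * tr
  if (length(events$onsets) && max(events$onsets) >= t_end) {
    stop(sprintf("event train extends past series end (%g s >= %g s)",
                 max(events$onsets), t_end), call. = FALSE)
  }
  invisible(TRUE)
}

# Extract the masked time-by-voxel matrix from a volume.
masked_series <- function(vol, mask) {
  d <- dim(vol$data)
  if (!identical(as.integer(d[1:3]), as.integer(dim(mask$data)))) {
    stop("mask grid does not match volume grid", call. = FALSE)
  }
  idx <- which(mask$data != 0)
  nt <- d[4]
  m <- matrix(vol$data, nrow = prod(d[1:3]), ncol = nt)
  t(m[idx, , drop = FALSE])
}

# Scatter a time-by-voxel matrix back into a 4D array on the mask.
unmask_series <- function(mat, mask, fill = 0) {
  d3 <- dim(mask$data)
  idx <- which(mask$data != 0)
  nt <- nrow(mat)
  out <- matrix(fill, nrow = prod(d3), ncol = nt)
  out[idx, ] <- t(mat)
  array(out, dim = c(d3, nt))
}

# Scatter a per-mask-voxel vector into a 3D array.
unmask_map <- function(values, mask, fill = 0) {
  out <- array(fill, dim = dim(mask$data))
  out[which(mask$data != 0)] <- values
  out
}
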