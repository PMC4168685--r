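# Synthetic 4D fMRI phantom with ground truth.
#
# The phantom emulates, at BOLD-realistic scale (baseline 1000, percent-level
# signal), the structured-noise taxonomy the pipeline must survive:
# event-locked sources with non-canonical shapes (early onset, dominant
# undershoot), an edge/motion ring, CSF-confined pulsation, near-Nyquist
# machine noise, spatially "spotty" noise, slow drift, and white measurement
# noise.  Generation is a pure function of the spec (seed included).

#' Phantom specification
#'
#' @param grid c(nx, ny, nz) voxel grid, each >= 8.
#' @param tr repetition time (s).
#' @param n_volumes number of volumes (>= 50).
#' @param voxel_size voxel edge lengths (mm).
#' @param events an [event_train], or NULL to draw a renewal train with
#'   minimum gap `event_min_gap` plus an exponential extra gap of mean
#'   `event_mean_extra_gap`.
#' @param event_min_gap minimum inter-event gap (s).
#' @param event_mean_extra_gap mean of the exponential extra gap (s).
#' @param neural_sources list of sources; each a list with `center`
#'   (relative grid coordinates in (0,1)^3), `sigma_mm` (Gaussian blob
#'   width), `kind` (see [make_response_shape]) and `amplitude_pct`
#'   (peak signal change, percent of baseline).
#' @param artifact_sources subset of `"edge_ring"`, `"csf_pulsation"`,
#'   `"high_freq_machine"`, `"spotty"`, `"drift"`.
#' @param artifact_amplitude_pct named amplitudes (percent of baseline).
#' @param noise_sd white measurement noise SD (signal units; baseline 1000).
#' @param seed integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(32, 32, 16), tr = 3, n_volumes = 400,
                         voxel_size = c(3, 3, 3), events = NULL,
                         event_min_gap = 12, event_mean_extra_gap = 9,
                         neural_sources = default_neural_sources(),
                         artifact_sources = c("edge_ring", "csf_pulsation",
                                              "high_freq_machine", "spotty"),
                         artifact_amplitude_pct = c(edge_ring = 2,
                                                    csf_pulsation = 2,
                                                    high_freq_machine = 1.5,
                                                    spotty = 2, drift = 2),
                         noise_sd = 2, seed = 1L) {
  stopifnot(all(grid >= 8), n_volumes >= 50, tr > 0)
  if (length(artifact_sources)) {
    artifact_sources <- match.arg(
      artifact_sources,
      c("edge_ring", "csf_pulsation", "high_freq_machine", "spotty", "drift"),
      several.ok = TRUE)
  }
  for (s in neural_sources) {
    if (s$amplitude_pct <= 0) stop("source amplitudes must be > 0",
                                   call. = FALSE)
  }
  structure(
    list(grid = as.integer(grid), tr = tr, n_volumes = as.integer(n_volumes),
         voxel_size = voxel_size, events = events,
         event_min_gap = event_min_gap,
         event_mean_extra_gap = event_mean_extra_gap,
         neural_sources = neural_sources,
         artifact_sources = artifact_sources,
         artifact_amplitude_pct = artifact_amplitude_pct,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Default pair of event-locked sources
#'
#' One canonical-shaped source and one with a 6 s pre-EEG-onset response,
#' mimicking early BOLD changes that precede the electrographic event.
#'
#' @return list of two source specifications.
#' @export
default_neural_sources <- function() {
  list(
    list(center = c(0.30, 0.38, 0.55), sigma_mm = 6, kind = "canonical_like",
         amplitude_pct = 1.2),
    list(center = c(0.70, 0.62, 0.45), sigma_mm = 6, kind = "early_onset",
         amplitude_pct = 1.0)
  )
}

#' Peri-event response shapes
#'
#' `canonical_like` is a difference of two gamma densities peaking about 5 s
#' after onset and identically zero before it; `early_onset` is the same
#' shape shifted so the response begins 6 s before time zero; and
#' `undershoot_dominant` has a post-event undershoot twice the positive
#' peak.  All curves are scaled to unit maximum absolute value.
#'
#' @param kind one of `"canonical_like"`, `"early_onset"`,
#'   `"undershoot_dominant"`.
#' @param bin_times bin times (s) relative to event onset.
#' @return numeric response curve on `bin_times`.
#' @export
make_response_shape <- function(kind = c("canonical_like", "early_onset",
                                         "undershoot_dominant"),
                                bin_times) {
  kind <- match.arg(kind)
  base <- function(t, undershoot_gain = 1 / 6) {
    out <- numeric(length(t))
    pos <- t > 0
    out[pos] <- stats::dgamma(t[pos], shape = 6, scale = 0.9) -
      undershoot_gain * stats::dgamma(t[pos], shape = 16, scale = 1)
    out
  }
  r <- switch(kind,
    canonical_like = base(bin_times),
    early_onset = base(bin_times + 6),
    undershoot_dominant = {
      t <- bin_times
      pos <- numeric(length(t)); und <- numeric(length(t))
      sel <- t > 0
      pos[sel] <- stats::dgamma(t[sel], shape = 6, scale = 0.9)
      und[sel] <- stats::dgamma(t[sel], shape = 16, scale = 1)
      cur <- pos - und * (2 * max(pos) / max(und))
      # rescale the negative lobe so |min| / max(positive lobe) == 2 exactly
      neg <- cur < 0
      cur[neg] <- cur[neg] * (2 * max(cur) / abs(min(cur)))
      cur
    })
  r / max(abs(r))
}

gaussian_blob <- function(grid, center_rel, sigma_mm, voxel_size) {
  cx <- center_rel * grid
  sig <- sigma_mm / voxel_size
  dx2 <- ((seq_len(grid[1]) - cx[1]) / sig[1])^2
  dy2 <- ((seq_len(grid[2]) - cx[2]) / sig[2])^2
  dz2 <- ((seq_len(grid[3]) - cx[3]) / sig[3])^2
  q <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  exp(-q / 2)
}

ellipsoid_mask <- function(grid, scale = 0.45) {
  c0 <- (grid + 1) / 2
  ax <- scale * grid
  dx2 <- ((seq_len(grid[1]) - c0[1]) / ax[1])^2
  dy2 <- ((seq_len(grid[2]) - c0[2]) / ax[2])^2
  dz2 <- ((seq_len(grid[3]) - c0[3]) / ax[3])^2
  q <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  array(as.integer(q <= 1), dim = grid)
}

# High-pass white noise: keep only periodogram bins above `cutoff_hz`.
highpass_noise <- function(n, tr, cutoff_hz) {
  x <- stats::rnorm(n)
  f <- stats::fft(x)
  freqs <- (seq_len(n) - 1) / (n * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)       # two-sided frequency magnitude
  f[freqs <= cutoff_hz] <- 0
  y <- Re(stats::fft(f, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Sample isolated in-mask voxels (no two chosen voxels 26-adjacent).
sample_isolated_voxels <- function(mask_arr, n_target) {
  idx <- which(mask_arr != 0)
  idx <- sample(idx)
  d <- dim(mask_arr)
  chosen <- matrix(numeric(0), ncol = 3)
  chosen_idx <- integer(0)
  for (i in idx) {
    co <- arrayInd(i, d)
    if (nrow(chosen) == 0 ||
        all(apply(abs(sweep(chosen, 2L, as.numeric(co))), 1L, max) > 1)) {
      chosen <- rbind(chosen, as.numeric(co))
      chosen_idx <- c(chosen_idx, i)
      if (length(chosen_idx) >= n_target) break
    }
  }
  chosen_idx
}

#' Generate a 4D fMRI phantom with ground truth
#'
#' Signal model: baseline 1000 plus each event-locked source (unit-max
#' Gaussian blob times its FIR-sampled response convolved with the event
#' train), plus the requested structured artifacts, plus white noise.
#' Deterministic given the spec (including its seed).
#'
#' @param spec a [phantom_spec].
#' @return list with `volume` (a [volume4d]) and `truth` (class
#'   `phantom_truth`): `source_maps`, `source_responses`, `source_kinds`,
#'   `amplitudes`, `artifact_maps`, `artifact_time_courses`, `brain`,
#'   `edge`, `csf` masks, `events`, `bin_times`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  grid <- spec$grid
  tr <- spec$tr
  nt <- spec$n_volumes
  t_end <- nt * tr

  brain_arr <- ellipsoid_mask(grid, 0.45)
  brain <- mask3d(brain_arr, "brain")
  # csf occupies ~3% of the brain: shrink each semi-axis by 0.03^(1/3)
  csf <- mask3d(ellipsoid_mask(grid, 0.45 * 0.03^(1 / 3)), "csf")
  edge <- make_edge_mask(brain, 1L)

  events <- spec$events
  if (is.null(events)) {
    onsets <- c()
    t0 <- 40
    while (t0 < t_end - 35) {
      onsets <- c(onsets, t0)
      t0 <- t0 + spec$event_min_gap + stats::rexp(1, 1 / spec$event_mean_extra_gap)
    }
    events <- event_train(onsets)
  }
  check_events_in_series(events, nt, tr)

  bin_times <- seq(-30, 30, by = tr)
  fir <- build_fir_design(events, nt, tr, window = c(-30, 30),
                          drift_order = 0L, policy = "accumulate")
  D <- fir$matrix[, seq_len(fir$n_bins), drop = FALSE]

  signal <- array(1000, dim = c(grid, nt))
  n_src <- length(spec$neural_sources)
  source_maps <- vector("list", n_src)
  source_responses <- vector("list", n_src)
  source_kinds <- character(n_src)
  amplitudes <- numeric(n_src)
  for (i in seq_len(n_src)) {
    s <- spec$neural_sources[[i]]
    blob <- gaussian_blob(grid, s$center, s$sigma_mm, spec$voxel_size)
    blob[brain_arr == 0] <- 0
    blob <- blob / max(blob)
    r <- make_response_shape(s$kind, bin_times)
    tc <- as.vector(D %*% r)
    amp <- s$amplitude_pct * 10          # percent of baseline 1000
    signal <- signal + outer_add4d(blob, amp * tc)
    source_maps[[i]] <- blob
    source_responses[[i]] <- r
    source_kinds[i] <- s$kind
    amplitudes[i] <- amp
  }

  vol_t <- (seq_len(nt) - 1) * tr
  nyquist <- 1 / (2 * tr)
  artifact_maps <- list()
  artifact_tcs <- list()
  for (a in spec$artifact_sources) {
    amp <- spec$artifact_amplitude_pct[[a]] * 10
    built <- switch(a,
      edge_ring = {
        m <- array(0, dim = grid)
        m[edge$data != 0] <- stats::runif(sum(edge$data), 0.5, 1)
        list(map = m, tc = highpass_noise(nt, tr, 0.08))
      },
      csf_pulsation = {
        m <- array(0, dim = grid)
        m[csf$data != 0] <- stats::runif(sum(csf$data), 0.5, 1)
        f <- stats::runif(1, 0.10, 0.15)
        tc <- sin(2 * pi * f * vol_t + stats::runif(1, 0, 2 * pi))
        list(map = m, tc = tc / stats::sd(tc))
      },
      high_freq_machine = {
        stripes <- array(rep(sin(2 * pi * seq_len(grid[2]) / 4),
                             each = grid[1]), dim = grid)
        tc <- sin(2 * pi * 0.9 * nyquist * vol_t + stats::runif(1, 0, 2 * pi))
        list(map = stripes, tc = tc / stats::sd(tc))
      },
      spotty = {
        m <- array(0, dim = grid)
        interior <- brain_arr * (1L - edge$data)
        m[sample_isolated_voxels(interior, 60L)] <- 1
        tc <- stats::rnorm(nt)
        list(map = m, tc = tc / stats::sd(tc))
      },
      drift = {
        m <- gaussian_blob(grid, c(0.5, 0.5, 0.5), 0.4 * grid[1] *
                             spec$voxel_size[1], spec$voxel_size)
        m[brain_arr == 0] <- 0
        x <- seq(-1, 1, length.out = nt)
        tc <- x + 0.8 * x^2
        list(map = m / max(m), tc = tc / stats::sd(tc))
      })
    signal <- signal + outer_add4d(built$map, amp * built$tc)
    artifact_maps[[a]] <- built$map
    artifact_tcs[[a]] <- built$tc
  }

  if (spec$noise_sd > 0) {
    signal <- signal + array(stats::rnorm(length(signal), sd = spec$noise_sd),
                             dim = dim(signal))
  }

  truth <- structure(
    list(source_maps = source_maps, source_responses = source_responses,
         source_kinds = source_kinds, amplitudes = amplitudes,
         artifact_maps = artifact_maps, artifact_time_courses = artifact_tcs,
         brain = brain, edge = edge, csf = csf, events = events,
         bin_times = bin_times),
    class = "phantom_truth")
  list(volume = volume4d(signal, tr = tr, voxel_size = spec$voxel_size),
       truth = truth)
}

# map (3D) x tc (length nt) outer product as a 4D array increment
outer_add4d <- function(map, tc) {
  array(as.vector(map) %o% tc, dim = c(dim(map), length(tc)))
}

#' Match recovered components to ground truth
#'
#' Greedy assignment on descending absolute spatial correlation without
#' reuse; ties broken by the lower recovered index.
#'
#' @param recovered_maps k x v matrix (rows = recovered maps over mask).
#' @param truth_maps m x v matrix (rows = truth maps over the same mask).
#' @param recovered_tcs optional T x k matrix of recovered time courses.
#' @param truth_tcs optional T x m matrix of truth time courses.
#' @return data.frame with `truth`, `recovered`, `spatial_r` and (when time
#'   courses are supplied) `temporal_r`; correlations are absolute values.
#' @export
match_components <- function(recovered_maps, truth_maps,
                             recovered_tcs = NULL, truth_tcs = NULL) {
  recovered_maps <- as.matrix(recovered_maps)
  truth_maps <- as.matrix(truth_maps)
  stopifnot(nrow(recovered_maps) >= 1L, nrow(truth_maps) >= 1L,
            ncol(recovered_maps) == ncol(truth_maps))
  C <- abs(stats::cor(t(recovered_maps), t(truth_maps)))
  C[!is.finite(C)] <- 0
  k <- nrow(C); m <- ncol(C)
  cand <- data.frame(recovered = rep(seq_len(k), m),
                     truth = rep(seq_len(m), each = k),
                     r = as.vector(C))
  cand <- cand[order(-cand$r, cand$recovered, cand$truth), ]
  used_r <- logical(k); used_t <- logical(m)
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    rc <- cand$recovered[i]; tc <- cand$truth[i]
    if (!used_r[rc] && !used_t[tc]) {
      used_r[rc] <- TRUE; used_t[tc] <- TRUE
      rows[[length(rows) + 1L]] <- cand[i, ]
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$truth), c("truth", "recovered", "r")]
  names(out)[3] <- "spatial_r"
  rownames(out) <- NULL
  if (!is.null(recovered_tcs) && !is.null(truth_tcs)) {
    out$temporal_r <- vapply(seq_len(nrow(out)), function(i) {
      abs(stats::cor(recovered_tcs[, out$recovered[i]],
                     truth_tcs[, out$truth[i]]))
    }, numeric(1))
  }
  out
}
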