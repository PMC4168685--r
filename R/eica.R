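# Event-related ICA: FIR deconvolution of peri-event BOLD responses, ICA of
# those responses with run-stability clustering, and mixture-model z-maps.

#' Build an FIR deconvolution design
#'
#' One indicator column per peri-event time bin over a window spanning
#' `window[1]` to `window[2]` seconds around each event onset (default -30 to
#' +30 s, which gives 21 bins at TR = 3 s), plus confound columns (intercept
#' and Legendre polynomial drift up to `drift_order`).  Events at sub-TR
#' offsets are assigned to the nearest volume.  Under the default `"cap"`
#' policy overlapping event windows leave each design cell at most 1;
#' `"accumulate"` sums hits.  Events whose window extends past the series
#' boundary contribute their in-range bins (set `drop_partial = TRUE` to use
#' only events with a complete window).
#'
#' @param events an [event_train].
#' @param n_volumes number of volumes in the series.
#' @param tr repetition time (s).
#' @param window c(pre, post) seconds relative to onset; must align to `tr`.
#' @param drift_order Legendre drift order (0 = intercept only).
#' @param policy `"cap"` or `"accumulate"`.
#' @param drop_partial drop events without a full window.
#' @return An object of class `fir_design`: `matrix`
#'   (n_volumes x (n_bins + n_confounds)), `n_bins`, `bin_times`, `window`,
#'   `confound_columns`, `events_used`, `tr`.
#' @export
build_fir_design <- function(events, n_volumes, tr, window = c(-30, 30),
                             drift_order = 1L,
                             policy = c("cap", "accumulate"),
                             drop_partial = FALSE) {
  policy <- match.arg(policy)
  stopifnot(inherits(events, "event_train"), n_volumes >= 2L, tr > 0)
  span <- window[2] - window[1]
  if (abs(span / tr - round(span / tr)) > 1e-9) {
    stop("bin grid must align to tr: window width is not a multiple of tr",
         call. = FALSE)
  }
  check_events_in_series(events, n_volumes, tr)
  bin_times <- seq(window[1], window[2], by = tr)
  n_bins <- length(bin_times)
  fir <- matrix(0, nrow = n_volumes, ncol = n_bins)
  vol_times <- (seq_len(n_volumes) - 1L) * tr
  used <- 0L
  for (o in events$onsets) {
    v_idx <- round((o + bin_times) / tr)       # 0-based volume indices
    in_range <- v_idx >= 0L & v_idx <= n_volumes - 1L
    if (drop_partial && !all(in_range)) next
    if (!any(in_range)) next
    used <- used + 1L
    rows <- v_idx[in_range] + 1L
    cols <- which(in_range)
    for (i in seq_along(rows)) {
      fir[rows[i], cols[i]] <- fir[rows[i], cols[i]] + 1
    }
  }
  if (used == 0L) stop("zero usable events for the FIR design", call. = FALSE)
  if (policy == "cap") fir[fir > 1] <- 1

  x <- seq(-1, 1, length.out = n_volumes)
  conf <- matrix(1, nrow = n_volumes, ncol = 1L)
  if (drift_order >= 1L) conf <- cbind(conf, x)
  if (drift_order >= 2L) {
    for (p in 2:drift_order) conf <- cbind(conf, legendre_poly(x, p))
  }
  colnames(fir) <- sprintf("bin_%+g", bin_times)
  colnames(conf) <- c("intercept",
                      if (drift_order >= 1L) sprintf("drift%d", 1:drift_order))
  structure(
    list(matrix = cbind(fir, conf), n_bins = n_bins, bin_times = bin_times,
         window = window, confound_columns = n_bins + seq_len(ncol(conf)),
         events_used = used, tr = tr),
    class = "fir_design"
  )
}

# Legendre polynomial P_p on [-1, 1] by Bonnet recursion.
legendre_poly <- function(x, p) {
  if (p == 0L) return(rep(1, length(x)))
  if (p == 1L) return(x)
  pm2 <- rep(1, length(x)); pm1 <- x
  for (k in 2:p) {
    cur <- ((2 * k - 1) * x * pm1 - (k - 1) * pm2) / k
    pm2 <- pm1; pm1 <- cur
  }
  pm1
}

#' @export
print.fir_design <- function(x, ...) {
  cat(sprintf("<fir_design> %d bins over [%g, %g] s, %d events used, %d confounds\n",
              x$n_bins, x$window[1], x$window[2], x$events_used,
              length(x$confound_columns)))
  invisible(x)
}

#' FIR deconvolution of peri-event responses
#'
#' Per-voxel least squares (Moore-Penrose pseudo-inverse, so collinear
#' designs return the minimum-norm solution) of the masked series on the FIR
#' design; the FIR coefficients are the estimated event-related response at
#' each bin time and confound coefficients are discarded.
#'
#' @param vol a [volume4d].
#' @param design a [fir_design] with rows matching `vol$n_volumes`.
#' @param mask brain [mask3d].
#' @return An object of class `peri_event_response`: `responses`
#'   (n_maskvoxels x n_bins), `bin_times`, `events_used`, `mask`, `tr`.
#' @export
deconvolve <- function(vol, design, mask) {
  stopifnot(inherits(vol, "volume4d"), inherits(design, "fir_design"),
            inherits(mask, "mask3d"))
  M <- design$matrix
  if (nrow(M) != vol$n_volumes) {
    stop("design rows must equal n_volumes", call. = FALSE)
  }
  fir_cols <- seq_len(design$n_bins)
  if (all(M[, fir_cols] == 0)) {
    stop("all FIR columns are zero: no events hit the series", call. = FALSE)
  }
  X <- masked_series(vol, mask)
  beta <- MASS::ginv(M) %*% X
  structure(
    list(responses = t(beta[fir_cols, , drop = FALSE]),
         bin_times = design$bin_times, events_used = design$events_used,
         mask = mask, tr = design$tr),
    class = "peri_event_response"
  )
}

#' @export
print.peri_event_response <- function(x, ...) {
  cat(sprintf("<peri_event_response> %d voxels x %d bins (%d events)\n",
              nrow(x$responses), length(x$bin_times), x$events_used))
  invisible(x)
}

#' Stack peri-event responses across subjects
#'
#' Subjects must share one registered voxel grid; per subject an optional
#' left-right flip is applied first (see [flip_lr]) and each subject's
#' response matrix is scaled to unit Frobenius norm so no subject dominates
#' the concatenated decomposition.
#'
#' @param responses list of `peri_event_response` objects.
#' @param flip_flags logical vector, one per subject.
#' @return An object of class `group_stack`: `subjects` (the possibly flipped
#'   inputs), `flip_flags`, `concatenated` ((sum n_bins) x n_voxels),
#'   `segment_rows` (row ranges per subject), `mask`.
#' @export
group_stack <- function(responses, flip_flags = NULL) {
  stopifnot(length(responses) >= 1L)
  if (is.null(flip_flags)) flip_flags <- rep(FALSE, length(responses))
  stopifnot(length(flip_flags) == length(responses))
  subs <- mapply(function(p, fl) if (fl) flip_lr(p) else p,
                 responses, flip_flags, SIMPLIFY = FALSE)
  ref_dim <- dim(subs[[1]]$mask$data)
  ref_idx <- which(subs[[1]]$mask$data != 0)
  for (s in subs) {
    if (!identical(which(s$mask$data != 0), ref_idx)) {
      stop("subjects do not share one registered voxel grid", call. = FALSE)
    }
  }
  blocks <- lapply(subs, function(s) {
    m <- t(s$responses)                       # n_bins x v
    nrm <- sqrt(sum(m^2))
    if (nrm > 0) m / nrm else m
  })
  rows <- cumsum(vapply(blocks, nrow, integer(1)))
  segment_rows <- Map(function(a, b) c(a, b),
                      c(1L, utils::head(rows, -1) + 1L), rows)
  structure(list(subjects = subs, flip_flags = flip_flags,
                 concatenated = do.call(rbind, blocks),
                 segment_rows = segment_rows, mask = subs[[1]]$mask),
            class = "group_stack")
}

#' Event-related ICA with run-stability clustering
#'
#' Runs FastICA `n_runs` times from derived seeds on the peri-event response
#' matrix (single subject) or the temporally concatenated group stack,
#' clusters the pooled components by average-linkage on 1 - |spatial
#' correlation| cut at `n_components` clusters, and returns per cluster the
#' centrotype (the member maximizing summed within-cluster |correlation|).
#' The stability index per component is the mean within-cluster |correlation|
#' minus the mean between-cluster |correlation|, clipped to [0, 1].  Spatial
#' maps are z-scaled; z-maps from a Gaussian mixture fit ([mixture_zmap])
#' preserve within-component voxel ranking.  Group runs return one common
#' spatial map set with per-subject time-course segments.
#'
#' @param per a `peri_event_response` or a [group_stack].
#' @param n_components model order (<= total bins).
#' @param seed integer seed.
#' @param n_runs number of ICA runs pooled for stability (>= 2 recommended).
#' @return An object of class `eica_result`: `spatial_maps`
#'   (k x n_maskvoxels), `time_courses` (n_bins x k, or per-subject list for
#'   groups), `z_maps`, `stability_index`, `n_components`, `bin_times`,
#'   `mask`, `zmap_fallback`.
#' @export
eica_decompose <- function(per, n_components = 10L, seed = 1L, n_runs = 10L) {
  is_group <- inherits(per, "group_stack")
  D <- if (is_group) per$concatenated else t(per$responses)  # T x v
  mask <- per$mask
  nt <- nrow(D); nv <- ncol(D)
  if (n_components > nt) {
    stop(sprintf("n_components = %d exceeds available bins (%d)",
                 n_components, nt), call. = FALSE)
  }
  mean_map <- colMeans(D)
  Dc <- sweep(D, 2L, mean_map)
  g <- rowMeans(Dc)
  Dcc <- Dc - g
  red <- pca_reduce(Dcc, order_fixed(min(n_components,
                                         qr(Dcc)$rank, nt - 1L)))
  k <- red$order
  runs <- lapply(seq_len(n_runs), function(r) {
    fastica_core(red$whitened, seed = derive_seed(seed, 100L + r))
  })
  pooled <- do.call(rbind, lapply(runs, `[[`, "S"))    # (n_runs*k) x v
  ac <- abs(stats::cor(t(pooled)))
  ac[!is.finite(ac)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - ac), method = "average")
  cl <- stats::cutree(hc, k = k)

  centro <- integer(k)
  stability <- numeric(k)
  for (cidx in seq_len(k)) {
    members <- which(cl == cidx)
    sub <- ac[members, members, drop = FALSE]
    centro[cidx] <- members[which.max(rowSums(sub))]
    within <- if (length(members) > 1L) {
      mean(sub[upper.tri(sub)])
    } else 1
    others <- which(cl != cidx)
    between <- if (length(others)) mean(ac[members, others]) else 0
    stability[cidx] <- min(1, max(0, within - between))
  }
  S <- pooled[centro, , drop = FALSE]
  mu <- rowMeans(S); sdev <- sqrt(rowMeans((S - mu)^2))
  S <- (S - mu) / sdev
  sk <- apply(S, 1L, function(r) mean(r^3))
  flip <- ifelse(sk < 0, -1, 1)
  S <- S * flip

  # time courses by least squares of the centered data on the final maps
  A <- Dc %*% t(S) %*% solve(S %*% t(S) + diag(1e-10, k))        # T x k

  ord <- order(colMeans(A^2), decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  A <- A[, ord, drop = FALSE]
  stability <- stability[ord]

  zres <- lapply(seq_len(k), function(j) mixture_zmap(S[j, ]))
  z_maps <- do.call(rbind, lapply(zres, `[[`, "z"))
  fallback <- vapply(zres, `[[`, logical(1), "fallback")

  time_courses <- if (is_group) {
    lapply(per$segment_rows, function(rg) A[rg[1]:rg[2], , drop = FALSE])
  } else A

  structure(
    list(spatial_maps = S, time_courses = time_courses, z_maps = z_maps,
         stability_index = stability, n_components = k,
         bin_times = if (is_group) per$subjects[[1]]$bin_times else
           per$bin_times,
         mask = mask, zmap_fallback = fallback, seed = as.integer(seed),
         n_runs = as.integer(n_runs), group = is_group),
    class = "eica_result"
  )
}

#' @export
print.eica_result <- function(x, ...) {
  cat(sprintf("<eica_result> %d components (%s), stability %.2f-%.2f\n",
              x$n_components, if (x$group) "group" else "single subject",
              min(x$stability_index), max(x$stability_index)))
  invisible(x)
}

#' Mixture-model z-map of a spatial map
#'
#' Fits a two-component Gaussian mixture by EM (deterministic initialization
#' at the robust location/scale with an offset second component; at most 200
#' iterations, tolerance 1e-8 on the log-likelihood), takes the
#' larger-weight component as the null background, and returns
#' `z = (value - mu_null) / sigma_null` — a monotone (affine) transform of
#' the input.  If the EM degenerates (a vanishing scale) the function falls
#' back to a robust z (median/MAD) and flags it.
#'
#' @param x numeric map values over mask voxels (>= 100 values).
#' @return list with `z`, `mu_null`, `sigma_null`, `weight_null`,
#'   `fallback`, `iterations`.
#' @export
mixture_zmap <- function(x) {
  if (length(x) < 100L) {
    stop("mixture_zmap needs at least 100 in-mask values", call. = FALSE)
  }
  m <- stats::median(x)
  s <- stats::mad(x)
  if (!is.finite(s) || s <= 0) s <- stats::sd(x)
  robust_z <- function() {
    sc <- if (is.finite(s) && s > 0) s else 1
    list(z = (x - m) / sc, mu_null = m, sigma_null = sc, weight_null = 1,
         fallback = TRUE, iterations = 0L)
  }
  if (!is.finite(s) || s <= 0) return(robust_z())

  mu <- c(m, m + 3 * s)
  sigma <- c(s, 2 * s)
  w <- c(0.95, 0.05)
  ll_old <- -Inf
  iter <- 0L
  for (iter in seq_len(200L)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sigma[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    r2 <- d2 / tot
    r1 <- 1 - r2
    n1 <- sum(r1); n2 <- sum(r2)
    if (n1 < 1e-8 || n2 < 1e-8) break
    mu <- c(sum(r1 * x) / n1, sum(r2 * x) / n2)
    sigma <- sqrt(c(sum(r1 * (x - mu[1])^2) / n1,
                    sum(r2 * (x - mu[2])^2) / n2))
    if (any(!is.finite(sigma)) || any(sigma < 1e-8 * s)) return(robust_z())
    w <- c(n1, n2) / length(x)
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) < 1e-8) break
    ll_old <- ll
  }
  null <- which.max(w)
  list(z = (x - mu[null]) / sigma[null], mu_null = mu[null],
       sigma_null = sigma[null], weight_null = w[null], fallback = FALSE,
       iterations = iter)
}

#' Threshold a z-map
#'
#' Two-sided Gaussian p-values per voxel; `correction = "fdr"` applies
#' Benjamini-Hochberg across the supplied values.  Surviving voxels keep
#' their signed z; all others are set to 0.
#'
#' @param z numeric z values (over mask voxels).
#' @param p significance level in (0, 1).
#' @param correction `"none"` or `"fdr"`.
#' @return numeric vector of thresholded signed z values.
#' @export
threshold_zmap <- function(z, p = 0.05, correction = c("none", "fdr")) {
  correction <- match.arg(correction)
  stopifnot(p > 0, p < 1)
  pv <- 2 * stats::pnorm(-abs(z))
  if (correction == "fdr") pv <- stats::p.adjust(pv, method = "BH")
  ifelse(pv <= p, z, 0)
}

#' Left-right flip
#'
#' Reverses the first voxel axis; `flip_lr(flip_lr(x))` is the identity.
#'
#' @param x a [volume4d] or `peri_event_response`.
#' @return object of the same class, flipped along x.
#' @export
flip_lr <- function(x) UseMethod("flip_lr")

#' @export
flip_lr.volume4d <- function(x) {
  d <- dim(x$data)
  x$data <- x$data[d[1]:1, , , , drop = FALSE]
  flipmat <- diag(4)
  flipmat[1, 1] <- -1
  flipmat[1, 4] <- d[1] - 1
  x$affine <- x$affine %*% flipmat
  x
}

#' @export
flip_lr.mask3d <- function(x) {
  d <- dim(x$data)
  x$data <- x$data[d[1]:1, , , drop = FALSE]
  x
}

#' @export
flip_lr.peri_event_response <- function(x) {
  new_mask <- flip_lr(x$mask)
  d <- dim(x$mask$data)
  n_bins <- ncol(x$responses)
  resp <- matrix(0, nrow = sum(new_mask$data), ncol = n_bins)
  for (b in seq_len(n_bins)) {
    m3 <- unmask_map(x$responses[, b], x$mask)
    m3 <- m3[d[1]:1, , , drop = FALSE]
    resp[, b] <- m3[which(new_mask$data != 0)]
  }
  x$responses <- resp
  x$mask <- new_mask
  x
}

#' Serialize a peri-event response
#'
#' Writes a 4D NIfTI with bins along the 4th axis plus a `bin_times.txt`
#' sidecar.
#'
#' @param per a `peri_event_response`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_peri_event_response <- function(per, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d3 <- dim(per$mask$data)
  arr <- array(0, dim = c(d3, length(per$bin_times)))
  for (b in seq_along(per$bin_times)) {
    arr[, , , b] <- unmask_map(per$responses[, b], per$mask)
  }
  nifti_write(file.path(dir, "responses.nii"), arr, tr = per$tr)
  writeLines(format(per$bin_times, trim = TRUE),
             file.path(dir, "bin_times.txt"))
  invisible(dir)
}

#' Serialize an eICA result
#'
#' Maps and z-maps as 4D NIfTI (components along the 4th axis), time courses
#' (per subject for group runs) and stability indices as tab-separated text.
#'
#' @param res an `eica_result`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_eica_result <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d3 <- dim(res$mask$data)
  k <- res$n_components
  maps <- array(0, dim = c(d3, k)); zs <- maps
  for (j in seq_len(k)) {
    maps[, , , j] <- unmask_map(res$spatial_maps[j, ], res$mask)
    zs[, , , j] <- unmask_map(res$z_maps[j, ], res$mask)
  }
  nifti_write(file.path(dir, "eica_maps.nii"), maps)
  nifti_write(file.path(dir, "eica_zmaps.nii"), zs)
  tcs <- if (res$group) res$time_courses else list(res$time_courses)
  for (i in seq_along(tcs)) {
    tab <- as.data.frame(tcs[[i]])
    names(tab) <- sprintf("IC%d", seq_len(k))
    utils::write.table(cbind(bin_time = res$bin_times, tab),
                       file.path(dir, sprintf("time_courses_sub%02d.tsv", i)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(
    data.frame(component = seq_len(k), stability = res$stability_index,
               zmap_fallback = res$zmap_fallback),
    file.path(dir, "stability.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  invisible(dir)
}
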