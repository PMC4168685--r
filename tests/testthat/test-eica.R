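test_that("FIR design places bins by direct index arithmetic", {
  ev <- event_train(60)
  d <- build_fir_design(ev, n_volumes = 50, tr = 3)
  expect_equal(d$n_bins, 21L)                       # +/-30 s at TR 3 s
  expect_equal(d$bin_times, seq(-30, 30, by = 3))
  # bin -30 s lands at volume (60-30)/3 = 10 (0-based) -> row 11
  expect_equal(which(d$matrix[, 1] == 1), 11L)
  # bin +30 s at volume (60+30)/3 = 30 -> row 31
  expect_equal(which(d$matrix[, 21] == 1), 31L)
  expect_equal(d$events_used, 1L)

  # two events 6 s apart: per-bin columns are shifted copies
  d2 <- build_fir_design(event_train(c(60, 66)), 50, 3)
  for (j in c(1, 11, 21)) {
    col <- d2$matrix[, j]
    hits <- which(col == 1)
    expect_equal(diff(hits), 2L)
  }

  # sub-TR offsets go to the nearest volume
  d3 <- build_fir_design(event_train(61.4), 50, 3)
  expect_equal(which(d3$matrix[, 11] == 1), 21L)    # round(61.4/3) = 20

  expect_error(build_fir_design(ev, 50, tr = 3, window = c(-29, 30)),
               "align to tr")
  expect_error(build_fir_design(event_train(10), 50, 3, drop_partial = TRUE),
               "zero usable")
  expect_error(build_fir_design(event_train(1000), 50, 3), "past series")
})

test_that("cap vs accumulate policies differ only on overlapping windows", {
  ev <- event_train(c(60, 60.1))                    # same nearest volumes
  dc <- build_fir_design(ev, 50, 3, policy = "cap")
  da <- build_fir_design(ev, 50, 3, policy = "accumulate")
  expect_equal(max(dc$matrix[, 1:21]), 1)
  expect_equal(max(da$matrix[, 1:21]), 2)
  expect_equal(da$matrix[, 1:21] > 0, dc$matrix[, 1:21] > 0)
})

test_that("deconvolution recovers injected shapes exactly when noiseless", {
  ev <- event_train(c(30, 96, 162, 228, 294))
  ph <- generate_phantom(tiny_phantom_spec(7, events = ev,
                                           artifact_sources = character(0),
                                           noise_sd = 0))
  d <- build_fir_design(ev, 120, 3)
  per <- deconvolve(ph$volume, d, ph$truth$brain)
  truth <- truth_response_field(ph$truth)
  expect_lte(max(abs(per$responses - truth)) / max(abs(truth)), 1e-8)
  expect_equal(per$bin_times, seq(-30, 30, by = 3))
  expect_equal(per$events_used, 5L)
})

test_that("response RMS shrinks like 1/sqrt(events) on pure noise", {
  # sparse, non-overlapping windows (126 s spacing) so the design stays well
  # conditioned and the OLS variance law applies
  nt <- 2200
  mask <- mask3d(array(1L, dim = c(6, 6, 3)), "brain")
  arr <- sockeica:::with_seed(77,
    array(rnorm(6 * 6 * 3 * nt), dim = c(6, 6, 3, nt)))
  vol <- volume4d(arr, tr = 3)
  rms_at <- function(n_events) {
    onsets <- seq(36, by = 126, length.out = n_events)
    d <- build_fir_design(event_train(onsets), nt, 3)
    per <- deconvolve(vol, d, mask)
    sqrt(mean(per$responses^2))
  }
  ratio <- rms_at(12) / rms_at(48)
  expect_gt(ratio, 2 * 0.75)
  expect_lt(ratio, 2 * 1.25)
})

test_that("rank-deficient designs fall back to the minimum-norm solution", {
  # both events sit close to the series start, so the earliest peri-event
  # bins never hit a volume: their FIR columns are all zero
  ev <- event_train(c(6, 15))
  ph <- generate_phantom(tiny_phantom_spec(3, events = ev,
                                           artifact_sources = character(0),
                                           noise_sd = 0.1))
  d <- build_fir_design(ev, 120, 3)
  zero_cols <- which(colSums(d$matrix[, 1:21]) == 0)
  expect_gt(length(zero_cols), 0L)
  expect_lt(qr(d$matrix)$rank, ncol(d$matrix))
  per <- deconvolve(ph$volume, d, ph$truth$brain)
  expect_true(all(is.finite(per$responses)))
  # minimum-norm solution leaves unidentifiable bins at (numerically) zero
  expect_lt(max(abs(per$responses[, zero_cols])), 1e-10)
})

test_that("eica is deterministic and agrees between group-of-one and single", {
  ph <- generate_phantom(tiny_phantom_spec(41, artifact_sources = character(0),
                                           noise_sd = 0.5))
  d <- build_fir_design(ph$truth$events, 120, 3)
  per <- deconvolve(ph$volume, d, ph$truth$brain)
  r1 <- eica_decompose(per, n_components = 2, seed = 6, n_runs = 4)
  r2 <- eica_decompose(per, n_components = 2, seed = 6, n_runs = 4)
  expect_identical(r1$spatial_maps, r2$spatial_maps)
  expect_identical(r1$stability_index, r2$stability_index)

  g <- group_stack(list(per))
  rg <- eica_decompose(g, n_components = 2, seed = 6, n_runs = 4)
  mt <- match_components(rg$spatial_maps, r1$spatial_maps)
  expect_true(all(mt$spatial_r >= 0.95))
  expect_true(is.list(rg$time_courses) && length(rg$time_courses) == 1L)

  expect_error(eica_decompose(per, n_components = 50), "exceeds")
})

test_that("group eica returns one map set with per-subject time courses", {
  pers <- lapply(1:3, function(s) {
    ph <- generate_phantom(tiny_phantom_spec(
      50 + s,
      neural_sources = list(list(center = c(0.35, 0.4, 0.5), sigma_mm = 6,
                                 kind = "canonical_like",
                                 amplitude_pct = 1.5)),
      artifact_sources = character(0), noise_sd = 0.5))
    d <- build_fir_design(ph$truth$events, 120, 3)
    list(per = deconvolve(ph$volume, d, ph$truth$brain), truth = ph$truth)
  })
  g <- group_stack(lapply(pers, `[[`, "per"))
  res <- eica_decompose(g, n_components = 2, seed = 2, n_runs = 4)
  expect_length(res$time_courses, 3L)
  truth_map <- t(sapply(pers[[1]]$truth$source_maps,
                        function(m) m[pers[[1]]$truth$brain$data != 0]))
  mt <- match_components(res$spatial_maps, truth_map)
  comp <- mt$recovered[1]
  truth_curve <- pers[[1]]$truth$source_responses[[1]]
  for (s in 1:3) {
    expect_gte(abs(cor(res$time_courses[[s]][, comp], truth_curve)), 0.85)
  }
})

test_that("mixture z-maps recover known mixtures and stay monotone", {
  x <- sockeica:::with_seed(99, rnorm(10000))
  fit <- mixture_zmap(x)
  expect_false(fit$fallback)
  expect_lt(abs(fit$mu_null), 0.05)
  expect_gt(fit$sigma_null, 0.9)
  expect_lt(fit$sigma_null, 1.1)

  y <- sockeica:::with_seed(7, c(rnorm(9500), rnorm(500, mean = 8)))
  f2 <- mixture_zmap(y)
  expect_true(all(f2$z[y > 5] >= 5))
  expect_identical(order(f2$z), order(y))           # monotone transform

  expect_error(mixture_zmap(rnorm(50)), "at least 100")
  const <- c(rep(1, 150))
  expect_true(mixture_zmap(const)$fallback)
})

test_that("z-map thresholding matches Gaussian quantiles and BH-FDR", {
  zb <- c(-1.959963, -1.959965, 1.959965, 1.0)
  thr <- threshold_zmap(zb, p = 0.05)
  expect_equal(thr != 0, c(FALSE, TRUE, TRUE, FALSE))

  zn <- sockeica:::with_seed(3, rnorm(10000))
  expect_lte(sum(threshold_zmap(zn, 0.05, "fdr") != 0), 5)
  frac <- mean(threshold_zmap(zn, 0.05, "none") != 0)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("flip_lr is an involution and mirrors positions", {
  set.seed(9)
  a <- array(rnorm(6 * 5 * 4 * 3), dim = c(6, 5, 4, 3))
  v <- volume4d(a, tr = 2)
  expect_identical(flip_lr(flip_lr(v))$data, v$data)
  one <- array(0, dim = c(6, 5, 4, 2)); one[1, 2, 2, ] <- 1
  f <- flip_lr(volume4d(one, tr = 1))
  expect_equal(which(f$data[, 2, 2, 1] == 1), 6L)

  # left-lateralized blob flips onto its right-lateralized mirror
  grid <- c(16, 16, 8)
  left <- sockeica:::gaussian_blob(grid, c(0.25, 0.5, 0.5), 4, c(1, 1, 1))
  right <- left[grid[1]:1, , ]
  mask <- mask3d(array(1L, dim = grid), "brain")
  per <- structure(list(responses = cbind(as.vector(left)[which(mask$data != 0)]),
                        bin_times = 0, events_used = 1L, mask = mask, tr = 3),
                   class = "peri_event_response")
  fp <- flip_lr(per)
  expect_equal(cor(fp$responses[, 1], as.vector(right)), 1.0)
  expect_equal(flip_lr(fp)$responses, per$responses, tolerance = 1e-15)
})

test_that("eica results and responses serialize to readable directories", {
  ph <- generate_phantom(tiny_phantom_spec(13, artifact_sources = character(0),
                                           noise_sd = 0.5))
  d <- build_fir_design(ph$truth$events, 120, 3)
  per <- deconvolve(ph$volume, d, ph$truth$brain)
  res <- eica_decompose(per, n_components = 2, seed = 1, n_runs = 3)
  out1 <- file.path(tempdir(), "per_out"); out2 <- file.path(tempdir(), "eica_out")
  write_peri_event_response(per, out1)
  write_eica_result(res, out2)
  expect_equal(length(readLines(file.path(out1, "bin_times.txt"))), 21L)
  maps <- sockeica:::nifti_read(file.path(out2, "eica_maps.nii"))
  expect_equal(maps$dim[4], 2L)
  tc <- utils::read.table(file.path(out2, "time_courses_sub01.tsv"),
                          header = TRUE, sep = "\t")
  expect_equal(nrow(tc), 21L)
})
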