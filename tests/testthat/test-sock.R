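test_that("edge mask of a solid cube has the exact shell count", {
  arr <- array(0L, dim = c(13, 13, 13))
  arr[3:11, 3:11, 3:11] <- 1L                     # 9x9x9 solid cube
  brain <- mask3d(arr, "brain")
  edge <- make_edge_mask(brain, 1L)
  expect_equal(sum(edge$data), 9^3 - 7^3)         # 386 by construction
  # edge and eroded core are disjoint, edge within brain
  core <- sockeica:::erode6(brain$data)
  expect_equal(sum(edge$data * core), 0L)
  expect_true(all(edge$data <= brain$data))

  expect_error(make_edge_mask(brain, 10L), "smaller width")
})

test_that("threshold_map applies |z| >= z_thr with an empty flag", {
  m <- c(-3, -1, 0, 1.5, 2.3, 4)         # boundary value 2.3 is included
  s <- threshold_map(m, 2.3)
  expect_equal(sum(s), 3)
  expect_false(attr(s, "empty"))
  expect_equal(sum(threshold_map(m, 0)), length(m))
  sz <- threshold_map(rep(0, 10), 2.3)
  expect_true(attr(sz, "empty"))

  set.seed(3)
  v <- rnorm(500, sd = 0.1)
  v[sample(500, 5)] <- c(3, -3, 2.5, -4, 2.31)
  expect_equal(sum(threshold_map(v, 2.3)), 5)
})

test_that("smoothness rises with salt-and-pepper structure; clusters count", {
  grid <- c(20, 20, 6)
  brain <- mask3d(array(1L, dim = grid), "brain")
  blob <- sockeica:::gaussian_blob(grid, c(0.5, 0.5, 0.5), 8 / 2.355, c(1, 1, 1))
  sm_blob <- smoothness_features(blob, brain)$smoothness

  set.seed(11)
  flips <- array(sample(c(1, -1), prod(grid), TRUE, prob = c(0.7, 0.3)),
                 dim = grid)
  sm_spotty <- smoothness_features(blob * flips, brain)$smoothness
  expect_lt(sm_blob, sm_spotty)

  # one big cluster -> fraction 0
  one <- array(0, dim = grid)
  one[5:9, 5:8, 2:6] <- 3                          # 100-voxel 26-connected block
  f <- smoothness_features(one, brain, z_thr = 2.3, s_min = 5L)
  expect_equal(f$small_cluster_fraction, 0)
  expect_equal(f$n_suprathreshold, 100)

  # isolated singletons -> fraction 1
  iso <- array(0, dim = grid)
  iso[cbind(seq(2, 18, by = 4), rep(seq(2, 18, by = 4), each = 5),
            rep(c(2, 5), length.out = 25)[1:25])] <- 3
  fi <- smoothness_features(iso, brain, z_thr = 2.3, s_min = 5L)
  expect_equal(fi$small_cluster_fraction, 1)

  # no qualifying slice -> smoothness undefined
  tiny <- mask3d(array(c(rep(1L, 10), rep(0L, prod(grid) - 10)), dim = grid),
                 "brain")
  expect_true(is.na(smoothness_features(blob, tiny)$smoothness))
})

test_that("region_fraction is exact set arithmetic", {
  grid <- c(10, 10, 4)
  region <- array(0L, dim = grid); region[1:5, , ] <- 1L
  reg <- mask3d(region, "csf")
  supra <- array(FALSE, dim = grid)
  supra[4:6, 1:8, 1:2] <- TRUE                     # 48 voxels, 16 x2 inside
  expect_equal(region_fraction(supra, reg), sum(supra & region == 1) / sum(supra))
  inside <- array(FALSE, dim = grid); inside[2, 2, 2] <- TRUE
  expect_equal(region_fraction(inside, reg), 1)
  outside <- array(FALSE, dim = grid); outside[8, 8, 3] <- TRUE
  expect_equal(region_fraction(outside, reg), 0)
  expect_equal(region_fraction(array(FALSE, grid), reg), 0)

  # 30 of 120 suprathreshold voxels in region -> 0.25
  s2 <- array(FALSE, dim = grid)
  s2[6:8, 1:10, 1:4] <- TRUE                       # 120 voxels, x in 6:8
  r2 <- array(0L, dim = grid); r2[6, 1:10, 1:3] <- 1L  # 30 of them
  expect_equal(region_fraction(s2, mask3d(r2, "csf")), 0.25)
})

test_that("tfn_fraction separates slow and fast sinusoids (oracle DFT)", {
  tvec <- (0:399) * 3
  slow <- sin(2 * pi * 0.01 * tvec)
  fast <- sin(2 * pi * 0.15 * tvec)
  expect_lte(tfn_fraction(slow, tr = 3), 0.05)
  expect_gte(tfn_fraction(fast, tr = 3), 0.95)

  # oracle: direct DFT power split at the cutoff
  o <- oracle_dft_power(slow, tr = 3)
  keep <- -1
  oracle_tfn <- sum(o$power[keep][o$freq[keep] > 0.08]) / sum(o$power[keep])
  expect_equal(tfn_fraction(slow, tr = 3), oracle_tfn, tolerance = 1e-8)

  expect_error(tfn_fraction(slow, tr = 3, cutoff = 0.2), "Nyquist")
  expect_equal(tfn_fraction(rep(1, 100), tr = 3), 0)
})

test_that("classification matches the exhaustive two-partition oracle", {
  base <- data.frame(component = 1:10, smoothness = 0.2,
                     small_cluster_fraction = 0.1, edge_fraction = 0.1,
                     csf_fraction = 0.1, tfn_fraction = 0.2, empty = FALSE)
  f <- base
  f$edge_fraction <- c(0.65, 0.6, 0.7, rep(0.1, 7))
  cls <- sock_classify(f, seed = 1)
  expect_equal(which(cls$table$label == "artifact"), 1:3)
  expect_true(all(cls$table$reasons[1:3] == "edge"))
  expect_equal(cls$rejected_fraction, 0.3)
  # oracle: optimal SSE split flags the same members
  oc <- oracle_two_partition(f$edge_fraction)
  expect_equal(which(oc == 2L), 1:3)

  f2 <- base
  f2$tfn_fraction <- c(rep(0.2, 9), 0.95)
  cls2 <- sock_classify(f2, seed = 1)
  expect_equal(cls2$rejected, 10L)
  expect_equal(cls2$table$reasons[10], "tfn")
  expect_equal(which(oracle_two_partition(f2$tfn_fraction) == 2L), 10L)
})

test_that("homogeneous features yield zero artifacts; floors gate clusters", {
  same <- data.frame(component = 1:6, smoothness = 0.5,
                     small_cluster_fraction = 0.2, edge_fraction = 0.3,
                     csf_fraction = 0.2, tfn_fraction = 0.4, empty = FALSE)
  expect_equal(length(sock_classify(same, seed = 1)$rejected), 0L)

  # clear bimodality but below the family floor -> not artifact-prone
  low <- same
  low$edge_fraction <- c(0.05, 0.05, 0.05, 0.3, 0.3, 0.3)
  expect_equal(length(sock_classify(low, seed = 1)$rejected), 0L)
})

test_that("labels are invariant to component order and to duplication", {
  f <- data.frame(component = 1:8, smoothness = 0.2,
                  small_cluster_fraction = c(rep(0.1, 6), 0.9, 0.95),
                  edge_fraction = 0.1, csf_fraction = 0.1,
                  tfn_fraction = c(rep(0.2, 4), 0.9, 0.9, 0.2, 0.2),
                  empty = FALSE)
  cls <- sock_classify(f, seed = 3)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  fp <- f[perm, ]; fp$component <- 1:8
  clsp <- sock_classify(fp, seed = 3)
  expect_equal(clsp$table$label, cls$table$label[perm])

  # duplicating an unlikely-artifact component flips no existing label
  dup <- rbind(f, f[1, ]); dup$component <- 1:9
  clsd <- sock_classify(dup, seed = 3)
  expect_equal(clsd$table$label[1:8], cls$table$label)
})

test_that("fewer than 3 components falls back to absolute floors", {
  f <- data.frame(component = 1:2, smoothness = c(0.2, 1.4),
                  small_cluster_fraction = c(0.1, 0.2),
                  edge_fraction = c(0.1, 0.55), csf_fraction = c(0.1, 0.1),
                  tfn_fraction = c(0.2, 0.3), empty = FALSE)
  cls <- sock_classify(f, seed = 1)
  expect_equal(cls$table$label, c("unlikely_artifact", "artifact"))
  expect_true(grepl("edge", cls$table$reasons[2]))
  expect_true(grepl("smoothness", cls$table$reasons[2]))
})

test_that("classification report round-trips through files", {
  f <- data.frame(component = 1:4, smoothness = 0.2,
                  small_cluster_fraction = 0.1,
                  edge_fraction = c(0.8, 0.8, 0.1, 0.1), csf_fraction = 0.1,
                  tfn_fraction = 0.2, empty = FALSE)
  cls <- sock_classify(f, seed = 1)
  d <- file.path(tempdir(), "sock_out")
  write_classification(cls, f, d)
  rej <- as.integer(readLines(file.path(d, "rejected.txt")))
  expect_equal(rej, cls$rejected)
  tab <- utils::read.table(file.path(d, "classification.tsv"), header = TRUE,
                           sep = "\t")
  expect_equal(tab$label, cls$table$label)
})
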