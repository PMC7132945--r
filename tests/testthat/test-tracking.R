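# Deterministic tracking: seeding, propagation, termination rules.

test_that("supersampled seeding emits k^3 points per voxel", {
  dims <- c(5, 5, 5)
  aff <- diag(c(1.25, 1.25, 1.25, 1))
  m1 <- one_voxel_mask(dims, c(2, 2, 2))
  expect_equal(nrow(seed_points(m1, aff, k = 4)), 64)
  s1 <- seed_points(m1, aff, k = 1)
  expect_equal(nrow(s1), 1)
  expect_equal(s1[1, ], voxel_to_world(c(2, 2, 2), aff)[1, ],
               ignore_attr = TRUE)
})

test_that("all seed points lie inside their voxel bounds", {
  dims <- c(6, 4, 3)
  aff <- diag(c(2, 2, 2, 1))
  m <- array(FALSE, dims); m[sample(length(m), 10)] <- TRUE
  pts <- seed_points(m, aff, k = 2)
  expect_equal(nrow(pts), 80)
  ijk <- world_to_voxel(pts, aff)
  nearest <- round(ijk)
  expect_true(all(abs(ijk - nearest) <= 0.5 + 1e-12))
  expect_true(all(m[cbind(nearest[, 1], nearest[, 2], nearest[, 3]) + 1]))
})

test_that("empty seed masks warn and return nothing", {
  expect_warning(p <- seed_points(array(FALSE, c(3, 3, 3)), diag(4)),
                 "empty seed mask")
  expect_equal(nrow(p), 0)
})

test_that("a straight corridor is tracked end to end", {
  f <- corridor_field(nx = 20)
  params <- tracking_params(step_size_mm = 0.5, max_length_mm = 100)
  start <- c(12, 3, 3)  # mid-corridor, world mm (voxel size 1)
  s <- propagate_streamline(f, start, params)
  expect_true(is.matrix(s))
  # corridor spans voxels x = 2..21 (0-based); ends within one step
  expect_lt(min(s[, 1]), 2 - 0.5 + 1e-9 + 1)
  expect_gt(max(s[, 1]), 21 - 1 + 0.5 - 1e-9 - 1)
  expect_equal(unique(round(s[, 2], 9)), 3)
})

test_that("a 90-degree elbow terminates under a 60-degree threshold", {
  f <- elbow_field(arm = 10)
  params <- tracking_params(step_size_mm = 0.5, max_length_mm = 100)
  s <- propagate_streamline(f, c(4, 2, 2), params)
  expect_true(is.matrix(s))
  # never enters the orthogonal (+y) limb
  expect_lt(max(s[, 2]), 2.5 + 1e-9)
  # but does reach the elbow region
  expect_gt(max(s[, 1]), 10)
})

test_that("the nearest peak wins at a crossing", {
  dims <- c(9, 5, 5)
  peaks <- array(0, c(dims, 2, 3))
  amps <- array(0, c(dims, 2))
  # single-peak (+x) seed voxel, then a corridor whose voxels carry both a
  # 0-degree and a 70-degree peak -- the 70-degree one with the LARGER
  # amplitude, so only the minimum-turning-angle rule can keep the track
  # straight
  d70 <- c(cos(70 * pi / 180), sin(70 * pi / 180), 0)
  peaks[3, 3, 3, 1, ] <- c(1, 0, 0)
  amps[3, 3, 3, 1] <- 0.5
  for (i in 4:8) {
    peaks[i, 3, 3, 1, ] <- c(1, 0, 0)
    peaks[i, 3, 3, 2, ] <- d70
    amps[i, 3, 3, 1] <- 0.5
    amps[i, 3, 3, 2] <- 0.9
  }
  f <- orientation_field(peaks, amps, diag(4))
  params <- tracking_params(step_size_mm = 0.5, max_length_mm = 50,
                            angle_threshold_deg = 60)
  s <- propagate_streamline(f, c(2, 2, 2), params)
  # after the first step every move follows the 0-degree peak, never the
  # 70-degree one (70 > 60 would also violate the threshold)
  expect_true(all(abs(diff(s[, 2])) < 1e-9))
  expect_gt(nrow(s), 5)
})

test_that("tracking is deterministic and respects step/angle invariants", {
  ph <- shared_phantom()
  tr <- ph$truth
  params <- tracking_params(step_size_mm = 0.5)
  t1 <- suppressWarnings(track_from_mask(ph$field, tr$rois$seed_left$mask,
                                         params))
  t2 <- suppressWarnings(track_from_mask(ph$field, tr$rois$seed_left$mask,
                                         params))
  expect_identical(t1$streamlines, t2$streamlines)
  expect_gt(length(t1$streamlines), 0)
  for (s in t1$streamlines[seq(1, length(t1$streamlines), length.out = 50)]) {
    gaps <- sqrt(rowSums(diff(s)^2))
    expect_true(all(abs(gaps - 0.5) < 1e-6))
    expect_true(all(turning_angles(s) <= 60 + 1e-6))
  }
})

test_that("seeds in isotropic background are rejected out of support", {
  ph <- shared_phantom()
  tr <- ph$truth
  bg <- array(FALSE, tr$grid_shape)
  bg[4:6, 4:6, 4:6] <- TRUE   # far corner: isotropic brain
  params <- tracking_params()
  expect_warning(t <- track_from_mask(ph$field, bg, params),
                 "no streamlines")
  expect_length(t$streamlines, 0)
  expect_equal(unname(attr(t, "rejections")["out_of_support"]), 27L * 64L)
})

test_that("bundle-interior seeds stay on the bundle (no drift)", {
  ph <- shared_phantom()
  tr <- ph$truth
  cl <- tr$centerlines$dhc
  params <- tracking_params(step_size_mm = 0.5, supersample_per_axis = 1L)
  vx <- 1.25
  # voxels within one voxel of the centerline; restrict to voxels carrying
  # only the commissural bundle's peak (where another bundle overlaps, the
  # largest-amplitude rule legitimately starts the track on that bundle)
  pure <- tr$bundle_masks$dhc & !tr$bundle_masks$fornix_decoy &
    !tr$bundle_masks$ac
  dhc_vox <- which(pure, arr.ind = TRUE) - 1
  ww <- voxel_to_world(dhc_vox, tr$affine)
  d2cl <- function(p) sqrt(min(colSums((t(cl) - p)^2)))
  dist0 <- apply(ww, 1, d2cl)
  near <- ww[dist0 <= vx / 2, , drop = FALSE]
  set.seed(5)
  near <- near[sample(nrow(near), min(40, nrow(near))), ]
  ok <- 0
  for (i in seq_len(nrow(near))) {
    s <- propagate_streamline(ph$field, near[i, ], params)
    if (!is.matrix(s)) next
    mean_dist <- mean(apply(s, 1, d2cl))
    if (mean_dist <= vx) ok <- ok + 1
  }
  expect_gte(ok / nrow(near), 0.9)
  # drift bound for seeds anywhere in the pure-bundle interior: the mean
  # distance to the centerline exceeds the seed's own offset by well under
  # a voxel (the parallel peak field transports the offset, it cannot
  # recentre a track)
  interior <- ww[dist0 <= max(dist0) - vx, , drop = FALSE]
  dist_int <- dist0[dist0 <= max(dist0) - vx]
  idx <- sample(nrow(interior), 40)
  for (i in idx) {
    s <- propagate_streamline(ph$field, interior[i, ], params)
    if (!is.matrix(s)) next
    drift <- mean(apply(s, 1, d2cl)) - dist_int[i]
    expect_lt(drift, 0.75 * vx)
  }
})
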