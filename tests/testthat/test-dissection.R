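# ROI rasterization, boolean gating, bilateral orchestration, segment
# cutting.

test_that("slab ROIs rasterize to the declared plane", {
  aff <- diag(4)
  spec <- roi_spec("s10", "NOT", slab = list(axis = "sagittal", slice = 10))
  m <- rasterize_roi(spec, c(20, 8, 8), aff)
  hit <- which(m, arr.ind = TRUE)
  expect_true(all(hit[, 1] == 11))            # 0-based slice 10
  expect_equal(nrow(hit), 8 * 8)
  # mm-offset flavour resolves to the same slice
  spec_mm <- roi_spec("s10mm", "NOT", slab = list(axis = "sagittal",
                                                  mm = 10))
  expect_identical(rasterize_roi(spec_mm, c(20, 8, 8), aff), m)
  expect_error(rasterize_roi(
    roi_spec("off", "NOT", slab = list(axis = "axial", slice = 30)),
    c(20, 8, 8), aff), "outside grid")
})

test_that("carve-out slabs equal the plane minus the boxes, voxel by voxel", {
  aff <- diag(4)
  dims <- c(10, 12, 10)
  box1 <- rbind(c(0, 3), c(0, 11), c(0, 4))
  box2 <- rbind(c(7, 9), c(0, 11), c(0, 4))
  spec <- roi_spec("coronal_cut", "NOT",
                   slab = list(axis = "coronal", slice = 6,
                               carve_out = list(box1, box2)))
  m <- rasterize_roi(spec, dims, aff)
  # independent set-algebra oracle
  oracle <- array(FALSE, dims)
  oracle[, 7, ] <- TRUE
  oracle[1:4, , 1:5] <- FALSE
  oracle[8:10, , 1:5] <- FALSE
  expect_identical(m, oracle)
})

test_that("a carve-out covering the whole plane is rejected", {
  spec <- roi_spec("empty", "NOT",
                   slab = list(axis = "axial", slice = 2,
                               carve_out = list(rbind(c(0, 9), c(0, 9),
                                                      c(0, 9)))))
  expect_error(rasterize_roi(spec, c(10, 10, 10), diag(4)),
               "empty mask")
})

test_that("gating keeps exactly the AND-and-not-NOT streamlines", {
  aff <- diag(4)
  dims <- c(12, 6, 6)
  and_mask <- array(FALSE, dims); and_mask[10:12, , ] <- TRUE
  not_mask <- array(FALSE, dims); not_mask[6, , ] <- TRUE
  gates <- list(ands = list(roi_spec("a", "AND", mask = and_mask)),
                nots = list(roi_spec("n", "NOT", mask = not_mask)))
  # exhaustive truth table: crosses AND? x touches NOT?
  sl <- list(
    and_yes_not_yes = line_streamline(c(0, 2, 2), c(11, 2, 2), 24),
    and_yes_not_no  = line_streamline(c(8, 2, 2), c(11, 2, 2), 8),
    and_no_not_yes  = line_streamline(c(0, 2, 2), c(7, 2, 2), 16),
    and_no_not_no   = line_streamline(c(0, 2, 2), c(3, 2, 2), 8))
  t <- tractogram(unname(sl), aff)
  kept <- filter_by_gates(t, gates)
  expect_length(kept$streamlines, 1)
  expect_equal(kept$streamlines[[1]], sl$and_yes_not_no, ignore_attr = TRUE)
})

test_that("gating is idempotent and monotone", {
  ph <- shared_phantom()
  tr <- ph$truth
  params <- tracking_params()
  raw <- track_from_mask(ph$field, tr$rois$seed_left$mask, params)
  gates <- list(ands = list(roi_spec("a", "AND",
                                     mask = tr$rois$and_right$mask)),
                nots = tr$protocols$dhc$nots)
  g1 <- filter_by_gates(raw, gates)
  g2 <- filter_by_gates(g1, gates)
  expect_identical(g1$streamlines, g2$streamlines)
  # adding a NOT can only shrink the survivor set
  extra_not <- roi_spec("x", "NOT", mask = tr$bundle_masks$fornix_decoy)
  g3 <- filter_by_gates(raw, list(ands = gates$ands,
                                  nots = c(gates$nots, list(extra_not))))
  expect_lte(length(g3$streamlines), length(g1$streamlines))
  # adding an AND can only shrink it too
  g4 <- filter_by_gates(raw, list(
    ands = c(gates$ands, list(roi_spec("b", "AND",
                                       mask = tr$rois$seed_left$mask))),
    nots = gates$nots))
  expect_lte(length(g4$streamlines), length(g1$streamlines))
})

test_that("the commissural protocol succeeds bilaterally and kills the decoy", {
  ph <- shared_phantom()
  tr <- ph$truth
  params <- tracking_params()
  rec <- run_bilateral_protocol(ph$field, tr$protocols$dhc, params)
  expect_false(rec$failed)
  expect_gt(length(rec$left$streamlines), 0)
  expect_gt(length(rec$right$streamlines), 0)
  # no survivor ventures into decoy-exclusive territory
  dec_only <- tr$bundle_masks$fornix_decoy & !tr$bundle_masks$dhc
  for (t in list(rec$left, rec$right)) {
    hits <- vapply(t$streamlines, function(s) {
      any(dissectr:::vertices_in_mask(s, dec_only, t$space$affine))
    }, logical(1))
    expect_equal(sum(hits), 0)
  }
})

test_that("the mirrored straight-commissure protocol is side-symmetric", {
  ph <- shared_phantom()
  params <- tracking_params()
  rec <- run_bilateral_protocol(ph$field, ph$truth$protocols$ac, params)
  nl <- length(rec$left$streamlines); nr <- length(rec$right$streamlines)
  expect_gt(nl, 0)
  expect_lt(abs(nl - nr) / max(nl, nr), 0.1)
  # survivors cross the midline
  mid <- ph$truth$midline_mm
  crossers <- vapply(rec$left$streamlines, function(s) {
    min(s[, 1]) < mid && max(s[, 1]) > mid
  }, logical(1))
  expect_true(all(crossers))
})

test_that("segment cutting keeps exactly the strictly-between runs", {
  aff <- diag(c(1.25, 1.25, 1.25, 1))
  # straight streamline along x with vertices at integer mm; planes at
  # +/- 5 slices (6.25 mm) about x = 0
  s <- cbind(seq(-20, 20, by = 1), 0, 0)
  t <- dissectr:::tractogram_allow(list(s), aff)
  seg <- cut_segment(t, c(-6.25, 6.25), "L2R")
  expect_length(seg$runs, 1)
  kept_x <- seg$runs[[1]][, 1]
  expect_equal(kept_x, seq(-6, 6, by = 1))  # enumeration oracle
  expect_equal(seg$n, 13)
  # endpoints outside the slab are discarded, inside ones survive intact
  inside_only <- cbind(seq(-3, 3, by = 1), 1, 1)
  t2 <- dissectr:::tractogram_allow(list(inside_only), aff)
  expect_equal(cut_segment(t2, c(-6.25, 6.25))$n, 7)
  # entirely outside contributes nothing
  outside <- cbind(seq(10, 20, by = 1), 0, 0)
  t3 <- dissectr:::tractogram_allow(list(outside), aff)
  expect_equal(cut_segment(t3, c(-6.25, 6.25))$n, 0)
  expect_error(cut_segment(t, c(6.25, -6.25)), "increasing")
})

test_that("a streamline weaving across a plane yields multiple runs", {
  aff <- diag(4)
  x <- c(-8, -4, 0, 4, 8, 4, 0, -4, -8)
  s <- cbind(x, 0, 0)
  t <- dissectr:::tractogram_allow(list(s), aff)
  seg <- cut_segment(t, c(-5, 5))
  expect_length(seg$runs, 2)
  expect_equal(seg$n, 6)
  # segment vertices are a subset of the original vertices
  expect_true(all(do.call(rbind, seg$runs)[, 1] %in% x))
})

test_that("survivors cross the midline where the true arc does", {
  ph <- shared_phantom()
  tr <- ph$truth
  params <- tracking_params()
  rec <- run_bilateral_protocol(ph$field, tr$protocols$dhc, params)
  mid <- tr$midline_mm
  cl <- tr$centerlines$dhc
  true_yz <- cl[which.min(abs(cl[, 1] - mid)), 2:3]
  cross_yz <- t(vapply(rec$left$streamlines, function(s) {
    s[which.min(abs(s[, 1] - mid)), 2:3]
  }, numeric(2)))
  mean_dev <- sqrt(sum((colMeans(cross_yz) - true_yz)^2))
  expect_lt(mean_dev, 1.25)  # within one voxel
})

test_that("protocol construction validates roles and cut planes", {
  m <- array(TRUE, c(4, 4, 4))
  seed <- roi_spec("s", "SEED", mask = m)
  and <- roi_spec("a", "AND", mask = m)
  expect_error(gate_protocol("p", seed, list(and), cut_planes = c(1, 2),
                             midline_mm = 5), "straddle")
  expect_s3_class(gate_protocol("p", seed, list(and),
                                cut_planes = c(-2, 2), midline_mm = 0),
                  "gate_protocol")
  expect_error(roi_spec("bad", "SEED"), "exactly one")
})
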