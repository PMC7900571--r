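test_that("1-D stack bone|cartilage|background classifies inner and outer", {
  # a column: bone in x 1..6, cartilage 7..10, background 11..16
  d <- c(16L, 5L, 5L); sp <- c(1, 1, 1)
  arr <- array(0L, d)
  arr[1:6, 3, 3] <- 1L
  arr[7:10, 3, 3] <- 4L
  vol <- label_volume(arr, sp, c(femur = 1L, femoral_cartilage = 4L))
  bp <- cartilage_thickness(vol, "femur", "femoral_cartilage")
  # the cartilage voxel adjacent to bone is inner; adjacent to background outer
  expect_true(any(bp$inner[, 1] == 7))
  expect_true(any(bp$outer[, 1] == 10))
  expect_false(any(bp$outer[, 1] == 7))
  expect_false(any(bp$inner[, 1] == 10))
})

test_that("annulus boundary classification is >= 95% correct vs radial truth", {
  ph <- annulus_phantom(10, 3)
  bp <- cartilage_thickness(ph$volume, "femur", "femoral_cartilage")
  sp <- ph$volume$spacing_mm
  rin <- sqrt(((bp$inner[, 1] - ph$center_vox[1]) * sp[1])^2 +
                ((bp$inner[, 2] - ph$center_vox[2]) * sp[2])^2)
  rout <- sqrt(((bp$outer[, 1] - ph$center_vox[1]) * sp[1])^2 +
                 ((bp$outer[, 2] - ph$center_vox[2]) * sp[2])^2)
  mid <- 10 + 3 / 2
  correct <- sum(rin < mid) + sum(rout > mid)
  expect_gte(correct / (length(rin) + length(rout)), 0.95)
})

test_that("floating shell (no bone contact) still partitions by bone-facing direction", {
  # cartilage annulus nowhere adjacent to its bone (core shrunk to leave a
  # gap): the classifier must still partition every boundary voxel, with
  # the ring facing the bone inner and the articular ring outer -- the
  # dot-product sign depends on facing direction, not on contact
  d <- c(41L, 41L, 5L); sp <- c(1, 1, 2)
  idx <- arrayInd(seq_len(prod(d)), d)
  r <- sqrt(((idx[, 1] - 21) * sp[1])^2 + ((idx[, 2] - 21) * sp[2])^2)
  arr <- array(0L, d)
  arr[r < 5] <- 1L                      # bone core
  arr[r >= 9 & r < 12] <- 4L            # shell separated by a 4 mm gap
  vol <- label_volume(arr, sp, c(femur = 1L, femoral_cartilage = 4L))
  cm <- label_mask(vol, "femoral_cartilage")
  bm <- label_mask(vol, "femur")
  bp <- classify_boundary(signed_distance(bm), signed_distance(cm), cm,
                          bone_mask = bm)
  nb <- sum(carthick:::boundary_voxels(cm$voxels))
  expect_equal(nrow(bp$inner) + nrow(bp$outer), nb)
  rin <- r[cbind(bp$inner[, 1] + (bp$inner[, 2] - 1) * d[1] +
                   (bp$inner[, 3] - 1) * d[1] * d[2])]
  rout <- r[cbind(bp$outer[, 1] + (bp$outer[, 2] - 1) * d[1] +
                    (bp$outer[, 3] - 1) * d[1] * d[2])]
  expect_gt((sum(rin < 10.5) + sum(rout > 10.5)) /
              (length(rin) + length(rout)), 0.95)
})

test_that("every cartilage boundary voxel lands in exactly one of inner/outer", {
  ph <- annulus_phantom(8, 2.5)
  cm <- label_mask(ph$volume, "femoral_cartilage")
  bm <- label_mask(ph$volume, "femur")
  bp <- classify_boundary(signed_distance(bm), signed_distance(cm), cm,
                          bone_mask = bm)
  nb <- sum(carthick:::boundary_voxels(cm$voxels))
  expect_equal(nrow(bp$inner) + nrow(bp$outer), nb)
  # disjoint
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  expect_length(intersect(key(bp$inner), key(bp$outer)), 0)
})

test_that("thickness via distance map equals brute-force nearest outer point", {
  ph <- annulus_phantom(6, 2, spacing_mm = c(0.8, 0.8, 2), n_slices = 4)
  bp <- cartilage_thickness(ph$volume, "femur", "femoral_cartilage")
  oracle <- brute_nearest_outer(bp$inner, bp$outer, ph$volume$spacing_mm)
  expect_equal(bp$thickness_mm, oracle, tolerance = 1e-12)
})

test_that("calibration annuli recover true thickness within one in-plane voxel", {
  for (t in c(1.5, 2, 3, 4)) {
    ph <- annulus_phantom(10, t)
    bp <- cartilage_thickness(ph$volume, "femur", "femoral_cartilage")
    expect_lt(abs(mean(bp$thickness_mm) - t), max(0.5, 0.05 * t),
              label = sprintf("recovered %.3f for true %.1f",
                              mean(bp$thickness_mm), t))
  }
})

test_that("doubling the true shell width doubles recovered thickness", {
  t1 <- mean(cartilage_thickness(annulus_phantom(10, 1.5)$volume,
                                 "femur", "femoral_cartilage")$thickness_mm)
  t2 <- mean(cartilage_thickness(annulus_phantom(10, 3)$volume,
                                 "femur", "femoral_cartilage")$thickness_mm)
  expect_lt(abs(t2 - 2 * t1), 2 * 0.5)
})

test_that("one-voxel shell thickness is bounded by the voxel diagonal", {
  d <- c(20L, 20L, 5L); sp <- c(1, 1, 1)
  idx <- arrayInd(seq_len(prod(d)), d)
  r <- sqrt((idx[, 1] - 10.5)^2 + (idx[, 2] - 10.5)^2)
  arr <- array(0L, d)
  arr[r < 6] <- 1L
  arr[r >= 6 & r < 7] <- 4L
  vol <- label_volume(arr, sp, c(femur = 1L, femoral_cartilage = 4L))
  bp <- cartilage_thickness(vol, "femur", "femoral_cartilage")
  expect_lte(max(bp$thickness_mm), sqrt(3) + 1e-9)
})

test_that("thickness is invariant to bone label identity and 90-degree rotation", {
  ph <- annulus_phantom(8, 2, spacing_mm = c(0.5, 0.5, 0.5), n_slices = 6)
  v <- ph$volume
  m1 <- mean(cartilage_thickness(v, "femur", "femoral_cartilage")$thickness_mm)
  # relabel the bone as tibia (code change only)
  arr2 <- v$data
  arr2[arr2 == 1L] <- 2L
  arr2[arr2 == 4L] <- 5L
  v2 <- label_volume(arr2, v$spacing_mm,
                     c(tibia = 2L, tibial_cartilage = 5L))
  m2 <- mean(cartilage_thickness(v2, "tibia", "tibial_cartilage")$thickness_mm)
  expect_identical(m1, m2)
  # rotate the grid 90 degrees in-plane (isotropic spacing so rigid)
  arr3 <- aperm(v$data, c(2, 1, 3))[dim(v$data)[2]:1, , ]
  v3 <- label_volume(arr3, v$spacing_mm, v$codes)
  m3 <- mean(cartilage_thickness(v3, "femur", "femoral_cartilage")$thickness_mm)
  expect_lt(abs(m3 - m1), 0.5)
})

test_that("sector-wise thickness profile is recovered region by region", {
  prof <- function(th) ifelse(abs(th) < pi / 2, 2, 1.5)
  ph <- annulus_phantom(10, prof)
  bp <- cartilage_thickness(ph$volume, "femur", "femoral_cartilage")
  sp <- ph$volume$spacing_mm
  ang <- atan2((bp$inner[, 2] - ph$center_vox[2]) * sp[2],
               (bp$inner[, 1] - ph$center_vox[1]) * sp[1])
  # keep clear of the profile step so the sector truth is unambiguous
  ant <- abs(ang) < pi / 2 - 0.15
  post <- abs(ang) > pi / 2 + 0.15
  expect_lt(abs(mean(bp$thickness_mm[ant]) - 2), 0.5)
  expect_lt(abs(mean(bp$thickness_mm[post]) - 1.5), 0.5)
})

test_that("per_region_thickness averages per region and reports missing", {
  ph <- annulus_phantom(10, 2)
  bp <- cartilage_thickness(ph$volume, "femur", "femoral_cartilage")
  n <- nrow(bp$inner)
  asg <- rep("FMA", n)
  out <- per_region_thickness(bp, asg)
  expect_equal(unname(out["FMA"]), mean(bp$thickness_mm))
  expect_true(all(is.na(out[setdiff(worms_regions, "FMA")])))
  # two-region arithmetic: {1,3} and {2}
  bp2 <- bp
  bp2$inner <- bp$inner[1:3, , drop = FALSE]
  bp2$thickness_mm <- c(1, 3, 2)
  out2 <- per_region_thickness(bp2, c("FMA", "FMA", "FMC"))
  expect_equal(unname(out2[c("FMA", "FMC")]), c(2, 2))
  expect_error(per_region_thickness(bp2, rep(NA_character_, 3)), "unassigned")
})

test_that("empty outer set errors as degenerate cartilage", {
  ph <- annulus_phantom(10, 2)
  cm <- label_mask(ph$volume, "femoral_cartilage")
  bm <- label_mask(ph$volume, "femur")
  bp <- classify_boundary(signed_distance(bm), signed_distance(cm), cm,
                          bone_mask = bm)
  bp$outer <- bp$outer[0, , drop = FALSE]
  expect_error(thickness_at_inner_points(bp), "degenerate")
})
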