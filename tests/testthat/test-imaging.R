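test_that("EDF picks the single textured plane pixel-for-pixel", {
  set.seed(1)
  tex <- matrix(runif(40 * 40), 40)
  vox <- array(0.5, c(40, 40, 4))
  vox[, , 3] <- tex
  stk <- image_stack(vox, pixel_size = 2, z_step = 50)
  out <- edf_project(stk, kernel_width = 8)
  expect_equal(out$pixels, tex)
})

test_that("EDF stitches a two-focus stack", {
  set.seed(2)
  sharp <- matrix(runif(40 * 60), 40)
  vox <- array(0.5, c(40, 60, 2))
  vox[, 1:30, 1] <- sharp[, 1:30]   # left half in focus at z = 0
  vox[, 31:60, 2] <- sharp[, 31:60] # right half in focus at z = 1
  stk <- image_stack(vox, pixel_size = 2, z_step = 50)
  out <- edf_project(stk, kernel_width = 8)
  # away from the seam the projection equals the sharp mosaic
  expect_equal(out$pixels[, 1:26], sharp[, 1:26])
  expect_equal(out$pixels[, 35:60], sharp[, 35:60])
})

test_that("EDF tie-break and single-plane idempotence", {
  vox <- array(0.3, c(10, 10, 3))
  vox[, , 2] <- 0.7  # constant planes: zero variance everywhere
  stk <- image_stack(vox, pixel_size = 1, z_step = 10)
  expect_equal(edf_project(stk)$pixels, vox[, , 1])  # lowest-z convention

  one <- matrix(runif(25), 5)
  stk1 <- image_stack(one, pixel_size = 1, z_step = 10)
  expect_equal(edf_project(stk1)$pixels, one)
})

test_that("segmentation: uniform disk is all bulk, spicule becomes protrusion", {
  ps <- 2
  disk <- disk_image(100, 100, 50, 50, 30)  # 60 um radius at 2 um/px
  img <- projected_image(disk, pixel_size = ps)
  mask <- segment_classes(img, intensity_threshold = 0.5, opening_radius = 15)
  expect_equal(sum(mask$labels == 2L), 0)
  expect_gt(sum(mask$labels == 1L), 0.95 * sum(disk))

  # attach a 5 um-wide, 80 um-long spicule
  withspic <- disk
  withspic[49:50, 50:90] <- 1  # ~4 um wide, extends to 80 um beyond centre
  m2 <- segment_classes(projected_image(withspic, ps),
                        intensity_threshold = 0.5, opening_radius = 15)
  spic_px <- withspic == 1 & disk == 0
  expect_gt(sum(m2$labels[spic_px] == 2L) / sum(spic_px), 0.9)
  # free-floating debris (thin, detached) stays background
  deb <- disk
  deb[5:6, 5:20] <- 1
  m3 <- segment_classes(projected_image(deb, ps),
                        intensity_threshold = 0.5, opening_radius = 15)
  expect_true(all(m3$labels[5:6, 5:20] == 0L))
})

test_that("segmentation degenerate inputs and partition property", {
  blank <- projected_image(matrix(0, 20, 20), 1)
  expect_true(all(segment_classes(blank)$labels == 0L))

  set.seed(3)
  noisy <- projected_image(matrix(runif(900), 30), 1)
  m <- segment_classes(noisy)
  expect_true(all(m$labels %in% 0:2))  # classes partition the frame
  expect_equal(sum(m$labels == 0) + sum(m$labels == 1) + sum(m$labels == 2),
               900)
})

test_that("small-object filter applies the equivalent-radius cutoff inclusively", {
  ps <- 2
  # equivalent radii ~30 and ~60 um
  m <- disk_image(200, 200, c(50, 130), c(50, 120), c(15, 30))
  mask <- class_mask(matrix(as.integer(m), 200, 200), ps)
  kept <- filter_small(mask, min_radius = 50)
  expect_equal(count_objects(kept), 1L)

  # a component of exactly 50 um equivalent radius is kept
  area_px <- ceiling(pi * 50^2 / ps^2)
  side <- floor(sqrt(area_px))
  sq <- matrix(0L, 80, 80)
  sq[1:side, 1:side] <- 1L
  extra <- area_px - side^2
  if (extra > 0) sq[side + 1, seq_len(extra)] <- 1L
  stopifnot(sum(sq) == area_px)
  m50 <- class_mask(sq, ps)
  expect_equal(count_objects(filter_small(m50, 50)), 1L)
})

test_that("small-object filter agrees with a flood-fill area oracle", {
  set.seed(7)
  for (rep in 1:5) {
    m <- matrix(0L, 80, 80)
    for (b in 1:8) {
      cy <- sample(10:70, 1); cx <- sample(10:70, 1); r <- sample(2:9, 1)
      m <- pmax(m, disk_image(80, 80, cy, cx, r))
    }
    mask <- class_mask(matrix(as.integer(m), 80, 80), pixel_size = 3)
    cut <- 15  # um
    filtered <- filter_small(mask, cut)
    areas <- flood_fill_areas(m > 0)
    expected_kept <- sum(sqrt(areas * 9 / pi) >= cut)
    expect_equal(count_objects(filtered), expected_kept)
  }
})

test_that("filter_small is idempotent and monotone in min_radius", {
  set.seed(8)
  m <- matrix(0L, 60, 60)
  for (b in 1:6) {
    m <- pmax(m, disk_image(60, 60, sample(8:52, 1), sample(8:52, 1),
                            sample(2:8, 1)))
  }
  mask <- class_mask(matrix(as.integer(m), 60, 60), 2)
  f1 <- filter_small(mask, 8)
  expect_identical(filter_small(f1, 8)$labels, f1$labels)
  counts <- vapply(c(0, 4, 8, 12, 16, 20), function(r) {
    count_objects(filter_small(mask, r))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("object counting equals the flood-fill oracle on random blob sets", {
  expect_equal(count_objects(class_mask(matrix(as.integer(
    disk_image(60, 60, c(20, 42), c(20, 42), c(8, 8))), 60, 60), 1)), 2L)
  expect_equal(count_objects(class_mask(matrix(as.integer(
    disk_image(60, 60, c(30, 36), c(30, 36), c(8, 8))), 60, 60), 1)), 1L)

  set.seed(11)
  for (rep in 1:100) {
    m <- matrix(rbinom(400, 1, runif(1, 0.2, 0.5)), 20, 20)
    mask <- class_mask(matrix(as.integer(m), 20, 20), 1)
    expect_equal(count_objects(mask), flood_fill_count(m > 0))
  }
})

test_that("diagonally touching pixels are one 8-connected object", {
  m <- matrix(0L, 5, 5)
  m[1, 1] <- 1L; m[2, 2] <- 1L; m[3, 3] <- 1L
  expect_equal(count_objects(class_mask(m, 1)), 1L)
})

test_that("total area and protrusive ratio are pixel arithmetic", {
  full <- class_mask(matrix(1L, 100, 100), 2)
  expect_equal(total_area(full), 40000)
  blank <- class_mask(matrix(0L, 10, 10), 2)
  expect_equal(total_area(blank), 0)

  lab <- matrix(0L, 50, 50)
  lab[1:20, 1:20] <- 1L
  lab[1:5, 11:50] <- 2L  # 200 px protrusion
  mask <- class_mask(lab, pixel_size = sqrt(10))  # 10 um^2 / px
  expect_equal(protrusive_ratio(mask, reference_area = 10000), 0.2)
  expect_equal(protrusive_ratio(class_mask(matrix(1L, 5, 5), 1), 100), 0)
  expect_error(protrusive_ratio(mask, 0), "positive")
})

test_that("object_table reports areas, equivalent radii and centroids", {
  m <- disk_image(80, 80, c(25, 60), c(25, 60), c(10, 5))
  tab <- object_table(class_mask(matrix(as.integer(m), 80, 80), 2))
  tab <- tab[order(tab$area_um2, decreasing = TRUE), ]
  expect_equal(nrow(tab), 2)
  expect_equal(tab$equiv_radius_um, sqrt(tab$area_um2 / pi))
  expect_equal(tab$centroid_y[1], 24, tolerance = 0.05)  # 0-based
  expect_equal(tab$area_um2[1], pi * 20^2, tolerance = 0.1)
})
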