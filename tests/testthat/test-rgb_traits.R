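# Green segmentation, green index, and reference-calibrated leaf area.

test_that("green segmentation recovers pure colours and synthetic truth exactly", {
  green <- rgb_image(array(rep(c(0L, 255L, 0L), each = 25), dim = c(5, 5, 3)))
  expect_true(all(unclass(segment_green(green)) == 1L))
  red <- rgb_image(array(rep(c(255L, 0L, 0L), each = 25), dim = c(5, 5, 3)))
  expect_true(all(unclass(segment_green(red)) == 0L))

  sc <- small_scene(seed = 2)
  expect_identical(unclass(segment_green(sc$rgb)),
                   unclass(sc$truth$green_mask))
})

test_that("green index is the exact foreground fraction", {
  green <- rgb_image(array(rep(c(10L, 200L, 10L), each = 16), dim = c(4, 4, 3)))
  expect_equal(green_index(green), 1)
  brown <- rgb_image(array(rep(c(120L, 85L, 60L), each = 16), dim = c(4, 4, 3)))
  expect_equal(green_index(brown), 0)

  # 10 x 10 image with exactly 37 green pixels
  a <- array(0L, dim = c(10, 10, 3))
  a[, , 1] <- 120L; a[, , 2] <- 85L; a[, , 3] <- 60L
  pick <- sample(100, 37)
  for (k in 1:3) {
    ch <- a[, , k]
    ch[pick] <- c(60L, 150L, 70L)[k]
    a[, , k] <- ch
  }
  expect_equal(green_index(rgb_image(a)), 0.37)
})

test_that("reference area reproduces the printed legacy value and scales with d^2", {
  expect_identical(reference_area(15, 3.14), 176.625)
  expect_equal(reference_area(15), pi * 7.5^2)
  expect_equal(reference_area(2, 3.14), 3.14)
  expect_error(reference_area(0), "> 0")
  expect_error(reference_area(-3), "> 0")
})

test_that("reference detection counts the disk in both modes", {
  # lone rasterized disk, radius 50
  H <- 121
  m <- matrix(0L, H, H)
  for (r in 1:H) for (c in 1:H) {
    if ((r - 61)^2 + (c - 61)^2 <= 50^2) m[r, c] <- 1L
  }
  det <- detect_reference(binary_mask(m), reference_spec(), "calibration_image")
  expect_equal(det$reference_pixels, oracle_disk_count(H, H, 61, 61, 50))

  # with a small speck removed upstream
  m2 <- m; m2[2, 2] <- 1L
  cleaned <- remove_small_objects(binary_mask(m2), 25)
  det2 <- detect_reference(cleaned, reference_spec(), "calibration_image")
  expect_equal(det2$reference_pixels, det$reference_pixels)

  # in-scene: disk picked over elongated leaf blobs by circularity
  p <- scene_params(leaves = c(rosette_leaves(3, c(70.5, 70.5), 35, 7),
                               list(list(shape = "disk", center = c(170.5, 170.5),
                                         axes = 30))))
  sc <- make_scene(p)
  mask <- remove_small_objects(median_filter(segment_green(sc$rgb)), 25)
  det3 <- detect_reference(mask, reference_spec(15), "in_scene", px_per_cm = 60 / 15)
  disk_px <- oracle_disk_count(240, 240, 170.5, 170.5, 30)
  expect_equal(det3$reference_pixels, disk_px, tolerance = 0.02)
  expect_gt(det3$circularity, 0.8)

  expect_error(detect_reference(binary_mask(matrix(0L, 4, 4)),
                                reference_spec(), "calibration_image"),
               "no components")
})

test_that("leaf area is the unit-pixel-area rule, linear in P", {
  r <- leaf_area(1000, 1000, 176.625)
  expect_identical(r$leaf_area_cm2, 176.625)
  expect_identical(leaf_area(0, 1000, 176.625)$leaf_area_cm2, 0)
  expect_error(leaf_area(10, 0, 176.625), "P1")

  # exact linearity in P at fixed P1, S1
  base <- leaf_area(1, 777, 176.625)$leaf_area_cm2
  for (P in c(2, 10, 500, 12345)) {
    expect_identical(leaf_area(P, 777, 176.625)$leaf_area_cm2, base * P)
  }

  # two disks: leaf radius 25 vs reference radius 50 -> area ratio ~ 1/4
  P1 <- oracle_disk_count(121, 121, 61, 61, 50)
  P <- oracle_disk_count(61, 61, 31, 31, 25)
  s <- leaf_area(P, P1, 176.625)
  expect_equal(s$leaf_area_cm2, 176.625 / 4, tolerance = 0.03)
})

test_that("leaf-area pipeline recovers synthetic truth within 3%", {
  sc <- make_scene(scene_params(seed = 5))
  res <- leaf_area_pipeline(sc$rgb, reference_spec(), ref_image = sc$ref_rgb)
  expect_lt(abs(res$leaf_area_cm2 - sc$truth$leaf_area_cm2) /
              sc$truth$leaf_area_cm2, 0.03)

  # zero leaves -> zero area
  empty <- make_scene(scene_params(leaves = list(), seed = 5))
  res0 <- leaf_area_pipeline(empty$rgb, reference_spec(), ref_image = empty$ref_rgb)
  expect_identical(res0$leaf_area_cm2, 0)

  # precomputed P1 shortcut agrees with detection
  res2 <- leaf_area_pipeline(sc$rgb, reference_spec(),
                             reference_pixels = res$reference_pixels)
  expect_equal(res2$leaf_area_cm2, res$leaf_area_cm2)
})

test_that("leaf area is invariant to uniform image rescaling", {
  p1 <- scene_params(seed = 9)
  p2 <- scene_params(width = 480L, height = 480L, box_center = c(240.5, 240.5),
                     box_diameter_px = 400, ref_diameter_px = 400,
                     leaves = rosette_leaves(3, c(240.5, 240.5), 80, 14),
                     seed = 9)
  a1 <- leaf_area_pipeline(make_scene(p1)$rgb, reference_spec(),
                           ref_image = make_scene(p1)$ref_rgb)$leaf_area_cm2
  sc2 <- make_scene(p2)
  a2 <- leaf_area_pipeline(sc2$rgb, reference_spec(),
                           ref_image = sc2$ref_rgb)$leaf_area_cm2
  expect_lt(abs(a2 - a1) / a1, 0.01)
})

test_that("green index is monotone non-decreasing as tau decreases", {
  sc <- small_scene(seed = 3, noise = list(rgb = 15, depth = 0, thermal = 0))
  gis <- vapply(c(60, 40, 20, 10, 0), function(tau) {
    green_index(sc$rgb, green_params(tau = tau))
  }, numeric(1))
  expect_true(all(diff(gis) >= 0))
  expect_true(all(gis >= 0 & gis <= 1))
})
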