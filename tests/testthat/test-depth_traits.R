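# Plant height: alignment, center location, patch-median depth, H = h2 - h3.

test_that("depth alignment gathers pixels per the mapping", {
  set.seed(4)
  d <- depth_image(matrix(sample(400:700, 36), 6, 6))
  expect_identical(align_depth_to_rgb(d), d)  # identity

  # horizontal flip is an involution
  H <- 6; W <- 6
  flip <- array(0L, dim = c(H, W, 2))
  flip[, , 1] <- matrix(seq_len(H), H, W)
  flip[, , 2] <- matrix(rev(seq_len(W)), H, W, byrow = TRUE)
  al <- depth_alignment(flip)
  once <- align_depth_to_rgb(d, al)
  expect_identical(unclass(align_depth_to_rgb(once, al)), unclass(d))

  # random permutation equals a brute-force per-pixel gather
  set.seed(5)
  perm <- sample(36)
  map <- array(0L, dim = c(6, 6, 2))
  map[, , 1] <- matrix((perm - 1) %% 6 + 1, 6, 6)
  map[, , 2] <- matrix((perm - 1) %/% 6 + 1, 6, 6)
  got <- unclass(align_depth_to_rgb(d, depth_alignment(map)))
  for (r in 1:6) for (c in 1:6) {
    expect_identical(got[r, c], unclass(d)[map[r, c, 1], map[r, c, 2]])
  }

  bad <- map; bad[1, 1, 1] <- 99L
  expect_error(align_depth_to_rgb(d, depth_alignment(bad)), "outside")
})

test_that("leaf center is the on-mask pixel nearest the centroid", {
  m <- matrix(0L, 21, 21)
  for (r in 1:21) for (c in 1:21) if ((r - 11)^2 + (c - 11)^2 <= 64) m[r, c] <- 1L
  lc <- locate_leaf_center(binary_mask(m))
  expect_equal(c(lc$row, lc$col), c(11, 11))

  cross <- matrix(0L, 21, 21); cross[11, ] <- 1L; cross[, 11] <- 1L
  lc2 <- locate_leaf_center(binary_mask(cross))
  expect_equal(c(lc2$row, lc2$col), c(11, 11))

  # two disjoint blobs: exhaustive distance scan oracle with row/col tie-break
  set.seed(8)
  m3 <- matrix(0L, 15, 15); m3[2:6, 2:6] <- 1L; m3[10:12, 11:13] <- 1L
  lc3 <- locate_leaf_center(binary_mask(m3))
  idx <- which(m3 == 1L)
  rows <- (idx - 1) %% 15 + 1; cols <- (idx - 1) %/% 15 + 1
  d2 <- (rows - mean(rows))^2 + (cols - mean(cols))^2
  best <- order(d2, rows, cols)[1]
  expect_equal(c(lc3$row, lc3$col), c(rows[best], cols[best]))

  expect_error(locate_leaf_center(binary_mask(matrix(0L, 3, 3))), "empty")
})

test_that("soil center is the nearest non-plant pixel, degenerating sensibly", {
  plant <- matrix(0L, 21, 21)
  for (r in 1:21) for (c in 1:21) if ((r - 11)^2 + (c - 11)^2 <= 25) plant[r, c] <- 1L
  box <- matrix(0L, 21, 21)
  for (r in 1:21) for (c in 1:21) if ((r - 11)^2 + (c - 11)^2 <= 100) box[r, c] <- 1L
  sp <- locate_soil_center(binary_mask(plant), binary_mask(box))
  d <- sqrt((sp$row - 11)^2 + (sp$col - 11)^2)
  expect_gt(d, 5)   # outside the plant
  expect_lt(d, 7)   # but adjacent to its boundary

  # empty plant -> box centroid rule
  sp2 <- locate_soil_center(binary_mask(matrix(0L, 21, 21)), binary_mask(box))
  expect_equal(c(sp2$row, sp2$col), c(11, 11))

  # plant fills the box -> no soil available
  expect_error(locate_soil_center(binary_mask(box), binary_mask(box)), "fills")
})

test_that("depth_at takes the window median of valid depths only", {
  u <- depth_image(matrix(600L, 9, 9))
  expect_equal(depth_at(u, c(5, 5)), 600)

  set.seed(12)
  m <- matrix(sample(c(0L, 490:500), 81, TRUE, prob = c(0.35, rep(1, 11))), 9, 9)
  d <- depth_image(m)
  win <- m[3:7, 3:7]
  vals <- sort(win[win > 0])
  want <- if (length(vals) %% 2 == 1) vals[(length(vals) + 1) / 2] else
    (vals[length(vals) / 2] + vals[length(vals) / 2 + 1]) / 2
  expect_equal(depth_at(d, c(5, 5), 5), want)

  expect_error(depth_at(depth_image(matrix(0L, 5, 5)), c(3, 3)), "no valid depth")
  expect_error(depth_at(u, c(50, 5)), "out of bounds")
})

test_that("plant height is the h2 - h3 difference with the printed stage values", {
  expect_equal(as.numeric(plant_height(60, 60)), 0)
  expect_equal(as.numeric(plant_height(60, 49.42)), 10.58)
  expect_equal(as.numeric(plant_height(60, 26.72)), 33.28)

  # antisymmetry under swapping the two distances
  h <- as.numeric(plant_height(58.3, 41.9))
  expect_equal(as.numeric(suppressWarnings(plant_height(41.9, 58.3))), -h)
  expect_warning(plant_height(40, 50), "below soil")
  expect_true(attr(suppressWarnings(plant_height(40, 50)), "below_soil"))
})

test_that("height pipeline recovers noise-free truth to depth quantization", {
  sc <- small_scene(seed = 4)
  hm <- plant_height_pipeline(sc$rgb, sc$depth)
  expect_s3_class(hm, "height_measurement")
  expect_equal(hm$height_cm, sc$truth$height_cm, tolerance = 0.011)  # 1 mm step
  expect_equal(hm$n_repeats, 5L)

  # zero-height plant: leaf plane at soil depth
  sc0 <- small_scene(seed = 4, camera_to_leaf_mm = 600)
  hm0 <- plant_height_pipeline(sc0$rgb, sc0$depth)
  expect_equal(hm0$height_cm, 0)
})

test_that("height is invariant under a whole-scene depth shift", {
  sc <- small_scene(seed = 6)
  h1 <- plant_height_pipeline(sc$rgb, sc$depth)$height_cm
  shifted <- depth_image(unclass(sc$depth) + 250L)
  h2 <- plant_height_pipeline(sc$rgb, shifted)$height_cm
  expect_equal(h1, h2)
})

test_that("height pipeline tolerates depth noise (seeded Monte-Carlo)", {
  errs <- vapply(1:30, function(i) {
    sc <- small_scene(seed = 300 + i, noise = list(rgb = 0, depth = 2, thermal = 0))
    hm <- plant_height_pipeline(sc$rgb, sc$depth, seed = i)
    abs(hm$height_cm - sc$truth$height_cm)
  }, numeric(1))
  expect_gte(mean(errs <= 0.3), 0.95)
})

test_that("the h1/box-height consistency residual is reported and flagged", {
  sc <- small_scene(seed = 7)
  # camera-to-ground = camera-to-soil + box height (consistent rig)
  hm <- plant_height_pipeline(sc$rgb, sc$depth, h1_cm = 60 + 12,
                              box_height_cm = 12)
  expect_lt(abs(hm$consistency_residual_cm), 1)
  expect_false(hm$consistency_flag)

  hm2 <- plant_height_pipeline(sc$rgb, sc$depth, h1_cm = 75, box_height_cm = 12)
  expect_true(hm2$consistency_flag)
})
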