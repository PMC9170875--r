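# Preprocessing operators against brute-force oracles.

test_that("median filter matches the per-pixel sort oracle and removes salt noise", {
  const <- gray_image(matrix(37L, 8, 8))
  expect_identical(unclass(median_filter(const, 3)), unclass(const))

  salt <- matrix(0L, 7, 7); salt[4, 4] <- 255L
  expect_true(all(unclass(median_filter(gray_image(salt), 3)) == 0L))

  for (seed in 1:5) {
    g <- random_gray(seed, 9)
    expect_equal(unclass(median_filter(g, 3)),
                 matrix(as.integer(round(oracle_median(unclass(g), 3))), 9, 9),
                 info = paste("seed", seed))
  }
  g <- random_gray(42, 11)
  expect_equal(unclass(median_filter(g, 5)),
               matrix(as.integer(round(oracle_median(unclass(g), 5))), 11, 11))

  expect_error(median_filter(const, 4), "odd")
  expect_error(median_filter(const, 1), "odd")
})

test_that("depth median filter excludes the invalid-zero sentinel", {
  set.seed(7)
  m <- matrix(sample(c(0L, 480:520), 81, TRUE, prob = c(0.3, rep(1, 41))), 9, 9)
  got <- unclass(median_filter(depth_image(m), 3))
  want <- round(oracle_median(m, 3, exclude_zero = TRUE))
  expect_equal(got, matrix(as.integer(want), 9, 9))

  allzero <- depth_image(matrix(0L, 5, 5))
  expect_true(all(unclass(median_filter(allzero, 3)) == 0L))
})

test_that("gray_histogram tallies every level and rejects empty input", {
  g <- gray_image(matrix(128L, 10, 10))
  h <- gray_histogram(g)
  expect_equal(unclass(h)[129], 100L)
  expect_equal(sum(unclass(h)), 100L)

  g2 <- random_gray(3, 12)
  h2 <- as.integer(gray_histogram(g2))
  tally <- vapply(0:255, function(lev) sum(unclass(g2) == lev), integer(1))
  expect_equal(h2, tally)
})

test_that("valley threshold finds the between-modes minimum and falls back to Otsu", {
  h <- integer(256); h[51] <- 100L; h[201] <- 80L  # spikes at 50 and 200
  hist <- structure(h, class = "histogram256", n_pixels = 180L)
  vt <- valley_threshold(hist)
  expect_identical(vt$method, "valley")
  expect_gt(vt$threshold, 50); expect_lt(vt$threshold, 200)
  expect_equal(vt$threshold, 125)  # midpoint of the flat zero plateau

  # constant image: no valley exists -> flagged Otsu fallback
  vt2 <- valley_threshold(gray_histogram(gray_image(matrix(99L, 6, 6))))
  expect_identical(vt2$method, "otsu_fallback")

  # unimodal histogram: fallback threshold equals the exhaustive Otsu scan
  set.seed(5)
  g <- gray_image(matrix(pmin(pmax(round(rnorm(400, 120, 10)), 0), 255), 20, 20))
  vt3 <- valley_threshold(gray_histogram(g))
  if (vt3$method == "otsu_fallback") {
    expect_equal(vt3$threshold, oracle_otsu(as.numeric(unclass(gray_histogram(g)))))
  }

  # well-separated bimodal image: thresholding classifies pixels exactly as
  # the two generating modes
  set.seed(6)
  lv <- c(sample(40:60, 200, TRUE), sample(180:220, 200, TRUE))
  g2 <- gray_image(matrix(lv, 20, 20))
  vt4 <- valley_threshold(gray_histogram(g2))
  expect_identical(vt4$method, "valley")
  expect_true(all((lv > vt4$threshold) == (lv >= 180)))
})

test_that("Otsu threshold equals the exhaustive 256-way scan", {
  h <- integer(256); h[1] <- 50L; h[256] <- 50L
  hist <- structure(h, class = "histogram256", n_pixels = 100L)
  t0 <- otsu_threshold(hist)
  expect_gte(t0, 0); expect_lt(t0, 255)

  one <- integer(256); one[101] <- 10L
  t1 <- otsu_threshold(structure(one, class = "histogram256", n_pixels = 10L))
  expect_equal(as.integer(t1), 100L)
  expect_true(attr(t1, "degenerate"))

  for (seed in 1:6) {
    set.seed(seed)
    counts <- rpois(256, lambda = runif(1, 0.1, 3))
    hist <- structure(as.integer(counts), class = "histogram256",
                      n_pixels = sum(counts))
    expect_equal(as.integer(otsu_threshold(hist)), oracle_otsu(counts),
                 info = paste("seed", seed))
  }
})

test_that("binarize matches the per-pixel comparison oracle", {
  g <- random_gray(9, 10)
  expect_true(all(unclass(binarize(g, 255, "above")) == 0L))
  expect_true(all(unclass(binarize(g, -1, "above")) == 1L))
  m <- unclass(g)
  expect_equal(unclass(binarize(g, 128, "above")), matrix(as.integer(m > 128), 10, 10))
  expect_equal(unclass(binarize(g, 128, "below")), matrix(as.integer(m < 128), 10, 10))
})

test_that("connected components agree with a BFS flood-fill oracle", {
  m <- matrix(0L, 8, 8)
  m[2:3, 2:3] <- 1L
  m[6:8, 5:7] <- 1L
  cc <- connected_components(binary_mask(m), 8)
  expect_length(cc$sizes, 2L)
  expect_setequal(cc$sizes, c(4L, 9L))
  expect_equal(sum(cc$sizes), sum(m))

  diag2 <- matrix(0L, 3, 3); diag2[1, 1] <- 1L; diag2[2, 2] <- 1L
  expect_length(connected_components(binary_mask(diag2), 8)$sizes, 1L)
  expect_length(connected_components(binary_mask(diag2), 4)$sizes, 2L)

  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(rbinom(30 * 30, 1, 0.4), 30, 30)
    for (conn in c(4, 8)) {
      got <- connected_components(binary_mask(m), conn)
      want <- oracle_flood_fill(m, conn)
      expect_true(same_partition(got$labels, want$labels),
                  info = paste("seed", seed, "conn", conn))
      expect_equal(sort(got$sizes), sort(want$sizes))
    }
  }
})

test_that("connected components agree with EBImage's 4-connected labelling", {
  skip_if_not_installed("EBImage")
  set.seed(21)
  m <- matrix(rbinom(40 * 40, 1, 0.35), 40, 40)
  got <- connected_components(binary_mask(m), 4)
  ref <- EBImage::imageData(EBImage::bwlabel(m))
  expect_true(same_partition(got$labels, ref))
})

test_that("small-object removal keeps components at exactly min_area and is monotone", {
  m <- matrix(0L, 10, 10); m[2:4, 2:4] <- 1L  # 9 px blob
  expect_true(all(unclass(remove_small_objects(binary_mask(m), 25)) == 0L))

  m25 <- matrix(0L, 10, 10); m25[1:5, 1:5] <- 1L  # exactly 25 px
  expect_equal(sum(unclass(remove_small_objects(binary_mask(m25), 25))), 25L)

  set.seed(13)
  mm <- matrix(rbinom(40 * 40, 1, 0.3), 40, 40)
  mask <- binary_mask(mm)
  for (amin in c(2, 5, 10)) {
    out <- remove_small_objects(mask, amin)
    cc <- oracle_flood_fill(mm, 8)
    keep <- which(cc$sizes >= amin)
    expect_equal(unclass(out),
                 matrix(as.integer(cc$labels %in% keep), 40, 40),
                 info = paste("min_area", amin))
    # idempotent
    expect_identical(unclass(remove_small_objects(out, amin)), unclass(out))
  }
  # monotone: larger threshold removes a superset
  a5 <- unclass(remove_small_objects(mask, 5))
  a10 <- unclass(remove_small_objects(mask, 10))
  expect_true(all(a10 <= a5))
})

test_that("histogram equalization follows the CDF remap and preserves ordering", {
  const <- gray_image(matrix(200L, 6, 6))
  expect_identical(unclass(histogram_equalize(const)), unclass(const))

  g <- random_gray(17, 16)
  eq <- histogram_equalize(g)
  # closed-form CDF remap computed independently
  v <- as.vector(unclass(g))
  cdf <- vapply(0:255, function(lev) sum(v <= lev), numeric(1))
  cdf_min <- min(cdf[cdf > 0])
  want <- round((cdf - cdf_min) / (length(v) - cdf_min) * 255)
  expect_equal(as.vector(unclass(eq)), want[v + 1])
  # weak monotonicity in input gray level
  ord <- order(v)
  expect_true(all(diff(as.vector(unclass(eq))[ord]) >= 0))
})
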