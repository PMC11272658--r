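test_that("background estimation recovers Gaussian noise parameters", {
  set.seed(21)
  ch <- matrix(rnorm(512^2, 30, 6), 512, 512)
  bg <- estimate_background(ch)
  expect_equal(bg$mean, 30, tolerance = 0.02)
  expect_equal(bg$sd, 6, tolerance = 0.02)
  # bright foreground does not drag the estimate (mode fit, not global)
  ch2 <- ch
  ch2[1:80, 1:80] <- 220
  bg2 <- estimate_background(ch2)
  expect_equal(bg2$method, "mode_fit")
  expect_equal(bg2$mean, 30, tolerance = 0.05)
  expect_equal(bg2$sd, 6, tolerance = 0.05)
})

test_that("thresholding keeps ~99.995% of a pure Gaussian background", {
  set.seed(22)
  ch <- matrix(rnorm(512^2, 25, 8), 512, 512)
  mask <- gaussian_background_threshold(ch)
  frac <- mean(mask)
  expect_lt(frac, 3e-4)          # retention above 99.97% even at 512^2
  expect_gt(mean(!mask), 0.9997)
})

test_that("degenerate images threshold to an empty mask", {
  z <- matrix(0, 32, 32)
  expect_false(any(gaussian_background_threshold(z)))
  expect_false(any(gaussian_background_threshold(matrix(7, 16, 16))))
})

test_that("thresholding recovers ground-truth bright ellipses", {
  set.seed(23)
  ch <- matrix(rnorm(300 * 300, 20, 8), 300, 300)
  gt <- draw_ellipse_mask(300, 300, cx = 150, cy = 140, a = 40, b = 20,
                          alpha = 0.4)
  ch[gt] <- 210
  mask <- gaussian_background_threshold(ch)
  expect_gte(sum(mask & gt) / sum(gt), 0.99)
})

test_that("despeckling removes isolated voxels and keeps solid blocks", {
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  expect_false(any(despeckle(m)))
  block <- matrix(FALSE, 14, 14); block[3:12, 3:12] <- TRUE
  out <- despeckle(block)
  expect_true(all(out[4:11, 4:11]))
})

test_that("despeckle equals the brute-force 3x3 median oracle", {
  set.seed(24)
  for (i in 1:20) {
    m <- random_mask(32, 32, p = runif(1, 0.1, 0.9))
    expect_identical(despeckle(m), oracle_median3(m))
  }
})

test_that("component labeling is 8-connected and matches flood fill", {
  # diagonal-only chain is one component
  d <- matrix(FALSE, 5, 5); d[1, 1] <- d[2, 2] <- d[3, 3] <- TRUE
  expect_equal(max(label_components(d)), 1L)
  set.seed(25)
  for (i in 1:15) {
    m <- random_mask(24, 24, p = runif(1, 0.2, 0.6))
    expect_true(same_partition(label_components(m), oracle_label8(m)))
  }
})

test_that("object identification measures ellipse geometry in microns", {
  # ellipse of ~20 um^2 (a = 4, b = 1.6 um) at 0.2 um pixels
  px <- 0.2
  gt <- draw_ellipse_mask(200, 200, cx = 20, cy = 18, a = 4, b = 1.6,
                          alpha = 0.7, px = px)
  obj <- identify_objects(gt, pixel_size_um = px, channel = "nucleus")
  expect_equal(nrow(obj), 1L)
  expect_lt(abs(obj$x_um - 20), px)
  expect_lt(abs(obj$y_um - 18), px)
  expect_equal(obj$major_axis_um, 8, tolerance = 0.1)
  expect_equal(obj$minor_axis_um, 3.2, tolerance = 0.1)
  expect_equal(obj$area_um2, pi * 4 * 1.6, tolerance = 0.05)
})

test_that("size segmentation applies channel-specific area thresholds", {
  # ~8 um^2 disc: below the 10 um^2 nucleus threshold, above the 2 um^2
  # Golgi threshold
  px <- 0.1
  gt <- draw_ellipse_mask(120, 120, cx = 6, cy = 6, a = 1.6, b = 1.6,
                          px = px)
  expect_equal(nrow(identify_objects(gt, px, "nucleus")), 0L)
  expect_equal(nrow(identify_objects(gt, px, "golgi")), 1L)
  expect_equal(nrow(identify_objects(matrix(FALSE, 10, 10), px, "golgi")),
               0L)
})

test_that("touching ellipses form a single labeled object", {
  px <- 0.1
  a <- draw_ellipse_mask(120, 120, cx = 5, cy = 6, a = 2, b = 1, px = px)
  b <- draw_ellipse_mask(120, 120, cx = 8.5, cy = 6, a = 2, b = 1, px = px)
  obj <- identify_objects(a | b, px, "golgi")
  expect_equal(nrow(obj), 1L)
})

test_that("each nucleus pairs with its nearest Golgi, ties to lowest id", {
  nuc <- tibble::tibble(id = 1L, channel = "nucleus", x_um = 0, y_um = 0,
                        major_axis_um = 10, minor_axis_um = 5,
                        area_um2 = 40, n_pixels = 100L)
  gol <- tibble::tibble(id = c(1L, 2L), channel = "golgi",
                        x_um = c(3, 10), y_um = c(4, 0),
                        major_axis_um = 2, minor_axis_um = 2,
                        area_um2 = 3, n_pixels = 30L)
  p <- pair_nucleus_to_golgi(nuc, gol)
  expect_equal(p$golgi_id, 1L)
  expect_equal(p$ng_length_um, 5)
  expect_equal(c(p$dx_um, p$dy_um), c(3, 4))
  expect_equal(p$nucleus_elongation, 2)
  # equidistant Golgi: deterministic lowest-id winner
  gol2 <- gol
  gol2$x_um <- c(0, 0); gol2$y_um <- c(5, -5)
  expect_equal(pair_nucleus_to_golgi(nuc, gol2)$golgi_id, 1L)
  gol3 <- gol2[c(2, 1), ]  # same set, shuffled rows
  expect_equal(pair_nucleus_to_golgi(nuc, gol3)$golgi_id, 1L)
  # degenerate inputs
  expect_equal(nrow(pair_nucleus_to_golgi(nuc, gol[0, ])), 0L)
  expect_equal(nrow(pair_nucleus_to_golgi(nuc[0, ], gol)), 0L)
})

test_that("one-to-one pairing never reuses a Golgi", {
  nuc <- tibble::tibble(id = 1:2, channel = "nucleus",
                        x_um = c(0, 1), y_um = 0,
                        major_axis_um = 10, minor_axis_um = 5,
                        area_um2 = 40, n_pixels = 100L)
  gol <- tibble::tibble(id = 1:2, channel = "golgi",
                        x_um = c(0.4, 30), y_um = 0,
                        major_axis_um = 2, minor_axis_um = 2,
                        area_um2 = 3, n_pixels = 30L)
  shared <- pair_nucleus_to_golgi(nuc, gol)
  expect_equal(shared$golgi_id, c(1L, 1L))
  strict <- pair_nucleus_to_golgi(nuc, gol, one_to_one = TRUE)
  expect_equal(sort(strict$golgi_id), c(1L, 2L))
})

test_that("angle to flow lives on the semicircle with exact landmarks", {
  expect_equal(angle_to_flow(2, 0, c(1, 0)), 0)
  expect_equal(angle_to_flow(-2, 0, c(1, 0)), 180)
  expect_equal(angle_to_flow(1, sqrt(3), c(1, 0)), 60, tolerance = 1e-10)
  expect_error(angle_to_flow(1, 1, c(0, 0)), "flow_direction")
  expect_warning(a <- angle_to_flow(c(0, 1), c(0, 0), c(1, 0)),
                 "zero-length")
  expect_true(is.na(a[1]) && a[2] == 0)
})

test_that("angles are invariant under joint rotation of image and flow", {
  set.seed(26)
  for (i in 1:25) {
    v <- rnorm(2); f <- rnorm(2)
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    vr <- R %*% v; fr <- R %*% f
    expect_equal(angle_to_flow(v[1], v[2], f),
                 angle_to_flow(vr[1], vr[2], as.vector(fr)),
                 tolerance = 1e-9)
  }
})

test_that("orientation classes use half-open 60/120 degree boundaries", {
  expect_equal(as.character(classify_orientation(c(0, 59.999, 60, 119.9,
                                                   120, 150, 180))),
               c("dromic", "dromic", "lateral", "lateral", "antidromic",
                 "antidromic", "antidromic"))
  expect_error(classify_orientation(181), "angle_deg")
  expect_error(classify_orientation(-1), "angle_deg")
  expect_true(is.na(classify_orientation(NA_real_)))
})

test_that("class frequencies sum to 100% and match the inputs", {
  set.seed(27)
  cls <- classify_orientation(runif(6000, 0, 180))
  s <- orientation_summary(cls)
  expect_equal(sum(s$pct), 100)
  expect_equal(sum(s$n), 6000L)
  expect_true(all(abs(s$pct - 100 / 3) < 3))  # equiprobable null
  s2 <- orientation_summary(classify_orientation(rep(150, 9)))
  expect_equal(s2$pct[s2$orientation_class == "antidromic"], 100)
  expect_error(orientation_summary(factor(character())), "no classified")
})

test_that("polarity metrics report means and SEM of the two parameters", {
  cells <- tibble::tibble(ng_length_um = c(4, 5, 6),
                          nucleus_elongation = c(1, 1, 1))
  m <- polarity_metrics(cells)
  expect_equal(m$mean_ng_length_um, 5)
  expect_equal(m$sem_ng_length_um, sd(c(4, 5, 6)) / sqrt(3))
  expect_equal(m$mean_elongation, 1)  # circular nuclei: exactly 1
  expect_error(polarity_metrics(cells[0, ]), "no paired")
})
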