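test_that("rolling-ball subtraction matches its morphological oracle", {
  # constant image -> all zeros
  const <- matrix(7, 32, 32)
  expect_equal(rolling_ball_subtract(const, 5), matrix(0, 32, 32))

  # narrow bright dot on a pedestal survives; oracle = brute-force opening
  img <- matrix(10, 41, 41)
  img[21, 21] <- 100
  out <- rolling_ball_subtract(img, 8)
  oracle <- img - brute_opening(img, 8)
  expect_equal(out, pmax(oracle, 0))
  expect_gt(out[21, 21], 0.95 * 90)

  # ball much larger than the image: output ~ input - min(input)
  ramp <- matrix(seq(5, 9, length.out = 20), 20, 20)
  expect_equal(rolling_ball_subtract(ramp, 500), ramp - min(ramp))

  # light background: background plateau maps to the image maximum
  lb <- matrix(100, 41, 41)
  lb[15, 15] <- 40  # dark vesicle lumen
  outl <- rolling_ball_subtract(lb, 8, light_background = TRUE)
  expect_equal(outl[1, 1], 100)
  expect_lt(outl[15, 15], 50)

  expect_error(rolling_ball_subtract(array(0, c(2, 2, 2)), 5), "2-D")
})

test_that("average projection is the per-pixel arithmetic mean", {
  a <- matrix(1:6, 2, 3)
  b <- matrix(6:1, 2, 3)
  expect_equal(average_projection(list(a, a, a)), a)
  expect_equal(average_projection(list(a, b)), (a + b) / 2)

  # moving dot over N disjoint positions projects to intensity / N
  frames <- lapply(1:5, function(k) {
    m <- matrix(0, 8, 8)
    m[4, k] <- 10
    m
  })
  proj <- average_projection(frames)
  expect_equal(proj[4, 1:5], rep(2, 5))

  arr <- array(0, c(2, 3, 4))
  arr[1, , ] <- 2
  arr[2, , ] <- 4
  st <- image_stack(arr, axes = c("z", "y", "x"), pixel_size = 1)
  expect_equal(average_projection(st, "z")$pixels, matrix(3, 3, 4))
})

test_that("bandpass keeps in-band structure and kills the DC and fine scales", {
  # constant image -> zero contrast
  flat <- bandpass_filter(matrix(5, 64, 64), autoscale = FALSE)
  expect_lt(max(abs(flat)), 1e-8)

  gain_for <- function(period) {
    x <- matrix(sin(2 * pi * seq_len(512) / period), 64, 512, byrow = TRUE)
    f <- bandpass_filter(x, large = 40, small = 5, autoscale = FALSE)
    # measure amplitude away from the borders
    sd(f[32, 65:448]) / sd(x[32, 65:448])
  }
  g_in <- gain_for(16)
  expect_gt(g_in, 0.5)
  expect_gt(g_in, 2 * gain_for(256))  # larger than `large` suppressed
  expect_lt(gain_for(3), 0.1 * g_in)  # smaller than `small` suppressed

  expect_error(bandpass_filter(matrix(0, 8, 8), large = 5, small = 5),
               "small")

  # autoscale maps to [0, 1]
  noisy <- matrix(rnorm(64^2), 64, 64)
  out <- bandpass_filter(noisy)
  expect_gte(min(out), 0)
  expect_lte(max(out), 1)
})

test_that("binarize covers manual values and automatic Otsu", {
  img <- matrix(runif(100, 1, 2), 10, 10)
  expect_true(all(binarize(img, 0) == 1))
  expect_true(all(binarize(img, 10) == 0))
  expect_equal(attr(binarize(img, 1.5), "threshold"), 1.5)

  # bimodal image: misclassification below 1 percent
  set.seed(42)
  truth <- disc_mask(128, 128, 64, 64, 30)
  img2 <- matrix(rnorm(128^2, 100, 8), 128, 128) + truth * 200
  mask <- binarize(img2, "otsu")
  expect_lt(mean(mask != truth), 0.01)

  # near-constant image yields an empty mask, not an error
  expect_true(all(binarize(matrix(3, 5, 5), "otsu") == 0))
})

test_that("mask clean-up fills rings, erodes once, and splits doublets", {
  # solid ring -> filled disc (minus one erosion)
  ring <- disc_mask(64, 64, 32, 32, 14) - disc_mask(64, 64, 32, 32, 10)
  out <- clean_mask(ring)
  expect_gte(sum(out), sum(disc_mask(64, 64, 32, 32, 12)))

  # 10x10 square erodes to 8x8
  sq <- matrix(0L, 20, 20)
  sq[6:15, 6:15] <- 1L
  expect_equal(sum(clean_mask(sq)), 64)

  # two overlapping discs, centers 1.5 r apart -> exactly two labels
  two <- pmin(disc_mask(80, 120, 40, 45, 20) +
                disc_mask(80, 120, 40, 75, 20), 1)
  lab <- EBImage::bwlabel(clean_mask(two) > 0)
  expect_equal(max(lab), 2)
})

test_that("particle measurement reports circle geometry and applies filters", {
  ps <- 0.1625
  r_px <- (10 / 2) / ps
  m <- disc_mask(128, 128, 64, 64, r_px)
  rois <- find_vesicles(m, ps, detection_params("zstack"))
  expect_equal(nrow(rois), 1)
  expect_lt(abs(rois$feret_um - 10), 2 * ps)
  expect_gt(rois$circularity, 0.95)
  expect_lte(rois$circularity, 1)
  expect_lt(abs(rois$area_um2 - pi * 25), 2)

  # 4 um disc fails the single-image 19.6 um^2 floor
  m4 <- disc_mask(128, 128, 64, 64, (4 / 2) / ps)
  expect_equal(nrow(find_vesicles(m4, ps, detection_params("single"))), 0)
  expect_equal(nrow(find_vesicles(m4, ps, detection_params("zstack"))), 1)

  # elongated bar fails the 0.70 circularity floor
  bar <- matrix(0L, 40, 40)
  bar[20:21, 10:29] <- 1L
  expect_equal(nrow(find_vesicles(bar, ps, detection_params("zstack"))), 0)

  # edge-touching particles are excluded unless asked otherwise
  edge <- disc_mask(64, 64, 5, 32, 6)
  expect_equal(nrow(find_vesicles(edge, ps, detection_params("zstack"))), 0)
  p_keep <- detection_params("zstack", exclude_edges = FALSE)
  expect_equal(nrow(find_vesicles(edge, ps, p_keep)), 1)

  expect_equal(nrow(find_vesicles(matrix(0L, 16, 16), ps)), 0)
})

test_that("measurements converge to circle values with resolution", {
  ps <- 1
  errs <- sapply(c(10, 30, 90), function(r_px) {
    m <- disc_mask(2 * r_px + 21, 2 * r_px + 21, r_px + 11, r_px + 11, r_px)
    v <- find_vesicles(m, ps, detection_params("zstack"))
    abs(v$feret_um - 2 * r_px) / (2 * r_px)
  })
  expect_true(all(diff(errs) < 0))
})

test_that("detection is translation invariant away from edges", {
  ps <- 0.5
  base <- disc_mask(100, 100, 40, 40, 12)
  shifted <- disc_mask(100, 100, 47, 55, 12)
  a <- find_vesicles(base, ps, detection_params("zstack"))
  b <- find_vesicles(shifted, ps, detection_params("zstack"))
  expect_equal(b$centroid_x_um - a$centroid_x_um, 15 * ps)
  expect_equal(b$centroid_y_um - a$centroid_y_um, 7 * ps)
  expect_equal(a$feret_um, b$feret_um)
  expect_equal(a$area_um2, b$area_um2)
})

test_that("the full detector finds synthetic vesicles and is deterministic", {
  acq <- small_acq(field_px = 384, n_z = 30)
  sc <- sample_population(8, list(law = "lognormal", meanlog = log(7),
                                  sdlog = 0.25, min = 5, max = 12),
                          seed = 20, acquisition = acq)
  st <- render_zstack(sc, noise = TRUE)
  rois <- detect_guvs(st, mode = "zstack")
  sc_score <- match_score(rois, sc$vesicles)
  expect_equal(unname(sc_score["recall"]), 1)
  expect_equal(unname(sc_score["precision"]), 1)
  rois2 <- detect_guvs(st, mode = "zstack")
  expect_identical(as.data.frame(rois), as.data.frame(rois2))

  # empty scene -> no detections (automatic thresholding assumes at least
  # one object in view, as the manual workflow does; see vignette)
  sc0 <- sample_population(0, seed = 1, acquisition = acq)
  expect_equal(nrow(detect_guvs(render_zstack(sc0, noise = FALSE),
                                mode = "zstack")), 0)

  # provenance carries the threshold actually used
  expect_true(is.finite(attr(rois, "provenance")$threshold))
})

test_that("ROI means agree exactly with a brute-force pixel loop", {
  set.seed(7)
  img <- matrix(runif(64^2, 0, 100), 64, 64)
  lab <- matrix(0L, 64, 64)
  for (l in 1:10) {
    rs <- sample(5:60, 1); cs <- sample(5:60, 1)
    lab[rs:(rs + 3), cs:(cs + 3)] <- l
  }
  df <- data.frame(id = 1:10, label = 1:10)
  rois <- guvquant:::.as_guv_rois(df, lab, 1, detection_params("single"))
  got <- measure_rois(img, rois)
  want <- vapply(1:10, function(l) {
    acc <- c()
    for (i in 1:64) for (j in 1:64) if (lab[i, j] == l)
      acc <- c(acc, img[i, j])
    mean(acc)
  }, numeric(1))
  expect_equal(got$mean_intensity, want)

  # constant image and a half/half ROI
  expect_equal(measure_rois(matrix(5, 64, 64), rois)$mean_intensity,
               rep(5, 10))
})
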