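test_that("population sampling handles the empty and fixed-size cases", {
  sc <- sample_population(0, seed = 1, acquisition = small_acq())
  expect_s3_class(sc, "SyntheticScene")
  expect_equal(nrow(sc$vesicles), 0)
  expect_equal(nrow(sc$ground_truth), 0)

  sc1 <- sample_population(1, list(law = "fixed", diameters = 10),
                           seed = 2, acquisition = small_acq())
  expect_equal(sc1$ground_truth$diameter, 10)
  expect_true(sc1$vesicles$diameter > 0)
})

test_that("the same seed reproduces a population bit for bit", {
  acq <- acquisition_config(field_px = 2048, n_z = 72)
  sd <- list(law = "lognormal", meanlog = log(8), sdlog = 0.4)
  a <- sample_population(500, sd, seed = 7, acquisition = acq)
  b <- sample_population(500, sd, seed = 7, acquisition = acq)
  expect_identical(a$vesicles, b$vesicles)
  c <- sample_population(500, sd, seed = 8, acquisition = acq)
  expect_false(identical(a$vesicles$x, c$vesicles$x))
})

test_that("vesicle footprints never overlap and stay inside the field", {
  sc <- sample_population(40, list(law = "lognormal", meanlog = log(7),
                                   sdlog = 0.3, min = 5, max = 15),
                          seed = 3, acquisition = small_acq(512))
  v <- sc$vesicles
  d <- as.matrix(dist(cbind(v$x, v$y)))
  lim <- outer(v$diameter, v$diameter, `+`) / 2
  diag(d) <- Inf
  expect_true(all(d >= lim))
  expect_true(all(v$x - v$diameter / 2 >= 0))
  expect_true(all(v$x + v$diameter / 2 <= field_um(sc$acquisition)[2]))
})

test_that("impossible packings raise an explicit error", {
  expect_error(
    sample_population(200, list(law = "fixed", diameters = 15),
                      seed = 1, acquisition = small_acq(128),
                      max_tries = 3000),
    "non-overlapping")
})

test_that("rendered rings follow the sphere-slice geometry", {
  acq <- small_acq(field_px = 160, n_z = 30)
  sc <- sample_population(1, list(law = "fixed", diameters = 10),
                          seed = 5, acquisition = acq)
  v <- sc$vesicles
  st <- render_zstack(sc, noise = FALSE)
  zc_slice <- which.min(abs(z_positions(st) - v$z))
  eq <- stack_frame(st, z = zc_slice, channel = 1)
  bg <- max(noise_params()$background_level * 1.2)
  idx <- which(eq > bg + 0.5 * v$membrane_intensity, arr.ind = TRUE)
  rad <- sqrt(((idx[, 2] - 0.5) * acq$pixel_size - v$x)^2 +
                ((idx[, 1] - 0.5) * acq$pixel_size - v$y)^2)
  # equatorial ring radius 5 um within a pixel
  expect_lt(abs(mean(rad) - 5), acq$pixel_size)

  # slices outside the sphere carry no signal above background
  far <- which(abs(z_positions(st) - v$z) > 5 + 1e-9)
  for (iz in far[c(1, length(far))]) {
    sl <- stack_frame(st, z = iz, channel = 1)
    expect_lt(max(sl), bg + 1e-6)
  }
})

test_that("noiseless lumen signal matches the analytic sphere-slice sum", {
  acq <- small_acq(field_px = 256, n_z = 40)
  sc <- sample_population(1, list(law = "fixed", diameters = 14),
                          seed = 6, acquisition = acq)
  sc$acquisition$channels <- "lumen"
  st <- render_zstack(sc, channels = "lumen", noise = FALSE)
  v <- sc$vesicles
  # subtract the vesicle-free background render to isolate the lumen signal
  sc0 <- sc
  sc0$vesicles <- sc$vesicles[0, ]
  st0 <- render_zstack(sc0, channels = "lumen", noise = FALSE)
  signal <- sum(st$pixels) - sum(st0$pixels)
  zp <- z_positions(st)
  r_z <- sqrt(pmax((v$diameter / 2)^2 - (zp - v$z)^2, 0))
  analytic <- v$lumen_dye * sum(pi * r_z^2) / acq$pixel_size^2
  expect_lt(abs(signal - analytic) / analytic, 0.02)
})

test_that("rendering is deterministic for a fixed seed", {
  acq <- small_acq(192, n_z = 10)
  sc <- sample_population(4, list(law = "fixed", diameters = 6),
                          seed = 9, acquisition = acq)
  a <- render_zstack(sc, noise = TRUE)
  b <- render_zstack(sc, noise = TRUE)
  expect_identical(a$pixels, b$pixels)
})

test_that("leakage kinetics honor their closed form", {
  acq <- small_acq(96, n_z = 30)
  # tight vesicle: constant lumen intensity across time
  sc <- sample_population(1, list(law = "fixed", diameters = 8),
                          assay_params = list(exterior_dye = 600,
                                              leak_rate = 0),
                          seed = 10, acquisition = acq)
  ser <- simulate_leakage_series(sc, "dye_influx", timepoints = c(1, 30, 60),
                                 noise = FALSE)
  expect_equal(ser$stacks[[1]]$pixels, ser$stacks[[3]]$pixels)
  expect_equal(ser$truth$leak20_percent, 0)

  # numerically instant leakage: lumen equals exterior by the first frame
  sc2 <- sample_population(1, list(law = "fixed", diameters = 8),
                           assay_params = list(exterior_dye = 600,
                                               leak_rate = 20),
                           seed = 10, acquisition = acq)
  ser2 <- simulate_leakage_series(sc2, "dye_influx", timepoints = c(1, 30),
                                  noise = FALSE)
  sc2_flat <- sc2
  sc2_flat$vesicles$lumen_dye <- 600  # fully equilibrated reference
  ref <- render_zstack(sc2_flat, channels = c("membrane", "hpts470"),
                       noise = FALSE)
  expect_lt(max(abs(ser2$stacks[[1]]$pixels - ref$pixels)), 1e-6 * 600)

  expect_error(simulate_leakage_series(sc, "dye_influx",
                                       timepoints = c(3, 2)), "increasing")
  sc_bad <- sc
  sc_bad$vesicles$leak_rate <- -1
  expect_error(simulate_leakage_series(sc_bad, "dye_influx",
                                       timepoints = c(1, 2)), ">= 0")
})

test_that("proton-efflux ratios relax and jump at the protonophore event", {
  acq <- small_acq(96)
  k <- log(2) / 20  # 50% ground-truth 20-min leakage
  sc <- sample_population(1, list(law = "fixed", diameters = 8),
                          assay_params = list(leak_rate = k,
                                              lumen_dye = 500),
                          seed = 12, acquisition = acq)
  tp <- c(0, 10, 20, 40, 60, 62, 66)
  ser <- simulate_leakage_series(sc, "proton_efflux", timepoints = tp,
                                 gramicidin_time = 62, noise = FALSE)
  expect_equal(ser$truth$leak20_percent, 50)
  rois <- detect_guvs(ser$membrane_frame, mode = "single")
  R <- vapply(ser$frames, function(f)
    hpts_ratio(measure_rois(stack_frame(f, channel = "hpts470"),
                            rois)$mean_intensity,
               measure_rois(stack_frame(f, channel = "hpts395"),
                            rois)$mean_intensity), numeric(1))
  out <- proton_leakage_percent(tp, R, t_end = 66)
  expect_lt(abs(out$percent - 50), 1)
  # post-gramicidin ratio equals the fully equilibrated ratio
  expect_gt(R[7], R[5])
})

test_that("flow series move only the mobile vesicles", {
  acq <- small_acq(256)
  sc <- sample_population(6, list(law = "fixed", diameters = 8),
                          assay_params = list(immobilized_fraction = 1),
                          seed = 13, acquisition = acq)
  fs <- simulate_flow_series(sc, flow_start = 2, displacement_per_frame = 20,
                             n_frames = 6, frame_interval = 1, noise = FALSE)
  expect_equal(fs$frames[[1]]$pixels, fs$frames[[6]]$pixels)

  sc2 <- sample_population(6, list(law = "fixed", diameters = 8),
                           assay_params = list(immobilized_fraction = 0),
                           seed = 13, acquisition = acq)
  fs2 <- simulate_flow_series(sc2, flow_start = 2,
                              displacement_per_frame = 0,
                              n_frames = 6, frame_interval = 1,
                              noise = FALSE)
  expect_equal(fs2$frames[[1]]$pixels, fs2$frames[[6]]$pixels)
})

test_that("fusion gains scale linearly with the proteo fraction", {
  acq <- small_acq(256)
  sc <- sample_population(5, list(law = "fixed", diameters = 8),
                          seed = 14, acquisition = acq)
  tp <- c(0, 30, 200)
  a <- simulate_fusion_series(sc, tp, proteo_fraction = 1, noise = FALSE)
  b <- simulate_fusion_series(sc, tp, proteo_fraction = 1 / 3,
                              noise = FALSE)
  # protein-channel gain of the full-proteo run is 3x the 1/3 run
  ga <- a$frames[[3]]$pixels[2, , ] - a$frames[[1]]$pixels[2, , ]
  gb <- b$frames[[3]]$pixels[2, , ] - b$frames[[1]]$pixels[2, , ]
  expect_equal(ga, 3 * gb, tolerance = 1e-12)

  z <- simulate_fusion_series(sc, tp, proteo_fraction = 0, noise = FALSE)
  gz <- z$frames[[3]]$pixels[2, , ] - z$frames[[1]]$pixels[2, , ]
  expect_true(all(gz == 0))
  expect_equal(z$truth$protein_gain, rep(0, 5))

  expect_error(simulate_fusion_series(sc, tp, proteo_fraction = 1.2),
               "proteo_fraction")

  # pre-addition frames are flat in time
  expect_equal(a$frames[[1]]$pixels, a$frames[[2]]$pixels)
})

test_that("noiseless added membrane signal matches the configured gains", {
  acq <- small_acq(256)
  sc <- sample_population(5, list(law = "fixed", diameters = 8),
                          seed = 15, acquisition = acq)
  ser <- simulate_fusion_series(sc, c(0, 30, 1e5), add_time = 30, tau = 60,
                                suv_gain = 300, noise = FALSE)
  added <- sum(ser$frames[[3]]$pixels[1, , ] - ser$frames[[1]]$pixels[1, , ])
  # analytic integral of a Gaussian-profiled ring of radius r:
  # amp * 2*pi*r * sigma * sqrt(2*pi) / ps^2
  sigma <- max(acq$blur_lateral, acq$pixel_size / 2)
  expected <- sum(ser$truth$membrane_gain * 2 * pi * 4 * sigma *
                    sqrt(2 * pi)) / acq$pixel_size^2
  expect_lt(abs(added - expected) / expected, 0.05)
})
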