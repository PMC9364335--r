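#' Acquisition geometry and noise for synthetic confocal rendering
#'
#' Defaults reproduce the acquisition used throughout the package's assays: a
#' 2048 x 2048 px field at 0.1625 um/px (332.8 um square), confocal Z-stacks
#' recorded top to bottom with a 1 um step over 72 steps, and a spinning-disk
#' style Poisson-Gaussian noise model with a smooth background ramp.
#'
#' @param pixel_size Lateral pixel size, um/px.
#' @param field_px Field size in pixels, `c(ny, nx)` (a single number is used
#'   for both).
#' @param z_step Axial step, um.
#' @param n_z Number of Z slices (>= 1).
#' @param frame_interval Time between frames of a time series, seconds.
#' @param channels Ordered channel labels, from
#'   `c("membrane", "hpts470", "hpts395", "lumen", "protein")`.
#' @param blur_lateral,blur_axial Optical blur (Gaussian sd), um. The lateral
#'   sd sets the radial profile of rendered membrane rings.
#' @param noise A [noise_params()] list.
#' @return A list of class `AcquisitionConfig`.
#' @export
acquisition_config <- function(pixel_size = 0.1625, field_px = c(2048, 2048),
                               z_step = 1, n_z = 72, frame_interval = 5,
                               channels = "membrane",
                               blur_lateral = 0.3, blur_axial = 1.0,
                               noise = noise_params()) {
  if (length(field_px) == 1) field_px <- c(field_px, field_px)
  stopifnot(pixel_size > 0, all(field_px >= 1), z_step > 0, n_z >= 1)
  channels <- match.arg(channels,
                        c("membrane", "hpts470", "hpts395", "lumen",
                          "protein"), several.ok = TRUE)
  structure(list(pixel_size = pixel_size, field_px = as.integer(field_px),
                 z_step = z_step, n_z = as.integer(n_z),
                 frame_interval = frame_interval, channels = channels,
                 blur_lateral = blur_lateral, blur_axial = blur_axial,
                 noise = noise),
            class = "AcquisitionConfig")
}

#' @rdname acquisition_config
#' @param poisson_scale Photon conversion factor: pixel counts are drawn as
#'   `rpois(value * poisson_scale) / poisson_scale`. 0 disables shot noise.
#' @param gaussian_sd Additive read noise sd, AFU.
#' @param background_level Mean background, AFU.
#' @param background_gradient Fractional linear ramp of the background across
#'   the field (0 = flat).
#' @export
noise_params <- function(poisson_scale = 0.25, gaussian_sd = 10,
                         background_level = 100, background_gradient = 0.2) {
  stopifnot(poisson_scale >= 0, gaussian_sd >= 0, background_level >= 0)
  list(poisson_scale = poisson_scale, gaussian_sd = gaussian_sd,
       background_level = background_level,
       background_gradient = background_gradient)
}

#' Field edge length of an acquisition, in micrometers
#' @param acq An [acquisition_config()].
#' @return Numeric vector `c(y, x)` in um.
#' @export
field_um <- function(acq) acq$field_px * acq$pixel_size

#' Sample a ground-truth vesicle population
#'
#' Draws `n` spherical vesicles with non-overlapping footprints (immobilized
#' GUVs settle on the slide as a monolayer, so non-overlap is enforced in the
#' xy projection by rejection sampling). Each vesicle rests on the slide
#' plane, placed just above the bottom of the Z range, so the top slices of a
#' rendered stack contain only background.
#'
#' @param n Number of vesicles (>= 0).
#' @param size_distribution A list describing the diameter law:
#'   `list(law = "lognormal", meanlog, sdlog, min, max)` (min/max optional
#'   truncation), `list(law = "uniform", min, max)`, or
#'   `list(law = "fixed", diameters = c(...))`.
#' @param assay_params Per-assay intensity/kinetics parameters; recognized
#'   entries (with defaults): `membrane_intensity` (800 AFU),
#'   `intensity_cv` (0.15), `lumen_dye` (600 AFU), `exterior_dye` (0 AFU),
#'   `ratio_in` (1.0), `ratio_out` (1.8), `leak_rate` (0 per minute; scalar or
#'   length-n), `immobilized_fraction` (1), `protein_density` (0 AFU),
#'   `fusogenicity_cv` (0.25).
#' @param seed Integer seed; the same seed reproduces the scene exactly.
#' @param acquisition An [acquisition_config()].
#' @param margin Minimum edge-to-edge gap between vesicle footprints, um.
#' @param edge_margin Minimum gap between a vesicle edge and the field border,
#'   um (keeps detections off the frame edge).
#' @param max_tries Rejection-sampling budget; exceeded packing raises an
#'   error.
#' @return A `SyntheticScene`: list with `vesicles` (data.frame, one row per
#'   vesicle), `acquisition`, `seed`, `assay_params`, and `ground_truth`
#'   (the vesicle table, the authoritative record for scoring).
#' @export
sample_population <- function(n,
                              size_distribution = list(law = "lognormal",
                                                       meanlog = log(8),
                                                       sdlog = 0.4,
                                                       min = 1, max = 40),
                              assay_params = list(), seed = 1,
                              acquisition = acquisition_config(),
                              margin = 2, edge_margin = 2,
                              max_tries = NULL) {
  stopifnot(n >= 0)
  ap <- utils::modifyList(
    list(membrane_intensity = 800, intensity_cv = 0.15, lumen_dye = 600,
         exterior_dye = 0, ratio_in = 1.0, ratio_out = 1.8, leak_rate = 0,
         immobilized_fraction = 1, protein_density = 0,
         fusogenicity_cv = 0.25),
    assay_params)
  fld <- field_um(acquisition)
  if (is.null(max_tries)) max_tries <- max(2000L, 400L * n)

  ves <- with_seed(seed, {
    d <- .sample_diameters(n, size_distribution)
    if (any(d <= 0)) stop("diameters must be positive")
    ord <- order(d, decreasing = TRUE)  # place large vesicles first
    d <- d[ord]
    x <- y <- numeric(n)
    placed <- 0L
    tries <- 0L
    while (placed < n) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("could not place ", n, " non-overlapping vesicles in a ",
             round(fld[2], 1), " x ", round(fld[1], 1),
             " um field after ", max_tries, " tries")
      r <- d[placed + 1L] / 2
      lo <- r + edge_margin
      cx <- stats::runif(1, lo, fld[2] - lo)
      cy <- stats::runif(1, lo, fld[1] - lo)
      ok <- placed == 0L ||
        all(sqrt((x[seq_len(placed)] - cx)^2 +
                 (y[seq_len(placed)] - cy)^2) >=
              (d[seq_len(placed)] + d[placed + 1L]) / 2 + margin)
      if (ok) {
        placed <- placed + 1L
        x[placed] <- cx
        y[placed] <- cy
      }
    }
    z_slide <- max((acquisition$n_z - 2L), 0L) * acquisition$z_step
    lk <- rep_len(ap$leak_rate, max(n, 1L))[seq_len(n)]
    if (n > 0 && any(lk < 0)) stop("leak_rate must be >= 0")
    n_imm <- if (n > 0) round(ap$immobilized_fraction * n) else 0L
    imm <- rep(FALSE, n)
    if (n_imm > 0) imm[sample.int(n, n_imm)] <- TRUE
    data.frame(
      id = seq_len(n),
      x = x, y = y, z = z_slide - d / 2,
      diameter = d,
      membrane_intensity = ap$membrane_intensity *
        exp(stats::rnorm(n, 0, ap$intensity_cv) - ap$intensity_cv^2 / 2),
      lumen_dye = rep_len(ap$lumen_dye, max(n, 1L))[seq_len(n)],
      leak_rate = lk,
      immobilized = imm,
      protein_density = rep_len(ap$protein_density, max(n, 1L))[seq_len(n)],
      fusogenicity = exp(stats::rnorm(n, 0, ap$fusogenicity_cv) -
                           ap$fusogenicity_cv^2 / 2)
    )
  })
  structure(list(vesicles = ves, acquisition = acquisition, seed = seed,
                 assay_params = ap, ground_truth = ves),
            class = "SyntheticScene")
}

.sample_diameters <- function(n, sd_spec) {
  if (n == 0) return(numeric(0))
  law <- match.arg(sd_spec$law, c("lognormal", "uniform", "fixed"))
  if (law == "fixed") {
    d <- rep_len(sd_spec$diameters, n)
  } else if (law == "uniform") {
    d <- stats::runif(n, sd_spec$min, sd_spec$max)
  } else {
    d <- stats::rlnorm(n, sd_spec$meanlog, sd_spec$sdlog)
    lo <- if (is.null(sd_spec$min)) 0 else sd_spec$min
    hi <- if (is.null(sd_spec$max)) Inf else sd_spec$max
    bad <- which(d < lo | d > hi)
    guard <- 0L
    while (length(bad) > 0) {
      guard <- guard + 1L
      if (guard > 1000L) stop("size truncation bounds too narrow")
      d[bad] <- stats::rlnorm(length(bad), sd_spec$meanlog, sd_spec$sdlog)
      bad <- which(d < lo | d > hi)
    }
  }
  d
}

#' @export
print.SyntheticScene <- function(x, ...) {
  cat("<SyntheticScene> ", nrow(x$vesicles), " vesicles, field ",
      paste(round(field_um(x$acquisition), 1), collapse = " x "),
      " um, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# ---- low-level rendering ------------------------------------------------

# Smooth background plane for one field.
.background_field <- function(acq) {
  ny <- acq$field_px[1]; nx <- acq$field_px[2]
  g <- acq$noise$background_gradient
  xn <- (seq_len(nx) - 0.5) / nx - 0.5
  yn <- (seq_len(ny) - 0.5) / ny - 0.5
  acq$noise$background_level *
    (1 + g * (matrix(yn, ny, nx) + matrix(xn, ny, nx, byrow = TRUE)))
}

# Add a Gaussian-profiled ring (membrane cross-section) in place.
.add_ring <- function(mat, ps, cx, cy, rho0, amp, sigma) {
  if (amp == 0) return(mat)
  half <- rho0 + 3.5 * sigma
  i0 <- max(1L, floor((cy - half) / ps) + 1L)
  i1 <- min(nrow(mat), ceiling((cy + half) / ps))
  j0 <- max(1L, floor((cx - half) / ps) + 1L)
  j1 <- min(ncol(mat), ceiling((cx + half) / ps))
  if (i0 > i1 || j0 > j1) return(mat)
  yy <- (i0:i1 - 0.5) * ps - cy
  xx <- (j0:j1 - 0.5) * ps - cx
  rho <- sqrt(outer(yy^2, xx^2, "+"))
  mat[i0:i1, j0:j1] <- mat[i0:i1, j0:j1] +
    amp * exp(-(rho - rho0)^2 / (2 * sigma^2))
  mat
}

# Add a filled disc (lumen cross-section) with half-pixel antialiasing.
.add_disc <- function(mat, ps, cx, cy, rho0, amp) {
  if (amp == 0 || rho0 <= 0) return(mat)
  half <- rho0 + ps
  i0 <- max(1L, floor((cy - half) / ps) + 1L)
  i1 <- min(nrow(mat), ceiling((cy + half) / ps))
  j0 <- max(1L, floor((cx - half) / ps) + 1L)
  j1 <- min(ncol(mat), ceiling((cx + half) / ps))
  if (i0 > i1 || j0 > j1) return(mat)
  yy <- (i0:i1 - 0.5) * ps - cy
  xx <- (j0:j1 - 0.5) * ps - cx
  rho <- sqrt(outer(yy^2, xx^2, "+"))
  w <- pmin(1, pmax(0, (rho0 - rho) / ps + 0.5))
  mat[i0:i1, j0:j1] <- mat[i0:i1, j0:j1] + amp * w
  mat
}

# Poisson shot noise + Gaussian read noise + 16-bit integer quantization.
.apply_noise <- function(mat, noise) {
  v <- as.vector(mat)
  if (noise$poisson_scale > 0)
    v <- stats::rpois(length(v), pmax(v, 0) * noise$poisson_scale) /
      noise$poisson_scale
  if (noise$gaussian_sd > 0)
    v <- v + stats::rnorm(length(v), 0, noise$gaussian_sd)
  v <- pmin(round(pmax(v, 0)), 65535)
  matrix(v, nrow(mat), ncol(mat))
}

# Render one 2-D plane. `rings` / `discs` are data.frames with columns
# x, y, radius, amp (um and AFU). `exterior` is a uniform dye level added on
# top of the camera background (dye-outside assays); disc amplitudes are
# applied relative to it so lumens can be darker than the exterior.
.render_plane <- function(acq, rings = NULL, discs = NULL, exterior = 0,
                          noise = TRUE, bg = NULL) {
  mat <- if (is.null(bg)) .background_field(acq) else bg
  if (exterior != 0) mat <- mat + exterior
  ps <- acq$pixel_size
  sigma <- max(acq$blur_lateral, ps / 2)
  if (!is.null(rings) && nrow(rings))
    for (i in seq_len(nrow(rings)))
      mat <- .add_ring(mat, ps, rings$x[i], rings$y[i], rings$radius[i],
                       rings$amp[i], sigma)
  if (!is.null(discs) && nrow(discs))
    for (i in seq_len(nrow(discs)))
      mat <- .add_disc(mat, ps, discs$x[i], discs$y[i], discs$radius[i],
                       discs$amp[i] - exterior)
  if (noise) mat <- .apply_noise(mat, acq$noise)
  mat
}

# Circle radius of the sphere/plane intersection; NA when the plane misses.
.slice_radius <- function(diameter, z_center, z) {
  dz2 <- (diameter / 2)^2 - (z - z_center)^2
  out <- sqrt(pmax(dz2, 0))
  out[dz2 <= 0] <- NA_real_
  out
}

#' Render a confocal Z-stack of a synthetic scene
#'
#' The membrane (and protein) channels draw each vesicle as a ring of radius
#' `sqrt((d/2)^2 - (z - z_c)^2)` on every slice that intersects the sphere,
#' with a Gaussian radial profile whose sd is the lateral optical blur. Lumen
#' channels (`lumen`, `hpts470`, `hpts395`) fill the disc interior; a uniform
#' exterior dye level supports dye-exclusion assays. Poisson-Gaussian noise
#' and integer quantization are applied last (when `noise = TRUE`).
#'
#' @param scene A [sample_population()] scene.
#' @param channels Channels to render (default: the acquisition's channels).
#' @param noise Apply the noise model? Noiseless renders stay
#'   continuous-valued.
#' @param lumen_fill Optional per-vesicle fraction (0-1) scaling the lumen dye
#'   relative to its nominal value (used by leakage simulations).
#' @return An [image_stack()] with axes `(z, channel, y, x)`.
#' @export
render_zstack <- function(scene, channels = NULL, noise = TRUE,
                          lumen_fill = NULL) {
  acq <- scene$acquisition
  if (is.null(channels)) channels <- acq$channels
  v <- scene$vesicles
  nz <- acq$n_z
  ny <- acq$field_px[1]; nx <- acq$field_px[2]
  out <- array(0, dim = c(nz, length(channels), ny, nx))
  bg <- .background_field(acq)
  zpos <- (seq_len(nz) - 1) * acq$z_step
  with_seed(scene$seed + 101L, {
    for (iz in seq_len(nz)) {
      rho <- if (nrow(v)) .slice_radius(v$diameter, v$z, zpos[iz]) else
        numeric(0)
      hit <- which(!is.na(rho))
      for (ic in seq_along(channels)) {
        ch <- channels[ic]
        rings <- discs <- NULL
        exterior <- 0
        if (ch %in% c("membrane", "protein") && length(hit)) {
          amp <- if (ch == "membrane") v$membrane_intensity[hit] else
            v$protein_density[hit]
          rings <- data.frame(x = v$x[hit], y = v$y[hit], radius = rho[hit],
                              amp = amp)
        } else if (ch %in% c("lumen", "hpts470", "hpts395")) {
          exterior <- .exterior_level(scene, ch)
          if (length(hit)) {
            amp <- .lumen_level(scene, ch)[hit]
            if (!is.null(lumen_fill)) amp <- lumen_fill[hit] * amp
            discs <- data.frame(x = v$x[hit], y = v$y[hit],
                                radius = rho[hit], amp = amp)
          }
        }
        out[iz, ic, , ] <- .render_plane(acq, rings, discs, exterior,
                                         noise = noise, bg = bg)
      }
    }
  })
  image_stack(out, axes = c("z", "channel", "y", "x"),
              pixel_size = acq$pixel_size, channel_labels = channels,
              z_step = acq$z_step)
}

.exterior_level <- function(scene, channel) {
  ap <- scene$assay_params
  switch(channel,
         lumen = ap$exterior_dye,
         hpts470 = if (!is.null(ap$exterior_hpts470)) ap$exterior_hpts470
                   else ap$exterior_dye,
         hpts395 = if (!is.null(ap$exterior_hpts395)) ap$exterior_hpts395
                   else ap$exterior_dye,
         0)
}

.lumen_level <- function(scene, channel) {
  v <- scene$vesicles
  switch(channel,
         lumen = v$lumen_dye,
         hpts470 = if (!is.null(v$i470)) v$i470 else v$lumen_dye,
         hpts395 = if (!is.null(v$i395)) v$i395 else v$lumen_dye,
         rep(0, nrow(v)))
}

#' Render a single 2-D frame at the vesicle equatorial plane
#'
#' Each vesicle appears at its full diameter: membrane/protein channels as a
#' ring, lumen channels as a filled disc. This is the focal-plane view used
#' by single-image detection and by the time-series assays.
#'
#' @param scene A [sample_population()] scene.
#' @param channels Channels to render.
#' @param noise Apply the noise model?
#' @return An [image_stack()] with axes `(channel, y, x)` (or `(y, x)` for a
#'   single channel).
#' @export
render_frame <- function(scene, channels = "membrane", noise = TRUE) {
  acq <- scene$acquisition
  v <- scene$vesicles
  mats <- with_seed(scene$seed + 11L, lapply(channels, function(ch) {
    if (ch %in% c("membrane", "protein")) {
      amp <- if (ch == "membrane") v$membrane_intensity else
        v$protein_density
      .render_plane(acq, rings = data.frame(x = v$x, y = v$y,
                                            radius = v$diameter / 2,
                                            amp = amp),
                    noise = noise)
    } else {
      .render_plane(acq,
                    discs = data.frame(x = v$x, y = v$y,
                                       radius = v$diameter / 2,
                                       amp = .lumen_level(scene, ch)),
                    exterior = .exterior_level(scene, ch), noise = noise)
    }
  }))
  if (length(channels) == 1)
    return(image_stack(mats[[1]], axes = c("y", "x"),
                       pixel_size = acq$pixel_size))
  arr <- array(0, dim = c(length(channels), acq$field_px))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  image_stack(arr, axes = c("channel", "y", "x"),
              pixel_size = acq$pixel_size, channel_labels = channels)
}

#' Simulate a leakage experiment
#'
#' Two modes mirror the two leakage assays. `dye_influx`: membrane-impermeant
#' dye is present outside at a fixed level and each vesicle's lumen approaches
#' the exterior concentration by first-order kinetics,
#' `f(t) = 1 - exp(-k t)`; a Z-stack is rendered at every timepoint.
#' `proton_efflux`: vesicles encapsulate a ratiometric pH dye; the
#' 470/395 excitation ratio relaxes from `ratio_in` toward `ratio_out` with
#' rate `k`, and jumps to `ratio_out` after the protonophore (gramicidin)
#' event; 2-D two-channel frames at the vesicle equatorial plane are rendered
#' per timepoint, plus one membrane frame for detection.
#'
#' @param scene A [sample_population()] scene; `leak_rate` (per minute) drives
#'   the kinetics.
#' @param mode `"dye_influx"` or `"proton_efflux"`.
#' @param timepoints Increasing acquisition times, minutes.
#' @param gramicidin_time Event time (minutes) for proton mode; ratios equal
#'   `ratio_out` at and after this time.
#' @param noise Apply the noise model?
#' @return A list: `times`; `stacks` (influx: list of Z-stacks) or `frames`
#'   (proton: list of `(channel, y, x)` stacks) plus `membrane_frame`;
#'   `truth` with per-vesicle rate and ground-truth 20-min leakage percent.
#' @export
simulate_leakage_series <- function(scene,
                                    mode = c("dye_influx", "proton_efflux"),
                                    timepoints, gramicidin_time = NULL,
                                    noise = TRUE) {
  mode <- match.arg(mode)
  if (any(diff(timepoints) <= 0)) stop("timepoints must be increasing")
  v <- scene$vesicles
  if (nrow(v) && any(v$leak_rate < 0)) stop("leak_rate must be >= 0")
  acq <- scene$acquisition
  ap <- scene$assay_params
  k <- v$leak_rate
  truth <- data.frame(id = v$id, leak_rate = k,
                      leak20_percent = 100 * (1 - exp(-k * 20)))
  if (mode == "dye_influx") {
    ext <- ap$exterior_dye
    if (ext <= 0) stop("dye_influx needs assay_params$exterior_dye > 0")
    stacks <- lapply(seq_along(timepoints), function(it) {
      f <- 1 - exp(-k * timepoints[it])
      sc <- scene
      sc$vesicles$lumen_dye <- f * ext
      sc$seed <- scene$seed + 1000L * it
      render_zstack(sc, channels = unique(c("membrane", "hpts470")),
                    noise = noise)
    })
    return(list(mode = mode, times = timepoints, stacks = stacks,
                truth = truth))
  }
  # proton efflux: equatorial-plane frames, hpts470 + hpts395
  i395 <- .lumen_level(scene, "hpts395")
  frames <- with_seed(scene$seed + 77L, lapply(
    seq_along(timepoints), function(it) {
      t <- timepoints[it]
      R <- ap$ratio_out + (ap$ratio_in - ap$ratio_out) * exp(-k * t)
      if (!is.null(gramicidin_time) && t >= gramicidin_time)
        R <- rep(ap$ratio_out, length(R))
      arr <- array(0, dim = c(2, acq$field_px[1], acq$field_px[2]))
      discs470 <- data.frame(x = v$x, y = v$y, radius = v$diameter / 2,
                             amp = R * i395)
      discs395 <- data.frame(x = v$x, y = v$y, radius = v$diameter / 2,
                             amp = i395)
      arr[1, , ] <- .render_plane(acq, discs = discs470, noise = noise)
      arr[2, , ] <- .render_plane(acq, discs = discs395, noise = noise)
      image_stack(arr, axes = c("channel", "y", "x"),
                  pixel_size = acq$pixel_size,
                  channel_labels = c("hpts470", "hpts395"))
    }))
  mem <- with_seed(scene$seed + 78L, {
    rings <- data.frame(x = v$x, y = v$y, radius = v$diameter / 2,
                        amp = v$membrane_intensity)
    m <- .render_plane(acq, rings = rings, noise = noise)
    image_stack(m, axes = c("y", "x"), pixel_size = acq$pixel_size)
  })
  list(mode = mode, times = timepoints, frames = frames,
       membrane_frame = mem, truth = truth)
}

#' Simulate a flow immobilization time series
#'
#' Renders membrane-channel frames at the vesicle equatorial plane. After
#' `flow_start`, vesicles with `immobilized = FALSE` translate along +x by
#' `displacement_per_frame` pixels per frame (leaving the field when out of
#' bounds); immobilized vesicles stay put.
#'
#' @param scene A [sample_population()] scene (set
#'   `assay_params$immobilized_fraction` when sampling).
#' @param flow_start Time (s) at which flow begins.
#' @param displacement_per_frame Per-frame displacement of mobile vesicles,
#'   pixels.
#' @param n_frames Number of frames.
#' @param frame_interval Seconds between frames (default: acquisition value).
#' @param noise Apply the noise model?
#' @return List with `times`, `frames` (list of 2-D [image_stack()]s),
#'   `flow_on` (logical per frame), and `truth` (per-vesicle immobilized
#'   flag plus the ground-truth immobilized percentage as an attribute).
#' @export
simulate_flow_series <- function(scene, flow_start = 15,
                                 displacement_per_frame = 10,
                                 n_frames = 24, frame_interval = NULL,
                                 noise = TRUE) {
  acq <- scene$acquisition
  if (is.null(frame_interval)) frame_interval <- acq$frame_interval
  v <- scene$vesicles
  times <- (seq_len(n_frames) - 1) * frame_interval
  flow_on <- times >= flow_start
  disp_um <- displacement_per_frame * acq$pixel_size
  frames <- with_seed(scene$seed + 55L, lapply(
    seq_len(n_frames), function(it) {
      shift <- disp_um * sum(flow_on[seq_len(it)])
      x <- v$x + ifelse(v$immobilized, 0, shift)
      keep <- x - v$diameter / 2 < field_um(acq)[2]
      rings <- data.frame(x = x[keep], y = v$y[keep],
                          radius = v$diameter[keep] / 2,
                          amp = v$membrane_intensity[keep])
      m <- .render_plane(acq, rings = rings, noise = noise)
      image_stack(m, axes = c("y", "x"), pixel_size = acq$pixel_size)
    }))
  truth <- data.frame(id = v$id, immobilized = v$immobilized)
  attr(truth, "percent_immobilized") <-
    if (nrow(v)) 100 * mean(v$immobilized) else NA_real_
  list(times = times, frames = frames, flow_on = flow_on, truth = truth)
}

#' Simulate a charge-mediated fusion time series
#'
#' Before `add_time` all intensities are flat. After vesicle addition, each
#' GUV's membrane-channel ring intensity rises along a saturating curve
#' `G_i * (1 - exp(-(t - add_time)/tau))` with per-vesicle gain
#' `G_i = fusogenicity_i * suv_gain`; the protein channel rises
#' proportionally, scaled by `proteo_fraction * calibration`.
#'
#' @param scene A [sample_population()] scene.
#' @param timepoints Acquisition times, seconds.
#' @param add_time SUV addition time, seconds.
#' @param proteo_fraction Fraction of added SUVs carrying labeled protein,
#'   in `[0, 1]`.
#' @param suv_gain Asymptotic membrane-intensity gain for a vesicle of unit
#'   fusogenicity, AFU.
#' @param tau Saturation time constant, seconds.
#' @param calibration Protein-channel AFU gained per membrane-channel AFU at
#'   `proteo_fraction = 1`.
#' @param noise Apply the noise model?
#' @return List with `times`, `frames` (list of `(channel, y, x)` stacks with
#'   channels `membrane`, `protein`), and `truth` (per-vesicle asymptotic
#'   membrane gain and protein gain).
#' @export
simulate_fusion_series <- function(scene, timepoints = seq(0, 300, by = 15),
                                   add_time = 30, proteo_fraction = 1,
                                   suv_gain = 400, tau = 60,
                                   calibration = 0.5, noise = TRUE) {
  if (proteo_fraction < 0 || proteo_fraction > 1)
    stop("proteo_fraction must be in [0, 1]")
  acq <- scene$acquisition
  v <- scene$vesicles
  G <- v$fusogenicity * suv_gain
  frames <- with_seed(scene$seed + 33L, lapply(
    seq_along(timepoints), function(it) {
      t <- timepoints[it]
      s <- if (t > add_time) 1 - exp(-(t - add_time) / tau) else 0
      mem <- v$membrane_intensity + G * s
      prot <- v$protein_density + proteo_fraction * calibration * G * s
      arr <- array(0, dim = c(2, acq$field_px[1], acq$field_px[2]))
      arr[1, , ] <- .render_plane(
        acq, rings = data.frame(x = v$x, y = v$y, radius = v$diameter / 2,
                                amp = mem), noise = noise)
      arr[2, , ] <- .render_plane(
        acq, rings = data.frame(x = v$x, y = v$y, radius = v$diameter / 2,
                                amp = prot), noise = noise)
      image_stack(arr, axes = c("channel", "y", "x"),
                  pixel_size = acq$pixel_size,
                  channel_labels = c("membrane", "protein"))
    }))
  truth <- data.frame(id = v$id, membrane_gain = G,
                      protein_gain = proteo_fraction * calibration * G)
  list(times = timepoints, frames = frames, truth = truth,
       proteo_fraction = proteo_fraction, calibration = calibration)
}
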