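#' Detection parameters for GUV particle analysis
#'
#' Bundles the parameters of the two-stage detection workflow. The Z-stack
#' path uses per-slice rolling-ball background subtraction (radius 100 px),
#' average projection and a 40/5 px bandpass before thresholding, with a size
#' acceptance of 0.75 um^2 to infinity. The single-image path thresholds the
#' frame directly and accepts 19.6-314.1 um^2, i.e. circles of 5-20 um
#' diameter. Circularity acceptance is 0.70-1.00 in both paths and
#' edge-touching particles are excluded.
#'
#' @param mode `"zstack"` or `"single"`; sets the size-filter defaults.
#' @param rolling_ball_radius Rolling-ball radius, px.
#' @param bandpass_large,bandpass_small Bandpass structure sizes, px.
#' @param threshold `"otsu"` or a fixed numeric threshold (the scripted
#'   stand-in for manual thresholding; the value used is always recorded).
#' @param min_area,max_area Particle area acceptance, um^2.
#' @param circularity_range Circularity acceptance `c(lo, hi)`; the upper
#'   bound of 1.00 admits discretized near-circles whose raw value exceeds 1
#'   (reported values are clamped to 1).
#' @param exclude_edges Drop particles touching the frame edge?
#' @return A list of class `DetectionParams`.
#' @export
detection_params <- function(mode = c("zstack", "single"),
                             rolling_ball_radius = 100,
                             bandpass_large = 40, bandpass_small = 5,
                             threshold = "otsu",
                             min_area = NULL, max_area = NULL,
                             circularity_range = c(0.70, 1.00),
                             exclude_edges = TRUE) {
  mode <- match.arg(mode)
  if (is.null(min_area)) min_area <- if (mode == "zstack") 0.75 else 19.6
  if (is.null(max_area)) max_area <- if (mode == "zstack") Inf else 314.1
  stopifnot(min_area < max_area,
            circularity_range[1] >= 0, circularity_range[1] <= 1)
  structure(list(mode = mode, rolling_ball_radius = rolling_ball_radius,
                 bandpass_large = bandpass_large,
                 bandpass_small = bandpass_small, threshold = threshold,
                 min_area = min_area, max_area = max_area,
                 circularity_range = circularity_range,
                 exclude_edges = exclude_edges),
            class = "DetectionParams")
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background of a single slice by grey-scale opening
#' with a disc structuring element and subtracts it. For radii above 16 px
#' the image is shrunk by block minimum, opened at the reduced radius, and
#' the background enlarged back by bilinear interpolation (the standard
#' speed-up for large radii). With `light_background` the image is inverted
#' about its maximum first, so bright uniform background maps back to a
#' bright plateau and dark objects are preserved as dips.
#'
#' @param image 2-D numeric matrix.
#' @param radius Ball radius, px (>= 1).
#' @param light_background Objects darker than the background?
#' @return Background-subtracted matrix; clipped at 0 for dark background.
#' @export
rolling_ball_subtract <- function(image, radius = 100,
                                  light_background = FALSE) {
  if (length(dim(image)) != 2)
    stop("rolling_ball_subtract expects a single 2-D slice")
  stopifnot(radius >= 1)
  if (light_background) {
    M <- max(image)
    return(M - rolling_ball_subtract(M - image, radius,
                                     light_background = FALSE))
  }
  shrink <- max(1L, floor(radius / 16))
  if (shrink > 1L) {
    small <- .block_min(image, shrink)
    r2 <- max(1, round(radius / shrink))
    if (2 * r2 + 1 >= min(dim(small))) {
      # ball larger than the field: the background estimate degenerates to
      # the global minimum
      bg <- matrix(min(image), nrow(image), ncol(image))
    } else {
      bg <- .grey_opening_disc(small, r2)
      bg <- EBImage::resize(EBImage::Image(bg), w = nrow(image),
                            h = ncol(image))
      bg <- EBImage::imageData(bg)
      bg <- pmin(bg, image)
    }
  } else if (2 * radius + 1 >= min(dim(image))) {
    bg <- matrix(min(image), nrow(image), ncol(image))
  } else {
    bg <- .grey_opening_disc(image, as.integer(radius))
  }
  pmax(image - bg, 0)
}

# Greyscale opening (erosion then dilation) with a flat disc element.
.grey_opening_disc <- function(m, radius) {
  .grey_dilate_disc(.grey_erode_disc(m, radius), radius)
}

# Block-minimum downscaling (pads the last partial block by replication).
.block_min <- function(m, s) {
  nr <- nrow(m); nc <- ncol(m)
  nr2 <- ceiling(nr / s); nc2 <- ceiling(nc / s)
  if (nr2 * s > nr) m <- m[c(seq_len(nr), rep(nr, nr2 * s - nr)), ,
                           drop = FALSE]
  if (nc2 * s > nc) m <- m[, c(seq_len(nc), rep(nc, nc2 * s - nc)),
                           drop = FALSE]
  out <- m[seq(1, nr2 * s, by = s), , drop = FALSE]
  for (k in seq_len(s - 1))
    out <- pmin(out, m[seq(1 + k, nr2 * s, by = s), , drop = FALSE])
  out2 <- out[, seq(1, nc2 * s, by = s), drop = FALSE]
  for (k in seq_len(s - 1))
    out2 <- pmin(out2, out[, seq(1 + k, nc2 * s, by = s), drop = FALSE])
  out2
}

#' Average projection of a stack
#'
#' Per-pixel arithmetic mean over the `z` or `time` axis. Accepts an
#' [image_stack()] (the axis is removed from the result) or a 3-D array whose
#' first dimension is the projection axis, or a list of equally-sized
#' matrices.
#'
#' @param stack Input stack.
#' @param axis `"z"` or `"time"` (for `ImageStack` input).
#' @return Projected image (matrix, or `ImageStack` without the axis).
#' @export
average_projection <- function(stack, axis = c("z", "time")) {
  axis <- match.arg(axis)
  if (is.list(stack) && !inherits(stack, "ImageStack")) {
    out <- Reduce(`+`, stack) / length(stack)
    return(out)
  }
  if (inherits(stack, "ImageStack")) {
    i <- match(axis, stack$axes)
    if (is.na(i)) stop("stack has no ", axis, " axis")
    px <- apply(stack$pixels, seq_along(dim(stack$pixels))[-i], mean)
    return(image_stack(px, axes = stack$axes[-i],
                       pixel_size = stack$pixel_size,
                       channel_labels = stack$channel_labels,
                       z_step = stack$z_step))
  }
  if (length(dim(stack)) == 3) return(apply(stack, c(2, 3), mean))
  stop("unsupported input to average_projection")
}

#' Bandpass filter with autoscaling
#'
#' Suppresses structures larger than `large` px and smaller than `small` px
#' using a difference of Gaussians (a Gaussian-tapered annular mask in
#' frequency space), then linearly rescales to `[0, 1]` with 0.5% tail
#' saturation, replicating the autoscale-with-saturation behavior of the
#' classic FFT bandpass. `suppress_stripes` and `tolerance_direction` are
#' accepted for config compatibility and ignored.
#'
#' @param image 2-D numeric matrix.
#' @param large,small Structure size cut-offs, px (`small < large`).
#' @param autoscale Rescale the result to `[0, 1]`?
#' @param saturation Total tail fraction saturated when autoscaling.
#' @param suppress_stripes,tolerance_direction Ignored (no-op compatibility
#'   keys).
#' @return Filtered matrix (in `[0, 1]` when autoscaled).
#' @export
bandpass_filter <- function(image, large = 40, small = 5, autoscale = TRUE,
                            saturation = 0.005, suppress_stripes = NULL,
                            tolerance_direction = NULL) {
  if (small >= large) stop("bandpass: small must be < large")
  # keep the Gaussian kernel inside the image for small inputs
  rad <- function(sigma) {
    r <- min(2 * ceiling(3 * sigma) + 1, min(dim(image)))
    if (r %% 2 == 0) r <- r - 1
    max(r, 3)
  }
  s_lo <- max(small / 2, 0.4)
  s_hi <- large / 2
  lo <- EBImage::gblur(image, sigma = s_lo, radius = rad(s_lo),
                       boundary = "replicate")
  hi <- EBImage::gblur(image, sigma = s_hi, radius = rad(s_hi),
                       boundary = "replicate")
  out <- EBImage::imageData(lo) - EBImage::imageData(hi)
  if (autoscale) {
    q <- stats::quantile(out, c(saturation / 2, 1 - saturation / 2),
                         names = FALSE)
    if (q[2] > q[1]) {
      out <- (out - q[1]) / (q[2] - q[1])
      out <- pmin(pmax(out, 0), 1)
    } else out <- array(0, dim = dim(out))
  }
  matrix(out, nrow(image), ncol(image))
}

#' Threshold an image into a binary mask
#'
#' @param image 2-D numeric matrix.
#' @param threshold A numeric cut-off (pixels `>=` threshold are foreground),
#'   or `"otsu"` for automatic Otsu thresholding. The threshold actually used
#'   is recorded in the `"threshold"` attribute of the mask.
#' @return Logical-valued 0/1 matrix with attribute `threshold`.
#' @export
binarize <- function(image, threshold = "otsu") {
  if (identical(threshold, "otsu")) {
    rng <- range(image)
    if (diff(rng) < .Machine$double.eps * max(abs(rng), 1)) {
      mask <- matrix(0L, nrow(image), ncol(image))
      attr(mask, "threshold") <- Inf
      return(mask)
    }
    norm <- (image - rng[1]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    threshold <- rng[1] + th * diff(rng)
  }
  mask <- (image >= threshold) * 1L
  attr(mask, "threshold") <- threshold
  mask
}

#' Clean a binary mask: fill holes, erode, watershed-split
#'
#' Applies the standard binary clean-up chain: holes (background components
#' not connected to the border) are filled, one erosion pass with a
#' 4-connected structuring element is applied, and touching blobs are split
#' by a distance-transform watershed; pixels on the boundary between distinct
#' watershed labels are cleared so components separate.
#'
#' @param mask 0/1 matrix.
#' @param watershed_tolerance Minimum distance-map depth between objects
#'   (px); higher merges more.
#' @return Cleaned 0/1 matrix.
#' @export
clean_mask <- function(mask, watershed_tolerance = 1) {
  br <- EBImage::makeBrush(3, "diamond")
  # seal 8-connected ring outlines before flood-filling: a one-pixel
  # dilation makes thin rings 4-connected so their interior is a hole,
  # then the dilation is undone (a closing with hole filling in between)
  m <- EBImage::dilate(mask > 0, br)
  m <- EBImage::fillHull(m)
  m <- EBImage::erode(m, br)
  m <- EBImage::erode(m, br)
  m <- EBImage::imageData(m) > 0
  if (!any(m)) return(matrix(0L, nrow(mask), ncol(mask)))
  d <- EBImage::distmap(m)
  w <- EBImage::imageData(EBImage::watershed(d, tolerance = watershed_tolerance,
                                             ext = 1))
  # clear pixels whose 4-neighborhood holds a different nonzero label
  nr <- nrow(w); nc <- ncol(w)
  sep <- matrix(FALSE, nr, nc)
  shift_pairs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  for (s in shift_pairs) {
    nb <- matrix(0, nr, nc)
    rs <- max(1, 1 + s[1]):min(nr, nr + s[1])
    cs <- max(1, 1 + s[2]):min(nc, nc + s[2])
    nb[rs - s[1], cs - s[2]] <- w[rs, cs]
    sep <- sep | (w > 0 & nb > 0 & nb != w)
  }
  out <- (w > 0 & !sep) * 1L
  out
}

#' Measure and filter particles in a mask
#'
#' Labels connected components and measures each: area and perimeter in
#' physical units, circularity `4*pi*A/P^2`, maximum-caliper (Feret)
#' diameter, and centroid. Components outside the area range, outside the
#' circularity range, or touching the frame edge (when `exclude_edges`) are
#' dropped. Perimeter is the convex-hull perimeter of the pixel centers plus
#' `pi` pixels (half-pixel boundary offset); Feret is the maximum pairwise
#' hull-vertex distance plus one pixel.
#'
#' @param mask 0/1 matrix (labelled internally).
#' @param pixel_size um/px.
#' @param params A [detection_params()].
#' @return A `data.frame` of class `guv_rois` with columns `id`,
#'   `centroid_x_um`, `centroid_y_um`, `area_um2`, `perimeter_um`,
#'   `circularity`, `feret_um`, `n_px`, `label`; the label matrix is attached
#'   as attribute `labels` and `pixel_size`/`params` as attributes.
#' @export
find_vesicles <- function(mask, pixel_size,
                          params = detection_params("single")) {
  stopifnot(pixel_size > 0)
  lab <- EBImage::imageData(EBImage::bwlabel(mask > 0))
  n <- max(lab)
  empty <- data.frame(id = integer(0), centroid_x_um = numeric(0),
                      centroid_y_um = numeric(0), area_um2 = numeric(0),
                      perimeter_um = numeric(0), circularity = numeric(0),
                      feret_um = numeric(0), n_px = integer(0),
                      label = integer(0))
  if (n == 0) return(.as_guv_rois(empty, lab, pixel_size, params))
  idx <- which(lab > 0)
  labs <- lab[idx]
  rows <- ((idx - 1) %% nrow(lab)) + 1
  cols <- ((idx - 1) %/% nrow(lab)) + 1
  nr <- nrow(lab); nc <- ncol(lab)
  by_lab_r <- split(rows, labs)
  by_lab_c <- split(cols, labs)
  res <- lapply(seq_len(n), function(l) {
    r <- by_lab_r[[as.character(l)]]
    cc <- by_lab_c[[as.character(l)]]
    npx <- length(r)
    on_edge <- any(r == 1L | r == nr | cc == 1L | cc == nc)
    if (npx >= 3) {
      pts <- unique(cbind(cc, r))
      h <- grDevices::chull(pts)
      hv <- pts[h, , drop = FALSE]
      per_px <- sum(sqrt(rowSums((hv - hv[c(2:nrow(hv), 1), ,
                                          drop = FALSE])^2))) + pi
      dmat <- as.matrix(stats::dist(hv))
      feret_px <- max(dmat) + 1
    } else {
      per_px <- pi * sqrt(npx)
      feret_px <- sqrt(npx)
    }
    area <- npx * pixel_size^2
    per <- per_px * pixel_size
    c(x = mean(cc), y = mean(r), area = area, per = per,
      circ = 4 * pi * area / per^2, feret = feret_px * pixel_size,
      npx = npx, edge = on_edge)
  })
  m <- do.call(rbind, res)
  keep <- m[, "area"] >= params$min_area & m[, "area"] <= params$max_area &
    m[, "circ"] >= params$circularity_range[1] &
    (params$circularity_range[2] >= 1 |
       m[, "circ"] <= params$circularity_range[2])
  if (params$exclude_edges) keep <- keep & m[, "edge"] == 0
  kept <- which(keep)
  df <- data.frame(
    id = seq_along(kept),
    centroid_x_um = (m[kept, "x"] - 0.5) * pixel_size,
    centroid_y_um = (m[kept, "y"] - 0.5) * pixel_size,
    area_um2 = m[kept, "area"],
    perimeter_um = m[kept, "per"],
    circularity = pmin(m[kept, "circ"], 1),
    feret_um = m[kept, "feret"],
    n_px = as.integer(m[kept, "npx"]),
    label = kept)
  rownames(df) <- NULL
  lab[!(lab %in% kept)] <- 0L
  .as_guv_rois(df, lab, pixel_size, params)
}

.as_guv_rois <- function(df, labels, pixel_size, params,
                         provenance = NULL) {
  attr(df, "labels") <- labels
  attr(df, "pixel_size") <- pixel_size
  attr(df, "params") <- params
  attr(df, "provenance") <- provenance
  class(df) <- c("guv_rois", "data.frame")
  df
}

#' Detect GUVs in a Z-stack or single frame
#'
#' The Z-stack path runs: rolling-ball background subtraction on every slice,
#' average Z projection, bandpass filtering, thresholding, mask clean-up
#' (fill holes / erode / watershed) and particle measurement with the Z-stack
#' size acceptance. The single-image path thresholds the frame directly and
#' uses the 19.6-314.1 um^2 acceptance (5-20 um circles). Full parameter
#' provenance, including the threshold actually applied, is attached to the
#' result.
#'
#' @param x An [image_stack()] or a 2-D matrix. For stacks the membrane
#'   channel (`channel`) is used.
#' @param params A [detection_params()]; defaults to the mode's defaults.
#' @param mode `"zstack"` or `"single"`.
#' @param channel Channel label or index used for detection.
#' @return A `guv_rois` data.frame (see [find_vesicles()]) with a
#'   `provenance` attribute (mode, params, threshold used).
#' @export
detect_guvs <- function(x, params = NULL, mode = c("zstack", "single"),
                        channel = "membrane") {
  mode <- match.arg(mode)
  if (is.null(params)) params <- detection_params(mode)
  if (inherits(x, "ImageStack")) {
    ps <- x$pixel_size
    if (mode == "zstack") {
      nz <- axis_length(x, "z")
      ch <- if (!is.null(x$channel_labels) &&
                channel %in% x$channel_labels) channel else 1L
      slices <- lapply(seq_len(nz), function(iz)
        rolling_ball_subtract(stack_frame(x, z = iz, channel = ch),
                              params$rolling_ball_radius))
      img <- average_projection(slices)
      img <- bandpass_filter(img, params$bandpass_large,
                             params$bandpass_small)
    } else {
      img <- stack_frame(x, channel = if (!is.null(x$channel_labels) &&
                                          channel %in% x$channel_labels)
        channel else 1L)
    }
  } else {
    ps <- attr(x, "pixel_size")
    if (is.null(ps))
      stop("matrix input needs a 'pixel_size' attribute (um/px)")
    img <- x
    if (mode == "zstack") {
      img <- rolling_ball_subtract(img, params$rolling_ball_radius)
      img <- bandpass_filter(img, params$bandpass_large,
                             params$bandpass_small)
    }
  }
  mask <- binarize(img, params$threshold)
  thr <- attr(mask, "threshold")
  mask <- clean_mask(mask)
  rois <- find_vesicles(mask, ps, params)
  attr(rois, "provenance") <- list(mode = mode, params = params,
                                   threshold = thr)
  rois
}

#' Mean intensity of each ROI on a frame
#'
#' Arithmetic mean of the pixels inside each ROI footprint, using the label
#' matrix attached to the ROI table.
#'
#' @param image 2-D matrix, same size as the detection frame.
#' @param rois A `guv_rois` table (from [find_vesicles()] / [detect_guvs()]).
#' @return `data.frame` with `id` and `mean_intensity`.
#' @export
measure_rois <- function(image, rois) {
  lab <- attr(rois, "labels")
  if (is.null(lab)) stop("rois carry no label matrix")
  if (!all(dim(image) == dim(lab)))
    stop("image and ROI label matrix sizes differ")
  if (nrow(rois) == 0)
    return(data.frame(id = integer(0), mean_intensity = numeric(0)))
  idx <- which(lab > 0)
  means <- tapply(image[idx], lab[idx], mean)
  data.frame(id = rois$id,
             mean_intensity = as.numeric(means[as.character(rois$label)]))
}
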