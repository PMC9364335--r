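#' Normalized Z intensity profiles of ROIs
#'
#' For each ROI, the per-slice mean intensity is extracted along the Z axis
#' and divided by the mean of the first `n_anchor` slices (recorded above the
#' vesicles, where only background is present). A ROI whose anchor mean is
#' not positive cannot be normalized and is excluded with a reason.
#'
#' @param stack An [image_stack()] with a `z` axis (the dye channel).
#' @param rois A `guv_rois` table whose label matrix matches the stack's
#'   frame size.
#' @param n_anchor Number of leading slices used as the normalization anchor.
#' @param channel Channel used when the stack has a channel axis.
#' @return Matrix of normalized profiles (`n_z` rows, one column per ROI,
#'   columns named by ROI id; excluded ROIs are dropped). Attributes:
#'   `n_anchor`, `excluded` (data.frame id/reason).
#' @export
normalized_z_profile <- function(stack, rois, n_anchor = 20,
                                 channel = "hpts470") {
  nz <- axis_length(stack, "z")
  if (nz < n_anchor)
    stop("stack has ", nz, " slices; need at least n_anchor = ", n_anchor)
  prof <- vapply(seq_len(nz), function(iz)
    measure_rois(stack_frame(stack, z = iz, channel = channel),
                 rois)$mean_intensity,
    numeric(nrow(rois)))
  prof <- matrix(prof, nrow = nrow(rois))  # rois x z
  anchor <- rowMeans(prof[, seq_len(n_anchor), drop = FALSE])
  bad <- which(anchor <= 0)
  excluded <- data.frame(id = rois$id[bad],
                         reason = rep("non-positive anchor", length(bad)))
  keep <- setdiff(seq_len(nrow(rois)), bad)
  out <- t(prof[keep, , drop = FALSE] / anchor[keep])
  colnames(out) <- rois$id[keep]
  attr(out, "n_anchor") <- n_anchor
  attr(out, "excluded") <- excluded
  out
}

#' Dye-exclusion score of vesicle Z profiles
#'
#' Background ROI profiles are averaged into a mean background profile; this
#' is subtracted from each vesicle profile and the result inverted, so a
#' vesicle that excludes the exterior dye scores positive. The score is the
#' maximum over Z, i.e. the largest absence of dye signal:
#' `score = max_z(mean background profile - vesicle profile)`.
#'
#' @param guv_profiles Matrix of normalized vesicle profiles (slices x
#'   vesicles), as from [normalized_z_profile()].
#' @param bg_profiles Matrix of normalized background-ROI profiles (slices x
#'   ROIs, >= 1 column; typically 20).
#' @return Named numeric vector of scores, one per vesicle column.
#' @export
exclusion_score <- function(guv_profiles, bg_profiles) {
  if (is.null(dim(bg_profiles))) bg_profiles <- cbind(bg_profiles)
  if (ncol(bg_profiles) < 1) stop("need at least one background profile")
  if (nrow(guv_profiles) != nrow(bg_profiles))
    stop("vesicle and background profiles have different slice counts")
  bg_mean <- rowMeans(bg_profiles)
  apply(guv_profiles, 2, function(p) max(bg_mean - p))
}

#' Classify vesicles as leaky from exclusion scores
#'
#' The leakage threshold is a fraction (default 25%) of the mean of the
#' per-condition score medians measured under designated low-adhesion
#' reference (control) conditions. Vesicles scoring below the threshold are
#' labelled leaky.
#'
#' @param scores Numeric vector of exclusion scores for the condition under
#'   test.
#' @param reference_scores Reference condition scores: a numeric vector or a
#'   list of numeric vectors (one per reference condition).
#' @param fraction Threshold fraction of the mean reference median.
#' @return List: `labels` (`"leaky"`/`"tight"` per vesicle), `threshold`,
#'   `leaky_percent`, `n`.
#' @export
classify_leaky <- function(scores, reference_scores, fraction = 0.25) {
  if (!is.list(reference_scores)) reference_scores <- list(reference_scores)
  if (length(reference_scores) == 0 ||
      any(!vapply(reference_scores, length, 1L)))
    stop("empty reference scores")
  thr <- fraction * mean(vapply(reference_scores, stats::median, numeric(1)))
  labels <- ifelse(scores < thr, "leaky", "tight")
  list(labels = labels, threshold = thr,
       leaky_percent = 100 * mean(scores < thr), n = length(scores))
}

#' Apply the dye-permeation analysis exclusion filters
#'
#' Reproduces the analysis caps of the exclusion assay: the ROI list is first
#' truncated to `caps[1]` vesicles in detection order, vesicles outside the
#' diameter band (`min_d`-`max_d`, default 7-20 um: small vesicles span too
#' few slices and tend to move) are discarded, and the remainder truncated to
#' `caps[2]`. Every exclusion is logged with its reason.
#'
#' @param rois A `guv_rois` table (detection order preserved).
#' @param min_d,max_d Feret-diameter band, um.
#' @param caps Two counts: sample cap applied before the band, analysis cap
#'   applied after.
#' @return Filtered `guv_rois` with attribute `exclusions`
#'   (data.frame id/reason).
#' @export
apply_hpts_exclusion_filters <- function(rois, min_d = 7, max_d = 20,
                                         caps = c(148, 85)) {
  excl <- data.frame(id = integer(0), reason = character(0))
  note <- function(ids, why) rbind(excl, data.frame(id = ids,
                                                    reason = why))
  keep <- seq_len(nrow(rois))
  if (length(keep) > caps[1]) {
    excl <- note(rois$id[keep[-seq_len(caps[1])]], "over sample cap")
    keep <- keep[seq_len(caps[1])]
  }
  d <- rois$feret_um[keep]
  sub7 <- keep[d < min_d]
  over <- keep[d > max_d]
  if (length(sub7)) excl <- note(rois$id[sub7],
                                 sprintf("sub-%g um", min_d))
  if (length(over)) excl <- note(rois$id[over],
                                 sprintf("over %g um", max_d))
  keep <- keep[d >= min_d & d <= max_d]
  if (length(keep) > caps[2]) {
    excl <- note(rois$id[keep[-seq_len(caps[2])]], "over analysis cap")
    keep <- keep[seq_len(caps[2])]
  }
  out <- rois[keep, , drop = FALSE]
  attr(out, "labels") <- attr(rois, "labels")
  attr(out, "pixel_size") <- attr(rois, "pixel_size")
  attr(out, "params") <- attr(rois, "params")
  class(out) <- class(rois)
  attr(out, "exclusions") <- excl
  out
}

#' Ratiometric pH-dye ratio
#'
#' The 470 nm excitation intensity of the dye rises with pH while the 395 nm
#' intensity is used as the reference, so `R = I470 / I395` reports lumen pH
#' independently of dye amount and bleaching.
#'
#' @param i470,i395 Intensities at 470 / 395 nm excitation (vectorized).
#' @return Ratio(s).
#' @export
hpts_ratio <- function(i470, i395) {
  if (any(i395 <= 0)) stop("reference (395 nm) intensity must be positive")
  i470 / i395
}

#' Proton-leakage percentage of one ratio trace
#'
#' The ratio increase over the first `t_mid` minutes is divided by the total
#' possible increase, i.e. the increase from `t0` to the post-protonophore
#' endpoint: `100 * (R(t_mid) - R(t0)) / (R(t_end) - R(t0))`. Vesicles whose
#' early ratio change is not positive are excluded (leakage would raise the
#' lumen pH); a non-positive total increase means no protonophore response
#' and also excludes the vesicle. The nearest acquired sample to each
#' requested time is used; alternatively `end_window` averages the ratio over
#' a post-protonophore plateau window.
#'
#' @param times Sample times, minutes.
#' @param ratios Ratio trace, same length as `times`.
#' @param t0,t_mid,t_end Evaluation times, minutes.
#' @param end_window Optional `c(from, to)` window (minutes) whose mean ratio
#'   replaces the single `t_end` sample.
#' @return List: `percent` (NA when excluded), `label`
#'   (`"ok"`/`"excluded"`), `reason`, and the ratios used.
#' @export
proton_leakage_percent <- function(times, ratios, t0 = 0, t_mid = 20,
                                   t_end = 66, end_window = NULL) {
  stopifnot(length(times) == length(ratios))
  at <- function(t) ratios[which.min(abs(times - t))]
  r0 <- at(t0)
  rm_ <- at(t_mid)
  re <- if (is.null(end_window)) at(t_end) else
    mean(ratios[times >= end_window[1] & times <= end_window[2]])
  d_mid <- rm_ - r0
  if (is.na(d_mid) || d_mid <= 0)
    return(list(percent = NA_real_, label = "excluded",
                reason = "negative 20-min delta", r0 = r0, r_mid = rm_,
                r_end = re))
  d_tot <- re - r0
  if (d_tot <= 0)
    return(list(percent = NA_real_, label = "excluded",
                reason = "no gramicidin response", r0 = r0, r_mid = rm_,
                r_end = re))
  list(percent = 100 * d_mid / d_tot, label = "ok", reason = NA_character_,
       r0 = r0, r_mid = rm_, r_end = re)
}

#' Proton-leakage table for a set of vesicles
#'
#' Applies [proton_leakage_percent()] to each column of a ratio matrix.
#'
#' @param times Sample times, minutes.
#' @param ratio_matrix Matrix of ratio traces, one column per vesicle
#'   (column names used as ids when present).
#' @param ... Passed to [proton_leakage_percent()].
#' @return `data.frame`: `guv_id`, `percent`, `label`, `reason`.
#' @export
proton_leakage_table <- function(times, ratio_matrix, ...) {
  ids <- colnames(ratio_matrix)
  if (is.null(ids)) ids <- seq_len(ncol(ratio_matrix))
  rows <- lapply(seq_len(ncol(ratio_matrix)), function(j) {
    r <- proton_leakage_percent(times, ratio_matrix[, j], ...)
    data.frame(guv_id = ids[j], percent = r$percent, label = r$label,
               reason = r$reason)
  })
  do.call(rbind, rows)
}

#' Place background ROIs in vesicle-free areas
#'
#' Samples square patches that do not intersect any detected vesicle
#' (vesicle footprints are avoided with a safety margin), mimicking
#' hand-drawn background regions but reproducibly.
#'
#' @param rois A `guv_rois` table carrying the vesicle label matrix.
#' @param n Number of background ROIs.
#' @param size_px Patch edge length, px.
#' @param margin_px Clearance kept from any vesicle pixel, px.
#' @param seed Integer seed.
#' @param max_tries Sampling budget.
#' @return A `guv_rois`-like table whose label matrix holds the background
#'   patches (ids 1..n).
#' @export
#' Paired background annulus next to every vesicle
#'
#' Builds one background ROI per vesicle: an annulus spanning `inner` to
#' `outer` vesicle radii from the centroid, excluding pixels belonging to
#' any detected vesicle (with a safety margin) and pixels of other annuli
#' already placed. This is the reproducible analogue of drawing a background
#' region right next to each vesicle, so local background (including smooth
#' gradients) cancels in the subtraction.
#'
#' @param rois A `guv_rois` table with the vesicle label matrix.
#' @param inner,outer Annulus radii in units of each vesicle's own radius.
#' @param margin_px Clearance kept from any vesicle pixel, px.
#' @return A `guv_rois`-like table (ids matching `rois$id`) whose label
#'   matrix holds the annuli.
#' @export
paired_background_rois <- function(rois, inner = 2, outer = 4,
                                   margin_px = 3) {
  lab <- attr(rois, "labels")
  ps <- attr(rois, "pixel_size")
  if (is.null(lab)) stop("rois carry no label matrix")
  occ <- lab > 0
  if (margin_px > 0)
    occ <- EBImage::imageData(
      EBImage::dilate(occ, EBImage::makeBrush(2 * margin_px + 1,
                                              "disc"))) > 0
  nr <- nrow(occ); nc <- ncol(occ)
  bg <- matrix(0L, nr, nc)
  for (i in seq_len(nrow(rois))) {
    r_v <- rois$feret_um[i] / 2 / ps        # vesicle radius, px
    cx <- rois$centroid_x_um[i] / ps + 0.5  # px coordinates
    cy <- rois$centroid_y_um[i] / ps + 0.5
    half <- outer * r_v
    i0 <- max(1L, floor(cy - half)); i1 <- min(nr, ceiling(cy + half))
    j0 <- max(1L, floor(cx - half)); j1 <- min(nc, ceiling(cx + half))
    yy <- (i0:i1) - cy
    xx <- (j0:j1) - cx
    rho <- sqrt(outer(yy^2, xx^2, "+"))
    sel <- rho >= inner * r_v & rho <= outer * r_v
    patch_occ <- occ[i0:i1, j0:j1] | bg[i0:i1, j0:j1] > 0
    sel <- sel & !patch_occ
    sub <- bg[i0:i1, j0:j1]
    sub[sel] <- i
    bg[i0:i1, j0:j1] <- sub
  }
  df <- data.frame(id = rois$id, label = seq_len(nrow(rois)))
  .as_guv_rois(df, bg, ps, attr(rois, "params"))
}

background_rois <- function(rois, n = 20, size_px = 15, margin_px = 5,
                            seed = 1, max_tries = 20000) {
  lab <- attr(rois, "labels")
  if (is.null(lab)) stop("rois carry no label matrix")
  occ <- lab > 0
  if (margin_px > 0)
    occ <- EBImage::imageData(
      EBImage::dilate(occ, EBImage::makeBrush(2 * margin_px + 1,
                                              "disc"))) > 0
  nr <- nrow(occ); nc <- ncol(occ)
  bg <- matrix(0L, nr, nc)
  with_seed(seed, {
    placed <- 0L
    tries <- 0L
    while (placed < n) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("could not place ", n, " background ROIs")
      r0 <- sample.int(nr - size_px, 1)
      c0 <- sample.int(nc - size_px, 1)
      rs <- r0:(r0 + size_px - 1L)
      cs <- c0:(c0 + size_px - 1L)
      if (!any(occ[rs, cs]) && !any(bg[rs, cs] > 0)) {
        placed <- placed + 1L
        bg[rs, cs] <- placed
      }
    }
  })
  df <- data.frame(id = seq_len(n), label = seq_len(n))
  .as_guv_rois(df, bg, attr(rois, "pixel_size"), attr(rois, "params"))
}
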