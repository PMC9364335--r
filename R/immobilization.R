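#' Count vesicles on the last frame before flow
#'
#' Runs single-image detection on the designated pre-flow frame. The frame
#' index and the threshold actually applied are recorded so the during-flow
#' count can reuse them.
#'
#' @param frame A 2-D [image_stack()] or matrix with a `pixel_size`
#'   attribute.
#' @param params A [detection_params()] (single-image defaults when `NULL`).
#' @param frame_index Index of the frame in its series, for provenance.
#' @return List with `n`, `rois`, `threshold`, `frame_index`.
#' @export
count_before_flow <- function(frame, params = NULL, frame_index = NA) {
  rois <- detect_guvs(frame, params = params, mode = "single")
  list(n = nrow(rois), rois = rois,
       threshold = attr(rois, "provenance")$threshold,
       frame_index = frame_index)
}

#' Count immobilized vesicles from the during-flow projection
#'
#' Averages all frames recorded during flow into one projection: moving
#' vesicles smear into faint streaks while immobilized vesicles retain their
#' intensity, so thresholding the projection at the pre-flow threshold counts
#' only immobilized vesicles.
#'
#' @param flow_frames List (>= 2) of 2-D [image_stack()]s or matrices
#'   recorded during flow.
#' @param params A [detection_params()]; its `threshold` should normally be
#'   set to the pre-flow frame's threshold so the two counts are comparable.
#' @return List with `n` and `rois`.
#' @export
detect_immobilized <- function(flow_frames, params = NULL) {
  if (length(flow_frames) < 2)
    stop("need at least 2 during-flow frames to form a projection")
  mats <- lapply(flow_frames, function(f)
    if (inherits(f, "ImageStack")) stack_frame(f) else f)
  ps <- if (inherits(flow_frames[[1]], "ImageStack"))
    flow_frames[[1]]$pixel_size else attr(flow_frames[[1]], "pixel_size")
  proj <- average_projection(mats)
  attr(proj, "pixel_size") <- ps
  rois <- detect_guvs(proj, params = params, mode = "single")
  list(n = nrow(rois), rois = rois)
}

#' Percentage of immobilized vesicles
#'
#' `100 * n_immobilized / n_before`. A zero pre-flow count gives `NA` with a
#' warning; a during-flow count exceeding the pre-flow count (possible only
#' on pathological input) is flagged and capped at 100.
#'
#' @param n_before Vesicle count before flow.
#' @param n_immobilized Vesicle count on the during-flow projection.
#' @return Percent in `[0, 100]` (or `NA`).
#' @export
percent_immobilized <- function(n_before, n_immobilized) {
  if (n_before == 0) {
    warning("no vesicles before flow; immobilized percentage undefined")
    return(NA_real_)
  }
  p <- 100 * n_immobilized / n_before
  if (p > 100) {
    warning("more vesicles detected during flow than before; capping at 100")
    p <- 100
  }
  p
}

#' Score a complete flow immobilization assay
#'
#' Convenience wrapper: detects vesicles on the pre-flow frame, forms the
#' during-flow average projection, re-detects using the pre-flow threshold,
#' and reports the immobilized percentage with full provenance.
#'
#' @param frames List of 2-D frames (the full time series).
#' @param pre_flow_frame Index of the last frame before visible flow
#'   (chosen by the experimenter, not auto-detected).
#' @param flow_frames Indices of the frames recorded during flow; default is
#'   every frame after `pre_flow_frame`.
#' @param params Optional [detection_params()] for the pre-flow detection.
#' @return A one-row `data.frame` (class `FlowAssayResult`): `n_before`,
#'   `n_immobilized`, `percent`, `threshold`, `pre_flow_frame`.
#' @export
run_flow_assay <- function(frames, pre_flow_frame,
                           flow_frames = NULL, params = NULL) {
  if (is.null(flow_frames))
    flow_frames <- seq(pre_flow_frame + 1L, length(frames))
  before <- count_before_flow(frames[[pre_flow_frame]], params = params,
                              frame_index = pre_flow_frame)
  p2 <- if (is.null(params)) detection_params("single") else params
  p2$threshold <- before$threshold
  during <- detect_immobilized(frames[flow_frames], params = p2)
  out <- data.frame(n_before = before$n, n_immobilized = during$n,
                    percent = percent_immobilized(before$n, during$n),
                    threshold = before$threshold,
                    pre_flow_frame = pre_flow_frame)
  class(out) <- c("FlowAssayResult", "data.frame")
  out
}
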