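#' Background-corrected intensity trace of each vesicle
#'
#' For every frame of a time series, the mean intensity inside each vesicle
#' ROI minus the mean of its paired background ROI. Pairing is by position in
#' the two tables (one background ROI per vesicle).
#'
#' @param frames List of 2-D frames ([image_stack()]s or matrices), one per
#'   timepoint; for multi-channel stacks `channel` selects the channel.
#' @param times Acquisition times, seconds.
#' @param rois Vesicle `guv_rois` table.
#' @param bg_rois Background `guv_rois` table, same number of rows as `rois`.
#' @param channel Channel label for multi-channel frames.
#' @return Long `data.frame` of class `FusionTrace`: `guv_id`, `time`,
#'   `intensity`, `channel`.
#' @export
fusion_trace <- function(frames, times, rois, bg_rois,
                         channel = "membrane") {
  stopifnot(length(frames) == length(times), all(diff(times) > 0))
  if (nrow(bg_rois) != nrow(rois))
    stop("need one paired background ROI per vesicle")
  rows <- lapply(seq_along(frames), function(it) {
    img <- frames[[it]]
    if (inherits(img, "ImageStack"))
      img <- stack_frame(img, channel = channel)
    v <- measure_rois(img, rois)$mean_intensity
    b <- measure_rois(img, bg_rois)$mean_intensity
    data.frame(guv_id = rois$id, time = times[it], intensity = v - b,
               channel = channel)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("FusionTrace", "data.frame")
  out
}

#' Aggregate fusion traces across vesicles and replicates
#'
#' Two-level aggregation matching how replicate experiments are summarized:
#' within each replicate the mean over vesicles is taken per timepoint, then
#' the cross-replicate mean and sample standard deviation (n - 1) are
#' reported per timepoint. With a single replicate the sd level degenerates
#' and is reported as `NA` with a warning.
#'
#' @param traces Long trace table (`guv_id`, `time`, `intensity`).
#' @param replicate_ids Replicate identifier per row of `traces` (or a named
#'   mapping applied to `guv_id`).
#' @return `data.frame`: `time`, `mean`, `sd`, `n_replicates`.
#' @export
aggregate_traces <- function(traces, replicate_ids) {
  if (length(replicate_ids) == nrow(traces)) rep_id <- replicate_ids
  else rep_id <- replicate_ids[as.character(traces$guv_id)]
  per_rep <- stats::aggregate(intensity ~ time + rep,
                              data = cbind(traces, rep = rep_id), FUN = mean)
  n_rep <- length(unique(per_rep$rep))
  if (n_rep < 2)
    warning("single replicate: cross-replicate sd undefined")
  out <- do.call(rbind, lapply(split(per_rep, per_rep$time), function(d)
    data.frame(time = d$time[1], mean = mean(d$intensity),
               sd = if (n_rep < 2) NA_real_ else stats::sd(d$intensity),
               n_replicates = n_rep)))
  out <- out[order(out$time), ]
  rownames(out) <- NULL
  out
}

#' Background-corrected endpoint intensities per vesicle
#'
#' Extracts the background-corrected mean intensity of every vesicle at the
#' frame nearest a designated endpoint time, for one or more channels
#' (channel pairing is preserved: each channel is measured on its own plane
#' of the same frame).
#'
#' @param frames List of frames (multi-channel [image_stack()]s).
#' @param times Acquisition times, seconds.
#' @param rois,bg_rois Vesicle and paired background ROI tables.
#' @param t_end Endpoint time, seconds.
#' @param channels Channel labels to extract.
#' @param t_baseline Optional pre-addition reference time; when given, the
#'   background-corrected value at the baseline frame is subtracted so the
#'   table reports per-vesicle intensity *gains* (this removes any static
#'   per-vesicle offset, e.g. pre-existing label in the membrane channel).
#' @return `data.frame` with `guv_id` and one column per channel.
#' @export
endpoint_table <- function(frames, times, rois, bg_rois, t_end,
                           channels = c("membrane", "protein"),
                           t_baseline = NULL) {
  it <- which.min(abs(times - t_end))
  ib <- if (is.null(t_baseline)) NA_integer_ else
    which.min(abs(times - t_baseline))
  corrected <- function(frame, ch) {
    img <- frame
    if (inherits(img, "ImageStack")) img <- stack_frame(img, channel = ch)
    measure_rois(img, rois)$mean_intensity -
      measure_rois(img, bg_rois)$mean_intensity
  }
  out <- data.frame(guv_id = rois$id)
  for (ch in channels) {
    v <- corrected(frames[[it]], ch)
    if (!is.na(ib)) v <- v - corrected(frames[[ib]], ch)
    out[[ch]] <- v
  }
  attr(out, "frame_index") <- it
  attr(out, "time") <- times[it]
  out
}

#' Ordinary least-squares regression of protein vs lipid signal
#'
#' Fits `y = a + b x` by OLS across vesicles, with x the membrane-dye
#' endpoint intensity and y the protein-dye endpoint intensity. The slope
#' scales with the fraction of protein-carrying vesicles in the fused
#' material, so it estimates relative protein incorporation without labeling
#' the protein in every experiment.
#'
#' @param x Membrane-channel intensities (or a 2-column data.frame/matrix).
#' @param y Protein-channel intensities.
#' @return List of class `RegressionResult`: `slope`, `intercept`,
#'   `r_squared`, `n_points`, `channel_pair`.
#' @export
protein_lipid_regression <- function(x, y = NULL) {
  if (is.null(y)) {
    stopifnot(ncol(x) >= 2)
    y <- x[[2]]
    x <- x[[1]]
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 points for a reported fit")
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else
                   NA_real_,
                 n_points = length(x),
                 channel_pair = c(x = "membrane", y = "protein")),
            class = "RegressionResult")
}

#' @export
print.RegressionResult <- function(x, ...) {
  cat(sprintf(
    "<RegressionResult> slope %.4g, intercept %.4g, r^2 %.4f (n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}
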