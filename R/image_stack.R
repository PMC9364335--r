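#' Multi-dimensional fluorescence image stack
#'
#' A lightweight container for pixel data with named axes, the physical pixel
#' size, and channel labels. Axes are stored in the canonical order
#' `time, z, channel, y, x` (any subset, but always in that order), matching
#' how confocal acquisitions are organized.
#'
#' @param pixels Numeric array of non-negative intensities. `length(dim(pixels))`
#'   must equal `length(axes)`; a plain matrix is treated as a `(y, x)` frame.
#' @param axes Character vector naming each array dimension, an ordered subset
#'   of `c("time", "z", "channel", "y", "x")`.
#' @param pixel_size Lateral pixel size in micrometers per pixel.
#' @param channel_labels Optional character vector of channel names, one per
#'   element of the channel axis (e.g. `"membrane"`, `"hpts470"`).
#' @param z_step Axial step between Z slices in micrometers (default 1).
#' @param times Optional numeric vector of acquisition times in seconds, one
#'   per element of the time axis.
#'
#' @return An object of class `ImageStack`: a list with elements `pixels`,
#'   `axes`, `pixel_size`, `channel_labels`, `z_step`, `times`.
#' @export
image_stack <- function(pixels, axes, pixel_size, channel_labels = NULL,
                        z_step = 1, times = NULL) {
  if (is.matrix(pixels) && missing(axes)) axes <- c("y", "x")
  axes <- match.arg(axes, c("time", "z", "channel", "y", "x"),
                    several.ok = TRUE)
  canonical <- c("time", "z", "channel", "y", "x")
  if (!identical(axes, canonical[canonical %in% axes]))
    stop("axes must be an ordered subset of time, z, channel, y, x")
  d <- dim(pixels)
  if (is.null(d)) stop("pixels must be an array or matrix")
  if (length(d) != length(axes))
    stop("pixels has ", length(d), " dimensions but ", length(axes),
         " axes were given")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("pixel_size must be a single positive number")
  if ("channel" %in% axes && !is.null(channel_labels)) {
    nc <- d[match("channel", axes)]
    if (length(channel_labels) != nc)
      stop("channel_labels length (", length(channel_labels),
           ") does not match channel axis length (", nc, ")")
  }
  if ("time" %in% axes && !is.null(times)) {
    nt <- d[match("time", axes)]
    if (length(times) != nt)
      stop("times length does not match time axis length")
  }
  structure(list(pixels = pixels, axes = axes, pixel_size = pixel_size,
                 channel_labels = channel_labels, z_step = z_step,
                 times = times),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  cat("<ImageStack> ", paste(x$axes, dim(x$pixels), sep = "=",
                             collapse = " x "),
      " | pixel size ", x$pixel_size, " um/px\n", sep = "")
  if (!is.null(x$channel_labels))
    cat("  channels: ", paste(x$channel_labels, collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Length of a named axis
#'
#' @param stack An [image_stack()].
#' @param axis Axis name.
#' @return Integer axis length (1 if the axis is absent).
#' @export
axis_length <- function(stack, axis) {
  i <- match(axis, stack$axes)
  if (is.na(i)) return(1L)
  dim(stack$pixels)[i]
}

#' Extract a single 2-D frame from a stack
#'
#' Indexes the non-spatial axes and returns the `(y, x)` matrix. Channels may
#' be addressed by label.
#'
#' @param stack An [image_stack()].
#' @param time,z,channel Indices along the respective axes (ignored when the
#'   axis is absent). `channel` may be a label from `channel_labels`.
#' @return A numeric matrix (rows = y, columns = x).
#' @export
stack_frame <- function(stack, time = 1L, z = 1L, channel = 1L) {
  if (is.character(channel)) {
    channel <- match(channel, stack$channel_labels)
    if (is.na(channel)) stop("unknown channel label")
  }
  idx <- list(time = time, z = z, channel = channel)
  args <- lapply(stack$axes, function(a)
    if (a %in% c("y", "x")) substitute() else idx[[a]])
  out <- do.call(`[`, c(list(stack$pixels), args, list(drop = FALSE)))
  dim(out) <- utils::tail(dim(stack$pixels), 2)
  out
}

#' Z positions of the slices of a stack, in micrometers
#'
#' Slice 1 (recorded top-most) is at 0; positions increase downward by
#' `z_step`.
#'
#' @param stack An [image_stack()].
#' @return Numeric vector of length `axis_length(stack, "z")`.
#' @export
z_positions <- function(stack) {
  (seq_len(axis_length(stack, "z")) - 1) * stack$z_step
}

# Evaluate expr with a temporarily-seeded RNG, restoring global state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
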