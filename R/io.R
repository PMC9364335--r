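#' Write an image stack to TIFF with a metadata sidecar
#'
#' Pixel data are written as a multi-page 16-bit TIFF (pages enumerate the
#' non-spatial axes in canonical order) and the axis layout, pixel size,
#' channel labels, z step and times go to a JSON sidecar `<path>.json`, so a
#' round trip through [read_stack()] is lossless for integer-valued pixels up
#' to 65535 AFU.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$pixels)
  nsp <- length(d) - 2L
  pages <- if (nsp == 0) list(stack$pixels / 65535) else {
    grid <- expand.grid(lapply(rev(d[seq_len(nsp)]), seq_len))
    grid <- grid[, rev(seq_len(ncol(grid))), drop = FALSE]  # row-major order
    lapply(seq_len(nrow(grid)), function(i) {
      args <- c(list(stack$pixels), as.list(unlist(grid[i, ])),
                rep(list(substitute()), 2), list(drop = FALSE))
      pg <- do.call(`[`, args)
      dim(pg) <- utils::tail(d, 2)
      pg / 65535
    })
  }
  pages <- lapply(pages, function(p) pmin(pmax(p, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  meta <- list(axes = stack$axes, dim = d, pixel_size = stack$pixel_size,
               channel_labels = stack$channel_labels,
               z_step = stack$z_step, times = stack$times, scale = 65535)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' Reads the multi-page TIFF and its JSON sidecar, restores the canonical
#' axis order and physical metadata. A pixel size is mandatory: it is taken
#' from the sidecar unless overridden (the override wins, with a warning),
#' and its absence is an error because all physical-unit filters depend on
#' it.
#'
#' @param path TIFF path (sidecar expected at `<path>.json`).
#' @param pixel_size Optional override, um/px.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_size = NULL) {
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("missing axis sidecar ", side,
         " (stacks must carry axes and pixel size)")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (!is.null(pixel_size)) {
    if (!is.null(meta$pixel_size) && meta$pixel_size != pixel_size)
      warning("overriding stored pixel size ", meta$pixel_size, " with ",
              pixel_size)
    meta$pixel_size <- pixel_size
  }
  if (is.null(meta$pixel_size))
    stop("no pixel size in metadata or arguments")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- if (is.null(meta$scale)) 65535 else meta$scale
  d <- as.integer(meta$dim)
  arr <- array(0, dim = d)
  nsp <- length(d) - 2L
  if (nsp == 0) arr[, ] <- pages[[1]] * scale else {
    grid <- expand.grid(lapply(rev(d[seq_len(nsp)]), seq_len))
    grid <- grid[, rev(seq_len(ncol(grid))), drop = FALSE]
    for (i in seq_along(pages)) {
      args <- c(list(arr), as.list(unlist(grid[i, ])),
                rep(list(substitute()), 2))
      arr <- do.call(`[<-`, c(args, list(value = pages[[i]] * scale)))
    }
  }
  image_stack(round(arr), axes = meta$axes, pixel_size = meta$pixel_size,
              channel_labels = meta$channel_labels,
              z_step = if (is.null(meta$z_step)) 1 else meta$z_step,
              times = meta$times)
}

#' Write a results table as annotated CSV
#'
#' Writes records with a stable column order and a comment header carrying
#' the tool version and, when a configuration is supplied, its hash — so any
#' result file names the exact parameters that produced it.
#'
#' @param records A data.frame (may have zero rows).
#' @param path Output CSV path.
#' @param config Optional configuration list to hash into the header.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, config = NULL) {
  ver <- as.character(utils::packageVersion("guvquant"))
  hdr <- paste0("# guvquant ", ver)
  if (!is.null(config))
    hdr <- paste0(hdr, "; config_hash=", config_hash(config))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(records, con, row.names = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path CSV path.
#' @return data.frame; the header comment is attached as attribute
#'   `"header"`.
#' @export
read_results <- function(path) {
  hdr <- readLines(path, n = 1)
  df <- utils::read.csv(path, comment.char = "#")
  attr(df, "header") <- hdr
  df
}

#' Stable hash of a configuration list
#'
#' @param config A list of parameters.
#' @return 32-character MD5 string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Read a run configuration from YAML
#'
#' Configurations store physical-unit parameters in the units used
#' throughout the package (um, um^2, uL, mm^2, ng/mm^2); conversions happen
#' inside the analysis functions, once, at the boundary.
#'
#' @param path YAML file.
#' @return Named list with attribute `"hash"` ([config_hash()] of the
#'   content).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}
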