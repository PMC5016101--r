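## ImageStack: a registered multichannel 2-D image with pixel size and
## per-channel modality/label metadata. Channels are plain numeric matrices
## indexed (row, col).

#' Construct an image stack
#'
#' @param channels list of numeric matrices, all of the same shape, with
#'   nonnegative intensities.
#' @param pixel_size_nm pixel size in nanometers (default 20).
#' @param labels character vector of channel names.
#' @param modality character vector, one of `"confocal"` or `"sted"` per
#'   channel.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(channels, pixel_size_nm = 20,
                        labels = paste0("ch", seq_along(channels)),
                        modality = rep("sted", length(channels))) {
  stopifnot(is.list(channels), length(channels) >= 1, pixel_size_nm > 0,
            length(labels) == length(channels),
            length(modality) == length(channels),
            all(modality %in% c("confocal", "sted")))
  dims <- vapply(channels, dim, integer(2))
  if (!all(dims[1, ] == dims[1, 1]) || !all(dims[2, ] == dims[2, 1]))
    stop("all channels must share the same shape")
  if (any(vapply(channels, function(ch) any(ch < 0), logical(1))))
    stop("channel intensities must be nonnegative")
  structure(list(
    channels = channels,
    pixel_size_nm = pixel_size_nm,
    meta = data.frame(label = labels, modality = modality,
                      stringsAsFactors = FALSE)
  ), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("image_stack: %d channel(s), %d x %d px, %.3g nm/px\n",
              length(x$channels), d[1], d[2], x$pixel_size_nm))
  for (i in seq_along(x$channels)) {
    cat(sprintf("  [%d] %-12s %-8s range [%.3g, %.3g]\n", i,
                x$meta$label[i], x$meta$modality[i],
                min(x$channels[[i]]), max(x$channels[[i]])))
  }
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$channels[[1]])

#' Write an image stack as a multipage TIFF with a JSON sidecar
#'
#' One 32-bit float page per channel. Pixel values are stored divided by a
#' per-channel scale (the channel maximum) to stay inside the TIFF [0, 1]
#' range; scales, labels, modality and pixel size go to `<path>.json`.
#'
#' @param stack an `image_stack`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  scales <- vapply(stack$channels, function(ch) max(ch, 1e-300), numeric(1))
  pages <- Map(function(ch, s) ch / s, stack$channels, scales)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  side <- list(pixel_size_nm = stack$pixel_size_nm,
               labels = stack$meta$label,
               modality = stack$meta$modality,
               scales = scales)
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#' @param path TIFF path (the `<path>.json` sidecar must exist).
#' @return an `image_stack`.
#' @export
read_stack <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  channels <- Map(function(p, s) p * s, pages, side$scales)
  image_stack(channels, pixel_size_nm = side$pixel_size_nm,
              labels = side$labels, modality = side$modality)
}
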