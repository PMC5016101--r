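## Detection of actively importing organelles as maxima of the smoothed
## matrix-marker channel, and construction of circular analysis regions
## (19 px / 380 nm) with matched random controls.

#' Find intensity maxima with a noise tolerance
#'
#' Gaussian-smooths the channel (sigma = 2 by default) and detects maxima
#' with Find-Maxima semantics: a candidate local maximum of value `v` is
#' accepted iff it cannot be reached from any strictly higher pixel along a
#' path whose values stay at or above `v - noise_tolerance`. Plateaus yield
#' a single point (rounded centroid). The tolerance applies to the smoothed
#' intensities and is relative, so adding a constant to the image leaves the
#' result unchanged.
#'
#' @param channel nonnegative numeric matrix.
#' @param sigma smoothing s.d. in pixels (default 2.0); 0 disables smoothing.
#' @param noise_tolerance prominence threshold in smoothed intensity units
#'   (default 10).
#' @return data.frame with columns `row`, `col`, `value` (smoothed intensity
#'   at the maximum), sorted by descending value.
#' @export
find_maxima <- function(channel, sigma = 2.0, noise_tolerance = 10) {
  stopifnot(is.matrix(channel), all(channel >= 0), sigma >= 0,
            noise_tolerance >= 0)
  sm <- gaussian_blur(channel, sigma)
  if (max(sm) == min(sm)) { # a flat image carries no detection signal
    return(data.frame(row = integer(0), col = integer(0), value = numeric(0)))
  }
  .fm_core(sm, noise_tolerance)
}

#' Build circular analysis regions around detected maxima
#'
#' One region of odd diameter (default 19 px = 380 nm at 20 nm/px) per
#' maximum; maxima whose disc would cross the image border are dropped (all
#' regions must contain the identical pixel count for paired statistics) and
#' counted in the `n_dropped` attribute.
#'
#' @param maxima data.frame from [find_maxima()].
#' @param image_shape integer `(rows, cols)`.
#' @param diameter_px odd region diameter >= 3 (default 19).
#' @return data.frame of regions (`id`, `row`, `col`, `diameter_px`, `kind`,
#'   `source_value`) with attribute `n_dropped`.
#' @export
make_regions <- function(maxima, image_shape, diameter_px = 19) {
  stopifnot(diameter_px >= 3, diameter_px %% 2 == 1)
  m <- (diameter_px - 1) %/% 2
  if (nrow(maxima) == 0) {
    out <- data.frame(id = integer(0), row = integer(0), col = integer(0),
                      diameter_px = integer(0), kind = character(0),
                      source_value = numeric(0))
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  keep <- maxima$row - m >= 1 & maxima$row + m <= image_shape[1] &
    maxima$col - m >= 1 & maxima$col + m <= image_shape[2]
  n_keep <- sum(keep)
  out <- data.frame(id = seq_len(n_keep),
                    row = maxima$row[keep], col = maxima$col[keep],
                    diameter_px = rep(as.integer(diameter_px), n_keep),
                    kind = rep("peroxisomal", n_keep),
                    source_value = maxima$value[keep])
  attr(out, "n_dropped") <- as.integer(sum(!keep))
  out
}

#' Exclusion mask for random-region placement
#'
#' Marks pixels carrying matrix-marker signal: the channel smoothed at the
#' detection scale and thresholded at the background median plus the
#' detection noise tolerance.
#'
#' @param channel matrix-marker image.
#' @param sigma smoothing s.d. (default 2.0, the detection scale).
#' @param noise_tolerance threshold offset above the median (default 10).
#' @return logical matrix.
#' @export
exclusion_mask <- function(channel, sigma = 2.0, noise_tolerance = 10) {
  sm <- gaussian_blur(channel, sigma)
  sm > stats::median(sm) + noise_tolerance
}

## TRUE iff two equal-diameter pixel discs at integer centers share a pixel.
discs_share_pixel <- function(diameter_px) {
  offs <- disc_offsets(diameter_px)
  m <- diameter_px # |difference| < diameter_px always for shared pixels
  tab <- matrix(FALSE, 2 * m + 1, 2 * m + 1)
  d1 <- rep(seq_len(nrow(offs)), each = nrow(offs))
  d2 <- rep(seq_len(nrow(offs)), times = nrow(offs))
  dd <- cbind(offs[d1, 1] - offs[d2, 1], offs[d1, 2] - offs[d2, 2])
  tab[cbind(dd[, 1] + m + 1, dd[, 2] + m + 1)] <- TRUE
  function(delta) {
    if (any(abs(delta) > m)) return(FALSE)
    tab[delta[1] + m + 1, delta[2] + m + 1]
  }
}

#' Generate matched random control regions
#'
#' Each detected region is translated to a uniform-random point within
#' `radius_px` (180 px = 3.6 um) of its source, re-drawn (up to `max_tries`
#' times) while the translated disc would leave the image, overlap any
#' peroxisomal disc, or touch any pixel of the exclusion mask. Regions that
#' exhaust the try budget are omitted and counted in `n_failed`.
#'
#' @param regions peroxisomal regions from [make_regions()].
#' @param exclusion logical matrix marking matrix-marker signal (see
#'   [exclusion_mask()]); `NULL` disables the mask test.
#' @param image_shape integer `(rows, cols)`.
#' @param radius_px maximum translation distance (default 180).
#' @param seed integer seed.
#' @param max_tries rejection-sampling budget per region (default 1000).
#' @return data.frame of `kind = "random"` regions with `source_id`, and
#'   attribute `n_failed`.
#' @export
make_random_regions <- function(regions, exclusion, image_shape,
                                radius_px = 180, seed = 1, max_tries = 1000) {
  stopifnot(nrow(regions) == 0 || all(regions$kind == "peroxisomal"))
  if (nrow(regions) == 0) {
    out <- regions
    out$source_id <- integer(0)
    attr(out, "n_failed") <- 0L
    return(out)
  }
  d <- regions$diameter_px[1]
  m <- (d - 1) %/% 2
  offs <- disc_offsets(d)
  overlap_fun <- discs_share_pixel(d)
  perox <- cbind(regions$row, regions$col)
  with_seed(seed, {
    rows <- integer(0); cols <- integer(0); src <- integer(0)
    n_failed <- 0L
    for (i in seq_len(nrow(regions))) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        repeat {
          u <- stats::runif(2, -radius_px, radius_px)
          if (sum(u^2) <= radius_px^2) break
        }
        cand <- c(regions$row[i], regions$col[i]) + round_half_up(u)
        if (cand[1] - m < 1 || cand[1] + m > image_shape[1] ||
            cand[2] - m < 1 || cand[2] + m > image_shape[2]) next
        hit <- FALSE
        for (k in seq_len(nrow(perox))) {
          if (overlap_fun(cand - perox[k, ])) { hit <- TRUE; break }
        }
        if (hit) next
        if (!is.null(exclusion) &&
            any(exclusion[cbind(cand[1] + offs[, 1], cand[2] + offs[, 2])]))
          next
        rows <- c(rows, cand[1]); cols <- c(cols, cand[2])
        src <- c(src, regions$id[i])
        placed <- TRUE
        break
      }
      if (!placed) n_failed <- n_failed + 1L
    }
    out <- data.frame(id = seq_along(rows), row = rows, col = cols,
                      diameter_px = rep(as.integer(d), length(rows)),
                      kind = rep("random", length(rows)),
                      source_value = rep(NA_real_, length(rows)),
                      source_id = src)
    attr(out, "n_failed") <- n_failed
    out
  })
}
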