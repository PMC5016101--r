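## Sub-organelle compartmentalization: average nearest-maxima distance
## between two channels within each region, paired with the region's
## colocalization value.

#' Locate intensity maxima within a region patch
#'
#' The patch is Gaussian-smoothed (sigma = 1), a 3x3 maximum filter is
#' applied, and pixels equal to their filtered value are local maxima.
#' Only maxima with smoothed value >= 50% of the patch's global maximum are
#' retained, and only those inside the disc support count. Flat patches
#' (e.g. all zeros) are rejected with the `flat` attribute set.
#'
#' @param patch square numeric matrix.
#' @param sigma smoothing s.d. in px (default 1.0).
#' @param retain_frac retention threshold as a fraction of the global
#'   maximum (default 0.5).
#' @param mask logical disc mask; `NULL` uses the full square.
#' @return two-column matrix of maxima positions (row, col) within the
#'   patch; attribute `flat` marks rejected flat patches.
#' @export
find_patch_maxima <- function(patch, sigma = 1.0, retain_frac = 0.5,
                              mask = disc_mask(nrow(patch))) {
  stopifnot(is.matrix(patch))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(patch), ncol(patch))
  sm <- gaussian_blur(patch, sigma)
  vals <- sm[mask]
  gmax <- max(vals)
  flat <- gmax <= 0 || (gmax - min(vals)) < 1e-9 * abs(gmax)
  if (flat) {
    out <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col")))
    attr(out, "flat") <- TRUE
    return(out)
  }
  mf <- max_filter3(sm)
  is_max <- (sm == mf) & mask & (sm >= retain_frac * gmax)
  idx <- which(is_max, arr.ind = TRUE)
  out <- cbind(row = as.integer(idx[, 1]), col = as.integer(idx[, 2]))
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  attr(out, "flat") <- FALSE
  out
}

#' Average interchannel nearest-maxima distance
#'
#' For each maximum in A the Euclidean distance to its nearest maximum in B,
#' and vice versa; the mean over both directed sets is returned (the metric
#' is therefore symmetric in its arguments).
#'
#' @param maxima_a,maxima_b nonempty two-column matrices of positions.
#' @return mean nearest-neighbour distance in pixels.
#' @export
interchannel_distance <- function(maxima_a, maxima_b) {
  stopifnot(nrow(maxima_a) >= 1, nrow(maxima_b) >= 1)
  d2 <- outer(maxima_a[, 1], maxima_b[, 1], "-")^2 +
    outer(maxima_a[, 2], maxima_b[, 2], "-")^2
  mean(c(sqrt(apply(d2, 1, min)), sqrt(apply(d2, 2, min))))
}

#' Compartmentalization table: distance vs colocalization per region
#'
#' Pairs each region's average interchannel nearest-maxima distance with its
#' real-variant pixel-wise Pearson value, and accumulates a normalized 2-D
#' frequency map over (distance, Pearson). Regions with a flat patch or no
#' retained maxima in either channel are excluded and counted.
#'
#' @param stack registered [image_stack()].
#' @param regions peroxisomal regions from [make_regions()].
#' @param ch1,ch2 channel indices.
#' @param sigma patch smoothing s.d. (default 1.0).
#' @param retain_frac maxima retention fraction (default 0.5).
#' @param dist_breaks,pearson_breaks bin edges of the 2-D frequency map.
#' @return list with `records` (data.frame `id`, `distance_px`,
#'   `distance_nm`, `pearson`, `n_maxima_ch1`, `n_maxima_ch2`), `freq_map`
#'   (matrix normalized to sum 1; distance bins x Pearson bins), and
#'   `n_invalid`.
#' @export
compartmentalization_table <- function(stack, regions, ch1, ch2,
                                       sigma = 1.0, retain_frac = 0.5,
                                       dist_breaks = seq(0, 20, by = 1),
                                       pearson_breaks = seq(-1, 1, by = 0.1)) {
  stopifnot(inherits(stack, "image_stack"))
  a <- stack$channels[[ch1]]; b <- stack$channels[[ch2]]
  px <- stack$pixel_size_nm
  recs <- list()
  n_invalid <- 0L
  if (nrow(regions) > 0) {
    msk <- disc_mask(regions$diameter_px[1])
    for (i in seq_len(nrow(regions))) {
      pa <- extract_patch(a, regions[i, ])
      pb <- extract_patch(b, regions[i, ])
      ma <- find_patch_maxima(pa, sigma, retain_frac, msk)
      mb <- find_patch_maxima(pb, sigma, retain_frac, msk)
      pear <- region_pearson(pa, pb, msk)
      if (nrow(ma) == 0 || nrow(mb) == 0 || is.na(pear)) {
        n_invalid <- n_invalid + 1L
        next
      }
      d <- interchannel_distance(ma, mb)
      recs[[length(recs) + 1]] <- data.frame(
        id = regions$id[i], distance_px = d, distance_nm = d * px,
        pearson = pear, n_maxima_ch1 = nrow(ma), n_maxima_ch2 = nrow(mb))
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(id = integer(0), distance_px = numeric(0),
               distance_nm = numeric(0), pearson = numeric(0),
               n_maxima_ch1 = integer(0), n_maxima_ch2 = integer(0))
  nd <- length(dist_breaks) - 1; np <- length(pearson_breaks) - 1
  freq <- matrix(0, nd, np)
  if (nrow(records) > 0) {
    di <- pmin(pmax(findInterval(records$distance_px, dist_breaks,
                                 rightmost.closed = TRUE), 1L), nd)
    pi_ <- pmin(pmax(findInterval(records$pearson, pearson_breaks,
                                  rightmost.closed = TRUE), 1L), np)
    for (k in seq_len(nrow(records))) {
      freq[di[k], pi_[k]] <- freq[di[k], pi_[k]] + 1
    }
    freq <- freq / sum(freq)
  }
  dimnames(freq) <- list(
    distance = sprintf("[%g,%g)", dist_breaks[-(nd + 1)], dist_breaks[-1]),
    pearson = sprintf("[%g,%g)", pearson_breaks[-(np + 1)], pearson_breaks[-1]))
  list(records = records, freq_map = freq, n_invalid = n_invalid)
}
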