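## Cluster morphometry: maximum-entropy thresholding of region patches,
## despeckle + erode cleanup, and perimeter-vs-area scoring against the
## circular reference curve (pi * d, pi * d^2 / 4).

#' Maximum-entropy threshold of an intensity patch
#'
#' Kapur-Sahoo-Wong threshold on a 256-bin histogram of the patch rescaled
#' to `[0, 255]`: the threshold bin `t` maximizes the sum of Shannon
#' entropies of the background (`<= t`) and foreground (`> t`) partitions.
#' Ties take the lowest bin.
#'
#' @param patch numeric matrix or vector with >= 2 distinct values.
#' @return threshold in original intensity units (foreground = values above
#'   it), with the selected bin in attribute `bin` (0-based, 0..254).
#' @export
threshold_max_entropy <- function(patch) {
  x <- as.numeric(patch)
  lo <- min(x); hi <- max(x)
  if (hi <= lo) stop("flat region: cannot threshold a constant patch")
  bin <- pmin(as.integer(floor((x - lo) / (hi - lo) * 256)), 255L)
  p <- tabulate(bin + 1L, nbins = 256L) / length(x)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P0 <- cumsum(p)
  E0 <- cumsum(plogp)
  ## class entropies for thresholds t = 0..254 (1-based index t+1)
  t <- 1:255
  valid <- P0[t] > 0 & P0[t] < 1
  H0 <- log(P0[t]) - E0[t] / P0[t]
  H1 <- log(1 - P0[t]) - (E0[256] - E0[t]) / (1 - P0[t])
  psi <- ifelse(valid, H0 + H1, -Inf)
  tbest <- t[which.max(psi)] - 1L # 0-based bin
  thr <- lo + (tbest + 1) * (hi - lo) / 256
  structure(thr, bin = tbest)
}

#' Despeckle and erode a binary mask
#'
#' A 3x3 median filter (majority of the 9-neighbourhood, borders
#' replicated) removes isolated speckle, then one binary erosion removes
#' foreground pixels with at least `count` background neighbours in the
#' chosen neighbourhood (image border counts as background).
#'
#' Note the composition: the median filter itself rounds convex corners
#' (a corner pixel of a filled square has only 4 of 9 foreground
#' neighbours), so `clean_mask` on a filled square removes the corners and
#' then erodes.
#'
#' @param mask logical matrix.
#' @param erode_count minimum number of background neighbours that erodes a
#'   pixel (default 1, the particle-analysis convention).
#' @param erode_connectivity 8 (default) or 4.
#' @param despeckle apply the median step (TRUE); FALSE gives plain erosion.
#' @return cleaned logical matrix (possibly empty).
#' @export
clean_mask <- function(mask, erode_count = 1, erode_connectivity = 8,
                       despeckle = TRUE) {
  stopifnot(is.matrix(mask), erode_connectivity %in% c(4, 8))
  m <- mask * 1
  nr <- nrow(m); nc <- ncol(m)
  if (despeckle) {
    pad_rep <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
    s <- matrix(0, nr, nc)
    for (dr in -1:1) for (dc in -1:1) {
      s <- s + pad_rep[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    }
    m <- (s >= 5) * 1 # median of 9 binary values
  }
  ## erosion: border = background (zero padding)
  pad0 <- matrix(0, nr + 2, nc + 2)
  pad0[2:(nr + 1), 2:(nc + 1)] <- m
  nbrs <- if (erode_connectivity == 4)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1)) else
      list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
           c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  bg <- matrix(0, nr, nc)
  for (o in nbrs) {
    bg <- bg + (1 - pad0[(2 + o[1]):(nr + 1 + o[1]),
                         (2 + o[2]):(nc + 1 + o[2])])
  }
  (m == 1) & (bg < erode_count)
}

#' Measure thresholded clusters
#'
#' Connected components (8-connectivity) of a binary mask; per component,
#' area = total pixel count and perimeter = count of component pixels with
#' at least one 4-neighbour outside the component (image border counts as
#' outside). Physical units via the pixel size.
#'
#' @param mask logical matrix.
#' @param pixel_size_nm pixel size in nm (default 20).
#' @param region_id optional region identifier carried into the result.
#' @return data.frame `region_id`, `cluster`, `area_px`, `perimeter_px`,
#'   `area_nm2`, `perimeter_nm`.
#' @export
measure_clusters <- function(mask, pixel_size_nm = 20, region_id = NA) {
  stopifnot(is.matrix(mask))
  lab <- label_components(mask, connectivity = 8)
  k <- max(lab)
  if (k == 0) {
    return(data.frame(region_id = region_id[0], cluster = integer(0),
                      area_px = integer(0), perimeter_px = integer(0),
                      area_nm2 = numeric(0), perimeter_nm = numeric(0)))
  }
  nr <- nrow(lab); nc <- ncol(lab)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- lab
  boundary <- lab > 0L &
    (pad[1:nr, 2:(nc + 1)] != lab | pad[3:(nr + 2), 2:(nc + 1)] != lab |
       pad[2:(nr + 1), 1:nc] != lab | pad[2:(nr + 1), 3:(nc + 2)] != lab)
  area <- tabulate(lab[lab > 0L], nbins = k)
  perim <- tabulate(lab[boundary], nbins = k)
  data.frame(region_id = region_id, cluster = seq_len(k),
             area_px = area, perimeter_px = perim,
             area_nm2 = area * pixel_size_nm^2,
             perimeter_nm = perim * pixel_size_nm)
}

#' Circular reference for the perimeter-area scatter
#' @param d circle diameter (any unit).
#' @return named vector `c(perimeter = pi * d, area = pi * d^2 / 4)`.
#' @export
circle_reference <- function(d) {
  stopifnot(all(d > 0))
  c(perimeter = pi * d, area = pi * d^2 / 4)
}

#' Threshold, clean and measure one region patch
#'
#' Convenience composition used by the pipeline: max-entropy threshold,
#' despeckle + erode, then cluster measurement. Flat patches yield zero
#' clusters (flagged via the `flat` attribute).
#'
#' @inheritParams measure_clusters
#' @param patch numeric matrix (a region's intensity values).
#' @return data.frame as [measure_clusters()]; attribute `flat` is TRUE when
#'   the patch could not be thresholded.
#' @export
measure_region_morphology <- function(patch, pixel_size_nm = 20,
                                      region_id = NA) {
  thr <- tryCatch(threshold_max_entropy(patch), error = function(e) NULL)
  if (is.null(thr)) {
    out <- measure_clusters(matrix(FALSE, nrow(patch), ncol(patch)),
                            pixel_size_nm, region_id)
    attr(out, "flat") <- TRUE
    return(out)
  }
  mask <- clean_mask(patch > as.numeric(thr))
  out <- measure_clusters(mask, pixel_size_nm, region_id)
  attr(out, "flat") <- FALSE
  out
}
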