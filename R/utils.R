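## Shared low-level image helpers. All coordinates are 1-based (row, col);
## angles are measured counterclockwise from the +col axis, in degrees.

FWHM_FACTOR <- 2 * sqrt(2 * log(2)) # FWHM = 2.3548 * sigma for a Gaussian

#' Round half away from zero
#'
#' Deterministic rounding used throughout the package (base `round()` rounds
#' half to even, which would make plateau centroids depend on parity).
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Pixel offsets of a digital disc
#'
#' Integer offsets `(dr, dc)` with `dr^2 + dc^2 <= (d/2)^2`. For the default
#' analysis diameter of 19 px this disc contains 293 pixels.
#'
#' @param diameter_px odd integer disc diameter in pixels.
#' @return two-column integer matrix of offsets (columns `dr`, `dc`).
#' @export
disc_offsets <- function(diameter_px) {
  stopifnot(length(diameter_px) == 1, diameter_px >= 1)
  r <- diameter_px / 2
  m <- floor(r)
  g <- expand.grid(dr = -m:m, dc = -m:m)
  keep <- g$dr^2 + g$dc^2 <= r^2
  cbind(dr = as.integer(g$dr[keep]), dc = as.integer(g$dc[keep]))
}

#' Logical disc mask on its bounding square
#' @param diameter_px odd integer diameter.
#' @return `diameter_px` x `diameter_px` logical matrix.
#' @export
disc_mask <- function(diameter_px) {
  c0 <- (diameter_px + 1) / 2
  r <- diameter_px / 2
  rr <- matrix(seq_len(diameter_px), diameter_px, diameter_px)
  cc <- t(rr)
  (rr - c0)^2 + (cc - c0)^2 <= r^2
}

#' Isotropic Gaussian smoothing
#'
#' Normalized Gaussian kernel (radius `ceiling(3.5*sigma)`) applied with
#' replicated borders, so flat regions stay flat near the edge and total
#' intensity of interior structure is conserved.
#'
#' @param img numeric matrix.
#' @param sigma Gaussian standard deviation in pixels; `0` returns `img`.
#' @return smoothed numeric matrix of the same shape.
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(is.matrix(img), sigma >= 0)
  if (sigma == 0) return(img)
  r <- max(1L, as.integer(ceiling(3.5 * sigma)))
  # kernel must fit in the image for EBImage::filter2
  r <- min(r, as.integer((min(dim(img)) - 1) %/% 2))
  x <- stats::dnorm(-r:r, sd = sigma)
  k <- outer(x, x)
  k <- k / sum(k)
  out <- EBImage::filter2(img, k, boundary = "replicate")
  matrix(as.numeric(out), nrow(img), ncol(img))
}

#' Translate an image by an integer shift with zero fill
#' @param img numeric matrix.
#' @param shift integer `(dr, dc)`: the content moves down by `dr` rows and
#'   right by `dc` columns; vacated pixels are set to 0.
#' @return translated matrix of the same shape.
#' @export
translate_zero <- function(img, shift) {
  stopifnot(is.matrix(img), length(shift) == 2)
  dr <- as.integer(shift[1]); dc <- as.integer(shift[2])
  if (dr == 0 && dc == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

#' Translate an image by a real-valued shift (bilinear interpolation)
#' @param img numeric matrix.
#' @param shift numeric `(dr, dc)`; pixels sampled from outside the image are 0.
#' @return shifted matrix.
#' @export
translate_bilinear <- function(img, shift) {
  stopifnot(is.matrix(img), length(shift) == 2, all(is.finite(shift)))
  if (all(shift == round(shift))) return(translate_zero(img, round(shift)))
  nr <- nrow(img); nc <- ncol(img)
  rr <- matrix(seq_len(nr), nr, nc) - shift[1]
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc) - shift[2]
  bilinear_sample(img, as.vector(rr), as.vector(cc), outside = 0) |>
    matrix(nr, nc)
}

#' Bilinear sampling at real-valued positions
#' @param img numeric matrix.
#' @param r,c numeric vectors of row/col positions (1-based).
#' @param outside value used for samples outside the image support.
#' @return numeric vector of sampled intensities.
#' @keywords internal
bilinear_sample <- function(img, r, c, outside = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    out <- rep(outside, length(ri))
    out[ok] <- img[cbind(ri[ok], ci[ok])]
    out
  }
  val(r0, c0) * (1 - fr) * (1 - fc) +
    val(r0 + 1L, c0) * fr * (1 - fc) +
    val(r0, c0 + 1L) * (1 - fr) * fc +
    val(r0 + 1L, c0 + 1L) * fr * fc
}

#' 3x3 maximum filter with replicated borders
#' @param img numeric matrix.
#' @return matrix of local 3x3 maxima.
#' @keywords internal
max_filter3 <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  p <- img[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  out <- img
  for (dr in -1:1) for (dc in -1:1) {
    out <- pmax(out, p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)])
  }
  out
}

#' Label connected components of a binary mask
#'
#' Two-pass scan with union-find. Used for cluster morphometry on small
#' thresholded patches.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8, the particle-analysis convention).
#' @return integer matrix of labels (0 = background), labelled in raster order.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nxt <- 0L
  prev <- if (connectivity == 4) list(c(-1L, 0L), c(0L, -1L)) else
    list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    ns <- integer(0)
    for (o in prev) {
      a <- i + o[1]; b <- j + o[2]
      if (a >= 1 && a <= nr && b >= 1 && b <= nc && lab[a, b] > 0L)
        ns <- c(ns, lab[a, b])
    }
    if (length(ns) == 0L) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[i, j] <- nxt
    } else {
      roots <- vapply(unique(ns), find, integer(1))
      r0 <- min(roots)
      for (r in roots) parent[r] <- r0
      lab[i, j] <- r0
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, integer(1))
  ur <- unique(roots)
  relab <- integer(nxt)
  relab[ur] <- seq_along(ur)
  pos <- lab > 0L
  lab[pos] <- relab[roots[lab[pos]]]
  lab
}

#' Evaluate an expression with a temporary RNG seed
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`; the caller's RNG state is restored afterwards.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
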