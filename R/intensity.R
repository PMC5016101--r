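## Per-cell intensity correlation between the matrix and a protein channel,
## normalized intensity-frequency histograms, line-profile FWHM and group
## comparison (one-way ANOVA with Tukey HSD).

#' Integrate region intensities in two channels
#'
#' Sums intensities over each region's pixel disc in the matrix channel
#' (`g`) and the protein channel (`r`), forming the per-region measurement
#' pairs used for per-cell correlation.
#'
#' @param stack an [image_stack()].
#' @param regions regions from [make_regions()] / [make_random_regions()].
#' @param matrix_ch,protein_ch channel indices.
#' @return data.frame `id`, `kind`, `g`, `r`.
#' @export
integrate_regions <- function(stack, regions, matrix_ch, protein_ch) {
  stopifnot(inherits(stack, "image_stack"))
  g <- numeric(nrow(regions)); r <- numeric(nrow(regions))
  if (nrow(regions) > 0) {
    offs <- disc_offsets(regions$diameter_px[1])
    mg <- stack$channels[[matrix_ch]]
    mr <- stack$channels[[protein_ch]]
    for (i in seq_len(nrow(regions))) {
      px <- cbind(regions$row[i] + offs[, 1], regions$col[i] + offs[, 2])
      g[i] <- sum(mg[px])
      r[i] <- sum(mr[px])
    }
  }
  data.frame(id = regions$id, kind = regions$kind, g = g, r = r)
}

#' Per-cell Pearson correlation of integrated region intensities
#'
#' @param pairs data.frame from [integrate_regions()] (>= 2 rows, nonzero
#'   variance in both coordinates).
#' @param cell_id optional cell identifier carried into the result.
#' @return one-row data.frame `cell`, `pearson_r`, `n_regions`.
#' @export
cell_correlation <- function(pairs, cell_id = 1L) {
  if (nrow(pairs) < 2) stop("degenerate intensity set: fewer than 2 regions")
  if (stats::var(pairs$g) == 0 || stats::var(pairs$r) == 0)
    stop("degenerate intensity set: zero variance")
  data.frame(cell = cell_id,
             pearson_r = stats::cor(pairs$g, pairs$r),
             n_regions = nrow(pairs))
}

#' Normalized intensity-frequency histogram
#'
#' Values are divided by `reference_max` (the per-cell maximum integrated
#' peroxisomal intensity, reused for that cell's random regions) and binned
#' into 25 fixed bins of width 0.04 on `[0, 1]`. Normalized values above 1
#' (possible for random regions) are kept in the top bin and counted in
#' `n_clipped`; exact zeros are counted in `n_zero` and fall in the first
#' bin. Histograms pool across cells by adding counts.
#'
#' @param values nonnegative numeric vector of integrated intensities.
#' @param reference_max positive normalization constant.
#' @param kind label carried on the histogram (`"peroxisomal"`/`"random"`).
#' @return object of class `intensity_histogram` with fields `breaks` (26
#'   edges), `counts` (25), `n_zero`, `n_clipped`, `kind`.
#' @export
normalized_histogram <- function(values, reference_max, kind = "peroxisomal") {
  if (!is.finite(reference_max) || reference_max <= 0)
    stop("reference_max must be positive")
  stopifnot(all(values >= 0))
  vn <- values / reference_max
  idx <- pmin(pmax(ceiling(vn / 0.04), 1L), 25L)
  counts <- tabulate(idx, nbins = 25L)
  structure(list(breaks = seq(0, 1, by = 0.04),
                 counts = counts,
                 n_zero = sum(vn == 0),
                 n_clipped = sum(vn > 1),
                 kind = kind),
            class = "intensity_histogram")
}

#' Pool intensity histograms by adding counts
#' @param ... `intensity_histogram` objects of the same kind.
#' @return pooled `intensity_histogram`.
#' @export
pool_histograms <- function(...) {
  hs <- list(...)
  if (length(hs) == 1 && is.list(hs[[1]]) &&
      !inherits(hs[[1]], "intensity_histogram")) hs <- hs[[1]]
  stopifnot(length(hs) >= 1,
            all(vapply(hs, inherits, logical(1), "intensity_histogram")))
  out <- hs[[1]]
  for (h in hs[-1]) {
    out$counts <- out$counts + h$counts
    out$n_zero <- out$n_zero + h$n_zero
    out$n_clipped <- out$n_clipped + h$n_clipped
  }
  out
}

#' Gaussian fit to an intensity histogram
#'
#' Unweighted least-squares fit of `A * exp(-(x - mu)^2 / (2 * sigma^2))`
#' to bin centers vs counts, giving the location and width of the intensity
#' distribution peak.
#'
#' @param hist an `intensity_histogram` with >= 5 nonzero bins.
#' @return named vector `c(mu, sigma)`.
#' @export
gaussian_peak <- function(hist) {
  stopifnot(inherits(hist, "intensity_histogram"))
  if (sum(hist$counts > 0) < 5)
    stop("fit rejected: fewer than 5 nonzero bins")
  x <- (hist$breaks[-1] + hist$breaks[-26]) / 2
  y <- hist$counts
  w <- y / sum(y)
  mu0 <- sum(w * x)
  s0 <- max(sqrt(sum(w * (x - mu0)^2)), 0.02)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * s^2)),
                      start = list(A = max(y), mu = mu0, s = s0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("gaussian peak fit failed: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  c(mu = unname(cf["mu"]), sigma = abs(unname(cf["s"])))
}

#' FWHM of an intensity line profile
#'
#' Samples the image along the segment `p0 -> p1` in 1 px steps with
#' bilinear interpolation. The full width at half maximum is measured at
#' half of (max - baseline) above the baseline (the profile minimum), with
#' the crossings located by linear interpolation, and converted to nm.
#'
#' @param channel numeric matrix.
#' @param p0,p1 segment endpoints `(row, col)`, inside the image.
#' @param pixel_size_nm pixel size in nm (default 20).
#' @return FWHM in nm.
#' @export
line_profile_fwhm <- function(channel, p0, p1, pixel_size_nm = 20) {
  nr <- nrow(channel); nc <- ncol(channel)
  stopifnot(all(c(p0, p1) >= 1), p0[1] <= nr, p1[1] <= nr,
            p0[2] <= nc, p1[2] <= nc)
  len <- sqrt(sum((p1 - p0)^2))
  stopifnot(len > 0)
  tt <- seq(0, 1, length.out = max(2, ceiling(len) + 1))
  prof <- bilinear_sample(channel,
                          p0[1] + tt * (p1[1] - p0[1]),
                          p0[2] + tt * (p1[2] - p0[2]))
  base <- min(prof)
  pk <- which.max(prof)
  half <- base + (max(prof) - base) / 2
  if (pk == 1 || pk == length(prof) || max(prof) == base)
    stop("no peak in profile")
  cross <- function(i0, i1) { # linear interpolation of the half crossing
    (half - prof[i0]) / (prof[i1] - prof[i0]) * (i1 - i0) + i0
  }
  left <- NA
  for (i in seq(pk, 2)) {
    if (prof[i - 1] <= half && prof[i] >= half) { left <- cross(i - 1, i); break }
  }
  right <- NA
  for (i in seq(pk, length(prof) - 1)) {
    if (prof[i + 1] <= half && prof[i] >= half) { right <- cross(i + 1, i); break }
  }
  if (is.na(left) || is.na(right)) stop("no peak in profile")
  step_nm <- len / (length(tt) - 1) * pixel_size_nm
  abs(right - left) * step_nm
}

#' Compare per-cell values across conditions
#'
#' One-way analysis of variance followed by Tukey's honest significant
#' difference pairwise comparisons.
#'
#' @param cell_values named list of numeric vectors (>= 2 groups of >= 2).
#' @return list with `anova_F`, `anova_p`, and a data.frame `pairwise`
#'   (`comparison`, `diff`, `p_adj`).
#' @export
compare_groups <- function(cell_values) {
  stopifnot(is.list(cell_values), length(cell_values) >= 2,
            all(vapply(cell_values, length, integer(1)) >= 2))
  if (is.null(names(cell_values)))
    names(cell_values) <- paste0("g", seq_along(cell_values))
  df <- data.frame(
    value = unlist(cell_values, use.names = FALSE),
    group = factor(rep(names(cell_values),
                       vapply(cell_values, length, integer(1)))))
  if (stats::var(df$value) == 0) stop("degenerate groups: zero total variance")
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  list(anova_F = an["group", "F value"],
       anova_p = an["group", "Pr(>F)"],
       pairwise = data.frame(comparison = rownames(tk),
                             diff = tk[, "diff"],
                             p_adj = tk[, "p adj"],
                             row.names = NULL))
}
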