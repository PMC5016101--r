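## Pixel-wise Pearson colocalization per region, with flip and random-region
## null controls.

#' Extract a region's square patch from a channel
#' @param channel numeric matrix.
#' @param region one row of a regions data.frame.
#' @return `d x d` numeric matrix centered on the region.
#' @export
extract_patch <- function(channel, region) {
  m <- (region$diameter_px - 1) %/% 2
  channel[(region$row - m):(region$row + m),
          (region$col - m):(region$col + m)]
}

#' Pixel-wise Pearson correlation over a circular region
#'
#' Correlates the two channels' pixel values over the disc pixels only
#' (corner pixels of the bounding square belong to neighbouring space).
#' Patches with zero variance inside the disc carry no information and
#' yield `NA` (callers exclude and count them).
#'
#' @param patch_g,patch_r same-shape square patches.
#' @param mask logical disc mask; `NULL` uses the full patch.
#' @return Pearson r in `[-1, 1]`, or `NA` for a zero-variance patch.
#' @export
region_pearson <- function(patch_g, patch_r, mask = disc_mask(nrow(patch_g))) {
  stopifnot(all(dim(patch_g) == dim(patch_r)))
  g <- if (is.null(mask)) as.numeric(patch_g) else patch_g[mask]
  r <- if (is.null(mask)) as.numeric(patch_r) else patch_r[mask]
  if (stats::var(g) == 0 || stats::var(r) == 0) return(NA_real_)
  stats::cor(g, r)
}

#' Mirror a patch about the vertical axis through its center
#'
#' The flip control: re-correlating after mirroring the second channel
#' estimates how much colocalization arises from coincidence under dense
#' packing. The disc support is mirror-symmetric, so the disc mask is
#' preserved.
#'
#' @param patch square numeric matrix.
#' @return column-reversed patch.
#' @export
flip_patch <- function(patch) {
  patch[, rev(seq_len(ncol(patch))), drop = FALSE]
}

#' Per-region colocalization with real, flip and random variants
#'
#' @param stack registered [image_stack()].
#' @param regions peroxisomal regions.
#' @param ch1,ch2 channel indices to correlate.
#' @param random_regions matched random regions (may be empty).
#' @return data.frame `id`, `variant` (real/flip/random), `pearson` (NA for
#'   zero-variance patches), with channel labels in attributes.
#' @export
coloc_table <- function(stack, regions, ch1, ch2, random_regions = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  a <- stack$channels[[ch1]]; b <- stack$channels[[ch2]]
  one <- function(regs, variants) {
    out <- list()
    if (!is.null(regs) && nrow(regs) > 0) {
      msk <- disc_mask(regs$diameter_px[1])
      for (i in seq_len(nrow(regs))) {
        pg <- extract_patch(a, regs[i, ])
        pr <- extract_patch(b, regs[i, ])
        for (v in variants) {
          p2 <- if (v == "flip") flip_patch(pr) else pr
          out[[length(out) + 1]] <- data.frame(
            id = regs$id[i], variant = v,
            pearson = region_pearson(pg, p2, msk))
        }
      }
    }
    out
  }
  rows <- c(one(regions, c("real", "flip")), one(random_regions, "random"))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), variant = character(0), pearson = numeric(0))
  attr(out, "channels") <- stack$meta$label[c(ch1, ch2)]
  out
}

#' Pooled colocalization histograms and medians per variant
#'
#' Bins the per-region Pearson values of each variant (real, flip, random)
#' into 40 bins on `[-1, 1]` and reports the per-variant medians.
#' Zero-variance regions (`NA`) are excluded from the histograms and
#' counted.
#'
#' @inheritParams coloc_table
#' @param n_bins number of histogram bins on `[-1, 1]` (default 40).
#' @return list with `table` (the [coloc_table()] result), `histograms`
#'   (data.frame `variant`, `bin_lo`, `bin_hi`, `count`), `medians` (named
#'   vector), and `n_flagged` (zero-variance count).
#' @export
coloc_histograms <- function(stack, regions, ch1, ch2, random_regions = NULL,
                             n_bins = 40) {
  tab <- coloc_table(stack, regions, ch1, ch2, random_regions)
  edges <- seq(-1, 1, length.out = n_bins + 1)
  hists <- list()
  meds <- c(real = NA_real_, flip = NA_real_, random = NA_real_)
  for (v in c("real", "flip", "random")) {
    x <- tab$pearson[tab$variant == v & !is.na(tab$pearson)]
    idx <- pmin(pmax(ceiling((x + 1) / 2 * n_bins), 1L), n_bins)
    hists[[v]] <- data.frame(variant = v, bin_lo = edges[-(n_bins + 1)],
                             bin_hi = edges[-1],
                             count = tabulate(idx, nbins = n_bins))
    if (length(x)) meds[v] <- stats::median(x)
  }
  list(table = tab, histograms = do.call(rbind, hists), medians = meds,
       n_flagged = sum(is.na(tab$pearson)))
}
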