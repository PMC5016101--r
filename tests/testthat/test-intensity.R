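make_regions_at <- function(centers, d = 19) {
  data.frame(id = seq_len(nrow(centers)), row = centers[, 1],
             col = centers[, 2], diameter_px = d, kind = "peroxisomal",
             source_value = NA_real_)
}

test_that("region integration equals exhaustive pixel enumeration", {
  set.seed(51)
  img_g <- matrix(runif(80 * 80), 80, 80)
  img_r <- matrix(runif(80 * 80), 80, 80)
  stk <- image_stack(list(img_g, img_r))
  regs <- make_regions_at(cbind(c(20, 45, 60), c(30, 50, 20)))
  pairs <- integrate_regions(stk, regs, 1, 2)
  for (i in 1:3) {
    gg <- 0; rr <- 0
    for (dr in -9:9) for (dc in -9:9) {
      if (dr^2 + dc^2 <= 9.5^2) {
        gg <- gg + img_g[regs$row[i] + dr, regs$col[i] + dc]
        rr <- rr + img_r[regs$row[i] + dr, regs$col[i] + dc]
      }
    }
    expect_equal(pairs$g[i], gg)
    expect_equal(pairs$r[i], rr)
  }
  # a delta at one region center integrates only there
  dimg <- matrix(0, 80, 80); dimg[20, 30] <- 100
  stk2 <- image_stack(list(dimg, dimg * 0))
  p2 <- integrate_regions(stk2, regs, 1, 2)
  expect_equal(p2$g, c(100, 0, 0))
  expect_equal(p2$r, c(0, 0, 0))
})

test_that("per-cell correlation matches hand-computed values", {
  mk <- function(g, r) data.frame(id = seq_along(g), kind = "peroxisomal",
                                  g = g, r = r)
  expect_equal(cell_correlation(mk(1:3, c(2, 4, 6)))$pearson_r, 1.0)
  expect_equal(cell_correlation(mk(1:3, c(3, 2, 1)))$pearson_r, -1.0)
  expect_equal(cell_correlation(mk(1:4, c(1, 3, 2, 4)))$pearson_r, 0.8)
  # invariant under positive affine rescaling of either channel
  p <- mk(c(3, 1, 4, 1, 5), c(9, 2, 6, 5, 3))
  r0 <- cell_correlation(p)$pearson_r
  p2 <- p; p2$g <- 7.3 * p2$g + 11
  expect_equal(cell_correlation(p2)$pearson_r, r0)
  expect_error(cell_correlation(mk(c(2, 2, 2), 1:3)), "degenerate")
  expect_error(cell_correlation(mk(1, 1)), "degenerate")
})

test_that("normalized histograms bin on the fixed 25-bin grid", {
  h <- normalized_histogram(c(40), 40)
  expect_equal(h$counts[25], 1)
  expect_equal(sum(h$counts), 1)
  hz <- normalized_histogram(c(0, 0, 0), 10)
  expect_equal(hz$n_zero, 3)
  expect_equal(hz$counts[1], 3)
  h4 <- normalized_histogram(c(10, 20, 30, 40), 40)
  expect_equal(which(h4$counts == 1), c(7, 13, 19, 25))
  # values above the reference (random regions) clip into the top bin
  hc <- normalized_histogram(c(50, 10), 40)
  expect_equal(hc$n_clipped, 1)
  expect_equal(hc$counts[25], 1)
  expect_error(normalized_histogram(c(1, 2), 0), "positive")
  # pooling conserves total mass
  pooled <- pool_histograms(h, hz, h4)
  expect_equal(sum(pooled$counts), 8)
})

test_that("the Gaussian peak fit recovers a known simulated peak", {
  set.seed(61)
  x <- rnorm(1e5, 0.5, 0.1)
  x <- x[x > 0 & x <= 1]
  h <- normalized_histogram(x, 1)
  fit <- gaussian_peak(h)
  expect_lt(abs(fit["mu"] - 0.5), 0.01)
  expect_lt(abs(fit["sigma"] - 0.1), 0.01)
  # too few informative bins is refused
  h2 <- normalized_histogram(c(rep(0.1, 5), rep(0.5, 5)), 1)
  expect_error(gaussian_peak(h2), "5 nonzero bins")
})

test_that("line-profile FWHM matches closed forms", {
  rr <- matrix(1:101, 101, 101); cc <- t(rr)
  # Gaussian spot, sigma 50 nm = 2.5 px: FWHM = 2.3548 * 50 = 117.74 nm
  g <- exp(-((rr - 51)^2 + (cc - 51)^2) / (2 * 2.5^2))
  fw <- line_profile_fwhm(g, c(51, 21), c(51, 81))
  expect_lt(abs(fw - 117.74) / 117.74, 0.05)
  # rectangular pulse of width w: FWHM = w within one pixel
  rect <- matrix(0, 101, 101); rect[, 45:52] <- 1
  fwr <- line_profile_fwhm(rect, c(50, 20), c(50, 80))
  expect_lt(abs(fwr - 8 * 20), 20)
  # monotone profile has no peak
  ramp <- matrix(rep(1:101, each = 101), 101, 101)
  expect_error(line_profile_fwhm(ramp, c(50, 10), c(50, 90)), "no peak")
})

test_that("group comparison flags only truly separated conditions", {
  same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  res <- compare_groups(same)
  expect_true(all(res$pairwise$p_adj > 0.999))
  set.seed(71)
  two <- list(ctrl = rnorm(20), treat = rnorm(20, 5))
  expect_lt(compare_groups(two)$anova_p, 1e-3)
  aa <- rnorm(15)
  three <- list(a = aa, b = aa, c = rnorm(15, 4)) # b duplicates a exactly
  res3 <- compare_groups(three)
  pw <- res3$pairwise
  involves_c <- grepl("c", pw$comparison)
  expect_true(all(pw$p_adj[involves_c] < 0.01))
  expect_true(all(pw$p_adj[!involves_c] > 0.99))
  expect_error(compare_groups(list(a = c(1, 1), b = c(1, 1))), "degenerate")
})
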