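test_that("max-entropy threshold separates a two-level patch", {
  vals <- c(rep(50, 90), rep(200, 10))
  set.seed(81)
  patch <- matrix(sample(vals), 10, 10)
  thr <- threshold_max_entropy(patch)
  expect_gt(as.numeric(thr), 50)
  expect_lt(as.numeric(thr), 200)
  expect_error(threshold_max_entropy(matrix(3, 5, 5)), "flat region")
})

test_that("max-entropy threshold equals the exhaustive entropy search", {
  set.seed(82)
  for (k in 1:150) {
    patch <- if (k %% 2) matrix(runif(19 * 19), 19, 19) else
      matrix(sample(0:40, 19 * 19, replace = TRUE), 19, 19)
    if (max(patch) == min(patch)) next
    expect_equal(attr(threshold_max_entropy(patch), "bin"),
                 oracle_entropy_bin(patch), info = paste("patch", k))
  }
})

test_that("despeckle and erode clean masks as expected", {
  m <- matrix(FALSE, 11, 11)
  m[6, 6] <- TRUE # isolated speckle
  expect_equal(sum(clean_mask(m)), 0)
  sq <- matrix(FALSE, 11, 11)
  sq[3:9, 3:9] <- TRUE # filled 7x7 square erodes to 5x5
  er <- clean_mask(sq, despeckle = FALSE)
  expect_equal(sum(er), 25)
  expect_true(all(er[4:8, 4:8]))
  # full cleanup: direct morphology oracle (median then erode, by definition)
  oracle_clean <- function(mask) {
    nr <- nrow(mask); nc <- ncol(mask)
    at <- function(m, i, j) m[min(max(i, 1), nr), min(max(j, 1), nc)]
    med <- mask
    for (i in 1:nr) for (j in 1:nc) {
      v <- c()
      for (a in -1:1) for (b in -1:1) v <- c(v, at(mask, i + a, j + b))
      med[i, j] <- sum(v) >= 5
    }
    out <- med
    for (i in 1:nr) for (j in 1:nc) {
      if (!med[i, j]) next
      for (a in -1:1) for (b in -1:1) {
        if (a == 0 && b == 0) next
        ii <- i + a; jj <- j + b
        if (ii < 1 || ii > nr || jj < 1 || jj > nc || !med[ii, jj])
          out[i, j] <- FALSE
      }
    }
    out
  }
  expect_equal(clean_mask(sq), oracle_clean(sq))
  set.seed(83)
  noisy <- matrix(runif(15 * 15) > 0.55, 15, 15)
  expect_equal(clean_mask(noisy), oracle_clean(noisy))
  expect_equal(sum(clean_mask(matrix(FALSE, 9, 9))), 0)
})

test_that("cluster measurement counts pixels and boundary pixels", {
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  m1 <- measure_clusters(one)
  expect_equal(m1$area_px, 1)
  expect_equal(m1$perimeter_px, 1)
  sq <- matrix(FALSE, 9, 9); sq[3:7, 3:7] <- TRUE
  m2 <- measure_clusters(sq)
  expect_equal(m2$area_px, 25)
  expect_equal(m2$perimeter_px, 16)
  expect_equal(m2$area_nm2, 25 * 400)
  # 8-connectivity joins diagonal neighbours into one cluster
  diagm <- matrix(FALSE, 6, 6); diagm[2, 2] <- TRUE; diagm[3, 3] <- TRUE
  m3 <- measure_clusters(diagm)
  expect_equal(nrow(m3), 1)
  expect_equal(m3$area_px, 2)
  # two separate clusters are measured independently
  two <- matrix(FALSE, 10, 10); two[2:3, 2:3] <- TRUE; two[7:8, 7:8] <- TRUE
  m4 <- measure_clusters(two)
  expect_equal(nrow(m4), 2)
  expect_equal(m4$area_px, c(4, 4))
})

test_that("the circular reference gives pi*d and pi*d^2/4", {
  expect_equal(unname(circle_reference(1)), c(pi, pi / 4))
  expect_equal(unname(circle_reference(10)), c(31.41593, 78.53982),
               tolerance = 1e-6)
})

test_that("digital discs approach the circular reference curve as d grows", {
  ds <- seq(9, 31, 2)
  rel <- vapply(ds, function(d) {
    m <- measure_clusters(rasterize_disc(d))
    ref <- circle_reference(d)
    sqrt((m$perimeter_px - ref["perimeter"])^2 +
           (m$area_px - ref["area"])^2) / sqrt(sum(ref^2))
  }, numeric(1))
  expect_lt(max(rel), 0.15)
  trend <- suppressWarnings(cor(ds, rel, method = "spearman"))
  expect_lt(trend, -0.5)
})

test_that("ring stainings score larger perimeter-to-area ratios than dots", {
  ratio_for <- function(mix, seed) {
    sp <- scene_spec(image_size_px = c(512, 512), n_organelles = 50,
                     diameter_range_nm = c(250, 500), morphology_mix = mix,
                     n_domains_per_organelle = 3, domain_sigma_deg = 40,
                     ring_base = 0.6, min_separation_nm = 800, seed = seed)
    sc <- generate_scene(sp)
    regs <- make_regions(find_maxima(sc$stack$channels[[1]]), c(512, 512))
    out <- numeric(0)
    for (i in seq_len(nrow(regs))) {
      m <- measure_region_morphology(
        extract_patch(sc$stack$channels[[2]], regs[i, ]))
      if (nrow(m)) {
        big <- which.max(m$area_px)
        out <- c(out, m$perimeter_px[big] / m$area_px[big])
      }
    }
    out
  }
  rings <- ratio_for(c(ring = 1), seed = 21)
  dots <- ratio_for(c(dot = 1), seed = 22)
  expect_gt(length(rings), 30)
  expect_gt(length(dots), 30)
  expect_lt(wilcox.test(rings, dots, alternative = "greater")$p.value, 0.01)
})
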