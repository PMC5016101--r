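test_that("maxima detection handles trivial inputs", {
  expect_equal(nrow(find_maxima(matrix(0, 20, 20))), 0)
  # a single isolated peak, amplitude far above tolerance
  img <- matrix(0, 40, 40)
  rr <- matrix(1:40, 40, 40); cc <- t(rr)
  img <- 500 * exp(-((rr - 17)^2 + (cc - 23)^2) / (2 * 2^2))
  mx <- find_maxima(img, sigma = 0, noise_tolerance = 10)
  expect_equal(nrow(mx), 1)
  expect_equal(c(mx$row, mx$col), c(17, 23))
})

test_that("maxima agree with the exhaustive flood oracle on random images", {
  set.seed(41)
  for (k in 1:40) {
    img <- matrix(sample(0:255, 24 * 24, replace = TRUE), 24, 24)
    for (tol in c(0, 5, 10)) {
      got <- find_maxima(img, sigma = 0, noise_tolerance = tol)
      want <- oracle_find_maxima(img, tol)
      expect_equal(got, want, info = sprintf("k=%d tol=%g", k, tol))
    }
  }
})

test_that("detection is invariant to a constant intensity offset", {
  set.seed(13)
  img <- matrix(sample(0:100, 30 * 30, replace = TRUE), 30, 30)
  base <- find_maxima(img, sigma = 2, noise_tolerance = 10)
  shifted <- find_maxima(img + 37, sigma = 2, noise_tolerance = 10)
  expect_equal(base[c("row", "col")], shifted[c("row", "col")])
  expect_equal(shifted$value - base$value, rep(37, nrow(base)))
})

test_that("every ground-truth organelle is detected in resolvable scenes", {
  for (seed in 1:3) {
    sp <- quiet_scene(n = 10, size = 320, seed = seed, diam = c(150, 400),
                      noise = FALSE, min_sep = 800)
    sc <- generate_scene(sp)
    mx <- find_maxima(sc$stack$channels[[1]])
    expect_equal(nrow(mx), 10)
    # each maximum sits near one true center
    d <- sqrt(outer(mx$row, sc$truth$organelles$row, "-")^2 +
                outer(mx$col, sc$truth$organelles$col, "-")^2)
    expect_lt(max(apply(d, 1, min)), 3)
  }
})

test_that("regions carry the full 19 px disc and drop border maxima", {
  mx <- data.frame(row = 50, col = 50, value = 1)
  regs <- make_regions(mx, c(100, 100))
  expect_equal(nrow(regs), 1)
  expect_equal(nrow(disc_offsets(regs$diameter_px[1])), 293)
  # a maximum 5 px from the border cannot host a 19 px disc
  near <- data.frame(row = c(5, 96, 50), col = c(50, 50, 5), value = 1)
  regs2 <- make_regions(near, c(100, 100))
  expect_equal(nrow(regs2), 0)
  expect_equal(attr(regs2, "n_dropped"), 3L)
  # empty input passes through
  expect_equal(nrow(make_regions(mx[0, ], c(100, 100))), 0)
  expect_error(make_regions(mx, c(100, 100), diameter_px = 18))
})

test_that("random regions respect distance, image and overlap constraints", {
  sp <- quiet_scene(n = 8, size = 320, seed = 6, diam = c(150, 400),
                    min_sep = 800)
  sc <- generate_scene(sp)
  mat <- sc$stack$channels[[1]]
  regs <- make_regions(find_maxima(mat), dim(mat))
  excl <- exclusion_mask(mat)
  rnd <- make_random_regions(regs, excl, dim(mat), seed = 17)
  expect_gt(nrow(rnd), 0)
  for (i in seq_len(nrow(rnd))) {
    src <- regs[regs$id == rnd$source_id[i], ]
    expect_lte(sqrt((rnd$row[i] - src$row)^2 + (rnd$col[i] - src$col)^2),
               180 + 0.71) # continuous draw <= 180, then rounded to pixels
    # disc fully inside the image
    expect_true(rnd$row[i] - 9 >= 1 && rnd$row[i] + 9 <= 320 &&
                  rnd$col[i] - 9 >= 1 && rnd$col[i] + 9 <= 320)
    # exhaustive pixel-set disjointness against every peroxisomal disc
    for (k in seq_len(nrow(regs))) {
      expect_false(oracle_discs_overlap(c(rnd$row[i], rnd$col[i]),
                                        c(regs$row[k], regs$col[k]), 19))
    }
    # no matrix-marker signal inside the disc
    offs <- disc_offsets(19)
    expect_false(any(excl[cbind(rnd$row[i] + offs[, 1],
                                rnd$col[i] + offs[, 2])]))
  }
  # reproducible for a fixed seed
  expect_identical(rnd, make_random_regions(regs, excl, dim(mat), seed = 17))
})

test_that("an all-TRUE exclusion mask defeats random placement entirely", {
  regs <- make_regions(data.frame(row = 60, col = 60, value = 1), c(120, 120))
  full <- matrix(TRUE, 120, 120)
  rnd <- make_random_regions(regs, full, c(120, 120), seed = 1,
                             max_tries = 50)
  expect_equal(nrow(rnd), 0)
  expect_equal(attr(rnd, "n_failed"), 1L)
})
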