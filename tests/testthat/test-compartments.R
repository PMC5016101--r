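test_that("patch maxima detection follows the retention rule", {
  rr <- matrix(1:19, 19, 19); cc <- t(rr)
  blob <- function(r0, c0, amp, s = 1.5)
    amp * exp(-((rr - r0)^2 + (cc - c0)^2) / (2 * s^2))
  one <- blob(10, 10, 100)
  m1 <- find_patch_maxima(one)
  expect_equal(nrow(m1), 1)
  expect_equal(unname(m1[1, ]), c(10L, 10L))
  # the 40-amplitude blob falls below 50% of the 100-amplitude one
  two <- blob(6, 6, 100) + blob(14, 14, 40)
  m2 <- find_patch_maxima(two)
  expect_equal(nrow(m2), 1)
  expect_equal(unname(m2[1, ]), c(6L, 6L))
  # equal blobs are both retained
  eq <- blob(6, 6, 100) + blob(14, 14, 90)
  expect_equal(nrow(find_patch_maxima(eq)), 2)
  # flat patches are rejected with the flag set
  flat <- find_patch_maxima(matrix(0, 19, 19))
  expect_equal(nrow(flat), 0)
  expect_true(attr(flat, "flat"))
})

test_that("patch maxima equal a brute-force scan of the smoothed patch", {
  set.seed(101)
  msk <- disc_mask(19)
  for (k in 1:25) {
    patch <- matrix(runif(19 * 19), 19, 19)
    got <- find_patch_maxima(patch, sigma = 1)
    sm <- gaussian_blur(patch, 1)
    gmax <- max(sm[msk])
    want <- matrix(0L, 0, 2)
    for (i in 1:19) for (j in 1:19) {
      if (!msk[i, j]) next
      nb <- sm[max(1, i - 1):min(19, i + 1), max(1, j - 1):min(19, j + 1)]
      if (sm[i, j] == max(nb) && sm[i, j] >= 0.5 * gmax)
        want <- rbind(want, c(i, j))
    }
    expect_equal(unname(unclass(got))[, ], want[, ],
                 info = paste("patch", k))
  }
})

test_that("the retention rule is scale invariant", {
  p <- random_disc_patch(seed = 102)
  a <- find_patch_maxima(p)
  b <- find_patch_maxima(137.5 * p)
  expect_equal(unclass(a)[, ], unclass(b)[, ])
})

test_that("interchannel distance averages both directed nearest distances", {
  expect_equal(interchannel_distance(cbind(3, 4), cbind(3, 4)), 0)
  expect_equal(interchannel_distance(cbind(0, 0), cbind(3, 4)), 5)
  a <- rbind(c(0, 0), c(10, 0)); b <- rbind(c(1, 0))
  expect_equal(interchannel_distance(a, b), mean(c(1, 9, 1)))
  # symmetric in its arguments
  set.seed(103)
  ma <- cbind(sample(1:19, 4), sample(1:19, 4))
  mb <- cbind(sample(1:19, 3), sample(1:19, 3))
  expect_equal(interchannel_distance(ma, mb), interchannel_distance(mb, ma))
})

test_that("domain offset drives distance up and colocalization down", {
  stats <- lapply(c(0, 120), function(off) {
    sp <- quiet_scene(n = 10, size = 320, seed = 15, offset = off,
                      diam = c(250, 380))
    sc <- generate_scene(sp)
    regs <- make_regions(find_maxima(sc$stack$channels[[1]]),
                         dim(sc$stack))
    cp <- compartmentalization_table(sc$stack, regs, 2, 3)
    cp$records
  })
  expect_gt(mean(stats[[2]]$distance_px), mean(stats[[1]]$distance_px))
  expect_lt(mean(stats[[2]]$pearson), mean(stats[[1]]$pearson))
  # distances stay within the region diameter
  all_rec <- rbind(stats[[1]], stats[[2]])
  expect_true(all(all_rec$distance_px <= 19))
  expect_true(all(all_rec$n_maxima_ch1 >= 1 & all_rec$n_maxima_ch2 >= 1))
  # distance-vs-Pearson map is a normalized frequency table
  sp <- quiet_scene(n = 10, size = 320, seed = 15, offset = 120,
                    diam = c(250, 380))
  sc <- generate_scene(sp)
  regs <- make_regions(find_maxima(sc$stack$channels[[1]]), dim(sc$stack))
  cp <- compartmentalization_table(sc$stack, regs, 2, 3)
  expect_equal(sum(cp$freq_map), 1)
})
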