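test_that("drift estimation recovers known shifts on synthetic scenes", {
  sp <- quiet_scene(n = 8, size = 160, seed = 2, diam = c(130, 300),
                    noise = FALSE, min_sep = 500)
  a <- generate_scene(sp)$stack$channels[[1]]
  expect_equal(unname(estimate_drift(a, a)), c(0L, 0L))
  for (s in list(c(3, -2), c(18, 18), c(-18, 5), c(0, -11))) {
    expect_equal(unname(estimate_drift(a, translate_zero(a, s))),
                 as.integer(s))
  }
  # antisymmetry on a noiseless pair
  b <- translate_zero(a, c(4, -7))
  expect_equal(unname(estimate_drift(a, b)), -unname(estimate_drift(b, a)))
})

test_that("FFT drift scoring agrees with the direct per-offset oracle", {
  set.seed(31)
  for (k in 1:8) {
    a <- matrix(runif(35 * 42), 35, 42)
    b <- matrix(runif(35 * 42), 35, 42)
    expect_equal(unname(estimate_drift(a, b, window = 6)),
                 oracle_drift(a, b, window = 6))
    expect_equal(unname(estimate_drift(a, b, window = 6,
                                       mode = "literal_minimum")),
                 oracle_drift(a, b, window = 6, mode = "literal_minimum"))
  }
})

test_that("registration without signal is refused", {
  z <- matrix(0, 32, 32)
  x <- matrix(runif(32 * 32), 32, 32)
  expect_error(estimate_drift(z, x), "no registration signal")
  expect_error(estimate_drift(x, z), "no registration signal")
})

test_that("chromatic shift is recovered to sub-pixel accuracy from beads", {
  beads0 <- simulate_beads(n_beads = 10, shift_px = c(0, 0), seed = 3)
  expect_lt(max(abs(estimate_chromatic_shift(beads0$a, beads0$b))), 0.05)
  beads <- simulate_beads(n_beads = 10, shift_px = c(1.5, -0.5), seed = 3)
  est <- estimate_chromatic_shift(beads$a, beads$b)
  expect_lt(max(abs(est - c(1.5, -0.5))), 0.1)
  # disjoint fields: nothing matches within the radius
  far <- translate_zero(beads$b, c(60, 60))
  expect_error(estimate_chromatic_shift(beads$a, far), "insufficient beads")
})

test_that("applying a correction closes the registration loop", {
  sp <- quiet_scene(n = 6, size = 192, seed = 8, diam = c(130, 300),
                    noise = FALSE, min_sep = 500)
  stack <- generate_scene(sp)$stack
  # identity transform leaves the stack untouched
  ident <- apply_correction(stack, correction_transform())
  expect_equal(ident$channels, stack$channels)
  # drift the STED channels, estimate from the reference pair, correct
  drift <- c(3, -2)
  drifted <- stack
  for (ch in 2:3) drifted <- apply_known_shift(drifted, drift, ch)
  ref_b <- translate_zero(stack$channels[[1]], drift)
  est <- estimate_drift(stack$channels[[1]], ref_b)
  expect_equal(unname(est), drift)
  fixed <- apply_correction(drifted, correction_transform(drift_shift_px = est))
  inner_r <- 5:188; inner_c <- 5:188
  expect_equal(fixed$channels[[2]][inner_r, inner_c],
               stack$channels[[2]][inner_r, inner_c])
  # residual shift re-estimates to zero
  re <- estimate_drift(stack$channels[[1]],
                       translate_zero(ref_b, -est))
  expect_equal(unname(re), c(0L, 0L))
  # sub-pixel chromatic correction undoes a known sub-pixel displacement
  beads <- simulate_beads(n_beads = 8, shift_px = c(0.75, -1.25), seed = 5)
  t <- correction_transform(chromatic_shift_px =
                              estimate_chromatic_shift(beads$a, beads$b))
  stk <- image_stack(list(beads$a, beads$b), labels = c("a", "b"),
                     modality = c("confocal", "sted"))
  fixed2 <- apply_correction(stk, t)
  resid <- estimate_chromatic_shift(fixed2$channels[[1]], fixed2$channels[[2]])
  expect_lt(max(abs(resid)), 0.15)
})
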