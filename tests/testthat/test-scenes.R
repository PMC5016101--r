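test_that("scene generation is deterministic and conserves the photon budget", {
  sp <- quiet_scene(n = 5, size = 192, seed = 7, diam = c(150, 350),
                    noise = FALSE, background_rate = 0)
  sc1 <- generate_scene(sp)
  sc2 <- generate_scene(sp)
  expect_identical(sc1$stack$channels, sc2$stack$channels)
  expect_identical(sc1$truth$organelles, sc2$truth$organelles)
  # noiseless, background-free channels integrate to budget * n exactly
  totals <- vapply(sc1$stack$channels, sum, numeric(1))
  expect_equal(totals, sp$photon_budget * 5, tolerance = 1e-12)
  # Poisson sampling is reproducible too
  spn <- quiet_scene(n = 5, size = 192, seed = 7, diam = c(150, 350))
  expect_identical(generate_scene(spn)$stack$channels,
                   generate_scene(spn)$stack$channels)
})

test_that("an empty scene is pure background with empty ground truth", {
  sp <- quiet_scene(n = 0, size = 96, noise = FALSE)
  sc <- generate_scene(sp)
  expect_equal(nrow(sc$truth$organelles), 0)
  for (ch in seq_along(sc$stack$channels)) {
    expect_equal(max(abs(sc$stack$channels[[ch]] - sp$background_rate[ch])), 0)
  }
})

test_that("congruent membrane domains render identically in both channels", {
  sp <- quiet_scene(n = 6, size = 256, seed = 4, offset = 0, noise = FALSE)
  sc <- generate_scene(sp)
  a <- sc$stack$channels[[2]]; b <- sc$stack$channels[[3]]
  # equal budgets and PSFs: identical; unequal budgets: identical up to scale
  expect_lt(max(abs(a - b)), 1e-9 * max(a))
  sp2 <- quiet_scene(n = 6, size = 256, seed = 4, offset = 0, noise = FALSE,
                     photon_budget = c(20000, 8000, 4000),
                     background_rate = 0)
  sc2 <- generate_scene(sp2)
  expect_lt(max(abs(sc2$stack$channels[[2]] - 2 * sc2$stack$channels[[3]])),
            1e-9 * max(sc2$stack$channels[[2]]))
})

test_that("a rendered spot matches direct numerical convolution of disc and PSF", {
  sp <- scene_spec(image_size_px = c(128, 128), n_organelles = 1,
                   diameter_range_nm = c(299, 300), morphology_mix = c(dot = 1),
                   psf_fwhm_nm = 60, poisson_noise = FALSE,
                   background_rate = 0, seed = 2)
  sc <- generate_scene(sp)
  org <- sc$truth$organelles
  sigma_px <- 60 / (2 * sqrt(2 * log(2))) / 20
  # oracle: rasterize the same disc, convolve by direct spatial summation
  nr <- 128
  rr <- matrix(seq_len(nr), nr, nr); cc <- t(rr)
  disc <- ((rr - org$row)^2 + (cc - org$col)^2 <=
             (org$diameter_px / 2)^2) * 1
  oracle_img <- oracle_convolve_gauss(disc, sigma_px)
  r0 <- round_half_up(org$row); c0 <- round_half_up(org$col)
  fw_pkg <- line_profile_fwhm(sc$stack$channels[[1]],
                              c(r0, c0 - 25), c(r0, c0 + 25))
  fw_oracle <- oracle_profile_fwhm(oracle_img[r0, (c0 - 25):(c0 + 25)]) * 20
  expect_lt(abs(fw_pkg - fw_oracle), 20) # within one 20 nm pixel
})

test_that("organelle diameters below two pixels are rejected", {
  expect_error(scene_spec(diameter_range_nm = c(30, 650)), "2 pixels")
  expect_error(scene_spec(morphology_mix = c(dot = 0.7, ring = 0.6)))
})

test_that("apply_known_shift is a faithful drift fixture", {
  sp <- quiet_scene(n = 4, size = 160, seed = 9, diam = c(130, 250))
  sc <- generate_scene(sp)
  # zero shift: identity
  sc0 <- apply_known_shift(sc, c(0, 0), channel = 2)
  expect_identical(sc0$stack$channels[[2]], sc$stack$channels[[2]])
  # shift then inverse restores the common support
  s1 <- apply_known_shift(sc$stack, c(3, -2), channel = 2)
  s2 <- apply_known_shift(s1, c(-3, 2), channel = 2)
  inner_r <- 4:157; inner_c <- 4:157
  expect_equal(s2$channels[[2]][inner_r, inner_c],
               sc$stack$channels[[2]][inner_r, inner_c])
  # a delta image relocates exactly
  img <- matrix(0, 32, 32); img[10, 12] <- 7
  stk <- image_stack(list(img))
  shifted <- apply_known_shift(stk, c(5, 5), channel = 1)
  expect_equal(shifted$channels[[1]][15, 17], 7)
  expect_equal(sum(shifted$channels[[1]]), 7)
  # shift recorded in ground truth; window enforced
  expect_equal(apply_known_shift(sc, c(2, 2), 2)$truth$drift_shift_px, c(2L, 2L))
  expect_error(apply_known_shift(sc, c(19, 0), 2), "window")
})

test_that("increasing the domain offset increases measured rim separation", {
  dists <- vapply(c(0, 60, 120, 180), function(off) {
    sp <- scene_spec(image_size_px = c(128, 128), n_organelles = 1,
                     diameter_range_nm = c(319, 320), morphology_mix = c(ring = 1),
                     n_domains_per_organelle = 1, domain_offset_deg = off,
                     poisson_noise = FALSE, seed = 5)
    sc <- generate_scene(sp)
    org <- sc$truth$organelles
    ctr <- c(round_half_up(org$row), round_half_up(org$col))
    reg <- data.frame(row = ctr[1], col = ctr[2], diameter_px = 19)
    ma <- find_patch_maxima(extract_patch(sc$stack$channels[[2]], reg))
    mb <- find_patch_maxima(extract_patch(sc$stack$channels[[3]], reg))
    interchannel_distance(ma, mb)
  }, numeric(1))
  expect_true(all(diff(dists) > 0))
  # chord geometry: separation ~ 2 R sin(offset / 2) at the rendered radius
  R <- 320 / 20 / 2
  expected <- 2 * R * sin(c(0, 60, 120, 180) / 2 * pi / 180)
  expect_lt(max(abs(dists - expected)), 3)
})

test_that("stacks round-trip through TIFF with their metadata", {
  sp <- quiet_scene(n = 3, size = 128, seed = 12, diam = c(130, 250))
  sc <- generate_scene(sp)
  path <- tempfile(fileext = ".tif")
  write_stack(sc$stack, path)
  back <- read_stack(path)
  expect_equal(back$meta, sc$stack$meta)
  expect_equal(back$pixel_size_nm, 20)
  for (ch in seq_along(back$channels)) {
    expect_lt(max(abs(back$channels[[ch]] - sc$stack$channels[[ch]])),
              1e-4 * max(sc$stack$channels[[ch]]))
  }
  unlink(c(path, paste0(path, ".json")))
})
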