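## Shared scene shortcuts for tests. Small frames keep the suite fast;
## min_separation is relaxed where many organelles must fit a small frame.

quiet_scene <- function(n = 8, size = 256, seed = 1, offset = 0,
                        mix = c(ring = 1), diam = c(150, 400),
                        noise = TRUE, min_sep = 600, ...) {
  scene_spec(image_size_px = c(size, size), n_organelles = n,
             diameter_range_nm = diam, morphology_mix = mix,
             n_domains_per_organelle = 1, domain_offset_deg = offset,
             min_separation_nm = min_sep, poisson_noise = noise, seed = seed, ...)
}

random_disc_patch <- function(d = 19, seed = 1) {
  withr::with_seed(seed, matrix(runif(d * d), d, d))
}
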