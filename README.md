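# peroxiquant

Quantification of protein distributions around peroxisomes in multicolor
STED/confocal images.

Super-resolution STED microscopy resolves peroxisomes (~130-650 nm) well
enough to see matrix cargo, membrane rings and sub-organelle protein
domains separately. This package implements the full quantitative pipeline
for such images, for microscopists and image analysts who need it as
tested, reusable code:

- **registration**: inter-acquisition drift by exhaustive product search
  over an 18 px window; sub-pixel chromatic shift from matched bead
  centroids;
- **detection**: peroxisomes as Find-Maxima-style maxima (smoothing
  sigma = 2.0, noise tolerance 10) of the matrix-marker channel, each
  wrapped in a circular 19 px / 380 nm region, plus matched random control
  regions (uniform translation within 180 px, avoiding all detections and
  any matrix signal);
- **intensity statistics**: per-cell Pearson correlation of integrated
  region intensities

  `r = sum((g_i - mu_g)(r_i - mu_r)) / sqrt(sum((g_i - mu_g)^2) sum((r_i - mu_r)^2))`

  over region pairs (g_i, r_i), pooled 25-bin normalized intensity
  histograms (`g_i / max(g_i)` per cell), Gaussian peak fits, line-profile
  FWHM, and one-way ANOVA with Tukey HSD across conditions;
- **morphology**: per-region Kapur maximum-entropy threshold, despeckle +
  erode, cluster area and boundary-pixel perimeter against the circular
  reference `(pi d, pi d^2 / 4)`;
- **colocalization**: pixel-wise Pearson over the region disc with flip
  (mirrored second channel) and random-region null controls;
- **compartmentalization**: per-channel region maxima (sigma = 1.0, 3x3
  maximum filter, 50% retention) and the mean interchannel nearest-maxima
  distance, paired with each region's Pearson value.

Because no raw micrographs are distributed, the package ships a
ground-truthed synthetic scene generator (organelle geometry, rim domains
with a controllable angular offset between channels, confocal/STED PSF
blur, Poisson noise, filament off-target channel) that every stage is
validated against. See the methods vignette
(`vignettes/peroxisome-quantification.Rmd`) for models, parameter
rationale and design notes.

## Worked example

```r
library(peroxiquant)

# a 512 px (10.24 um) field of 40 ring-type organelles whose two membrane
# proteins sit in domains offset by 90 degrees
sp <- scene_spec(image_size_px = c(512, 512), n_organelles = 40,
                 morphology_mix = c(ring = 1), n_domains_per_organelle = 1,
                 domain_offset_deg = 90, domain_sigma_deg = 40,
                 min_separation_nm = 800, seed = 600 + 90)
sc   <- generate_scene(sp)
mat  <- sc$stack$channels[[1]]
regs <- make_regions(find_maxima(mat), dim(sc$stack))
rnd  <- make_random_regions(regs, exclusion_mask(mat), dim(sc$stack),
                            seed = 740)
ch   <- coloc_histograms(sc$stack, regs, 2, 3, rnd)
round(ch$medians, 3)
#>   real   flip random
#>  0.336  0.269  0.004
cp <- compartmentalization_table(sc$stack, regs, 2, 3)
round(mean(cp$records$distance_nm), 1)
#> [1] 167.1
```

All 40 organelles are detected; the median pixel-wise Pearson value of the
real channel pairing (0.34) exceeds both null controls, the flip control
(0.27) revealing how much correlation dense packing alone produces, and
the random regions centering at 0. The mean interchannel nearest-maxima
distance of ~170 nm reflects the 90 degree domain offset at these organelle
radii; sweeping the offset from 0 to 180 degrees drives this distance up
monotonically while colocalization falls (Spearman rho = -0.95 pooled over
250 regions in `analysis/07_compartments.R`).

The `analysis/` directory holds the numbered workflow drivers
(`01_simulate.R` ... `08_pipeline.R`): scene simulation, registration,
detection, intensity, morphology, colocalization, compartmentalization and
a deterministic end-to-end pipeline run. Each is a thin script over the
package functions and writes its tables (and figures, if ggplot2 is
present) under `results/`.

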