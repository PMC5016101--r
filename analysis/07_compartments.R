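#!/usr/bin/env Rscript
## Compartmentalization stage: sweep the angular offset between the two
## membrane-protein channels, pair each region's interchannel
## nearest-maxima distance with its Pearson value, and map their joint
## frequency.

library(peroxiquant)
dir.create("results", showWarnings = FALSE)

offsets <- c(0, 45, 90, 135, 180)
recs <- list(); summary_rows <- list()
for (i in seq_along(offsets)) {
  sp <- scene_spec(image_size_px = c(512, 512), n_organelles = 50,
                   diameter_range_nm = c(250, 380), morphology_mix = c(ring = 1),
                   n_domains_per_organelle = 1, domain_offset_deg = offsets[i],
                   domain_sigma_deg = 40, min_separation_nm = 800, seed = 700)
  sc <- generate_scene(sp)
  regs <- make_regions(find_maxima(sc$stack$channels[[1]]), c(512, 512))
  cp <- compartmentalization_table(sc$stack, regs, 2, 3)
  if (offsets[i] == 90) {
    write.csv(as.data.frame(as.table(cp$freq_map)), "results/07_freq_map.csv",
              row.names = FALSE)
  }
  r <- cp$records; r$offset_deg <- offsets[i]
  recs[[i]] <- r
  summary_rows[[i]] <- data.frame(
    offset_deg = offsets[i], n = nrow(r),
    mean_distance_nm = mean(r$distance_nm), mean_pearson = mean(r$pearson))
  cat(sprintf("offset %3d deg: mean distance %6.1f nm, mean Pearson %+.3f (n=%d)\n",
              offsets[i], mean(r$distance_nm), mean(r$pearson), nrow(r)))
}
all_rec <- do.call(rbind, recs)
write.csv(all_rec, "results/07_compartment_records.csv", row.names = FALSE)
write.csv(do.call(rbind, summary_rows), "results/07_compartment_sweep.csv",
          row.names = FALSE)
rho <- cor(all_rec$distance_px, all_rec$pearson, method = "spearman")
cat(sprintf("pooled Spearman rho(distance, Pearson) = %.3f over %d regions\n",
            rho, nrow(all_rec)))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dir.create("results/figures", showWarnings = FALSE)
  ggsave("results/figures/07_distance_vs_pearson.png",
         ggplot(all_rec, aes(distance_nm, pearson,
                             colour = factor(offset_deg))) +
           geom_point(alpha = 0.6) +
           labs(x = "interchannel nearest-maxima distance (nm)",
                y = "pixel-wise Pearson r", colour = "offset (deg)") +
           theme_minimal(),
         width = 6, height = 4, dpi = 120)
}
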