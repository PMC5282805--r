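#!/usr/bin/env Rscript
# Step 4: statistical shape model.
#
# Builds the SSM statistics from the fitted coefficients: mean shapes
# per bone and side, left/right correlation of mean coefficient vectors
# (full and with the dominant size coefficient removed), and the two-way
# ANOVA over bones x coefficients with its reduced variant.

library(tarsalSSM)

seed <- 1
dir.create("results", showWarnings = FALSE)
cfg <- pipeline_config("synthetic", n_per_side = 15, L = 6,
                       n_folds = 10, n_trees = 40, seed = seed,
                       out_dir = file.path("scratch", "pipeline_run"))
res <- suppressMessages(run_pipeline(cfg))

lat_tab <- do.call(rbind, lapply(names(res$laterality), function(bn) {
  l <- res$laterality[[bn]]
  data.frame(bone = bn, r_squared = l$r_squared, p_value = l$p_value,
             r_squared_reduced = l$r_squared_reduced,
             dropped_k = l$dropped_k)
}))
write.csv(lat_tab, "results/04_laterality.csv", row.names = FALSE)

anova_tab <- rbind(cbind(variant = "full", res$anova$full),
                   cbind(variant = "reduced", res$anova$reduced))
write.csv(anova_tab, "results/04_anova.csv", row.names = FALSE)

vol_tab <- do.call(rbind, lapply(names(res$mean_shapes), function(key) {
  m <- reconstruct_mesh(res$mean_shapes[[key]])
  data.frame(group = key,
             mean_radius_mm = res$mean_shapes[[key]]$coeffs[1] /
               (2 * sqrt(pi)),
             volume_mm3 = mesh_signed_volume(m))
}))
write.csv(vol_tab, "results/04_mean_shapes.csv", row.names = FALSE)

cat("Left/right correlation of mean SPHARM coefficient vectors:\n")
print(lat_tab, digits = 4)
cat("\nThe full-vector r^2 is high for every bone (the shared class",
    "mean and the\ndominant size coefficient drive it); dropping that",
    "dominant coefficient\n(always k =", unique(lat_tab$dropped_k),
    ", the l = 0 size term) collapses the correlation because\nmirrored",
    "left shapes carry systematic sign flips on the odd-order",
    "harmonics.\n\n")
cat("Two-way ANOVA over bones x coefficients:\n")
print(anova_tab, digits = 4)
cat("\nAll three effects are overwhelmingly significant in both",
    "variants, matching\nthe designed between-class coefficient",
    "separation.\n\nMean shapes:\n")
print(vol_tab, digits = 4)
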