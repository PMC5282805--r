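#!/usr/bin/env Rscript
# Step 1: simulate the study population.
#
# Generates the default synthetic cohort emulating the study design:
# 4 tarsal bone classes (calcaneus-, talus-, cuboid-, navicular-like),
# 15 right and 15 left samples per class, each a closed star-shaped
# surface with known degree-4 SPHARM coefficients, painted landmark
# patches and mirrored left sides. Writes a per-class summary table.

library(tarsalSSM)

seed <- 1
dir.create("results", showWarnings = FALSE)
classes <- default_bone_classes()

rows <- list()
for (ci in seq_along(classes)) {
  spec <- classes[[ci]]
  pop <- sample_population(spec, 15, seed = seed * 100 + ci)
  radii <- vapply(pop, function(s) {
    mean(sqrt(rowSums(sweep(s$mesh$vertices, 2,
                            colMeans(s$mesh$vertices))^2)))
  }, numeric(1))
  patch_sizes <- vapply(c("a", "b", "c"), function(lab) {
    mean(vapply(pop, function(s) sum(s$mesh$labels == lab), numeric(1)))
  }, numeric(1))
  vols <- vapply(pop, function(s) mesh_signed_volume(s$mesh), numeric(1))
  rows[[spec$name]] <- data.frame(
    class = spec$name, n_right = 15, n_left = 15,
    mean_radius_mm = mean(radii), sd_radius_mm = sd(radii),
    mean_volume_mm3 = mean(vols),
    patch_a_vertices = patch_sizes[1],
    patch_b_vertices = patch_sizes[2],
    patch_c_vertices = patch_sizes[3])
}
summary_tab <- do.call(rbind, rows)
rownames(summary_tab) <- NULL
write.csv(summary_tab, "results/01_population_summary.csv",
          row.names = FALSE)

cat("Simulated", length(classes), "classes x 30 samples each.\n")
print(summary_tab, digits = 4)
cat("\nAll", 4 * 30, "meshes are closed, star-shaped and carry their",
    "three landmark patches;\nper-class sizes follow the relative sizes",
    "of the real bones (calcaneus largest).\n")
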