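#!/usr/bin/env Rscript
# Step 3: landmarking, pose normalization and SPHARM decomposition.
#
# Runs the full model-building chain on the simulated cohort: detect the
# three landmarks per bone from the painted patches, place each bone in
# its canonical landmark frame (rotate the landmark plane onto z = 0,
# landmark c to the origin, landmark a onto +x), parameterize the
# surface radius about the centroid and fit the degree-6 SPHARM
# expansion (49 real coefficients) per bone. Also reports the MDL order
# curve for one example bone.

library(tarsalSSM)

seed <- 1
dir.create("results", showWarnings = FALSE)
run_dir <- file.path("scratch", "pipeline_run")
cfg <- pipeline_config("synthetic", n_per_side = 15, L = 6,
                       n_folds = 10, n_trees = 40, seed = seed,
                       out_dir = run_dir)
res <- suppressMessages(run_pipeline(cfg))

# compact per-coefficient statistics per bone and side
file.copy(file.path(run_dir, "coefficient_stats.csv"),
          "results/03_coefficient_stats.csv", overwrite = TRUE)

# MDL order selection on one sample (fitting degree is a config choice;
# MDL tells us the generator's effective order is recovered)
s1 <- res$samples[[1]]
sel <- select_order_mdl(parameterize(s1$mesh), 8)
mdl_tab <- data.frame(L = 0:8, n_coeffs = (1:9)^2, mdl = sel$mdl[1:9],
                      rss = sel$rss[1:9])
write.csv(mdl_tab, "results/03_mdl_curve.csv", row.names = FALSE)

cat("Fitted", length(res$models), "bones at L = 6 (49 coefficients).\n")
cat("Mean RMS fit residual:",
    round(mean(vapply(res$models, function(m) m$rms_residual,
                      numeric(1))), 5), "mm\n")
cat("MDL on one generated bone selects L =", sel$L_opt,
    "(generating degree 4).\n")
print(mdl_tab, digits = 4)
cat("\nThe full run directory (per-sample coefficients, mean-shape",
    "surfaces, reports)\nis under", run_dir, "; summary tables are in",
    "results/.\n")
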