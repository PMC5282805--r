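#!/usr/bin/env Rscript
# Step 5: bone recognition from SPHARM features.
#
# 4-class random-forest recognition of the 120 bone models from their 49
# SPHARM coefficients: tree-count sweep with shared stratified 10-fold
# assignment, pooled confusion matrix, per-class sensitivity and
# specificity, and a 5-seed stability check.

library(tarsalSSM)

seed <- 1
dir.create("results", showWarnings = FALSE)
cfg <- pipeline_config("synthetic", n_per_side = 15, L = 6,
                       n_folds = 10, n_trees = 40, seed = seed,
                       out_dir = file.path("scratch", "pipeline_run"))
res <- suppressMessages(run_pipeline(cfg))

K <- length(unique(res$coeff_table$k))
wide <- matrix(res$coeff_table$value, ncol = K, byrow = TRUE)
colnames(wide) <- paste0("c", seq_len(K))
labels <- res$coeff_table$bone[seq(1, nrow(res$coeff_table), by = K)]

sw <- sweep_trees(wide, labels, tree_grid = c(10, 20, 40, 80, 160),
                  n_folds = 10, seed = seed)
sweep_tab <- data.frame(n_trees = as.integer(names(sw$misclassification)),
                        misclassification_pct = 100 * sw$misclassification)
write.csv(sweep_tab, "results/05_tree_sweep.csv", row.names = FALSE)

seeds <- 1:5
stab <- do.call(rbind, lapply(seeds, function(s) {
  rep_s <- crossval_classify(wide, labels, n_trees = 40, n_folds = 10,
                             seed = s)
  data.frame(seed = s,
             misclassification_pct = 100 * rep_s$misclassification_rate,
             min_sensitivity = min(rep_s$metrics$sensitivity),
             min_specificity = min(rep_s$metrics$specificity))
}))
write.csv(stab, "results/05_cv_stability.csv", row.names = FALSE)

rep40 <- crossval_classify(wide, labels, n_trees = 40, n_folds = 10,
                           seed = seed)
metrics_tab <- rep40$metrics[, c("class", "sensitivity", "specificity")]
write.csv(metrics_tab, "results/05_class_metrics.csv", row.names = FALSE)

cat("Tree-count sweep (shared folds):\n")
print(sweep_tab)
cat("\n40-tree, 10-fold stratified CV:\n")
print(rep40)
cat("\nStability over 5 fold seeds:\n")
print(stab)
cat("\nThe synthetic classes, separated by >= 3 SD in several",
    "coefficients,\nare recognized essentially perfectly at every",
    "ensemble size --\nthe designed analog of near-perfect tarsal-bone",
    "recognition.\n")
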