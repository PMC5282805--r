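#' Stratified fold assignment
#'
#' Assigns each sample to one of \code{n_folds} folds so that every class
#' is spread as evenly as possible across folds (within-class shuffled,
#' then folds dealt round-robin). Errors if any class has fewer members
#' than folds.
#'
#' @param labels class label per sample.
#' @param n_folds number of folds (>= 2).
#' @param seed RNG seed for the within-class shuffles.
#' @return integer vector of fold ids in 1..n_folds.
#' @export
stratified_folds <- function(labels, n_folds, seed) {
  stopifnot(n_folds >= 2)
  labels <- as.character(labels)
  counts <- table(labels)
  if (min(counts) < n_folds) {
    stop("class '", names(counts)[which.min(counts)], "' has only ",
         min(counts), " members; cannot stratify into ", n_folds,
         " folds")
  }
  set.seed(seed)
  folds <- integer(length(labels))
  for (cl in names(counts)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

#' Per-class sensitivity and specificity from a confusion matrix
#'
#' One-vs-rest decomposition of a square confusion matrix (rows = truth,
#' columns = predicted): sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP). Zero denominators yield NA (undefined), never 0.
#'
#' @param confusion square nonnegative integer matrix with matching
#'   row/column names.
#' @return data.frame per class: tp, fn, fp, tn, sensitivity,
#'   specificity.
#' @export
class_metrics <- function(confusion) {
  stopifnot(nrow(confusion) == ncol(confusion), all(confusion >= 0))
  if (sum(confusion) == 0) stop("all-zero confusion matrix")
  total <- sum(confusion)
  out <- do.call(rbind, lapply(seq_len(nrow(confusion)), function(i) {
    tp <- confusion[i, i]
    fn <- sum(confusion[i, ]) - tp
    fp <- sum(confusion[, i]) - tp
    tn <- total - tp - fn - fp
    data.frame(class = rownames(confusion)[i], tp = tp, fn = fn,
               fp = fp, tn = tn,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Cross-validated random-forest bone classification
#'
#' Stratified k-fold cross-validation of a random-forest classifier on
#' SPHARM feature vectors: per fold, a forest is trained on the other
#' folds and predicts the held-out rows; the confusion matrix is pooled
#' over folds and the misclassification rate is the pooled error
#' fraction (matching a single rate over all samples rather than a
#' per-fold average). Fully seeded: the same seed reproduces the report.
#'
#' @param features numeric matrix, rows = samples, columns = SPHARM
#'   coefficients; no missing values.
#' @param labels class label per row (>= 2 classes).
#' @param n_trees forest size.
#' @param n_folds number of CV folds.
#' @param seed RNG seed driving fold assignment and forest training.
#' @param folds optional precomputed fold assignment (overrides seed for
#'   the assignment, e.g. to share folds across a tree sweep).
#' @return object of class \code{classifier_report}: list with
#'   \code{n_trees}, \code{confusion}, \code{misclassification_rate},
#'   \code{metrics} (from \code{class_metrics}), \code{folds},
#'   \code{seed}.
#' @export
crossval_classify <- function(features, labels, n_trees = 40,
                              n_folds = 10, seed = 1, folds = NULL) {
  features <- as.matrix(features)
  labels <- factor(labels)
  stopifnot(nrow(features) == length(labels), !anyNA(features),
            nlevels(labels) >= 2)
  if (is.null(folds)) folds <- stratified_folds(labels, n_folds, seed)
  classes <- levels(labels)
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(truth = classes,
                                      predicted = classes))
  pred_all <- factor(rep(classes[1], length(labels)), levels = classes)
  for (f in sort(unique(folds))) {
    test <- folds == f
    set.seed(seed * 1000L + f)
    rf <- randomForest::randomForest(features[!test, , drop = FALSE],
                                     labels[!test], ntree = n_trees)
    pred_all[test] <- stats::predict(rf,
                                     features[test, , drop = FALSE])
  }
  for (i in seq_along(labels)) {
    confusion[labels[i], pred_all[i]] <- confusion[labels[i],
                                                   pred_all[i]] + 1L
  }
  structure(list(n_trees = n_trees, confusion = confusion,
                 misclassification_rate = mean(pred_all != labels),
                 metrics = class_metrics(confusion),
                 folds = folds, seed = seed),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("classifier_report:", x$n_trees, "trees,",
      length(unique(x$folds)), "folds, misclassification ",
      format(100 * x$misclassification_rate, digits = 3), "%\n")
  print(x$confusion)
  print(x$metrics[, c("class", "sensitivity", "specificity")])
  invisible(x)
}

#' Sweep the forest size over a grid
#'
#' Runs \code{crossval_classify} once per tree count on a shared fold
#' assignment and returns the count with the smallest pooled
#' misclassification (ties resolve to the smaller count).
#'
#' @param features,labels,n_folds,seed as in \code{crossval_classify}.
#' @param tree_grid non-empty vector of tree counts.
#' @return list with \code{best_n_trees}, \code{misclassification}
#'   (named numeric per grid point) and \code{reports}.
#' @export
sweep_trees <- function(features, labels, tree_grid = c(10, 20, 40, 80, 160),
                        n_folds = 10, seed = 1) {
  stopifnot(length(tree_grid) >= 1)
  folds <- stratified_folds(labels, n_folds, seed)
  reports <- lapply(tree_grid, function(nt) {
    crossval_classify(features, labels, n_trees = nt, n_folds = n_folds,
                      seed = seed, folds = folds)
  })
  mis <- vapply(reports, function(r) r$misclassification_rate, numeric(1))
  names(mis) <- tree_grid
  o <- order(mis, tree_grid)
  list(best_n_trees = tree_grid[o[1]], misclassification = mis,
       reports = reports)
}
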