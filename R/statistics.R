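#' Build a long coefficient table from fitted SPHARM models
#'
#' One row per (subject, bone, side, coefficient index); the common
#' currency of the descriptive statistics, ANOVA and laterality analyses.
#'
#' @param models list of \code{spharm_model}s.
#' @param subject_id,bone,side vectors parallel to \code{models}.
#' @return data.frame with columns subject_id, bone, side, k, value.
#' @export
coefficient_table <- function(models, subject_id, bone, side) {
  stopifnot(length(models) == length(subject_id),
            length(models) == length(bone),
            length(models) == length(side))
  K <- length(models[[1]]$coeffs)
  tab <- do.call(rbind, lapply(seq_along(models), function(i) {
    if (length(models[[i]]$coeffs) != K) {
      stop("model ", i, " has a different number of coefficients")
    }
    data.frame(subject_id = subject_id[i], bone = bone[i], side = side[i],
               k = seq_len(K), value = models[[i]]$coeffs)
  }))
  if (anyDuplicated(tab[, c("subject_id", "bone", "side", "k")])) {
    stop("duplicate (subject, bone, side, k) keys in coefficient table")
  }
  tab
}

#' Per-coefficient descriptive statistics
#'
#' Quartiles (linear-interpolation convention), mean, and the outliers
#' beyond 1.5 IQR from the quartiles, per coefficient index, optionally
#' restricted to one bone and/or side.
#'
#' @param table a coefficient table (see \code{coefficient_table}).
#' @param bone,side optional filters.
#' @return data.frame per k: q1, median, q3, mean, n, n_outliers; the
#'   outlier values are attached as attribute \code{"outliers"} (list by
#'   k).
#' @export
coefficient_stats <- function(table, bone = NULL, side = NULL) {
  if (!is.null(bone)) table <- table[table$bone == bone, ]
  if (!is.null(side)) table <- table[table$side == side, ]
  if (!nrow(table)) stop("empty group: no rows after filtering")
  ks <- sort(unique(table$k))
  outliers <- vector("list", length(ks))
  stats_df <- do.call(rbind, lapply(seq_along(ks), function(i) {
    v <- table$value[table$k == ks[i]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    out <- v[v < q[1] - 1.5 * iqr | v > q[3] + 1.5 * iqr]
    outliers[[i]] <<- out
    data.frame(k = ks[i], q1 = q[1], median = q[2], q3 = q[3],
               mean = mean(v), n = length(v), n_outliers = length(out))
  }))
  attr(stats_df, "outliers") <- outliers
  stats_df
}

#' Mean shape of a group of SPHARM models
#'
#' Element-wise mean of the coefficient vectors (and of the expansion
#' origins); by linearity of the expansion this is the SPHARM model of
#' the group's mean radius function.
#'
#' @param models non-empty list of \code{spharm_model}s sharing L.
#' @return \code{spharm_model}.
#' @export
mean_shape <- function(models) {
  stopifnot(length(models) >= 1)
  L <- models[[1]]$L
  if (any(vapply(models, function(m) m$L, integer(1)) != L)) {
    stop("models have mismatched degrees L; cannot average")
  }
  co <- rowMeans(vapply(models, function(m) m$coeffs,
                        numeric(sh_n_coeffs(L))))
  org <- rowMeans(vapply(models, function(m) m$origin, numeric(3)))
  spharm_model(L, co, origin = org)
}

#' Left/right laterality correlation of mean coefficient vectors
#'
#' Squared Pearson correlation between the left-group and right-group
#' mean SPHARM coefficient vectors, with the p-value from the two-sided
#' t transform on n - 2 degrees of freedom; plus the reduced variant
#' dropping the single dominant coefficient (largest |left mean|, in
#' practice the l = 0 size term), which otherwise inflates r^2.
#'
#' @param left_mean,right_mean equal-length (>= 3) coefficient vectors.
#' @return list: r_squared, p_value, r_squared_reduced, p_value_reduced,
#'   dropped_k (index removed in the reduced variant).
#' @export
laterality_correlation <- function(left_mean, right_mean) {
  stopifnot(length(left_mean) == length(right_mean),
            length(left_mean) >= 3)
  if (stats::sd(left_mean) == 0 || stats::sd(right_mean) == 0) {
    stop("zero variance in a coefficient vector; correlation undefined")
  }
  ct <- stats::cor.test(left_mean, right_mean)
  drop_k <- which.max(abs(left_mean))
  lred <- left_mean[-drop_k]
  rred <- right_mean[-drop_k]
  if (length(lred) < 3) {
    # two points always correlate perfectly; report the reduced variant
    # as undefined instead of a vacuous 1
    return(list(r_squared = unname(ct$estimate^2), p_value = ct$p.value,
                r_squared_reduced = NA_real_,
                p_value_reduced = NA_real_, dropped_k = drop_k))
  }
  if (stats::sd(lred) == 0 || stats::sd(rred) == 0) {
    stop("zero variance after dropping the dominant coefficient")
  }
  ctr <- stats::cor.test(lred, rred)
  list(r_squared = unname(ct$estimate^2), p_value = ct$p.value,
       r_squared_reduced = unname(ctr$estimate^2),
       p_value_reduced = ctr$p.value, dropped_k = drop_k)
}

#' Two-way fixed-effects ANOVA over bones x coefficients
#'
#' Classical balanced two-factor ANOVA with interaction on the long
#' coefficient table: factor A = bone, factor B = coefficient index,
#' replicates = subjects. Requires a balanced layout (equal replicate
#' count >= 2 in every cell); unbalanced input errors rather than
#' silently picking a sum-of-squares type.
#'
#' @param tab coefficient table (columns bone, k, value).
#' @param exclude_k optional coefficient indices to exclude before
#'   testing (e.g. the dominant size term).
#' @return data.frame with rows bone, coefficient, interaction,
#'   residual and columns df, sum_sq, mean_sq, F, p.
#' @export
two_way_anova <- function(tab, exclude_k = NULL) {
  if (!is.null(exclude_k)) tab <- tab[!(tab$k %in% exclude_k), ]
  cells <- table(factor(tab$bone), factor(tab$k))
  if (length(unique(as.integer(cells))) != 1 || min(cells) < 2) {
    stop("unbalanced design: replicate counts per bone x coefficient ",
         "cell range from ", min(cells), " to ", max(cells),
         "; two_way_anova requires a balanced layout")
  }
  d <- data.frame(A = factor(tab$bone), B = factor(tab$k), y = tab$value)
  fit <- stats::aov(y ~ A * B, data = d)
  s <- summary(fit)[[1]]
  out <- data.frame(
    effect = c("bone", "coefficient", "interaction", "residual"),
    df = s[["Df"]], sum_sq = s[["Sum Sq"]], mean_sq = s[["Mean Sq"]],
    F = s[["F value"]], p = s[["Pr(>F)"]])
  # identically constant data: all SS are numerical noise (~1e-30) and
  # aov reports F = noise/noise; call the effects null instead
  eps <- 1e-20 * (sum(d$y^2) + 1)
  if (sum(out$sum_sq) <= eps) {
    out$sum_sq <- rep(0, 4)
    out$mean_sq <- rep(0, 4)
    out$F[1:3] <- 0
    out$p[1:3] <- 1
  }
  degen <- is.nan(out$F) & out$sum_sq <= 0
  out$F[degen] <- 0
  out$p[degen] <- 1
  rownames(out) <- NULL
  out
}
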