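#' @name scoring
#' @title Comparing density vectors on a mask
#' @description
#' Two density maps restricted to the same mask are compared with four
#' metrics: Pearson correlation (the cryo-EM real-space cross-correlation),
#' Spearman rank correlation (Pearson on midranks), a k-nearest-neighbour
#' mutual-information estimate (Kraskov estimator, k = 6, in nats), and the
#' area under the precision-recall curve for recovering the reference map's
#' high-density voxels (> 3 sigma of the mask values) by thresholding the
#' predicted map. Metrics that cannot be computed carry a typed reason code
#' rather than a silent zero.
NULL

check_vector_pair <- function(x, xo) {
  if (length(x) != length(xo)) stop("vectors differ in length")
  if (length(x) < 2L) undefined_metric("too_few_voxels", "fewer than 2 voxels")
}

#' Pearson correlation coefficient of two density vectors
#'
#' The centred dot product over the product of centred norms — the standard
#' cryo-EM real-space cross-correlation.
#'
#' @param x,xo numeric vectors of equal length (predicted, reference).
#' @return scalar in [-1, 1]; a constant input raises a classed
#'   `cryoshell_undefined_metric` error (reason `"constant_input"`).
#' @export
pearson_cc <- function(x, xo) {
  check_vector_pair(x, xo)
  dx <- x - mean(x); do <- xo - mean(xo)
  sx <- sqrt(sum(dx^2)); so <- sqrt(sum(do^2))
  if (sx == 0 || so == 0)
    undefined_metric("constant_input", "correlation undefined for a constant vector")
  sum(dx * do) / (sx * so)
}

#' Spearman rank correlation of two density vectors
#'
#' Pearson correlation of the rank vectors; ties receive average ranks
#' (midranks).
#'
#' @inheritParams pearson_cc
#' @return scalar in [-1, 1]; an all-tied vector raises
#'   `cryoshell_undefined_metric`.
#' @export
spearman_rho <- function(x, xo) {
  check_vector_pair(x, xo)
  rx <- rank(x, ties.method = "average")
  ro <- rank(xo, ties.method = "average")
  if (sd(rx) == 0 || sd(ro) == 0)
    undefined_metric("constant_input", "rank correlation undefined for an all-tied vector")
  pearson_cc(rx, ro)
}

#' k-nearest-neighbour mutual information between two density vectors
#'
#' Kraskov-type continuous MI estimate (estimator 1, Chebyshev metric) with
#' neighbourhood `k`, the estimator behind scikit-learn's
#' `mutual_info_regression`. A tiny seeded jitter (relative magnitude
#' `jitter`) breaks exact ties, as required by the estimator; the estimate
#' is clipped at 0.
#'
#' @inheritParams pearson_cc
#' @param k neighbourhood size (default 6).
#' @param seed seed for the tie-breaking jitter (default 0).
#' @param jitter relative jitter magnitude (default 1e-10 of the value sd).
#' @return MI in nats, >= 0; vectors of length <= k + 1 raise
#'   `cryoshell_undefined_metric` (reason `"too_few_voxels"`).
#' @export
mutual_information <- function(x, xo, k = 6, seed = 0, jitter = 1e-10) {
  check_vector_pair(x, xo)
  if (length(x) <= k + 1)
    undefined_metric("too_few_voxels",
                     sprintf("need more than k + 1 = %d voxels, have %d", k + 1, length(x)))
  with_seed(seed, {
    x <- x + rnorm(length(x), 0, jitter * (sd(x) + 1e-300) + 1e-300)
    xo <- xo + rnorm(length(xo), 0, jitter * (sd(xo) + 1e-300) + 1e-300)
  })
  cpp_ksg_mi(x, xo, as.integer(k))
}

#' Label high-density voxels of the reference vector
#'
#' A voxel is positive when its reference value exceeds `sigma_mult` times
#' the standard deviation of the reference values within the mask (the
#' comparison universe); this is the sigma-contour convention of cryo-EM
#' visualization, applied mask-locally.
#'
#' @param xo reference density vector.
#' @param sigma_mult threshold in mask-local standard deviations (default 3).
#' @param sigma optionally a fixed sigma (e.g. the whole-map sd) overriding
#'   the mask-local value.
#' @return logical vector of labels.
#' @export
classify_high_density <- function(xo, sigma_mult = 3, sigma = NULL) {
  if (is.null(sigma)) sigma <- sd(xo)
  if (!is.finite(sigma) || sigma == 0)
    undefined_metric("constant_input", "zero-variance reference; sigma threshold undefined")
  xo > sigma_mult * sigma
}

#' Precision-recall curve for recovering labelled voxels by thresholding
#'
#' Sweeps descending thresholds over the distinct predicted values; at each
#' threshold voxels with predicted value >= threshold are called positive.
#' Precision = TP / predicted positives, recall = TP / actual positives,
#' plus the false positive rate. The area under the curve is the
#' right-continuous step sum \eqn{\sum_i (recall_i - recall_{i-1})
#' precision_i}, which is invariant to strictly monotone transforms of the
#' predictions.
#'
#' @param x predicted density vector.
#' @param labels logical vector from [classify_high_density()].
#' @return a `pr_curve`: list with `thresholds`, `precision`, `recall`,
#'   `false_positive_rate`, `auc_pr`. Single-class labels raise
#'   `cryoshell_undefined_metric` (reason `"single_class"`).
#' @export
pr_curve <- function(x, labels) {
  if (length(x) != length(labels)) stop("vectors differ in length")
  P <- sum(labels); N <- sum(!labels)
  if (P == 0L || N == 0L)
    undefined_metric("single_class",
                     sprintf("labels have %d positives and %d negatives", P, N))
  ord <- order(x, decreasing = TRUE)
  xs <- x[ord]; ls <- labels[ord]
  tp <- cumsum(ls); fp <- cumsum(!ls)
  # last occurrence of each distinct value = the ">= threshold" call set
  last <- c(which(diff(xs) != 0), length(xs))
  thr <- xs[last]
  tp <- tp[last]; fp <- fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / P
  fpr <- fp / N
  auc <- sum(diff(c(0, recall)) * precision)
  structure(list(thresholds = thr, precision = precision, recall = recall,
                 false_positive_rate = fpr, auc_pr = auc),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve> %d thresholds, AUC-PR = %.4f\n",
              length(x$thresholds), x$auc_pr))
  invisible(x)
}

#' AUC-PR across reference-map sigma thresholds
#'
#' Recomputes the high-density labels and the PR curve for each sigma
#' multiplier of the reference, showing how accuracy changes as the focus
#' moves to more ordered solvent.
#'
#' @param x predicted density vector.
#' @param xo reference density vector.
#' @param sigma_mults numeric vector of sigma multipliers.
#' @return data frame with `sigma_mult`, `auc_pr` (NA when undefined) and
#'   `reason`.
#' @export
auc_pr_vs_reference_threshold <- function(x, xo, sigma_mults = seq(1, 5, by = 0.5)) {
  rows <- lapply(sigma_mults, function(m) {
    res <- tryCatch({
      labels <- classify_high_density(xo, m)
      list(auc = pr_curve(x, labels)$auc_pr, reason = "")
    }, cryoshell_undefined_metric = function(e)
      list(auc = NA_real_, reason = e$reason))
    data.frame(sigma_mult = m, auc_pr = res$auc, reason = res$reason)
  })
  do.call(rbind, rows)
}

#' Score a predicted map against a reference map on a mask
#'
#' Extracts the two maps' values on the mask and computes all four metrics;
#' metrics that cannot be computed are NA with a reason code in `reasons`.
#'
#' @param pred,ref `density_grid`s on the mask's lattice (resample first if
#'   needed), or bare numeric vectors already extracted on the mask.
#' @param mask a `shell_mask` (ignored when vectors are passed).
#' @param config a [cryoshell_config()] list (sigma multiplier, MI
#'   neighbourhood and voxel minimum).
#' @param mi_seed seed for the MI tie-breaking jitter.
#' @return a `score_set`: list with `pearson_cc`, `spearman_rho`,
#'   `mutual_info`, `auc_pr`, `n_voxels`, `reasons`.
#' @export
score_pair <- function(pred, ref, mask = NULL, config = cryoshell_config(),
                       mi_seed = 0) {
  x <- if (inherits(pred, "density_grid")) mask_values(pred, mask) else as.numeric(pred)
  xo <- if (inherits(ref, "density_grid")) mask_values(ref, mask) else as.numeric(ref)
  if (length(x) != length(xo)) stop("predicted and reference vectors differ in length")
  reasons <- character()
  run <- function(metric, fn) {
    tryCatch(fn(), cryoshell_undefined_metric = function(e) {
      reasons[[metric]] <<- e$reason
      NA_real_
    })
  }
  out <- list(
    pearson_cc = run("pearson_cc", function() pearson_cc(x, xo)),
    spearman_rho = run("spearman_rho", function() spearman_rho(x, xo)),
    mutual_info = run("mutual_info", function() {
      if (length(x) < config$min_voxels_mi)
        undefined_metric("too_few_voxels",
                         sprintf("%d voxels < min_voxels_mi = %d",
                                 length(x), config$min_voxels_mi))
      mutual_information(x, xo, k = config$mi_k, seed = mi_seed,
                         jitter = config$mi_jitter)
    }),
    auc_pr = run("auc_pr", function()
      pr_curve(x, classify_high_density(xo, config$sigma_mult))$auc_pr),
    n_voxels = length(x),
    reasons = reasons
  )
  structure(out, class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
  cat(sprintf("<score_set> n=%d  CC=%s  rho=%s  MI=%s  AUC-PR=%s\n",
              x$n_voxels, fmt(x$pearson_cc), fmt(x$spearman_rho),
              fmt(x$mutual_info), fmt(x$auc_pr)))
  if (length(x$reasons))
    cat("  skipped:", paste(names(x$reasons), x$reasons, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.score_set <- function(x, ...) {
  data.frame(pearson_cc = x$pearson_cc, spearman_rho = x$spearman_rho,
             mutual_info = x$mutual_info, auc_pr = x$auc_pr,
             n_voxels = x$n_voxels)
}

.metric_names <- c("pearson_cc", "spearman_rho", "mutual_info", "auc_pr")
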