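#' Discretize a putative ground truth at a binarization threshold
#'
#' Per-node Cohen's d effects are discretized into positive significant,
#' negative significant and null regions: sign 0 wherever `|d| < threshold`.
#'
#' @param d Numeric per-node effect sizes (Cohen's d).
#' @param threshold Positive binarization threshold on `|d|`.
#' @return List of class `ground_truth` with `d`, `threshold` and `sign`
#'   (integer in `\{-1, 0, 1\}`).
#' @export
discretize_truth <- function(d, threshold) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be positive", call. = FALSE)
  sgn <- integer(length(d))
  sgn[!is.na(d) & d >= threshold] <- 1L
  sgn[!is.na(d) & d <= -threshold] <- -1L
  structure(list(d = as.numeric(d), threshold = threshold, sign = sgn),
            class = "ground_truth")
}

#' Per-node sensitivity across repeated inferences
#'
#' For each node, the proportion of repetitions in which the node was part of
#' a significant cluster whose sign agrees with the ground-truth sign.
#' Wrong-sign detections count as misses. For truth-null nodes (sign 0) the
#' returned value is the node's detection proportion, i.e. a per-node
#' false-positive rate; these nodes are flagged in the `is_null_node`
#' attribute.
#'
#' @param results Non-empty list of [run_inference()] results over the same
#'   nodes.
#' @param truth A [discretize_truth()] result.
#' @return Numeric per-node vector in `[0, 1]` with attribute `is_null_node`.
#' @export
sensitivity_map <- function(results, truth) {
  if (!is.list(results) || length(results) == 0L)
    stop("a non-empty list of inference results is required", call. = FALSE)
  stopifnot(inherits(truth, "ground_truth"))
  n <- length(truth$sign)
  acc <- numeric(n)
  for (res in results) {
    ps <- predicted_sign(res)
    if (length(ps) != n)
      stop("result and truth disagree on n_nodes", call. = FALSE)
    hit <- ifelse(truth$sign != 0L, ps == truth$sign, ps != 0L)
    acc <- acc + hit
  }
  out <- acc / length(results)
  attr(out, "is_null_node") <- truth$sign == 0L
  out
}

#' Moving-average power curve over effect size
#'
#' Nodes are ordered by effect size; a moving window (width in d units, 50%
#' overlap between consecutive windows) averages the per-node power, and a
#' cubic spline through the windowed means gives a continuous estimate of
#' statistical power as a function of effect size.
#'
#' @param power Numeric per-node power values in `[0, 1]`.
#' @param d Numeric per-node effect sizes.
#' @param window Window width in d units (default 0.05).
#' @param use_abs Pool positive and negative effects by `|d|` (default TRUE).
#' @return An object of class `power_curve`: `centers`, `mean_power`,
#'   `window`, and `spline` (a function of d).
#' @export
power_curve <- function(power, d, window = 0.05, use_abs = TRUE) {
  stopifnot(length(power) == length(d))
  ok <- !is.na(power) & !is.na(d)
  power <- power[ok]; d <- if (use_abs) abs(d[ok]) else d[ok]
  if (length(d) < 10L) stop("at least 10 nodes are required", call. = FALSE)
  rng <- range(d)
  if (window > diff(rng))
    stop("window is wider than the observed effect range", call. = FALSE)
  centers <- seq(rng[1] + window / 2, rng[2] - window / 2, by = window / 2)
  if (length(centers) == 0L) centers <- mean(rng)
  mean_power <- vapply(centers, function(ct)
    mean(power[d >= ct - window / 2 & d <= ct + window / 2]), numeric(1))
  keep <- !is.nan(mean_power)
  centers <- centers[keep]; mean_power <- mean_power[keep]
  spl <- if (length(centers) >= 4L)
    stats::splinefun(centers, mean_power, method = "natural")
  else stats::approxfun(centers, mean_power, rule = 2)
  structure(list(centers = centers, mean_power = mean_power, window = window,
                 spline = function(x) spl(pmin(pmax(x, min(centers)), max(centers)))),
            class = "power_curve")
}

#' Bookmaker informedness of a signed prediction
#'
#' The inference outcome is viewed as a binary classifier of nodes into
#' significant and null. Truth-signal nodes (sign != 0) detected with the
#' correct sign are true positives, otherwise false negatives; truth-null
#' nodes detected (either sign) are false positives, otherwise true negatives.
#' Bookmaker informedness `BM = TPR + TNR - 1` is chance-corrected: 0 for a
#' random classifier, 1 for perfect classification, -1 for completely
#' incorrect classification.
#'
#' @param predicted Integer per-node predicted signs in `\{-1, 0, 1\}` (see
#'   [predicted_sign()]).
#' @param truth A [discretize_truth()] result.
#' @return An object of class `confusion_summary`: `TP`, `FP`, `TN`, `FN`,
#'   `TPR`, `TNR`, `BM`.
#' @export
informedness <- function(predicted, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  predicted <- as.integer(predicted)
  if (length(predicted) != length(truth$sign))
    stop("prediction and truth disagree on n_nodes", call. = FALSE)
  sig <- truth$sign != 0L
  TP <- sum(sig & predicted == truth$sign)
  FN <- sum(sig) - TP
  FP <- sum(!sig & predicted != 0L)
  TN <- sum(!sig) - FP
  TPR <- if (TP + FN > 0L) TP / (TP + FN) else NA_real_
  TNR <- if (TN + FP > 0L) {
    TN / (TN + FP)
  } else {
    # truth has no null class: the only possible false detections are
    # wrong-sign ones, so specificity is the fraction of detections that are
    # not sign errors (1 when nothing is detected or everything is correct,
    # 0 for a total sign inversion)
    wrong <- sum(sig & predicted != 0L & predicted != truth$sign)
    det <- sum(predicted != 0L)
    if (det > 0L) 1 - wrong / det else 1
  }
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 TPR = TPR, TNR = TNR, BM = TPR + TNR - 1),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("<confusion_summary> TP %d FP %d TN %d FN %d | TPR %.3f TNR %.3f BM %.3f\n",
              x$TP, x$FP, x$TN, x$FN, x$TPR, x$TNR, x$BM))
  invisible(x)
}

#' Informedness across binarization thresholds with normalized partial AUC
#'
#' The putative ground truth is re-discretized at each threshold of the grid
#' and mean bookmaker informedness (over repetitions) is recomputed. The
#' normalized partial area under the curve is the trapezoidal integral over
#' the grid divided by the grid span, so a constant curve at level b yields
#' exactly b. The default grid spans the range from the effect detectable at
#' uncorrected alpha = 0.05 to the effect surviving Bonferroni correction over
#' a dense brain map at N = 1000 (`|d|` from 0.06 to 0.16).
#'
#' @param results List of [run_inference()] results (or a list of per-node
#'   predicted-sign vectors).
#' @param truth_d Numeric per-node ground-truth effect sizes (Cohen's d).
#' @param thresholds Increasing grid of binarization thresholds.
#' @return List with `thresholds`, `BM` (mean informedness per threshold) and
#'   `partial_auc`.
#' @export
informedness_curve <- function(results, truth_d,
                               thresholds = seq(0.06, 0.16, length.out = 21)) {
  if (length(thresholds) == 0L || is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be a non-empty increasing grid", call. = FALSE)
  if (!is.list(results)) results <- list(results)
  preds <- lapply(results, function(r)
    if (inherits(r, "inference_result")) predicted_sign(r) else as.integer(r))
  bm <- vapply(thresholds, function(th) {
    truth <- discretize_truth(truth_d, th)
    mean(vapply(preds, function(p) informedness(p, truth)$BM, numeric(1)))
  }, numeric(1))
  pauc <- if (length(thresholds) > 1L) {
    span <- diff(range(thresholds))
    sum(diff(thresholds) * (utils::head(bm, -1) + utils::tail(bm, -1)) / 2) / span
  } else bm
  list(thresholds = thresholds, BM = bm, partial_auc = pauc)
}

#' Analytic power bounds for one-sample t tests
#'
#' Two-sided one-sample t-test power from the noncentral t distribution with
#' noncentrality `d * sqrt(n)`, at the uncorrected level `alpha` (sensitivity
#' upper bound) and after Bonferroni correction over `n_tests` comparisons
#' (lower bound). The minimal detectable effect for each bound is the smallest
#' d on a fine grid whose t statistic `d * sqrt(n)` reaches the two-sided
#' critical value.
#'
#' @param n Sample size (at least 2).
#' @param alpha Test level (default 0.05).
#' @param n_tests Number of comparisons for the Bonferroni bound (default
#'   91282, a dense whole-brain map).
#' @param d_grid Effect sizes at which to evaluate power.
#' @param d_step Grid resolution for the minimal detectable effect search.
#' @return List with `d_grid`, `power_uncorrected`, `power_bonferroni`,
#'   `min_detectable_uncorrected`, `min_detectable_bonferroni`.
#' @export
analytic_power_bounds <- function(n, alpha = 0.05, n_tests = 91282L,
                                  d_grid = seq(0, 1, by = 0.01),
                                  d_step = 1e-4) {
  if (!is.numeric(n) || n < 2) stop("n must be at least 2", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  if (n_tests < 1) stop("n_tests must be at least 1", call. = FALSE)
  df <- n - 1
  pw <- function(d, level) {
    crit <- stats::qt(1 - level / 2, df)
    ncp <- d * sqrt(n)
    out <- stats::pt(crit, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-crit, df, ncp = ncp)
    # central case computed exactly (the noncentral algorithm is ~1e-8 abs):
    # at d = 0 the two-sided power is the size of the test
    out[ncp == 0] <- level
    out
  }
  min_d <- function(level) {
    crit <- stats::qt(1 - level / 2, df)
    grid <- seq(0, 10, by = d_step)
    grid[which(grid * sqrt(n) >= crit)[1]]
  }
  list(d_grid = d_grid,
       power_uncorrected = pw(d_grid, alpha),
       power_bonferroni = pw(d_grid, alpha / n_tests),
       min_detectable_uncorrected = min_d(alpha),
       min_detectable_bonferroni = min_d(alpha / n_tests))
}
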