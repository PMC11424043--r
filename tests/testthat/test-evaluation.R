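# Minimal stand-in inference result carrying a per-node predicted sign:
# every detected node is its own significant cluster.
fake_result <- function(pred_sign) {
  pred_sign <- as.integer(pred_sign)
  det <- which(pred_sign != 0L)
  cluster_id <- integer(length(pred_sign))
  cluster_id[det] <- seq_along(det)
  structure(list(cluster_id = cluster_id,
                 cluster_sign = pred_sign[det],
                 extent = rep(1L, length(det)),
                 p_fwer = rep(0.001, length(det)),
                 significant = pred_sign != 0L,
                 alpha = 0.05),
            class = "inference_result")
}

test_that("truth discretization splits positive, negative and null nodes", {
  tr <- discretize_truth(c(0.2, -0.2, 0.05, -0.05, 0.1), threshold = 0.1)
  expect_identical(tr$sign, c(1L, -1L, 0L, 0L, 1L)) # boundary included
  expect_error(discretize_truth(1:3, 0), "positive")
})

test_that("sensitivity is the correct-sign detection proportion", {
  truth <- discretize_truth(c(1, -1, 1, 0), 0.5)
  results <- c(rep(list(fake_result(c(1L, -1L, -1L, 0L))), 250),
               rep(list(fake_result(c(1L, 0L, 1L, 1L))), 250))
  pw <- sensitivity_map(results, truth)
  expect_equal(pw[1], 1)            # detected correctly in all runs
  expect_equal(pw[2], 0.5)          # detected in half
  expect_equal(pw[3], 0.5)          # wrong sign counts as a miss
  expect_equal(pw[4], 0.5)          # null node: detection rate (FPR)
  expect_identical(attr(pw, "is_null_node"), c(FALSE, FALSE, FALSE, TRUE))
  expect_error(sensitivity_map(list(), truth), "non-empty")
})

test_that("power curve reproduces brute-force windowed means", {
  set.seed(12)
  d <- stats::runif(200, 0, 1)
  power <- stats::plogis(10 * (d - 0.4)) # smooth step in d
  pc <- power_curve(power, d, window = 0.1)
  # re-computation oracle at each center
  oracle <- vapply(pc$centers, function(ct)
    mean(power[abs(d - ct) <= 0.05]), numeric(1))
  expect_equal(pc$mean_power, oracle)
  # spline interpolates the windowed means
  expect_equal(pc$spline(pc$centers), pc$mean_power, tolerance = 1e-8)
  # flat power gives a flat curve
  flat <- power_curve(rep(1, 50), stats::runif(50), window = 0.2)
  expect_equal(flat$mean_power, rep(1, length(flat$centers)))
  expect_equal(flat$spline(c(0.3, 0.6)), c(1, 1), tolerance = 1e-9)
  # monotone through a step within modest spline overshoot
  step_power <- as.numeric(d > 0.5)
  ps <- power_curve(step_power, d, window = 0.1)
  at <- seq(min(ps$centers), max(ps$centers), length.out = 50)
  expect_true(all(ps$spline(at) > -0.15 & ps$spline(at) < 1.15))
  expect_lt(mean(ps$spline(at[at < 0.35])), 0.2)
  expect_gt(mean(ps$spline(at[at > 0.65])), 0.8)
  expect_error(power_curve(rep(1, 20), stats::runif(20, 0, 0.01), window = 0.5),
               "wider")
})

test_that("bookmaker informedness identities hold", {
  set.seed(13)
  truth_sign <- sample(c(-1L, 0L, 1L), 400, replace = TRUE)
  truth <- discretize_truth(truth_sign * 0.3, 0.2)
  expect_identical(truth$sign, truth_sign)
  # perfect prediction
  expect_equal(informedness(truth_sign, truth)$BM, 1)
  # total sign inversion on an all-signal truth
  all_sig <- discretize_truth(rep(c(0.5, -0.5), 50), 0.2)
  expect_equal(informedness(-all_sig$sign, all_sig)$BM, -1)
  # TPR 0.8, TNR 0.7 -> BM 0.5 by construction
  tr <- discretize_truth(c(rep(1, 10), rep(0, 10)), 0.5)
  pred <- c(rep(1L, 8), rep(-1L, 2), rep(1L, 3), rep(0L, 7))
  cs <- informedness(pred, tr)
  expect_equal(cs$TPR, 0.8)
  expect_equal(cs$TNR, 0.7)
  expect_equal(cs$BM, 0.5, tolerance = 1e-12)
  # BM = TPR + TNR - 1 against direct confusion counting, random instances
  for (seed in 1:10) {
    set.seed(seed)
    ts <- sample(c(-1L, 0L, 1L), 100, replace = TRUE)
    ps <- sample(c(-1L, 0L, 1L), 100, replace = TRUE)
    tr2 <- discretize_truth(ts * 0.4, 0.2)
    cs2 <- informedness(ps, tr2)
    TP <- sum(ts != 0 & ps == ts); FN <- sum(ts != 0) - TP
    FP <- sum(ts == 0 & ps != 0); TN <- sum(ts == 0) - FP
    expect_identical(c(cs2$TP, cs2$FP, cs2$TN, cs2$FN), c(TP, FP, TN, FN))
    expect_equal(cs2$BM, TP / (TP + FN) + TN / (TN + FP) - 1)
    expect_true(cs2$BM >= -1 && cs2$BM <= 1)
  }
})

test_that("BM is symmetric under joint label swap and ~0 under shuffling", {
  set.seed(14)
  ts <- sample(c(-1L, 0L, 1L), 300, replace = TRUE)
  ps <- sample(c(-1L, 0L, 1L), 300, replace = TRUE)
  tr <- discretize_truth(ts * 0.4, 0.2)
  tr_swapped <- discretize_truth(-ts * 0.4, 0.2)
  expect_equal(informedness(ps, tr)$BM, informedness(-ps, tr_swapped)$BM)
  # label-shuffled binary detection map against a single-contrast truth:
  # a random classifier has expected informedness zero
  truth_pos <- discretize_truth(ifelse(ts == 1L, 0.4, 0), 0.2)
  det <- as.integer(ts == 1L) # perfect detection map, then shuffled
  bm <- replicate(300, informedness(sample(det), truth_pos)$BM)
  expect_lt(abs(mean(bm)), 3 * stats::sd(bm) / sqrt(300))
})

test_that("informedness curve integrates to the normalized partial AUC", {
  # default grid spans the stated binarization range
  ic_default <- informedness_curve(list(fake_result(rep(0L, 4))),
                                   truth_d = c(1, -1, 0, 0.5))
  expect_equal(range(ic_default$thresholds), c(0.06, 0.16))
  # constant curve at level b integrates to exactly b
  truth_d <- rep(c(5, -5, 0, 0), 25)
  pred_perfect <- rep(c(1L, -1L, 0L, 0L), 25)
  ic1 <- informedness_curve(list(pred_perfect), truth_d)
  expect_equal(ic1$BM, rep(1, 21))
  expect_equal(ic1$partial_auc, 1)
  ic0 <- informedness_curve(list(rep(0L, 100)), truth_d)
  expect_equal(ic0$partial_auc, 0)
  # three-point trapezoid against hand computation
  thr <- c(0.1, 0.2, 0.4)
  d3 <- c(0.15, 0.3, 0.5, 0, 0)
  p3 <- c(0L, 1L, 1L, 0L, 1L)
  bm3 <- vapply(thr, function(th)
    informedness(p3, discretize_truth(d3, th))$BM, numeric(1))
  ic3 <- informedness_curve(list(p3), d3, thr)
  hand <- (0.1 * (bm3[1] + bm3[2]) / 2 + 0.2 * (bm3[2] + bm3[3]) / 2) / 0.3
  expect_equal(ic3$partial_auc, hand)
  expect_error(informedness_curve(list(p3), d3, numeric(0)), "increasing")
})

test_that("analytic power bounds follow the noncentral t distribution", {
  pb <- analytic_power_bounds(n = 1000, alpha = 0.05, n_tests = 91282)
  # size of the test at d = 0
  expect_equal(pb$power_uncorrected[pb$d_grid == 0], 0.05, tolerance = 1e-10)
  expect_equal(pb$power_bonferroni[pb$d_grid == 0], 0.05 / 91282,
               tolerance = 1e-12)
  # monotone non-decreasing in d, uncorrected dominates Bonferroni
  expect_true(all(diff(pb$power_uncorrected) >= 0))
  expect_true(all(diff(pb$power_bonferroni) >= 0))
  expect_true(all(pb$power_uncorrected >= pb$power_bonferroni))
  # minimal detectable effects: d sqrt(n) at the two-sided critical value,
  # up to the search grid resolution of 1e-4
  expect_lt(abs(pb$min_detectable_uncorrected -
                  stats::qt(0.975, 999) / sqrt(1000)), 1e-4)
  expect_lt(abs(pb$min_detectable_bonferroni -
                  stats::qt(1 - 0.05 / 91282 / 2, 999) / sqrt(1000)), 1e-4)
  expect_error(analytic_power_bounds(1), "at least 2")
  expect_error(analytic_power_bounds(10, alpha = 2), "alpha")
})
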