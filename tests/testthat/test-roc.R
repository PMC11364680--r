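test_that("perfect separation gives an operating point with sens = spec = 1", {
  curve <- build_roc(c(10, 90), c(FALSE, TRUE))
  best <- youden_threshold(curve)
  expect_equal(best$sensitivity, 1)
  expect_equal(best$specificity, 1)
  expect_equal(best$youden_j, 1)
  expect_equal(roc_auc(curve), 1)
})

test_that("an anti-concordant pair has best achievable J = 0 and AUC 0", {
  curve <- build_roc(c(90, 10), c(FALSE, TRUE))
  expect_equal(youden_threshold(curve)$youden_j, 0)
  expect_equal(roc_auc(curve), 0)
})

test_that("single-class input is rejected as degenerate", {
  expect_error(build_roc(c(1, 2, 3), c(TRUE, TRUE, TRUE)),
               class = "screentriage_degenerate_error")
})

test_that("per-threshold sens/spec equal an exhaustive recount", {
  set.seed(20)
  scores <- round(runif(20, 0, 100), 0)   # duplicates likely
  labels <- runif(20) < 0.4
  labels[1] <- TRUE; labels[2] <- FALSE
  curve <- build_roc(scores, labels)
  oracle <- brute_force_roc(scores, labels, curve$threshold)
  expect_equal(curve$sensitivity, oracle$sensitivity)
  expect_equal(curve$specificity, oracle$specificity)
  # monotone in threshold
  expect_true(all(diff(curve$sensitivity) <= 0))
  expect_true(all(diff(curve$specificity) >= 0))
  # endpoints: everything positive at the minimum, nothing above the max
  expect_equal(curve$sensitivity[1], 1)
  expect_equal(curve$specificity[1], 0)
  expect_equal(curve$sensitivity[nrow(curve)], 0)
  expect_equal(curve$specificity[nrow(curve)], 1)
})

test_that("trapezoid AUC equals the all-pairs concordance oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(10:200, 1)
    scores <- round(runif(n, 0, 100), sample(0:2, 1))  # with ties
    labels <- runif(n) < 0.5
    labels[1] <- TRUE; labels[2] <- FALSE
    auc <- roc_auc(build_roc(scores, labels))
    expect_equal(auc, concordance_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("Youden selection equals the brute-force grid maximum", {
  for (seed in 1:8) {
    set.seed(seed)
    scores <- round(runif(50, 0, 100), 1)
    labels <- scores / 100 + rnorm(50, sd = 0.4) > 0.5
    if (!any(labels) || all(labels)) next
    best <- youden_threshold(build_roc(scores, labels))
    oracle <- brute_force_youden(scores, labels)
    expect_equal(best$youden_j, oracle$j, tolerance = 1e-12)
    expect_lte(best$youden_j, oracle$j + 1e-12)
    expect_equal(best$youden_j,
                 best$sensitivity + best$specificity - 1)
  }
})

test_that("Youden ties break toward the lowest qualifying threshold", {
  # thresholds 2 and 4 both achieve J = 0.5; the lower one wins
  scores <- c(1, 2, 3, 4)
  labels <- c(FALSE, TRUE, FALSE, TRUE)
  best <- youden_threshold(build_roc(scores, labels))
  expect_equal(best$threshold, 2)
  expect_equal(best$n_tied, 2)
  expect_equal(best$tie_break, "lowest threshold")
})

test_that("AUC and Youden point agree with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(99)
  scores <- round(runif(300, 0, 100), 1)
  labels <- scores / 100 + rnorm(300, sd = 0.35) > 0.55
  curve <- build_roc(scores, labels)
  ref <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
  expect_equal(roc_auc(curve), as.numeric(pROC::auc(ref)),
               tolerance = 1e-10)
  best <- youden_threshold(curve)
  co <- pROC::coords(ref, "best", best.method = "youden",
                     ret = c("sensitivity", "specificity"))
  expect_equal(best$sensitivity + best$specificity,
               co$sensitivity[1] + co$specificity[1], tolerance = 1e-10)
})

test_that("the recovered threshold converges to the class-density crossing", {
  # piecewise-uniform class densities calibrated to the packaged category
  # masses cross exactly at the configured high cut (cancer density below
  # it is lower than non-cancer, above it higher), so the Youden threshold
  # should converge there as n grows
  nc <- calibrate_score_model(c(1928, 2616, 349) / 4893, 1, 30.44)
  ca <- calibrate_score_model(c(5, 24, 76) / 105, 1, 30.44)
  set.seed(17)
  n <- 100000
  scores <- c(sample_scores(nc, n), sample_scores(ca, n))
  labels <- rep(c(FALSE, TRUE), each = n)
  best <- youden_threshold(build_roc(scores, labels))
  expect_lt(abs(best$threshold - 30.44), 0.5)
})

test_that("bootstrap CI is ordered, covers the point, and is reproducible", {
  set.seed(5)
  scores <- runif(80, 0, 100)
  labels <- scores / 100 + rnorm(80, sd = 0.3) > 0.5
  ci1 <- auc_bootstrap_ci(scores, labels, n_boot = 200, seed = 1)
  ci2 <- auc_bootstrap_ci(scores, labels, n_boot = 200, seed = 1)
  expect_equal(unclass(ci1), unclass(ci2))
  expect_lte(ci1[1], attr(ci1, "point"))
  expect_gte(ci1[2], attr(ci1, "point"))
})

test_that("bootstrap CI of perfectly separated data is (1, 1)", {
  ci <- auc_bootstrap_ci(c(1, 2, 3, 80, 90, 95),
                         c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
                         n_boot = 100, seed = 3)
  expect_equal(as.numeric(ci), c(1, 1))
})

test_that("bootstrap CI covers a designed AUC in repeated experiments", {
  # classes drawn so the true concordance is ~0.9; the 95% interval should
  # cover it in most repetitions
  covered <- 0
  for (rep in 1:10) {
    set.seed(100 + rep)
    pos <- rnorm(60, mean = 1.82)
    neg <- rnorm(60, mean = 0)   # AUC = Phi(1.82/sqrt(2)) ~ 0.90
    scores <- c(pos, neg)
    labels <- rep(c(TRUE, FALSE), each = 60)
    ci <- auc_bootstrap_ci(scores, labels, n_boot = 400, seed = rep)
    if (ci[1] <= 0.9 && 0.9 <= ci[2]) covered <- covered + 1
  }
  expect_gte(covered, 8)
})
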