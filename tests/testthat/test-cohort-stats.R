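test_that("the ROC area equals the Mann-Whitney pairwise probability", {
  expect_equal(roc_auc(c(1, 2, 3, 2.5, 4),
                       c(FALSE, FALSE, FALSE, TRUE, TRUE))$auc, 5 / 6)
  # perfect separation and pure ties
  expect_equal(roc_auc(c(1, 2, 10, 11), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(c(5, 5, 5, 5), c(0, 0, 1, 1))$auc, 0.5)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("rank-based AUC matches brute-force counting on random tied cohorts", {
  set.seed(41)
  for (k in 1:50) {
    n <- sample(5:30, 1)
    scores <- round(stats::rnorm(n), 1)          # coarse grid forces ties
    labels <- c(TRUE, FALSE, stats::runif(n - 2) < 0.3)
    expect_equal(roc_auc(scores, labels)$auc, brute_auc(scores, labels))
  }
})

test_that("the AUC is invariant under strictly monotone score transforms", {
  set.seed(42)
  scores <- stats::rnorm(40)
  labels <- c(rep(TRUE, 12), rep(FALSE, 28))
  a0 <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, a0)
  expect_equal(roc_auc(3 * scores - 7, labels)$auc, a0)
  expect_equal(roc_auc(-scores, labels)$auc, 1 - a0)  # fixed orientation
})

test_that("DeLong variance and interval agree with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  scores <- c(stats::rnorm(20, 0), stats::rnorm(10, 1))
  labels <- c(rep(FALSE, 20), rep(TRUE, 10))
  ours <- roc_auc(scores, labels)
  ref <- pROC::roc(response = labels, predictor = scores,
                   direction = "<", levels = c(FALSE, TRUE), quiet = TRUE)
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)))
  expect_equal(ours$se, sqrt(as.numeric(pROC::var(ref, method = "delong"))),
               tolerance = 1e-10)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(ours$ci_low, max(0, ci[1]), tolerance = 1e-10)
  expect_equal(ours$ci_high, min(1, ci[3]), tolerance = 1e-10)
})

test_that("confidence bounds are clipped to the unit interval", {
  a <- roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(a$ci_high, 1)
  expect_gte(a$ci_low, 0)
})

test_that("the Youden threshold maximises sensitivity plus specificity", {
  y <- youden_threshold(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(y$threshold, 2.5)
  expect_equal(y$j, 1)
  expect_equal(c(y$tp, y$fn, y$fp, y$tn), c(2, 0, 0, 2))
})

test_that("no candidate cut-point ever beats the returned Youden threshold", {
  set.seed(43)
  for (k in 1:50) {
    n <- sample(6:30, 1)
    scores <- round(stats::rnorm(n), 1)
    labels <- c(TRUE, FALSE, stats::runif(n - 2) < 0.4)
    y <- youden_threshold(scores, labels)
    x <- scores[as.logical(labels)]; yy <- scores[!labels]
    grid <- sort(unique(c(scores - 1e-6, scores + 1e-6, scores)))
    j_all <- vapply(grid, function(t) mean(x > t) + mean(yy <= t) - 1,
                    numeric(1))
    expect_gte(y$j + 1e-12, max(j_all))
    # reported counts are consistent with the reported rates
    expect_equal(y$sens_pct, 100 * y$tp / (y$tp + y$fn))
    expect_equal(y$spec_pct, 100 * y$tn / (y$tn + y$fp))
  }
})

test_that("Youden ties break toward higher specificity", {
  # J = 0.5 at thresholds 1.5 (spec 50 %) and 3.5 (spec 100 %)
  y <- youden_threshold(c(1, 3, 2, 4), c(0, 0, 1, 1))
  expect_equal(y$threshold, 3.5)
  expect_equal(y$spec_pct, 100)
  expect_equal(y$sens_pct, 50)
})

test_that("identical scores give a degenerate threshold with a warning", {
  expect_warning(y <- youden_threshold(rep(2, 6), c(0, 0, 0, 1, 1, 1)),
                 "degenerate")
  expect_equal(y$j, 0)
})

test_that("confusion statistics handle zero denominators as missing", {
  cs <- confusion_stats(tp = 4, fn = 2, fp = 0, tn = 20)
  expect_equal(cs$rounded,
               list(sens_pct = 67, spec_pct = 100, ppv_pct = 100, npv_pct = 91))
  cs0 <- confusion_stats(tp = 0, fn = 0, fp = 0, tn = 5)
  expect_true(is.na(cs0$sens_pct))
  expect_true(is.na(cs0$ppv_pct))
  expect_equal(cs0$spec_pct, 100)
  expect_equal(confusion_stats(2, 1, 3, 5)$spec_pct, 62.5)
  expect_error(confusion_stats(1, 2, -1, 3), "non-negative")
})

test_that("summary-statistic and raw-vector t tests agree to machine precision", {
  set.seed(44)
  x <- stats::rnorm(20, 0, 5); y <- stats::rnorm(6, 4, 6)
  raw <- two_sample_t_pooled(x, y)
  summ <- two_sample_t_pooled(mean(x), stats::sd(x), length(x),
                              mean(y), stats::sd(y), length(y))
  expect_equal(raw$t, summ$t, tolerance = 1e-12)
  expect_equal(raw$p, summ$p, tolerance = 1e-12)
  ref <- stats::t.test(y, x, var.equal = TRUE)
  expect_equal(raw$p, ref$p.value, tolerance = 1e-12)
  expect_equal(abs(raw$t), abs(unname(ref$statistic)), tolerance = 1e-12)
  # identical groups: no effect
  same <- two_sample_t_pooled(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(two_sample_t_pooled(0, 0, 10, 1, 1, 10), "positive")
  expect_error(two_sample_t_pooled(0, 1, 1, 1, 1, 10), "n >= 2")
})

test_that("the paired t test handles degenerate differences explicitly", {
  b <- c(70, 75, 80, 85)
  expect_equal(paired_t(b, b), list(t = 0, df = 3, p = 1, mean_diff = 0))
  expect_warning(res <- paired_t(b, b + 5), "zero-variance")
  expect_equal(res$p, 0)
  expect_equal(res$mean_diff, 5)
  set.seed(45)
  before <- stats::rnorm(26, 80, 10)
  after <- before + stats::rnorm(26, 9, 5)
  res2 <- paired_t(before, after)
  ref <- stats::t.test(after, before, paired = TRUE)
  expect_equal(res2$p, ref$p.value)
  expect_lt(res2$p, 1e-5)
  expect_error(paired_t(1:3, 1:4), "length")
})

test_that("Spearman correlation is rank-based and handles constants", {
  x <- c(1, 5, 9, 20, 50)
  expect_equal(spearman_rho(x, x^3)$rho, 1)       # monotone transform
  expect_equal(spearman_rho(x, -sqrt(x))$rho, -1)
  r <- spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$rho, 0.6)
  expect_true(is.na(spearman_rho(c(1, 1, 1), c(1, 2, 3))$rho))
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("empirical AUC converges to the binormal closed form", {
  m0 <- -0.1; s0 <- 5.6; m1 <- 5.9; s1 <- 6.6
  theory <- stats::pnorm((m1 - m0) / sqrt(s0^2 + s1^2))
  set.seed(46)
  reps <- 400
  aucs <- vapply(seq_len(reps), function(i) {
    roc_auc(c(stats::rnorm(50, m0, s0), stats::rnorm(50, m1, s1)),
            rep(c(FALSE, TRUE), each = 50))$auc
  }, numeric(1))
  expect_equal(mean(aucs), theory, tolerance = 0.01)
})
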