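test_that("agreement statistics hit the exact-identity cases", {
  x <- c(0.4, 0.6, 0.8, 1.0, 1.2)
  a <- agreement_stats(x, x)
  expect_equal(a$pearson_r, 1); expect_equal(a$r2, 1); expect_equal(a$rmse, 0)
  expect_equal(agreement_stats(x, -x)$pearson_r, -1)
  expect_error(agreement_stats(x, rep(1, 5)), "zero variance")
  expect_error(agreement_stats(1:2, 1:2), "at least 3")
})

test_that("agreement statistics match longhand sum-of-squares formulas", {
  set.seed(50)
  p <- runif(50, 0.4, 1.2)
  m <- 0.95 * p + rnorm(50, 0, 0.05)
  a <- agreement_stats(p, m)
  # longhand Pearson
  r_long <- sum((p - mean(p)) * (m - mean(m))) /
    sqrt(sum((p - mean(p))^2) * sum((m - mean(m))^2))
  expect_equal(a$pearson_r, r_long, tolerance = 1e-12)
  # longhand OLS of measured on predicted
  b1 <- sum((p - mean(p)) * (m - mean(m))) / sum((p - mean(p))^2)
  b0 <- mean(m) - b1 * mean(p)
  res <- m - b0 - b1 * p
  expect_equal(a$rmse, sqrt(mean(res^2)), tolerance = 1e-12)
  expect_equal(a$r2, 1 - sum(res^2) / sum((m - mean(m))^2), tolerance = 1e-12)
  cal <- calibration(p, m)
  expect_equal(cal$slope, b1, tolerance = 1e-12)
  expect_equal(cal$citl, mean(m) - mean(p), tolerance = 1e-12)
})

test_that("calibration detects pure shifts with unit slope", {
  set.seed(2)
  m <- runif(30, 0.4, 1.2)
  p <- m + 0.05
  cal <- calibration(p, m)
  expect_equal(cal$slope, 1, tolerance = 1e-9)
  expect_equal(cal$citl, -0.05, tolerance = 1e-12)
})

test_that("Bland-Altman bias and SD follow the measured-minus-predicted convention", {
  x <- c(0.5, 0.7, 0.9)
  expect_equal(bland_altman(x, x)$bias, 0)
  ba <- bland_altman(x + 0.003, x)
  expect_equal(ba$bias, -0.003, tolerance = 1e-12)
  expect_equal(ba$sd, 0, tolerance = 1e-12)
  set.seed(4)
  p <- runif(40); m <- runif(40)
  ba <- bland_altman(p, m)
  d <- m - p
  expect_equal(ba$bias, sum(d) / 40, tolerance = 1e-12)
  expect_equal(ba$sd, sqrt(sum((d - mean(d))^2) / 39), tolerance = 1e-12)
})

test_that("calibration-in-the-large is identically the Bland-Altman bias", {
  set.seed(13)
  for (i in 1:20) {
    p <- runif(25, 0.4, 1.3)
    m <- p * runif(1, 0.8, 1.2) + rnorm(25, 0, 0.08)
    expect_equal(calibration(p, m)$citl, bland_altman(p, m)$bias,
                 tolerance = 1e-12)
  }
})

test_that("confusion metrics recompute published predictive values from counts", {
  hip_ppv <- confusion_metrics(tp = 524, fp = 549 - 524, tn = 0 + 3812, fn = 196)
  expect_equal(100 * hip_ppv$ppv$est, 100 * 524 / 549, tolerance = 1e-12)
  expect_equal(round_half_up(100 * hip_ppv$ppv$est, 1), 95.4)
  expect_equal(round_half_up(100 * hip_ppv$npv$est, 1), 95.1)
  sp <- confusion_metrics(tp = 4750, fp = 5030 - 4750, tn = 7418, fn = 7765 - 7418)
  expect_equal(round_half_up(100 * sp$ppv$est, 1), 94.4)
  expect_equal(round_half_up(100 * sp$npv$est, 1), 95.5)
})

test_that("confusion metrics satisfy the accuracy decomposition", {
  set.seed(31)
  for (i in 1:25) {
    cells <- rpois(4, 40) + 1
    cm <- confusion_metrics(cells[1], cells[2], cells[3], cells[4])
    P <- cells[1] + cells[4]; N <- cells[2] + cells[3]
    expect_equal(cm$sensitivity$est * P / (P + N) + cm$specificity$est * N / (P + N),
                 cm$accuracy$est, tolerance = 1e-12)
    expect_equal(cm$odds_ratio$est,
                 (cells[1] * cells[3]) / (cells[2] * cells[4]),
                 tolerance = 1e-12)
    expect_true(cm$odds_ratio$lo <= cm$odds_ratio$est)
    expect_true(cm$odds_ratio$hi >= cm$odds_ratio$est)
  }
})

test_that("degenerate confusion cells get the continuity correction", {
  cm <- confusion_metrics(10, 0, 10, 0)
  expect_equal(cm$accuracy$est, 1)
  expect_true(cm$odds_ratio$continuity_corrected)
  expect_equal(cm$odds_ratio$est, (10.5 * 10.5) / (0.5 * 0.5))
  expect_true(is.finite(cm$odds_ratio$hi))
  expect_error(confusion_metrics(1.5, 0, 1, 0), "nonnegative integers")
})

test_that("ROC/PR curves hit the separable and uninformative limits", {
  sep <- roc_pr_curves(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T))
  expect_equal(sep$auroc, 1); expect_equal(sep$auprc, 1)
  set.seed(17)
  n <- 4000
  ind <- roc_pr_curves(runif(n), runif(n) < 0.4)
  expect_lt(abs(ind$auroc - 0.5), 0.03)
})

test_that("AUROC equals brute-force concordance, AUPRC its step-sum oracle", {
  set.seed(23)
  for (i in 1:15) {
    n <- sample(8:30, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # forces ties
    labels <- runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    got <- roc_pr_curves(scores, labels)
    expect_equal(got$auroc, oracle_auroc(scores, labels), tolerance = 1e-12)
    expect_equal(got$auprc, oracle_auprc(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(29)
  scores <- rnorm(60)
  labels <- runif(60) < plogis(scores)
  if (any(labels) && !all(labels)) {
    got <- roc_pr_curves(scores, labels)$auroc
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(got, ref, tolerance = 1e-9)
  }
})

test_that("threshold search matches the exhaustive scan", {
  set.seed(37)
  for (i in 1:15) {
    n <- 40
    values <- round(runif(n, 0.3, 1.2), 2)
    labels <- values + rnorm(n, 0, 0.15) < 0.7
    if (!any(labels) || all(labels)) next
    for (type in c("ppv", "npv")) {
      got <- find_threshold(values, labels, target = 0.9, type = type)
      want <- oracle_threshold(values, labels, 0.9, type)
      if (is.null(want)) {
        expect_false(got$achieved)
      } else {
        expect_true(got$achieved)
        expect_equal(got$threshold, want$t)
        expect_equal(got$attained, want$val, tolerance = 1e-12)
        expect_equal(got$n_called, want$n)
      }
    }
  }
})

test_that("threshold search handles perfect separation and unattainable targets", {
  values <- c(0.4, 0.45, 0.5, 0.9, 0.95, 1.0)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  got <- find_threshold(values, labels, target = 1.0, type = "ppv")
  expect_true(got$achieved)
  expect_equal(got$attained, 1.0)
  expect_equal(got$n_called, 3L) # all positives captured at PPV 1
  # one mislabelled positive at the top makes NPV 1.0 unattainable
  labels2 <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE)
  got2 <- find_threshold(values, labels2, target = 1.0, type = "npv")
  expect_false(got2$achieved)
  expect_identical(got2$threshold, NA_real_)
})

test_that("metrics_report bundles agreement, discrimination, and confusion", {
  set.seed(41)
  truth <- runif(120, 0.4, 1.2)
  pred <- truth + rnorm(120, 0, 0.05)
  pos <- truth < 0.65
  rep <- metrics_report(pred, truth, positive = pos, pred_positive = pred < 0.65)
  expect_true(rep$pearson_r > 0.9)
  expect_true(rep$auroc > 0.9)
  expect_equal(rep$citl, rep$ba_bias, tolerance = 1e-12)
  expect_s3_class(rep$confusion, "confusion_metrics")
})
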