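test_that("confusion counts match an exhaustive per-pixel tally", {
  g <- matrix(c(1, 0, 1, 0, 1, 0, 1, 0, 1), 3)
  expect_identical(confusion(g, g)$FP + confusion(g, g)$FN, 0L)
  comp <- 1 - g
  cc <- confusion(comp, g)
  expect_identical(cc$TP + cc$TN, 0L)

  set.seed(13)
  for (i in 1:5) {
    p <- matrix(rbinom(9, 1, 0.5), 3)
    gt <- matrix(rbinom(9, 1, 0.5), 3)
    fov <- matrix(rbinom(9, 1, 0.8), 3)
    got <- confusion(p, gt, fov)
    ora <- confusion_oracle(p, gt, fov)
    expect_identical(got$TP, ora$TP)
    expect_identical(got$TN, ora$TN)
    expect_identical(got$FP, ora$FP)
    expect_identical(got$FN, ora$FN)
  }
  expect_error(confusion(matrix(0.5, 2, 2), matrix(1, 2, 2)), "binary")
})

test_that("classification metrics follow their defining ratios", {
  m <- seg_metrics(list(TP = 50, TN = 940, FP = 5, FN = 5))
  expect_equal(m$acc, 990 / 1000)
  expect_equal(m$sensitivity, 50 / 55)
  expect_equal(m$specificity, 940 / 945)
  expect_equal(m$precision, 50 / 55)
  expect_equal(m$f1, 50 / (50 + 5))

  perfect <- seg_metrics(list(TP = 10, TN = 90, FP = 0, FN = 0))
  expect_true(all(unlist(perfect) == 1))

  allbg <- seg_metrics(list(TP = 0, TN = 90, FP = 0, FN = 10))
  expect_equal(allbg$sensitivity, 0)
  expect_true(is.na(allbg$precision))   # zero denominator -> undefined

  # identity ACC = (SE*P + SP*N) / (P + N), and F1 between precision/recall
  set.seed(3)
  for (i in 1:10) {
    cc <- list(TP = rpois(1, 20) + 1, TN = rpois(1, 50) + 1,
               FP = rpois(1, 5) + 1, FN = rpois(1, 5) + 1)
    mm <- seg_metrics(cc)
    P <- cc$TP + cc$FN
    N <- cc$TN + cc$FP
    expect_equal(mm$acc, (mm$sensitivity * P + mm$specificity * N) / (P + N))
    expect_gte(mm$f1, min(mm$precision, mm$sensitivity) - 1e-12)
    expect_lte(mm$f1, max(mm$precision, mm$sensitivity) + 1e-12)
    # F1 = harmonic mean of precision and recall
    expect_equal(mm$f1, 2 * mm$precision * mm$sensitivity /
                   (mm$precision + mm$sensitivity))
  }
})

test_that("mean IoU agrees with the exhaustive per-class tally", {
  g <- matrix(rbinom(16, 1, 0.5), 4)
  expect_equal(miou(g, g), 1)
  expect_equal(miou(list(vessel = c(TP = 1, FP = 1, FN = 1),
                         background = c(TP = 9, FP = 1, FN = 0))),
               mean(c(1 / 3, 0.9)))
  # vessel IoU 0.5 and background IoU 0.9 average to 0.7
  expect_equal(miou(list(a = c(TP = 5, FP = 5, FN = 0),
                         b = c(TP = 9, FP = 0, FN = 1))), 0.7)

  set.seed(21)
  for (i in 1:10) {
    p <- matrix(rbinom(16, 1, 0.5), 4)
    gt <- matrix(rbinom(16, 1, 0.5), 4)
    expect_equal(miou(p, gt), miou_oracle(p, gt))
  }
  # empty-union classes are skipped, not scored zero
  expect_equal(miou(matrix(1, 2, 2), matrix(1, 2, 2)), 1)
})

test_that("trapezoidal AUC equals the pairwise concordance statistic", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  labs <- c(1, 0, 1, 0, 1)
  expect_equal(roc_auc(1 - labs, labs)$auc, 0)

  ten <- data.frame(s = c(0.9, 0.8, 0.8, 0.7, 0.6, 0.5, 0.5, 0.3, 0.2, 0.1),
                    y = c(1, 1, 0, 1, 0, 1, 0, 0, 1, 0))
  expect_equal(roc_auc(ten$s, ten$y)$auc, auc_concordance(ten$s, ten$y))

  set.seed(31)
  for (i in 1:100) {
    n <- sample(10:200, 1)
    s <- round(runif(n), sample(1:3, 1))       # coarse rounding forces ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    r <- roc_auc(s, y)
    expect_equal(r$auc, auc_concordance(s, y), tolerance = 1e-12)
    # curve contract: endpoints and monotone coordinates
    expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
    expect_equal(c(r$fpr[length(r$fpr)], r$tpr[length(r$tpr)]), c(1, 1))
    expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  }
  expect_error(roc_auc(runif(5), rep(1, 5)), "one class")
})

test_that("AUC agrees with an established implementation and ignores score scale", {
  set.seed(8)
  s <- runif(300)
  y <- rbinom(300, 1, plogis(4 * s - 2))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  ours <- roc_auc(s, y)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
  # invariance under strictly monotone transforms
  expect_equal(roc_auc(s^3, y)$auc, ours, tolerance = 1e-12)
  expect_equal(roc_auc(exp(5 * s), y)$auc, ours, tolerance = 1e-12)
  expect_equal(roc_auc(qnorm(s * 0.98 + 0.01), y)$auc, ours,
               tolerance = 1e-12)
})

test_that("binarisation uses the >= threshold convention", {
  expect_true(all(binarize(matrix(0.7, 3, 3), 0.5) == 1))
  expect_true(all(binarize(matrix(c(0, 0.2), 1), 0) == 1))
  expect_equal(binarize(matrix(c(0.3, 0.5, 0.7), 1), 0.5)[1, ],
               c(0, 1, 1))   # tie maps to 1
})

test_that("whole-image evaluation is exact for an oracle and sane for a coin flip", {
  fx <- synth_fixture(64, 4)
  plane <- gray_plane(fx$mask * 1, "unit")   # plane IS the ground truth
  oracle <- function(patches) patches
  rep <- evaluate_image(oracle, plane, fx$mask, fx$fov, patch_size = 16)
  expect_equal(rep$acc, 1)
  expect_equal(rep$sensitivity, 1)
  expect_equal(rep$specificity, 1)
  expect_equal(rep$f1, 1)
  expect_equal(rep$miou, 1)
  expect_equal(rep$auc, 1)

  half <- function(patches) patches * 0 + 0.5
  rep2 <- evaluate_image(half, plane, fx$mask, fx$fov, patch_size = 16)
  expect_equal(rep2$auc, 0.5)          # single tie group
  expect_equal(rep2$sensitivity, 1)    # 0.5 >= 0.5 -> everything positive
  expect_equal(rep2$specificity, 0)

  df <- metrics_csv(list(img1 = rep, img2 = rep2),
                    file.path(tempdir(), "metrics.csv"))
  expect_identical(nrow(df), 2L)
  expect_true(all(c("image_id", "ACC", "SE", "SP", "F1", "MIOU", "AUC") %in%
                    names(df)))
})
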