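test_that("confusion counts match a brute-force pixel loop", {
  truth <- matrix(FALSE, 20, 20); truth[4:13, 4:13] <- TRUE  # 100 lesion px
  cc <- confusion_counts(truth, truth)
  expect_identical(unlist(cc[c("TP", "TN", "FP", "FN")]),
                   c(TP = 100L, TN = 300L, FP = 0L, FN = 0L))

  comp <- confusion_counts(!truth, truth)
  expect_identical(comp$TP, 0L); expect_identical(comp$TN, 0L)

  set.seed(31)
  p <- matrix(runif(256) > 0.5, 16, 16)
  t2 <- matrix(runif(256) > 0.5, 16, 16)
  ref <- brute_confusion(p, t2)
  got <- confusion_counts(p, t2)
  for (k in c("TP", "TN", "FP", "FN")) expect_identical(got[[k]], ref[[k]])

  v <- matrix(runif(256) > 0.3, 16, 16)
  gv <- confusion_counts(p, t2, v)
  expect_identical(gv$TP + gv$TN + gv$FP + gv$FN, sum(v))
  expect_identical(gv$TP, sum(p & t2 & v))
  expect_identical(gv$FP, sum(p & !t2 & v))

  expect_error(confusion_counts(p, matrix(TRUE, 8, 8)), "shape")
})

test_that("metric formulas give the hand-computed values", {
  perfect <- structure(list(TP = 100L, TN = 300L, FP = 0L, FN = 0L),
                       class = "confusion_counts")
  m <- seg_metrics(perfect)
  for (k in c("accuracy", "sensitivity", "specificity", "jaccard",
              "dice", "f_measure"))
    expect_equal(m[[k]], 1)

  half <- structure(list(TP = 50L, TN = 300L, FP = 50L, FN = 0L),
                    class = "confusion_counts")
  m2 <- seg_metrics(half)
  expect_equal(m2$jaccard, 0.5)
  expect_equal(m2$dice, 2 / 3)
  expect_equal(m2$sensitivity, 1)
  expect_equal(m2$specificity, 300 / 350, tolerance = 1e-3)

  # empty truth and prediction: sensitivity undefined, flagged
  none <- structure(list(TP = 0L, TN = 400L, FP = 0L, FN = 0L),
                    class = "confusion_counts")
  m3 <- seg_metrics(none)
  expect_true(is.nan(m3$sensitivity))
  expect_true("sensitivity" %in% m3$undefined)

  zero <- structure(list(TP = 0L, TN = 0L, FP = 0L, FN = 0L),
                    class = "confusion_counts")
  expect_error(seg_metrics(zero), "zero")
})

test_that("Dice/Jaccard/F identities hold on random mask pairs", {
  for (s in 1:50) {
    set.seed(s)
    p <- matrix(runif(400) > runif(1, 0.3, 0.7), 20, 20)
    t2 <- matrix(runif(400) > runif(1, 0.3, 0.7), 20, 20)
    m <- seg_metrics(confusion_counts(p, t2))
    if (!is.nan(m$jaccard) && !is.nan(m$dice)) {
      expect_equal(m$dice, 2 * m$jaccard / (1 + m$jaccard), tolerance = 1e-12)
      if (!is.nan(m$f_measure))
        expect_equal(m$f_measure, m$dice, tolerance = 1e-12)
    }
  }
})

test_that("Hausdorff distance is exact, symmetric and translation-invariant", {
  d0 <- hausdorff_distance(disk_mask(40, r = 10), disk_mask(40, r = 10))
  expect_identical(d0$raw, 0)

  a <- matrix(FALSE, 100, 100); a[1, 1] <- TRUE
  b <- matrix(FALSE, 100, 100); b[4, 5] <- TRUE   # offset (3, 4)
  hd <- hausdorff_distance(a, b)
  expect_equal(hd$raw, 5)
  expect_equal(hd$norm, 5 / sqrt(2 * 100^2))

  m1 <- rand_blob(40, seed = 3); m2 <- rand_blob(40, seed = 9)
  h12 <- hausdorff_distance(m1, m2); h21 <- hausdorff_distance(m2, m1)
  expect_identical(h12$raw, h21$raw)

  # shifting both masks together changes nothing
  sh <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  hs <- hausdorff_distance(sh(m1, 3, 5), sh(m2, 3, 5))
  expect_equal(hs$raw, h12$raw)

  # triangle inequality on a triple
  m3 <- rand_blob(40, seed = 12)
  h13 <- hausdorff_distance(m1, m3)$raw
  h23 <- hausdorff_distance(m2, m3)$raw
  expect_lte(h13, h12$raw + h23 + 1e-9)

  expect_error(hausdorff_distance(matrix(FALSE, 40, 40), m1), "non-empty")
})

test_that("area agreement reproduces closed-form OLS and Bland-Altman", {
  a <- c(10, 20, 30, 40)
  r1 <- area_agreement(a, a)
  expect_equal(r1$mean_diff, 0); expect_equal(r1$sd_diff, 0)
  expect_equal(r1$slope, 1); expect_equal(r1$r, 1)

  r2 <- area_agreement(a + 10, a)
  expect_equal(r2$mean_diff, 10)
  expect_equal(r2$slope, 1); expect_equal(r2$intercept, 10)

  set.seed(17)
  truth <- runif(50, 500, 5000)
  pred <- 1.05 * truth - 30 + rnorm(50, 0, 40)
  fit <- area_agreement(pred, truth)
  # normal-equations oracle
  sxy <- sum((truth - mean(truth)) * (pred - mean(pred)))
  sxx <- sum((truth - mean(truth))^2)
  slope <- sxy / sxx
  expect_equal(fit$slope, slope, tolerance = 1e-10)
  expect_equal(fit$intercept, mean(pred) - slope * mean(truth),
               tolerance = 1e-10)
  expect_equal(fit$r, sxy / sqrt(sxx * sum((pred - mean(pred))^2)),
               tolerance = 1e-10)
  d <- pred - truth
  expect_equal(fit$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-10)
  expect_true(fit$loa_low <= fit$mean_diff && fit$mean_diff <= fit$loa_high)

  r3 <- area_agreement(c(1, 2, 3), c(5, 5, 5))
  expect_false(r3$regression_defined)
  expect_true(is.nan(r3$slope))
})
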