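test_that("ROC curves handle perfect separation, ties and orientation", {
  # perfect separation passes through the (0, 1) corner
  curve <- roc_points(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE), "higher")
  expect_true(any(curve$fpr == 0 & curve$tpr == 1))
  expect_equal(curve[1, c("tpr", "fpr")], data.frame(tpr = 0, fpr = 0))
  expect_equal(curve[nrow(curve), c("tpr", "fpr")],
               data.frame(tpr = 1, fpr = 1), ignore_attr = TRUE)

  # tied values collapse to one threshold: a diagonal tie segment
  tied <- roc_points(c(1, 2, 2, 3), c(FALSE, TRUE, FALSE, TRUE), "higher")
  expect_equal(tied$tpr, c(0, 0.5, 1, 1))
  expect_equal(tied$fpr, c(0, 0, 0.5, 1))

  # flipping orientation rotates the curve by 180 degrees
  set.seed(7)
  inst <- random_instance(40)
  a <- roc_points(inst$values, inst$events, "higher")
  b <- roc_points(inst$values, inst$events, "lower")
  expect_equal(sort(1 - b$tpr), sort(a$tpr))
  expect_equal(sort(1 - b$fpr), sort(a$fpr))

  expect_error(roc_points(1:4, rep(TRUE, 4), "higher"), "non-event")
  expect_error(roc_points(1:4, rep(FALSE, 4), "higher"), "event")
  expect_error(roc_points(1:3, c(TRUE, FALSE), "higher"), "length")
})

test_that("curves are monotone staircases whose area equals the concordance AUC", {
  set.seed(21)
  for (i in 1:100) {
    inst <- random_instance(sample(10:80, 1))
    orientation <- sample(c("higher", "lower"), 1)
    curve <- roc_points(inst$values, inst$events, orientation)
    expect_true(all(diff(curve$tpr) >= 0))
    expect_true(all(diff(curve$fpr) >= 0))
    expect_equal(trapezoid_area(curve),
                 auc_concordance(inst$values, inst$events, orientation))
  }
})

test_that("AUC equals brute-force pair counting and flips with orientation", {
  expect_equal(auc_concordance(1:4, c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(auc_concordance(1:4, c(TRUE, TRUE, FALSE, FALSE)), 0)
  # ties count one half: pairs (1,2)=1, (2,2)=.5, (2,3)=1, (3,2)=1 -> 0.875
  expect_equal(auc_concordance(c(1, 2, 2, 3), c(FALSE, TRUE, FALSE, TRUE)),
               0.875)
  set.seed(33)
  for (i in 1:100) {
    inst <- random_instance(sample(5:60, 1))
    auc <- auc_concordance(inst$values, inst$events)
    expect_equal(auc, auc_oracle(inst$values, inst$events))
    expect_equal(auc_concordance(inst$values, inst$events, "lower"), 1 - auc)
  }
})

test_that("DeLong standard errors are sane and match a bootstrap at small n", {
  # perfectly separated data: zero-variance placements
  perfect <- auc_with_ci(c(1:10, 21:40), rep(c(FALSE, TRUE), c(10, 20)))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$se, 0)

  set.seed(55)
  values <- c(rnorm(25, 1), rnorm(15))
  events <- rep(c(TRUE, FALSE), c(25, 15))
  res <- auc_with_ci(values, events)
  expect_true(res$ci_low <= res$auc && res$auc <= res$ci_high)

  boot <- replicate(2000, {
    i <- sample(which(events), replace = TRUE)
    j <- sample(which(!events), replace = TRUE)
    auc_concordance(values[c(i, j)], events[c(i, j)])
  })
  expect_equal(res$se, sd(boot), tolerance = 0.1)
})

test_that("DeLong AUC inference agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  values <- c(rnorm(40, 0.8), rnorm(60))
  events <- rep(c(TRUE, FALSE), c(40, 60))
  ours <- auc_with_ci(values, events)
  theirs <- pROC::roc(response = events, predictor = values,
                      direction = "<", levels = c(FALSE, TRUE), quiet = TRUE)
  ci <- pROC::ci.auc(theirs, method = "delong")
  expect_equal(ours$auc, as.numeric(pROC::auc(theirs)))
  expect_equal(ours$ci_low, ci[1], tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(ours$ci_high, ci[3], tolerance = 1e-6, ignore_attr = TRUE)

  other <- values + rnorm(100, sd = 1.5)
  test <- delong_paired_test(values, other, events)
  ref <- pROC::roc.test(theirs,
                        pROC::roc(response = events, predictor = other,
                                  direction = "<", levels = c(FALSE, TRUE),
                                  quiet = TRUE),
                        method = "delong", paired = TRUE)
  expect_equal(test$p, ref$p.value, tolerance = 1e-6)
  expect_equal(test$z, unname(ref$statistic), tolerance = 1e-6)
})

test_that("the paired test degenerates gracefully and is antisymmetric", {
  set.seed(91)
  inst <- random_instance(50)
  other <- inst$values + rnorm(50)

  same <- delong_paired_test(inst$values, inst$values, inst$events)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  ab <- delong_paired_test(inst$values, other, inst$events)
  ba <- delong_paired_test(other, inst$values, inst$events)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  expect_true(ab$p > 0 && ab$p <= 1)

  # mixed orientations: comparing a score with its own flipped copy
  flip <- delong_paired_test(inst$values, -inst$values, inst$events,
                             "higher", "lower")
  expect_equal(flip$p, 1)
  expect_equal(flip$auc_a, flip$auc_b)
})
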