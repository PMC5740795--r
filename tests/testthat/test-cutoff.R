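test_that("confusion metrics at a fixed cutoff match a hand-built table", {
  # TP 3, FN 1, FP 2, TN 4
  values <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
  events <- rep(c(TRUE, FALSE), c(4, 6))
  m <- cutoff_metrics(values, events, cutoff = 0.5, orientation = "higher")
  expect_equal(m$tp, 3); expect_equal(m$fn, 1)
  expect_equal(m$fp, 2); expect_equal(m$tn, 4)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 2 / 3)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$ppv, 0.6)
  expect_equal(m$npv, 0.8)
  expect_equal(m$youden_j, 0.75 + 2 / 3 - 1)
})

test_that("degenerate cutoffs give the predict-all margins and NaN predictive values", {
  values <- c(1, 2, 3, 4)
  events <- c(FALSE, FALSE, TRUE, TRUE)
  expect_warning(below <- cutoff_metrics(values, events, 0, "higher"),
                 "NPV undefined")
  expect_equal(below$sensitivity, 1)
  expect_equal(below$specificity, 0)
  expect_warning(above <- cutoff_metrics(values, events, 5, "higher"),
                 "PPV undefined")
  expect_true(is.nan(above$ppv))
  expect_equal(above$npv, 0.5)

  perfect <- cutoff_metrics(values, events, 2.5, "higher")
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "accuracy",
                                "ppv", "npv")]),
               c(sensitivity = 1, specificity = 1, accuracy = 1, ppv = 1, npv = 1))

  # lower orientation classifies strictly below the cutoff
  low <- cutoff_metrics(values, !events, 2.5, "lower")
  expect_equal(low$sensitivity, 1)
  expect_equal(low$specificity, 1)
})

test_that("the Youden scan finds the perfect split and handles no-discrimination", {
  r <- youden_optimal_cutoff(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$youden_j, 1)
  expect_true(r$cutoff > 2 && r$cutoff < 3)

  suppressWarnings(flat <- youden_optimal_cutoff(rep(5, 8),
                                                 rep(c(TRUE, FALSE), 4)))
  expect_equal(flat$youden_j, 0)

  # ties in J resolve toward the higher-specificity cutoff
  values <- c(1, 2, 3, 4, 5, 6)
  events <- c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  r2 <- youden_optimal_cutoff(values, events)
  direct <- sapply(c(1.5, 3.5, 5.5), function(cut) {
    m <- cutoff_metrics(values, events, cut)
    c(m$youden_j, m$specificity)
  })
  expect_equal(r2$youden_j, max(direct[1, ]))
  expect_equal(r2$specificity,
               max(direct[2, direct[1, ] == max(direct[1, ])]))
})

test_that("the optimal J equals exhaustive search on random instances", {
  set.seed(202)
  for (i in 1:200) {
    inst <- random_instance(sample(8:50, 1))
    orientation <- sample(c("higher", "lower"), 1)
    r <- suppressWarnings(
      youden_optimal_cutoff(inst$values, inst$events, orientation))
    expect_equal(r$youden_j,
                 youden_oracle(inst$values, inst$events, orientation))
    # the report row reproduces itself at its own cutoff
    again <- suppressWarnings(
      cutoff_metrics(inst$values, inst$events, r$cutoff, orientation))
    expect_equal(again$youden_j, r$youden_j)
  }
})

test_that("rate identities reproduce empirical confusion metrics exactly", {
  set.seed(303)
  for (i in 1:50) {
    inst <- random_instance(40)
    r <- suppressWarnings(youden_optimal_cutoff(inst$values, inst$events))
    prev <- mean(inst$events)
    mr <- suppressWarnings(
      metrics_from_rates(r$sensitivity, r$specificity, prev))
    expect_equal(mr$accuracy, r$accuracy)
    if (!is.nan(r$ppv)) expect_equal(mr$ppv, r$ppv)
    if (!is.nan(r$npv)) expect_equal(mr$npv, r$npv)
  }
  perfect <- metrics_from_rates(1, 1, 0.3)
  expect_equal(unlist(perfect), c(accuracy = 1, ppv = 1, npv = 1))
  expect_warning(und <- metrics_from_rates(0, 1, 0.5), "PPV undefined")
  expect_true(is.nan(und$ppv))
  expect_error(metrics_from_rates(1.2, 0.5, 0.1), "\\[0, 1\\]")
})
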