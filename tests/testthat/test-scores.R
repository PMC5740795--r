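test_that("physiology categorisation follows the published bands", {
  # respiratory rate (breaths/min)
  expect_identical(score_respiratory_rate(c(20, 10, 29, 35, 30, 9, 6, 5, 1, 0)),
                   c(4L, 4L, 4L, 3L, 3L, 2L, 2L, 1L, 1L, 0L))
  # systolic blood pressure (mmHg)
  expect_identical(score_systolic_bp(c(120, 90, 89, 76, 75, 60, 50, 49, 1, 0)),
                   c(4L, 4L, 3L, 3L, 2L, 2L, 2L, 1L, 1L, 0L))
  # Glasgow Coma Scale
  expect_identical(score_gcs(c(15, 13, 12, 9, 8, 7, 6, 5, 4, 3)),
                   c(4L, 4L, 3L, 3L, 2L, 2L, 2L, 1L, 1L, 0L))
  expect_error(score_respiratory_rate(-1), "non-negative")
  expect_error(score_systolic_bp(-5), "non-negative")
  expect_error(score_gcs(17), "\\[3, 15\\]")
  expect_error(score_gcs(2), "\\[3, 15\\]")
})

test_that("RTS is the published weighted sum with range [0, 7.8408]", {
  expect_equal(compute_rts(20, 120, 15), 7.8408)
  expect_equal(compute_rts(0, 0, 3), 0)
  expect_equal(compute_rts(20, 60, 7), 4.5020)  # 4*0.2908 + 2*0.7326 + 2*0.9368
  expect_equal(4 * (0.2908 + 0.7326 + 0.9368), 7.8408)

  # monotone increasing in each category score (raw values ordered by band)
  rr_by_cat <- c(0, 3, 8, 35, 20)      # category scores 0..4
  sbp_by_cat <- c(0, 20, 60, 80, 120)
  gcs_by_cat <- c(3, 4, 7, 10, 15)
  expect_equal(score_respiratory_rate(rr_by_cat), 0:4)
  expect_equal(score_systolic_bp(sbp_by_cat), 0:4)
  expect_equal(score_gcs(gcs_by_cat), 0:4)
  for (sbp in sbp_by_cat) for (gcs in gcs_by_cat) {
    expect_true(all(diff(compute_rts(rr_by_cat, sbp, gcs)) > 0))
    expect_true(all(diff(compute_rts(20, sbp, gcs_by_cat)) > 0))
  }
  for (rr in rr_by_cat) for (gcs in gcs_by_cat) {
    expect_true(all(diff(compute_rts(rr, sbp_by_cat, gcs)) > 0))
  }
})

test_that("ISS and NISS match published examples and the AIS-6 convention", {
  expect_equal(compute_iss(c("head_neck", "chest"), c(5, 3)), 34)
  expect_equal(compute_iss(character(0), integer(0)), 0L)
  expect_equal(compute_iss(c("abdomen", "chest"), c(6, 2)), 75L)
  expect_equal(compute_niss(c(5, 4, 3)), 50)
  expect_equal(compute_niss(1), 1)
  expect_equal(compute_niss(c(5, 4, 3, 2)), 50)
  expect_equal(compute_niss(c(6, 1)), 75L)
  # same-region severities all count for NISS but not ISS
  expect_equal(compute_iss(c("head_neck", "head_neck", "chest"), c(5, 4, 3)), 34)
  expect_equal(compute_niss(c(5, 4, 3)), 50)
  expect_error(compute_niss(c(0, 3)), "1-6")
  expect_error(compute_niss(7), "1-6")
})

test_that("ISS and NISS agree with subset-enumeration oracles and NISS >= ISS", {
  set.seed(101)
  for (i in 1:200) {
    inj <- random_injury_list()
    iss <- compute_iss(inj$region, inj$severity)
    niss <- compute_niss(inj$severity)
    expect_equal(iss, iss_oracle(inj$region, inj$severity))
    expect_equal(niss, niss_oracle(inj$severity))
    expect_gte(niss, iss)
    expect_true(iss >= 0 && niss <= 75)
  }
})

test_that("the age index splits at 55 and is 0 below 15", {
  expect_identical(age_index(c(36, 54, 55, 80, 14, 15)),
                   c(0L, 0L, 1L, 1L, 0L, 0L))
  expect_error(age_index(-1), "non-negative")
})

test_that("MTOS-TRISS reproduces hand-computed survival probabilities", {
  # blunt: b = -0.4499 + 0.8085 * 7.8408 = 5.8894
  expect_equal(ps_mtos_triss(7.8408, 0, 36, "blunt"), 0.99724, tolerance = 1e-4)
  # blunt worst case: b = -0.4499 - 0.0835*75 - 1.7430 = -8.4554
  expect_equal(ps_mtos_triss(0, 75, 60, "blunt"), 2.12e-4, tolerance = 1e-2)
  # penetrating: b = -2.5355 + 0.9934 * 7.8408 = 5.2535
  expect_equal(ps_mtos_triss(7.8408, 0, 36, "penetrating"), 0.99480,
               tolerance = 1e-4)
  expect_error(ps_mtos_triss(7, 9, 36, "ballistic"), "mechanism")
})

test_that("NTrD-TRISS reproduces hand-computed survival probabilities", {
  # b = -3.6167 + 4*(0.2671 + 0.8206 + 0.6071) = 3.1625
  expect_equal(ps_ntrd_triss(0, 36, 4, 4, 4), 0.9594, tolerance = 1e-4)
  # b = -3.6167 - 0.016*75 - 1.1358 = -5.9525
  expect_equal(ps_ntrd_triss(75, 60, 0, 0, 0), 2.59e-3, tolerance = 1e-2)
})

test_that("coefficient-set selection maps blast and children to the blunt set", {
  expect_equal(mtos_coefficient_set(36, "blunt"), "blunt")
  expect_equal(mtos_coefficient_set(36, "penetrating"), "penetrating")
  expect_equal(mtos_coefficient_set(36, "blast"), "blunt")
  expect_equal(mtos_coefficient_set(14, "penetrating"), "blunt")
  expect_equal(mtos_coefficient_set(15, "penetrating"), "penetrating")
})

test_that("survival probabilities are proper and monotone in severity", {
  rts_grid <- seq(0, 7.8408, length.out = 9)
  iss_grid <- seq(0, 75, by = 15)
  for (mech in c("blunt", "penetrating")) {
    # strictly decreasing in ISS, strictly increasing in RTS
    expect_true(all(diff(ps_mtos_triss(4.0, iss_grid, 36, mech)) < 0))
    expect_true(all(diff(ps_mtos_triss(rts_grid, 20, 36, mech)) > 0))
    # AgeIndex 1 strictly lowers Ps
    expect_lt(ps_mtos_triss(4.0, 20, 60, mech), ps_mtos_triss(4.0, 20, 40, mech))
  }
  expect_true(all(diff(ps_ntrd_triss(0:75, 36, 2, 2, 2)) < 0))
  expect_lt(ps_ntrd_triss(20, 60, 2, 2, 2), ps_ntrd_triss(20, 40, 2, 2, 2))
  # proper probabilities at the extremes
  ps <- c(ps_mtos_triss(c(0, 7.8408), c(75, 0), c(99, 14), "blunt"),
          ps_ntrd_triss(c(0, 75), c(14, 99), c(4, 0), c(4, 0), c(4, 0)))
  expect_true(all(ps > 0 & ps < 1))
})

test_that("the cohort score panel is self-consistent", {
  rec <- make_record(age = 36, injuries = "head_neck:3;chest:4")
  p <- score_panel(rec)
  expect_equal(p$iss, 25L)   # 16 + 9, two distinct regions
  expect_equal(p$niss, 25L)
  expect_equal(p$rts, 7.8408)

  clean <- make_record(injuries = "")
  p0 <- score_panel(clean)
  expect_equal(p0$iss, 0L)
  expect_equal(p0$niss, 0L)
  expect_equal(p0$rts, 7.8408)

  scored <- score_cohort(toy_cohort())
  expect_true(all(scored$niss >= scored$iss))
  expect_equal(scored$ps_mtos,
               ps_mtos_triss(scored$rts, scored$iss, scored$age, scored$mechanism))
  expect_equal(scored$ps_ntrd,
               ps_ntrd_triss(scored$niss, scored$age, scored$rr_score,
                             scored$sbp_score, scored$gcs_score))
  expect_equal(scored$rts, compute_rts(scored$rr, scored$sbp, scored$gcs))
})
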