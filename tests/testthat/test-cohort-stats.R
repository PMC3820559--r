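test_that("Woolf odds ratios reproduce the published 2x2 results", {
  # age under 50, suspected vs non-suspected
  age <- odds_ratio_woolf(contingency_2x2(7, 20, 16, 130))
  expect_equal(round_half_up(age$odds_ratio, 2), 2.84)
  expect_equal(age$ci_low, 1.04, tolerance = 0.005)
  expect_equal(age$ci_high, 7.77, tolerance = 0.001)
  # synchronous ovarian cancer
  ov <- odds_ratio_woolf(contingency_2x2(5, 22, 22, 103))
  expect_equal(round_half_up(ov$odds_ratio, 2), 1.06)
  expect_equal(ov$ci_low, 0.36, tolerance = 0.01)
  expect_equal(ov$ci_high, 3.11, tolerance = 0.01)
  # symmetry: balanced tables give OR 1
  for (k in c(1, 3, 10, 50)) {
    r <- odds_ratio_woolf(contingency_2x2(k, k, k, k))
    expect_equal(r$odds_ratio, 1)
    expect_true(r$ci_low < 1 && r$ci_high > 1)
  }
})

test_that("Woolf intervals behave under row swap, scaling and zero cells", {
  set.seed(31)
  for (i in 1:20) {
    t <- random_table() + 1  # avoid zeros
    r1 <- odds_ratio_woolf(contingency_2x2(t[1], t[2], t[3], t[4]))
    r2 <- odds_ratio_woolf(contingency_2x2(t[3], t[4], t[1], t[2]))
    expect_equal(r1$odds_ratio * r2$odds_ratio, 1)
    expect_equal(r1$ci_low * r2$ci_high, 1, tolerance = 1e-10)
    # CI width (on the log scale) shrinks as counts scale up
    widths <- vapply(c(1, 2, 5, 10), function(f) {
      r <- odds_ratio_woolf(contingency_2x2(f * t[1], f * t[2],
                                            f * t[3], f * t[4]))
      log(r$ci_high) - log(r$ci_low)
    }, numeric(1))
    expect_true(all(diff(widths) < 0))
  }
  expect_error(odds_ratio_woolf(contingency_2x2(1, 0, 3, 4)), "zero cell")
  expect_error(odds_ratio_woolf(contingency_2x2(1, 0, 3, 4)), "b")
  corrected <- odds_ratio_woolf(contingency_2x2(1, 0, 3, 4),
                                zero_cell = "haldane")
  expect_true(corrected$corrected)
  expect_true(is.finite(corrected$ci_high))
})

test_that("exact conditional odds-ratio machinery matches fisher.test", {
  r <- odds_ratio_exact(contingency_2x2(5, 3, 1, 10))
  expect_equal(r$odds_ratio, 50 / 3)  # cross-product point estimate
  ft <- stats::fisher.test(matrix(c(5, 1, 3, 10), 2))
  expect_equal(r$or_cmle, unname(ft$estimate), tolerance = 1e-4)
  expect_equal(r$ci_low, ft$conf.int[1], tolerance = 5e-3)
  expect_equal(r$ci_high, ft$conf.int[2], tolerance = 0.02)
  expect_equal(r$p, ft$p.value, tolerance = 1e-6)
  # exact CI is wider than Woolf on this sparse table
  w <- odds_ratio_woolf(contingency_2x2(5, 3, 1, 10))
  expect_lt(r$ci_low, w$ci_low)
  expect_gt(r$ci_high, w$ci_high)
  # symmetric table
  expect_equal(odds_ratio_exact(contingency_2x2(4, 4, 4, 4))$odds_ratio, 1)
  # randomized agreement with fisher.test across small tables
  set.seed(41)
  for (i in 1:25) {
    t <- random_table()
    mine <- odds_ratio_exact(t)
    ft <- stats::fisher.test(matrix(c(t[1], t[3], t[2], t[4]), 2))
    expect_equal(mine$ci_low, ft$conf.int[1], tolerance = 5e-3,
                 label = paste(t, collapse = ","))
    expect_equal(mine$ci_high, ft$conf.int[2], tolerance = 0.02,
                 label = paste(t, collapse = ","))
    expect_equal(mine$p, ft$p.value, tolerance = 1e-6,
                 label = paste(t, collapse = ","))
    if (is.finite(ft$estimate) && ft$estimate > 0) {
      expect_equal(mine$or_cmle, unname(ft$estimate), tolerance = 1e-3)
    }
  }
  # zero cell: uncorrected gives an infinite bound, Haldane keeps it finite
  plain <- odds_ratio_exact(contingency_2x2(1, 0, 0, 1))
  expect_identical(plain$ci_high, Inf)
  corr <- odds_ratio_exact(contingency_2x2(1, 0, 0, 1),
                           zero_cell = "haldane")
  expect_true(is.finite(corr$ci_low) && is.finite(corr$ci_high))
  expect_true(corr$ci_low < corr$ci_high)
  expect_error(odds_ratio_exact(contingency_2x2(0, 0, 1, 1)),
               "degenerate margin")
})

test_that("automatic method selection switches on sparse cells", {
  expect_identical(odds_ratio(contingency_2x2(7, 20, 16, 130))$method,
                   "woolf")
  expect_identical(odds_ratio(contingency_2x2(5, 22, 22, 103))$method,
                   "woolf")   # min cell is 5, not below it
  expect_identical(odds_ratio(contingency_2x2(4, 22, 22, 103))$method,
                   "exact")
  expect_identical(odds_ratio(contingency_2x2(4, 22, 22, 103),
                              method = "woolf")$method, "woolf")
})

test_that("Pearson chi-squared matches the closed form and the oracle", {
  # the published age comparison: p rounds to 0.04 without Yates correction
  age <- chi_squared(contingency_2x2(7, 20, 16, 130))
  expect_equal(round_half_up(age$p, 2), 0.04)
  # Yates-corrected version is available but is not the default
  expect_gt(chi_squared(contingency_2x2(7, 20, 16, 130), correct = TRUE)$p,
            0.05)
  expect_equal(chi_squared(contingency_2x2(6, 6, 6, 6))$statistic, 0)
  expect_equal(chi_squared(contingency_2x2(6, 6, 6, 6))$p, 1)
  # expected-counts oracle via chisq.test, plus transposition invariance
  set.seed(51)
  tables <- c(list(contingency_2x2(30, 10, 10, 30)),
              replicate(20, random_table() + 1, simplify = FALSE))
  for (t in tables) {
    mine <- chi_squared(t)
    oracle <- suppressWarnings(
      stats::chisq.test(matrix(c(t[1], t[3], t[2], t[4]), 2),
                        correct = FALSE))
    expect_equal(mine$statistic, unname(oracle$statistic))
    expect_equal(mine$p, oracle$p.value)
    transposed <- chi_squared(contingency_2x2(t[1], t[3], t[2], t[4]))
    expect_equal(mine$statistic, transposed$statistic)
    mine_y <- chi_squared(t, correct = TRUE)
    oracle_y <- suppressWarnings(
      stats::chisq.test(matrix(c(t[1], t[3], t[2], t[4]), 2), correct = TRUE))
    expect_equal(mine_y$statistic, unname(oracle_y$statistic))
  }
  expect_error(chi_squared(contingency_2x2(0, 0, 5, 5)), "zero margin")
})

test_that("summary-statistic t-test matches t.test on reconstructed data", {
  # the published age comparison rounds to p = 0.01
  pub <- t_test_summary(summary_stats(57.70, 12.45, 27),
                        summary_stats(64.31, 12.12, 146))
  expect_equal(round_half_up(pub$p, 2), 0.01)
  expect_identical(pub$df, 171L)
  # identical groups
  same <- t_test_summary(summary_stats(10, 2, 20), summary_stats(10, 2, 20))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # antisymmetry
  swapped <- t_test_summary(summary_stats(64.31, 12.12, 146),
                            summary_stats(57.70, 12.45, 27))
  expect_equal(swapped$t, -pub$t)
  expect_equal(swapped$p, pub$p)
  # oracle: rebuild vectors with exactly these moments, run t.test
  set.seed(61)
  for (i in 1:10) {
    n1 <- sample(3:40, 1); n2 <- sample(3:40, 1)
    m1 <- runif(1, -5, 5); m2 <- runif(1, -5, 5)
    s1 <- runif(1, 0.5, 3); s2 <- runif(1, 0.5, 3)
    x <- vector_with_moments(n1, m1, s1)
    y <- vector_with_moments(n2, m2, s2)
    mine <- t_test_summary(summary_stats(m1, s1, n1),
                           summary_stats(m2, s2, n2))
    oracle <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(mine$t, unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(mine$p, oracle$p.value, tolerance = 1e-10)
  }
  expect_error(t_test_summary(summary_stats(1, 1, 2), list(mean = 1, sd = 1,
                                                           n = 1)), "n must")
})

test_that("cascade summary counts the funnel and applies exclusions", {
  # tiny hand-built cohort: 1 proficient, 1 sporadic, 1 suspected tested
  # pathogenic, 1 suspected untested
  cohort <- make_cohort(
    make_row(),
    make_row(msi = rep(c("unstable", "stable"), c(2, 3)),
             ihc = c("lost", "retained", "retained", "lost"),
             tumor_probes = c(0.4, 0.4)),
    make_row(msi = rep(c("unstable", "stable"), c(2, 3)),
             ihc = c("retained", "lost", "lost", "retained"),
             germline = c("not_done", "pathogenic", "not_done", "not_done",
                          "not_done")),
    make_row(ihc = c("retained", "retained", "lost", "retained")))
  cs <- cascade_summary(triage_cohort(cohort), cohort)
  expect_identical(cs$n_total, 4L)
  expect_identical(cs$n_mmr_deficient, 3L)
  expect_identical(cs$n_mlh1_loss, 1L)
  expect_identical(cs$n_mlh1_methylated, 1L)
  expect_identical(cs$n_sporadic_methylated, 1L)
  expect_identical(cs$n_suspected, 2L)
  expect_identical(cs$n_tested, 1L)
  expect_identical(cs$n_pathogenic, 1L)
  expect_equal(cs$prevalence_observed, 1 / 4)
  expect_equal(cs$predictive_frequency, (2 * 1 / 1) / 4)
  # germline results attached to non-suspected patients are excluded
  cohort2 <- cohort
  cohort2$germline_mlh1[1] <- "negative"
  expect_warning(cs2 <- cascade_summary(triage_cohort(cohort2), cohort2),
                 "non-suspected")
  expect_identical(cs2$n_tested, 1L)
  # no deficiency at all
  flat <- make_cohort(make_row(), make_row(), make_row())
  cs3 <- cascade_summary(triage_cohort(flat), flat)
  expect_identical(cs3$n_suspected, 0L)
  expect_equal(cs3$prevalence_observed, 0)
  expect_true(is.na(cs3$predictive_frequency))
  expect_error(cascade_summary(triage_cohort(flat)[0, ]), "empty")
})

test_that("predictive frequency extrapolates the tested-case yield", {
  cohort <- paper_fixture()
  cs <- cascade_summary(triage_cohort(cohort), cohort)
  expect_equal(round_half_up(100 * predictive_frequency(cs), 1), 6.6)
  # full testing uptake: prediction equals observation
  expect_equal(predictive_frequency(list(n_suspected = 10, n_pathogenic = 4,
                                         n_tested = 10, n_total = 100)),
               0.04)
  expect_equal(predictive_frequency(list(n_suspected = 10, n_pathogenic = 0,
                                         n_tested = 5, n_total = 100)), 0)
  expect_error(predictive_frequency(list(n_suspected = 10, n_pathogenic = 0,
                                         n_tested = 0, n_total = 100)),
               "no tested")
})
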