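test_that("tables are built from predictions with complete-case exclusion", {
  t1 <- contingency_from_predictions(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unclass(t1)[c("tp", "fn", "fp", "tn")],
               list(tp = 1L, fn = 1L, fp = 1L, tn = 1L))
  t2 <- contingency_from_predictions(c(1, 0), c(NA, 0))
  expect_equal(c(t2$tp, t2$fn, t2$fp, t2$tn), c(0, 0, 0, 1))
  expect_error(contingency_from_predictions(c(1, 0), c(NA, NA)), "missing")
  expect_error(contingency_table(-1, 1, 1, 1))
  expect_error(sens_spec(contingency_table(0, 0, 1, 1)), "margin")
})

test_that("a generated feature with sensitivity 1 yields no false negatives", {
  ch <- study_cohort(seed = 5)
  tab <- contingency_from_predictions(ch$outcome, ch$history_du_ps)
  expect_equal(tab$fn, 0L)
})

test_that("odds ratios, Woolf intervals and corrections match direct arithmetic", {
  est <- odds_ratio(contingency_table(15, 7, 10, 44), correction = "none")
  expect_equal(est$or, 660 / 70)
  expect_equal(round(est$or, 1), 9.4)
  expect_false(est$corrected)

  expect_equal(odds_ratio(contingency_table(1, 1, 1, 1))$or, 1.0)

  # zero-cell table: Haldane-Anscombe correction on all four cells
  est <- odds_ratio(contingency_table(22, 0, 30, 24), correction = "haldane_if_zero")
  expect_true(est$corrected)
  expect_equal(est$or, (22.5 * 24.5) / (0.5 * 30.5))
  expect_equal(round(est$ci_low, 1), 2.1)
  expect_equal(round(est$ci_high), 626)

  expect_error(odds_ratio(contingency_table(22, 0, 30, 24), correction = "none"),
               "zero cell")
  # haldane_always corrects even without zeros
  est2 <- odds_ratio(contingency_table(1, 1, 1, 1), correction = "haldane_always")
  expect_equal(est2$or, 1.0)
  expect_true(est2$corrected)
})

test_that("odds ratio is invariant under the diagonal swap of the table", {
  set.seed(42)
  for (i in 1:20) {
    cells <- rpois(4, 8) + 1L
    a <- odds_ratio(do.call(contingency_table, as.list(cells)), "none")
    b <- odds_ratio(contingency_table(cells[4], cells[3], cells[2], cells[1]), "none")
    expect_equal(a$or, b$or)
    expect_equal(a$ci_low, b$ci_low)
    expect_equal(a$p_value, b$p_value)
  }
})

test_that("sensitivity and specificity follow the table margins", {
  expect_equal(round(sens_spec(contingency_table(15, 7, 10, 44)), 3),
               c(sensitivity = 0.682, specificity = 0.815))
  expect_equal(sens_spec(contingency_table(0, 5, 0, 5)),
               c(sensitivity = 0, specificity = 1))
  expect_equal(round(sens_spec(contingency_table(18, 1, 30, 15)), 3),
               c(sensitivity = 0.947, specificity = 0.333))
})

test_that("tables reconstructed from printed summaries invert sens_spec", {
  t1 <- reconstruct_table(0.682, 0.815, 22, 54)
  expect_equal(c(t1$tp, t1$fn, t1$fp, t1$tn), c(15, 7, 10, 44))
  t2 <- reconstruct_table(1.0, 0.444, 22, 54)
  expect_equal(c(t2$tp, t2$fn, t2$fp, t2$tn), c(22, 0, 30, 24))
  t3 <- reconstruct_table(0.5, 0.5, 2, 2)
  expect_equal(c(t3$tp, t3$fn, t3$fp, t3$tn), c(1, 1, 1, 1))
  # round-trip property: se/sp recovered within rounding error 0.5/n
  set.seed(7)
  for (i in 1:50) {
    se <- runif(1); sp <- runif(1)
    n1 <- sample(5:60, 1); n0 <- sample(5:60, 1)
    ss <- sens_spec(reconstruct_table(se, sp, n1, n0))
    expect_lte(abs(ss[["sensitivity"]] - se), 0.5 / n1)
    expect_lte(abs(ss[["specificity"]] - sp), 0.5 / n0)
  }
})

test_that("the Fisher p-value equals brute-force hypergeometric enumeration", {
  set.seed(13)
  for (i in 1:25) {
    cells <- as.integer(rmultinom(1, sample(10:40, 1), rep(0.25, 4)))
    if (cells[1] + cells[2] < 1 || cells[3] + cells[4] < 1) next
    tab <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    p <- odds_ratio(tab, "haldane_if_zero")$p_value
    # enumerate all tables with the observed margins
    m_pos <- cells[1] + cells[3]   # feature-positive margin
    n_ev <- cells[1] + cells[2]
    n_tot <- sum(cells)
    support <- max(0, m_pos - (n_tot - n_ev)):min(m_pos, n_ev)
    probs <- dhyper(support, n_ev, n_tot - n_ev, m_pos)
    p_obs <- dhyper(cells[1], n_ev, n_tot - n_ev, m_pos)
    p_brute <- sum(probs[probs <= p_obs * (1 + 1e-7)])
    expect_equal(p, p_brute, tolerance = 1e-10)
  }
})

test_that("the logistic slope exponentiates to the uncorrected odds ratio", {
  set.seed(21)
  for (i in 1:10) {
    cells <- rpois(4, 15) + 1L
    tab <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    x <- rep(c(1, 0, 1, 0), cells)
    y <- rep(c(1, 1, 0, 0), cells)
    fit <- fit_logistic(x, y)
    expect_equal(exp(fit$slope), odds_ratio(tab, "none")$or, tolerance = 1e-6)
  }
})
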