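test_that("the published-study config carries the printed conditional prevalences", {
  cfg <- cipdus_config()
  expect_equal(cfg$n_events, 22L)
  expect_equal(cfg$n_nonevents, 54L)
  expect_equal(cfg$features[["mrss_gt8"]]$p_given_event, 0.682)
  expect_equal(cfg$features[["history_du_ps"]]$p_given_event, 1.0)
  expect_equal(cfg$features[["diffuse_subtype"]]$p_given_nonevent, 1 - 0.741)
  expect_equal(cfg$n_events / (cfg$n_events + cfg$n_nonevents), 22 / 76)
  # missingness implied by the published per-feature denominators
  expect_equal(cfg$features[["nc_density_reduced"]]$missing_rate_events, 3 / 22)
  expect_equal(cfg$features[["foi_missing_enhancement"]]$missing_rate_nonevents, 10 / 54)
  # events carry no mass on a normal capillaroscopy pattern
  expect_equal(unname(cfg$features[["nc_pattern"]]$ordinal_dist_event[["normal"]]), 0)
  expect_equal(sum(cfg$features[["nc_pattern"]]$ordinal_dist_nonevent), 1)
})

test_that("invalid specs and configs are rejected before generation", {
  expect_error(feature_spec("f", "binary", p_given_event = 1.2, p_given_nonevent = 0),
               "probability")
  expect_error(feature_spec("f", "ordinal_nc_pattern",
                            ordinal_dist_event = c(0.5, 0.5, 0.5, 0.5),
                            ordinal_dist_nonevent = rep(0.25, 4)),
               "summing to 1")
  f <- feature_spec("f", "binary", p_given_event = 1, p_given_nonevent = 0)
  expect_error(cohort_config(0, 10, list(f)))
  expect_error(cohort_config(5, 5, list(f, f)), "unique")
  expect_error(scale_config(cohort_config(5, 5, list(f)), 1.5), "positive integer")
})

test_that("generation is stratified, deterministic, and never drops the outcome", {
  cfg <- cipdus_config(seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(sum(a$outcome == 1), 22)
  expect_equal(sum(a$outcome == 0), 54)
  expect_false(anyNA(a$outcome))
  c <- generate_cohort(cipdus_config(seed = 12))
  expect_false(identical(a, c))
})

test_that("degenerate probabilities produce a perfectly separating feature", {
  cfg <- toy_config(p1 = 1, p0 = 0)
  ch <- generate_cohort(cfg)
  expect_true(all(ch$f1[ch$outcome == 1] == 1))
  expect_true(all(ch$f1[ch$outcome == 0] == 0))
})

test_that("scaling a config preserves everything but the group sizes", {
  cfg <- cipdus_config()
  expect_identical(scale_config(cfg, 1), cfg)
  big <- scale_config(cfg, 100)
  expect_equal(big$n_events, 2200L)
  expect_equal(big$n_nonevents, 5400L)
  expect_identical(big$features, cfg$features)
  ch <- generate_cohort(scale_config(cfg, 3))
  expect_equal(mean(ch$outcome), 22 / 76)
})

test_that("empirical conditional prevalences converge to the configured ones", {
  ch <- study_cohort(factor = 100, seed = 3)
  ev <- ch$outcome == 1
  expect_lt(abs(mean(ch$mrss_gt8[ev]) - 0.682), 0.02)
  # every binary feature, multiple seeds: within 3 binomial standard errors
  cfg <- cipdus_config()
  bin_feats <- names(Filter(function(f) f$kind == "binary", cfg$features))
  n_checks <- 0; n_ok <- 0
  for (seed in 1:25) {
    ch <- study_cohort(factor = 100, seed = seed)
    ev <- ch$outcome == 1
    for (f in bin_feats) {
      v <- ch[[f]][ev]
      p <- cfg$features[[f]]$p_given_event
      n <- sum(!is.na(v))
      tol <- 3 * sqrt(max(p * (1 - p), 1e-4) / n)
      n_checks <- n_checks + 1
      n_ok <- n_ok + (abs(mean(v, na.rm = TRUE) - p) < max(tol, 1e-3))
    }
  }
  expect_gte(n_ok / n_checks, 0.99)
})

test_that("missingness hits the configured rates and only the configured features", {
  ch <- study_cohort(factor = 100, seed = 2)
  ev <- ch$outcome == 1
  expect_lt(abs(mean(is.na(ch$nc_density_reduced[ev])) - 3 / 22), 0.02)
  expect_lt(abs(mean(is.na(ch$foi_missing_enhancement[!ev])) - 10 / 54), 0.02)
  for (f in c("diffuse_subtype", "mrss_gt8", "pah", "present_du_ps",
              "history_du_ps", "nc_pattern", "cdus_pathologic_gt35"))
    expect_false(anyNA(ch[[f]]))
})

test_that("per-feature substreams: adding a feature does not perturb the others", {
  base <- toy_config(seed = 9)
  extended <- cohort_config(50L, 50L, c(base$features, list(
    feature_spec("f3", "binary", p_given_event = 0.3, p_given_nonevent = 0.3))),
    seed = 9L)
  a <- generate_cohort(base)
  b <- generate_cohort(extended)
  expect_identical(a$f1, b$f1)
  expect_identical(a$f2, b$f2)
})

test_that("a cohort round-trips through CSV losslessly", {
  ch <- study_cohort(seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(ch, path)
  back <- read_cohort(path)
  expect_identical(ch, back)
})
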