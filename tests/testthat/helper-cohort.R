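# Shared fixtures: cohorts generated in code at test time.

study_cohort <- function(factor = 1L, seed = 1L) {
  generate_cohort(scale_config(cipdus_config(seed = seed), factor))
}

# a small deterministic two-feature config for focused generator tests
toy_config <- function(p1 = 0.8, p0 = 0.2, n1 = 50L, n0 = 50L, seed = 1L) {
  cohort_config(n1, n0, list(
    feature_spec("f1", "binary", p_given_event = p1, p_given_nonevent = p0),
    feature_spec("f2", "binary", p_given_event = 0.5, p_given_nonevent = 0.5)
  ), seed = seed)
}
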