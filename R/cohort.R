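# Synthetic cohort generation: patient cohorts whose outcome-conditional
# feature prevalences match a stated configuration.

NC_LEVELS <- c("normal", "early", "active", "late")

#' Describe one feature of a synthetic cohort
#'
#' A feature is simulated conditionally on the outcome: among events
#' (patients with new digital ulcers at follow-up) a binary feature is
#' positive with probability `p_given_event` (the feature's sensitivity);
#' among non-events with probability `p_given_nonevent` (one minus its
#' specificity). Values are independently set to missing at per-group rates,
#' mirroring features that could not be assessed in every patient.
#'
#' @param name Feature name (unique within a config; used as CSV column name).
#' @param kind `"binary"` or `"ordinal_nc_pattern"` (the four-level
#'   capillaroscopy pattern normal/early/active/late).
#' @param p_given_event,p_given_nonevent Probabilities of a positive value
#'   conditional on outcome (binary features only).
#' @param missing_rate_events,missing_rate_nonevents Per-group probabilities
#'   that the value is missing.
#' @param ordinal_dist_event,ordinal_dist_nonevent Probability vectors over
#'   `c("normal","early","active","late")` (ordinal features only); each must
#'   sum to 1.
#' @return An object of class `"feature_spec"`.
#' @export
#' @examples
#' feature_spec("mrss_gt8", "binary", p_given_event = 0.682, p_given_nonevent = 0.185)
feature_spec <- function(name,
                         kind = c("binary", "ordinal_nc_pattern"),
                         p_given_event = NULL,
                         p_given_nonevent = NULL,
                         missing_rate_events = 0,
                         missing_rate_nonevents = 0,
                         ordinal_dist_event = NULL,
                         ordinal_dist_nonevent = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  chk_prob <- function(p, what) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
      stop(sprintf("'%s' must be a probability in [0, 1] for feature '%s'", what, name),
           call. = FALSE)
  }
  chk_prob(missing_rate_events, "missing_rate_events")
  chk_prob(missing_rate_nonevents, "missing_rate_nonevents")
  if (kind == "binary") {
    chk_prob(p_given_event, "p_given_event")
    chk_prob(p_given_nonevent, "p_given_nonevent")
    ordinal_dist_event <- ordinal_dist_nonevent <- NULL
  } else {
    chk_dist <- function(d, what) {
      if (!is.numeric(d) || length(d) != 4L || any(is.na(d)) || any(d < 0) ||
          abs(sum(d) - 1) > 1e-12)
        stop(sprintf("'%s' must be 4 non-negative probabilities summing to 1 for '%s'",
                     what, name), call. = FALSE)
      stats::setNames(as.numeric(d), NC_LEVELS)
    }
    ordinal_dist_event <- chk_dist(ordinal_dist_event, "ordinal_dist_event")
    ordinal_dist_nonevent <- chk_dist(ordinal_dist_nonevent, "ordinal_dist_nonevent")
    p_given_event <- p_given_nonevent <- NULL
  }
  structure(list(name = name, kind = kind,
                 p_given_event = p_given_event,
                 p_given_nonevent = p_given_nonevent,
                 missing_rate_events = missing_rate_events,
                 missing_rate_nonevents = missing_rate_nonevents,
                 ordinal_dist_event = ordinal_dist_event,
                 ordinal_dist_nonevent = ordinal_dist_nonevent),
            class = "feature_spec")
}

#' Configuration of a synthetic cohort
#'
#' Outcome counts are fixed exactly (stratified generation): a generated
#' cohort always contains `n_events` patients with the outcome and
#' `n_nonevents` without, mirroring a realized study cohort rather than
#' sampling prevalence.
#'
#' @param n_events,n_nonevents Positive integer group sizes.
#' @param features List of [feature_spec()] objects with unique names.
#' @param seed Integer seed driving all randomness of [generate_cohort()].
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_events, n_nonevents, features, seed = 1L) {
  stopifnot(length(n_events) == 1L, length(n_nonevents) == 1L,
            n_events >= 1, n_nonevents >= 1,
            n_events == as.integer(n_events), n_nonevents == as.integer(n_nonevents))
  if (!is.list(features) || !all(vapply(features, inherits, TRUE, "feature_spec")))
    stop("'features' must be a list of feature_spec objects", call. = FALSE)
  nm <- vapply(features, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("feature names must be unique", call. = FALSE)
  names(features) <- nm
  structure(list(n_events = as.integer(n_events),
                 n_nonevents = as.integer(n_nonevents),
                 features = features, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generator configuration matching the published CIP-DUS development cohort
#'
#' Returns a [cohort_config()] with 22 events and 54 non-events and one
#' feature per published score row, where each binary feature's conditional
#' prevalences equal the printed sensitivity (`p_given_event`) and one minus
#' the printed specificity (`p_given_nonevent`). Two features carry the
#' missingness implied by their published denominators: reduced capillary
#' density (19 of 22 events, 45 of 54 non-events assessed) and FOI initial
#' enhancement (16 of 22 events, 44 of 54 non-events assessed). The
#' capillaroscopy pattern is ordinal; events carry no mass on "normal"
#' (the published sensitivity of "any scleroderma pattern" is 100%) and the
#' split across early/active/late defaults to uniform — a synthetic-only
#' choice, since the published table does not report it.
#'
#' @param seed Integer seed stored in the config.
#' @return A `"cohort_config"` object.
#' @export
#' @examples
#' cfg <- cipdus_config()
#' cfg$n_events / (cfg$n_events + cfg$n_nonevents)  # 22/76, ~29% incidence
cipdus_config <- function(seed = 1L) {
  pub <- .cipdus_published()
  row <- function(f) pub[pub$feature == f, ]
  bin <- function(f, miss_e = 0, miss_ne = 0) {
    r <- row(f)
    feature_spec(f, "binary",
                 p_given_event = r$sensitivity,
                 p_given_nonevent = 1 - r$specificity,
                 missing_rate_events = miss_e,
                 missing_rate_nonevents = miss_ne)
  }
  sp_nc <- row("nc_pattern_any")$specificity  # fraction of non-events with normal pattern
  features <- list(
    bin("diffuse_subtype"),
    bin("mrss_gt8"),
    bin("pah"),
    bin("present_du_ps"),
    bin("history_du_ps"),
    feature_spec("nc_pattern", "ordinal_nc_pattern",
                 ordinal_dist_event = c(0, 1, 1, 1) / 3,
                 ordinal_dist_nonevent = c(sp_nc, rep((1 - sp_nc) / 3, 3))),
    bin("nc_density_reduced", miss_e = 3 / 22, miss_ne = 9 / 54),
    bin("foi_missing_enhancement", miss_e = 6 / 22, miss_ne = 10 / 54),
    bin("cdus_pathologic_gt35")
  )
  cohort_config(22L, 54L, features, seed = seed)
}

#' Scale a cohort configuration
#'
#' Multiplies both outcome-group sizes by an integer factor, leaving the
#' event fraction and all feature parameters unchanged. Useful for
#' law-of-large-numbers checks of the generator.
#'
#' @param config A `"cohort_config"`.
#' @param factor Positive integer.
#' @return A `"cohort_config"` with scaled group sizes.
#' @export
scale_config <- function(config, factor) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(factor) != 1L || is.na(factor) || factor < 1 || factor != as.integer(factor))
    stop("'factor' must be a positive integer", call. = FALSE)
  config$n_events <- config$n_events * as.integer(factor)
  config$n_nonevents <- config$n_nonevents * as.integer(factor)
  config
}

# Deterministic per-feature substream seed: a name hash folded with the config
# seed, so adding or reordering features does not perturb the draws of others.
.feature_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + (seed %% 2147483647) * 2654435) %% 2147483647)
}

# Run expr under a temporary RNG state, restoring the caller's stream.
.with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic patient cohort
#'
#' Draws exactly `config$n_events` patients with `outcome = 1` and
#' `config$n_nonevents` with `outcome = 0`; each feature is drawn from its
#' outcome-conditional distribution and independently masked as missing (`NA`)
#' at the configured rates. The outcome itself is never missing. Generation is
#' fully reproducible from `config$seed`, with one deterministic substream per
#' feature.
#'
#' @param config A [cohort_config()].
#' @return A data frame with columns `patient_id`, `outcome`, then one column
#'   per feature (integer 0/1 for binary features, character level for the
#'   capillaroscopy pattern).
#' @export
#' @examples
#' cohort <- generate_cohort(cipdus_config(seed = 42))
#' table(cohort$outcome)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n1 <- config$n_events; n0 <- config$n_nonevents; n <- n1 + n0
  out <- data.frame(patient_id = sprintf("P%05d", seq_len(n)),
                    outcome = rep(c(1L, 0L), c(n1, n0)),
                    stringsAsFactors = FALSE)
  is_event <- out$outcome == 1L
  for (fs in config$features) {
    vals <- .with_seed(.feature_seed(config$seed, fs$name), {
      if (fs$kind == "binary") {
        v <- integer(n)
        v[is_event] <- stats::rbinom(n1, 1L, fs$p_given_event)
        v[!is_event] <- stats::rbinom(n0, 1L, fs$p_given_nonevent)
      } else {
        v <- character(n)
        v[is_event] <- sample(NC_LEVELS, n1, replace = TRUE, prob = fs$ordinal_dist_event)
        v[!is_event] <- sample(NC_LEVELS, n0, replace = TRUE, prob = fs$ordinal_dist_nonevent)
      }
      miss <- logical(n)
      if (fs$missing_rate_events > 0)
        miss[is_event] <- stats::runif(n1) < fs$missing_rate_events
      if (fs$missing_rate_nonevents > 0)
        miss[!is_event] <- stats::runif(n0) < fs$missing_rate_nonevents
      v[miss] <- NA
      v
    })
    out[[fs$name]] <- vals
  }
  out
}
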