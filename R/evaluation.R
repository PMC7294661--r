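# Calibration and added-value statistics: Hosmer-Lemeshow chi-square,
# continuous net reclassification improvement (NRI) and integrated
# discrimination improvement (IDI).

#' Hosmer-Lemeshow calibration test
#'
#' Patients are ranked by predicted probability and cut into `n_groups`
#' risk-quantile groups, with tied probabilities kept together (so heavily
#' tied integer-score models yield fewer groups). The statistic is
#' `sum((obs - exp)^2 / (exp * (1 - exp/n)))` over groups. The default
#' degrees of freedom are `g - 2` (with `g` the realized number of groups),
#' the convention for probabilities fitted on the same data; pass
#' `df = n_groups` when the probabilities come from an external model. When
#' fewer than 3 distinct probability values exist, quantile grouping is
#' impossible and patients are split into equal-sized groups by position,
#' with a warning.
#'
#' @param probabilities Predicted event probabilities, strictly in (0, 1).
#' @param outcomes 0/1 vector.
#' @param n_groups Number of quantile groups (default 10).
#' @param df Degrees of freedom for the chi-square reference; default
#'   `g - 2`.
#' @return An object of class `"calibration_result"`: `chi_square`,
#'   `degrees_freedom`, `p_value`, `group_table` (per-group n, observed and
#'   expected events).
#' @export
hosmer_lemeshow <- function(probabilities, outcomes, n_groups = 10L, df = NULL) {
  p <- as.numeric(probabilities); y <- as.numeric(outcomes)
  stopifnot(length(p) == length(y))
  if (anyNA(p) || any(p <= 0) || any(p >= 1))
    stop("'probabilities' must lie strictly in (0, 1)", call. = FALSE)
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2L)
    stop("'outcomes' must be 0/1 with both classes present", call. = FALSE)
  if (length(unique(p)) < 3L) {
    warning("fewer than 3 distinct probabilities; using equal-sized groups by position")
    grp <- ceiling(seq_along(p) / (length(p) / n_groups))
  } else {
    breaks <- unique(stats::quantile(p, probs = seq(0, 1, length.out = n_groups + 1)))
    if (length(breaks) < 4L)  # ties collapsed the quantiles too far
      breaks <- unique(c(min(p), breaks, max(p)))
    grp <- cut(p, breaks, include.lowest = TRUE, labels = FALSE)
  }
  obs <- tapply(y, grp, sum)
  expc <- tapply(p, grp, sum)
  ng <- tapply(p, grp, length)
  chi2 <- sum((obs - expc)^2 / (expc * (1 - expc / ng)))
  g <- length(obs)
  if (is.null(df)) df <- max(g - 2L, 1L)
  pv <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  structure(list(chi_square = chi2, degrees_freedom = df, p_value = pv,
                 group_table = data.frame(group = seq_len(g), n = as.integer(ng),
                                          observed = as.integer(obs),
                                          expected = as.numeric(expc))),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow: chi-square = %.2f (%d df), p = %.3g\n",
              x$chi_square, x$degrees_freedom, x$p_value))
  invisible(x)
}

#' Continuous NRI and IDI between two risk models
#'
#' Category-free ("any movement") net reclassification improvement: a patient
#' counts as reclassified up/down when the new model's predicted probability
#' is strictly higher/lower than the old model's. On the x100 (percent-style)
#' scale,
#' `NRI = 100 * ((events_up - events_down)/n_events +
#'               (nonevents_down - nonevents_up)/n_nonevents)`,
#' with an asymptotic normal p-value from the multinomial variance of the two
#' net proportions. The integrated discrimination improvement is
#' `IDI = 100 * (discrimination slope of new model - slope of old model)`,
#' where the discrimination slope is the mean predicted probability among
#' events minus that among non-events; its p-value is a two-group z-test on
#' the per-patient probability changes. Identical probability vectors give
#' NRI = IDI = 0 with p = 1.
#'
#' @param probs_old,probs_new Predicted probabilities under the reference and
#'   the new model, aligned per patient.
#' @param outcomes 0/1 vector.
#' @return An object of class `"reclassification_result"` with counts
#'   (`events_up`, `events_down`, `nonevents_up`, `nonevents_down`), `nri`,
#'   `nri_p`, `idi`, `idi_p`, `n_events`, `n_nonevents`.
#' @export
#' @examples
#' # the published reclassification counts: 14 up / 4 down of 22 events,
#' # 18 down / 9 up of 54 non-events give NRI = 62.1
#' 100 * ((14 - 4) / 22 + (18 - 9) / 54)
reclassification <- function(probs_old, probs_new, outcomes) {
  po <- as.numeric(probs_old); pn <- as.numeric(probs_new)
  y <- as.numeric(outcomes)
  stopifnot(length(po) == length(y), length(pn) == length(y))
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2L)
    stop("'outcomes' must be 0/1 with both classes present", call. = FALSE)
  e <- y == 1
  n1 <- sum(e); n0 <- sum(!e)
  up <- pn > po; down <- pn < po
  eu <- sum(up & e); ed <- sum(down & e)
  nu <- sum(up & !e); nd <- sum(down & !e)
  nri <- 100 * ((eu - ed) / n1 + (nd - nu) / n0)
  # multinomial variance of the two net movement proportions
  v1 <- ((eu + ed) / n1 - ((eu - ed) / n1)^2) / n1
  v0 <- ((nu + nd) / n0 - ((nu - nd) / n0)^2) / n0
  se_nri <- sqrt(v1 + v0)
  nri_p <- if (se_nri == 0) 1 else
    2 * stats::pnorm(-abs(nri / 100) / se_nri)
  d <- pn - po
  idi <- 100 * (mean(d[e]) - mean(d[!e]))
  se_idi <- sqrt(stats::var(d[e]) / n1 + stats::var(d[!e]) / n0)
  idi_p <- if (se_idi == 0) {
    if (idi == 0) 1 else 0
  } else 2 * stats::pnorm(-abs(idi / 100) / se_idi)
  structure(list(n_events = n1, n_nonevents = n0,
                 events_up = eu, events_down = ed,
                 nonevents_up = nu, nonevents_down = nd,
                 nri = nri, nri_p = nri_p, idi = idi, idi_p = idi_p),
            class = "reclassification_result")
}

#' @rdname reclassification
#' @export
nri <- function(probs_old, probs_new, outcomes) {
  reclassification(probs_old, probs_new, outcomes)
}

#' @rdname reclassification
#' @export
idi <- function(probs_old, probs_new, outcomes) {
  reclassification(probs_old, probs_new, outcomes)
}

#' @export
print.reclassification_result <- function(x, ...) {
  cat(sprintf("Events:     %d up / %d down of %d\n",
              x$events_up, x$events_down, x$n_events))
  cat(sprintf("Non-events: %d up / %d down of %d\n",
              x$nonevents_up, x$nonevents_down, x$n_nonevents))
  cat(sprintf("NRI = %.1f (p = %.3g), IDI = %.1f (p = %.3g)\n",
              x$nri, x$nri_p, x$idi, x$idi_p))
  invisible(x)
}

# Map integer scores to event probabilities. Logistic-mapped risks are kept
# off the exact 0/1 boundary (capped-slope fits under quasi-separation would
# otherwise return probabilities of numerically 0 or 1, which are meaningless
# as risks and degenerate in the Hosmer-Lemeshow denominator).
.score_probs <- function(score, outcomes, mapping = c("logistic", "empirical")) {
  mapping <- match.arg(mapping)
  if (mapping == "logistic") {
    f <- fit_logistic(score, outcomes)
    pmin(pmax(predict_prob(f, score), 1e-6), 1 - 1e-6)
  } else {
    # empirical event rate at each observed score value
    rates <- tapply(outcomes, score, mean)
    unname(rates[as.character(score)])
  }
}

#' Compare the full and the reduced score on one cohort
#'
#' Scores the cohort under both weight schemes, maps each score to a
#' predicted probability through its own univariate logistic fit of outcome
#' on score (or the raw empirical rate per score value with
#' `mapping = "empirical"`), and returns discrimination (both AUCs and the
#' DeLong comparison), reclassification (NRI and IDI with the full scheme as
#' the "new" model), and calibration of both models.
#'
#' @param cohort Cohort data frame.
#' @param scheme_full,scheme_reduced Weight schemes to compare; default the
#'   canonical published schemes with and without the imaging components.
#' @param cutoff Classification cutoff passed to [compute_scores()].
#' @param mapping Score-to-probability mapping: `"logistic"` (default) or
#'   `"empirical"`.
#' @param n_groups Hosmer-Lemeshow groups.
#' @return A list with `auc_full`, `auc_reduced`, `delong`,
#'   `reclassification`, `calibration_full`, `calibration_reduced`,
#'   `scores_full`, `scores_reduced`.
#' @export
compare_models <- function(cohort,
                           scheme_full = canonical_weights(TRUE),
                           scheme_reduced = canonical_weights(FALSE),
                           cutoff = 10L,
                           mapping = c("logistic", "empirical"),
                           n_groups = 10L) {
  mapping <- match.arg(mapping)
  y <- cohort$outcome
  s_full <- compute_scores(cohort, scheme_full, cutoff)$score
  s_red <- compute_scores(cohort, scheme_reduced, cutoff)$score
  p_full <- .score_probs(s_full, y, mapping)
  p_red <- .score_probs(s_red, y, mapping)
  cal <- function(p) {
    ok <- all(p > 0) && all(p < 1)
    if (ok) hosmer_lemeshow(p, y, n_groups = n_groups) else NULL
  }
  list(auc_full = auc_mann_whitney(s_full, y),
       auc_reduced = auc_mann_whitney(s_red, y),
       delong = delong_compare(s_full, s_red, y),
       reclassification = reclassification(p_red, p_full, y),
       calibration_full = cal(p_full),
       calibration_reduced = cal(p_red),
       scores_full = s_full, scores_reduced = s_red)
}
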