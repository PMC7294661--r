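# 2x2 contingency tables linking a binary predictor to the outcome, and the
# diagnostic statistics derived from them.

#' Create a 2x2 contingency table
#'
#' Cells follow the diagnostic-test convention: `tp` feature-positive events,
#' `fn` feature-negative events, `fp` feature-positive non-events, `tn`
#' feature-negative non-events.
#'
#' @param tp,fn,fp,tn Non-negative integer counts; the table must contain at
#'   least one patient. Statistics that need a non-empty outcome margin
#'   ([sens_spec()]) check for one themselves.
#' @return An object of class `"contingency_table"`.
#' @export
#' @examples
#' contingency_table(15, 7, 10, 44)
contingency_table <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  if (sum(cells) < 1)
    stop("the table must contain at least one patient", call. = FALSE)
  structure(as.list(as.integer(cells)), names = names(cells),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2,
              dimnames = list(predictor = c("positive", "negative"),
                              outcome = c("event", "non-event")))
  print(m)
  invisible(x)
}

#' @export
as.matrix.contingency_table <- function(x, ...) {
  matrix(c(x$tp, x$fn, x$fp, x$tn), 2,
         dimnames = list(predictor = c("positive", "negative"),
                         outcome = c("event", "non-event")))
}

#' Tabulate a binary predictor against outcomes
#'
#' Pairs where the predictor is missing are excluded (complete-case per
#' feature, matching per-feature denominators that differ across features).
#'
#' @param outcomes 0/1 vector, no missing values.
#' @param predictor 0/1 vector of the same length, `NA` allowed.
#' @return A [contingency_table()].
#' @export
contingency_from_predictions <- function(outcomes, predictor) {
  stopifnot(length(outcomes) == length(predictor))
  if (anyNA(outcomes) || !all(outcomes %in% c(0, 1)))
    stop("'outcomes' must be 0/1 with no missing values", call. = FALSE)
  keep <- !is.na(predictor)
  if (!any(keep)) stop("predictor is missing for every patient", call. = FALSE)
  p <- predictor[keep]
  if (!all(p %in% c(0, 1))) stop("'predictor' must be 0/1 or NA", call. = FALSE)
  y <- outcomes[keep]
  contingency_table(tp = sum(p == 1 & y == 1), fn = sum(p == 0 & y == 1),
                    fp = sum(p == 1 & y == 0), tn = sum(p == 0 & y == 0))
}

#' Odds ratio with Woolf confidence interval and Fisher exact p-value
#'
#' The odds ratio is `(tp*tn)/(fn*fp)` computed on the (possibly
#' continuity-corrected) cells. The Haldane-Anscombe correction adds 0.5 to
#' all four cells; with `correction = "haldane_if_zero"` (the default) it is
#' applied only when some cell is zero, which is the convention that
#' reproduces the published interval of the history-of-ulcers feature.
#' The 95% CI is the Woolf log-normal interval
#' `exp(log OR +/- z * sqrt(sum of reciprocal cells))` on the corrected cells.
#' The p-value is the two-sided Fisher exact test (sum of hypergeometric
#' probabilities not exceeding that of the observed table) on the
#' *uncorrected* counts.
#'
#' @param table A [contingency_table()].
#' @param correction `"haldane_if_zero"`, `"none"` or `"haldane_always"`.
#' @param conf_level Confidence level of the Woolf interval.
#' @return An object of class `"or_estimate"`: `or`, `ci_low`, `ci_high`,
#'   `p_value`, `corrected`.
#' @export
#' @examples
#' odds_ratio(contingency_table(15, 7, 10, 44))   # OR ~ 9.43
odds_ratio <- function(table,
                       correction = c("haldane_if_zero", "none", "haldane_always"),
                       conf_level = 0.95) {
  stopifnot(inherits(table, "contingency_table"))
  correction <- match.arg(correction)
  cells <- c(table$tp, table$fn, table$fp, table$tn)
  apply_cc <- switch(correction,
                     none = FALSE,
                     haldane_always = TRUE,
                     haldane_if_zero = any(cells == 0L))
  if (!apply_cc && any(cells == 0L))
    stop("odds ratio undefined: zero cell and no continuity correction", call. = FALSE)
  cc <- cells + 0.5 * apply_cc
  or <- (cc[1] * cc[4]) / (cc[2] * cc[3])
  se <- sqrt(sum(1 / cc))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or) + c(-1, 1) * z * se)
  p <- stats::fisher.test(as.matrix(table))$p.value
  structure(list(or = or, ci_low = ci[1], ci_high = ci[2],
                 p_value = p, corrected = apply_cc),
            class = "or_estimate")
}

#' @export
print.or_estimate <- function(x, ...) {
  cat(sprintf("OR %.2f (95%% CI %.2f-%.2f), Fisher p = %.4g%s\n",
              x$or, x$ci_low, x$ci_high, x$p_value,
              if (x$corrected) " [Haldane-corrected]" else ""))
  invisible(x)
}

#' Sensitivity and specificity of a 2x2 table
#'
#' @param table A [contingency_table()].
#' @return Named numeric vector `c(sensitivity =, specificity =)`.
#' @export
#' @examples
#' sens_spec(contingency_table(15, 7, 10, 44))  # 0.682, 0.815
sens_spec <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  if (table$tp + table$fn < 1 || table$fp + table$tn < 1)
    stop("sensitivity/specificity undefined: an outcome margin is empty",
         call. = FALSE)
  c(sensitivity = table$tp / (table$tp + table$fn),
    specificity = table$tn / (table$fp + table$tn))
}

# round half away from zero (commercial rounding), matching printed tables
.round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Reconstruct a 2x2 table from printed sensitivity/specificity
#'
#' Inverts a published summary: `tp = round(se * n_events)` and
#' `tn = round(sp * n_nonevents)` (half rounded away from zero), with the
#' complements filling `fn` and `fp`. Used to recover the implicit tables
#' behind published odds-ratio rows.
#'
#' @param sensitivity,specificity Proportions in \[0, 1\].
#' @param n_events,n_nonevents Group denominators (at least 1).
#' @return A [contingency_table()].
#' @export
#' @examples
#' reconstruct_table(0.682, 0.815, 22, 54)  # (15, 7, 10, 44)
reconstruct_table <- function(sensitivity, specificity, n_events, n_nonevents) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, specificity >= 0, specificity <= 1,
            n_events >= 1, n_nonevents >= 1)
  tp <- .round_half_up(sensitivity * n_events)
  tn <- .round_half_up(specificity * n_nonevents)
  contingency_table(tp = tp, fn = n_events - tp, fp = n_nonevents - tn, tn = tn)
}
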