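# Univariate logistic regression and k-fold cross-validated AUC.

# |slope| beyond this on the logit scale is treated as (quasi-)separation;
# the reported slope is capped here and flagged.
SLOPE_CAP <- 15

#' Univariate logistic regression of a binary outcome on one predictor
#'
#' Maximum-likelihood fit (iteratively reweighted least squares via
#' [stats::glm()]). Pairs with a missing predictor are dropped
#' (complete-case per feature). Separation is flagged when the fitted slope
#' magnitude exceeds 15 on the log-odds scale; the reported slope is then
#' capped at +/-15 — the ordering of predictions, and hence any AUC, is
#' unaffected by the cap.
#'
#' @param predictor Numeric vector (`NA` allowed).
#' @param outcomes 0/1 vector of the same length.
#' @param max_iter Maximum IRLS iterations.
#' @param tol Convergence tolerance (relative deviance change).
#' @return An object of class `"logistic_fit"`: `intercept`, `slope`,
#'   `converged`, `separation_detected`, `n_used`.
#' @export
#' @examples
#' fit <- fit_logistic(c(1, 1, 0, 0, 1, 0), c(1, 1, 1, 0, 0, 0))
#' exp(fit$slope)  # odds ratio
fit_logistic <- function(predictor, outcomes, max_iter = 100L, tol = 1e-12) {
  stopifnot(length(predictor) == length(outcomes))
  keep <- !is.na(predictor) & !is.na(outcomes)
  x <- as.numeric(predictor[keep])
  y <- as.numeric(outcomes[keep])
  if (!all(y %in% c(0, 1))) stop("'outcomes' must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("cannot fit: only one outcome class present", call. = FALSE)
  if (length(unique(x)) < 2L)
    stop("cannot fit: predictor is constant", call. = FALSE)
  fit <- suppressWarnings(stats::glm(
    y ~ x, family = stats::binomial(),
    control = stats::glm.control(epsilon = tol, maxit = max_iter)))
  b <- unname(stats::coef(fit))
  slope <- b[2]
  sep <- !is.finite(slope) || abs(slope) > SLOPE_CAP
  if (sep) slope <- sign(slope) * SLOPE_CAP
  structure(list(intercept = b[1], slope = slope,
                 converged = isTRUE(fit$converged) && !sep,
                 separation_detected = sep, n_used = length(y)),
            class = "logistic_fit")
}

#' Predicted event probabilities from a univariate logistic fit
#'
#' @param fit A [fit_logistic()] result.
#' @param predictor Numeric vector of predictor values.
#' @return Probabilities `plogis(intercept + slope * predictor)`.
#' @export
predict_prob <- function(fit, predictor) {
  stopifnot(inherits(fit, "logistic_fit"))
  stats::plogis(fit$intercept + fit$slope * as.numeric(predictor))
}

# Outcome-stratified fold labels in 1..k, reproducible from seed.
.make_folds <- function(outcomes, k, seed, stratified = TRUE) {
  n <- length(outcomes)
  .with_seed(seed, {
    folds <- integer(n)
    if (stratified) {
      for (cls in unique(outcomes)) {
        idx <- which(outcomes == cls)
        folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    } else {
      folds <- sample(rep_len(seq_len(k), n))
    }
    folds
  })
}

#' k-fold cross-validated AUC of a univariate logistic model
#'
#' Splits the complete-case data into `k` outcome-stratified folds, fits the
#' univariate logistic model on each set of `k - 1` folds, predicts the
#' held-out fold, and computes one AUC on the pooled out-of-fold predictions.
#' Pooling (rather than averaging per-fold AUCs) keeps the estimate defined
#' when folds contain very few events.
#'
#' @param predictor Numeric vector (`NA` allowed; complete-case).
#' @param outcomes 0/1 vector.
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling fold assignment.
#' @param stratified Stratify folds by outcome (default `TRUE`).
#' @return Cross-validated AUC in \[0, 1\].
#' @export
cv_auc <- function(predictor, outcomes, k = 10L, seed = 1L, stratified = TRUE) {
  stopifnot(length(predictor) == length(outcomes))
  keep <- !is.na(predictor) & !is.na(outcomes)
  x <- as.numeric(predictor[keep])
  y <- as.numeric(outcomes[keep])
  n <- length(y)
  if (n < k) stop("need at least k observations after dropping missing values",
                  call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("cannot cross-validate: only one outcome class present", call. = FALSE)
  folds <- .make_folds(y, k, seed, stratified)
  oof <- numeric(n)
  for (i in seq_len(k)) {
    tr <- folds != i
    if (!any(folds == i)) next
    if (length(unique(y[tr])) < 2L)
      stop(sprintf(paste("training data for fold %d contains a single outcome",
                         "class; use stratified folds or a smaller k"), i),
           call. = FALSE)
    f <- fit_logistic(x[tr], y[tr])
    oof[folds == i] <- predict_prob(f, x[folds == i])
  }
  auc_mann_whitney(oof, y)
}

#' Assess one feature: diagnostic statistics, AUC, cvAUC and rule weight
#'
#' Combines, for one cohort column, the 2x2 contingency statistics (odds
#' ratio with Haldane correction when needed, Fisher p, sensitivity,
#' specificity), the apparent AUC, the k-fold cross-validated AUC, and the
#' integer weight assigned by the cvAUC rule ([weight_from_cvauc()];
#' `NA` = excluded). The four-level capillaroscopy pattern is coded
#' 0 (normal) to 3 (late) for the logistic model and AUCs, and dichotomized
#' as "any scleroderma pattern" for the contingency statistics. When the
#' feature separates the outcome (a zero table cell), the reported OR comes
#' from the continuity-corrected table, not from the capped logistic slope.
#'
#' @param cohort Cohort data frame (see [generate_cohort()] / [read_cohort()]).
#' @param feature Column name to assess.
#' @param k,seed Cross-validation folds and fold seed.
#' @return An object of class `"feature_assessment"`.
#' @export
assess_feature <- function(cohort, feature, k = 10L, seed = 1L) {
  if (!feature %in% names(cohort))
    stop(sprintf("feature '%s' not found in cohort", feature), call. = FALSE)
  y <- cohort$outcome
  raw <- cohort[[feature]]
  if (is.character(raw) || is.factor(raw)) {
    num <- match(tolower(as.character(raw)), NC_LEVELS) - 1L
    bin <- as.integer(num > 0L)
  } else {
    num <- as.numeric(raw)
    bin <- as.integer(num)
  }
  tab <- contingency_from_predictions(y, bin)
  orr <- odds_ratio(tab, correction = "haldane_if_zero")
  ss <- sens_spec(tab)
  keep <- !is.na(num)
  auc <- auc_mann_whitney(num[keep], y[keep])
  cv <- cv_auc(num, y, k = k, seed = seed)
  structure(list(feature = feature, table = tab, or_estimate = orr,
                 sensitivity = unname(ss["sensitivity"]),
                 specificity = unname(ss["specificity"]),
                 auc = auc, cv_auc = cv,
                 weight = weight_from_cvauc(cv),
                 n_used = sum(keep)),
            class = "feature_assessment")
}

#' Assess every feature of a cohort
#'
#' Runs [assess_feature()] on each feature column and assembles the rows into
#' a table mirroring a published score-development table: odds ratio, 95% CI,
#' Fisher p, sensitivity, specificity, apparent and cross-validated AUC, and
#' the rule-based weight.
#'
#' @param cohort Cohort data frame.
#' @param features Character vector of columns to assess; defaults to every
#'   column except `patient_id` and `outcome`.
#' @param k,seed Passed to [assess_feature()].
#' @return A data frame with one row per feature.
#' @export
assess_cohort <- function(cohort, features = NULL, k = 10L, seed = 1L) {
  if (is.null(features))
    features <- setdiff(names(cohort), c("patient_id", "outcome"))
  rows <- lapply(features, function(f) {
    a <- assess_feature(cohort, f, k = k, seed = seed)
    data.frame(feature = f, or = a$or_estimate$or,
               ci_low = a$or_estimate$ci_low, ci_high = a$or_estimate$ci_high,
               p = a$or_estimate$p_value,
               sensitivity = a$sensitivity, specificity = a$specificity,
               auc = a$auc, cv_auc = a$cv_auc,
               weight = a$weight, n_used = a$n_used,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
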