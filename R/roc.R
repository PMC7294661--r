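# Empirical ROC analysis: curves, Mann-Whitney AUC, Youden cutoff, and the
# DeLong variance/covariance machinery for comparing two correlated AUCs.

#' Empirical ROC curve
#'
#' A patient is classified positive when `score >= threshold`. The curve has
#' one point per distinct observed score (ties grouped) plus the two
#' endpoints: a threshold above every score (sensitivity 0, specificity 1)
#' and the lowest score (sensitivity 1, specificity 0 only if every score is
#' reached). The AUC is the trapezoidal area under the
#' (1 - specificity, sensitivity) staircase.
#'
#' @param scores Numeric vector.
#' @param outcomes 0/1 vector of the same length.
#' @return An object of class `"roc_curve"` with `thresholds` (descending),
#'   `sensitivities`, `specificities`, `auc`.
#' @export
#' @examples
#' roc_curve(c(3, 2, 2, 1), c(1, 1, 0, 0))$auc  # 0.875
roc_curve <- function(scores, outcomes) {
  stopifnot(length(scores) == length(outcomes))
  keep <- !is.na(scores)
  s <- as.numeric(scores[keep]); y <- as.numeric(outcomes[keep])
  if (!all(y %in% c(0, 1))) stop("'outcomes' must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("ROC curve requires both outcome classes", call. = FALSE)
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  se <- vapply(thr, function(t) sum(s >= t & y == 1) / n1, 0)
  sp <- vapply(thr, function(t) sum(s < t & y == 0) / n0, 0)
  fpr <- 1 - sp
  auc <- sum(diff(fpr) * (utils::head(se, -1) + utils::tail(se, -1)) / 2)
  structure(list(thresholds = thr, sensitivities = se, specificities = sp,
                 auc = auc, n_events = n1, n_nonevents = n0),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("Empirical ROC: %d thresholds, %d events / %d non-events, AUC = %.3f\n",
              length(x$thresholds), x$n_events, x$n_nonevents, x$auc))
  invisible(x)
}

#' ROC points as a data frame
#'
#' @param x A `"roc_curve"`.
#' @param ... Unused.
#' @return Data frame with `threshold`, `sensitivity`, `specificity`.
#' @export
as.data.frame.roc_curve <- function(x, ...) {
  data.frame(threshold = x$thresholds, sensitivity = x$sensitivities,
             specificity = x$specificities)
}

#' Mann-Whitney AUC
#'
#' The probability that a randomly chosen event scores higher than a randomly
#' chosen non-event, with ties credited 0.5 — computed via midranks, which is
#' exactly the mean over all event/non-event pairs and equals the trapezoidal
#' ROC area. This is a code path independent of [roc_curve()], which the test
#' suite exploits as a cross-check.
#'
#' @param scores Numeric vector.
#' @param outcomes 0/1 vector.
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(scores, outcomes) {
  stopifnot(length(scores) == length(outcomes))
  keep <- !is.na(scores)
  s <- as.numeric(scores[keep]); y <- as.numeric(outcomes[keep])
  if (!all(y %in% c(0, 1))) stop("'outcomes' must be 0/1", call. = FALSE)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC requires both outcome classes", call. = FALSE)
  r <- rank(s)  # midranks handle ties as 0.5 credit
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement values: for each event, the fraction of non-events it
# outscores (ties 0.5), and vice versa. Returns list(v10, v01, auc).
.placements <- function(scores, outcomes) {
  s1 <- scores[outcomes == 1]; s0 <- scores[outcomes == 0]
  psi <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong variance of a single empirical AUC
#'
#' @param scores Numeric vector.
#' @param outcomes 0/1 vector.
#' @return The estimated sampling variance of the AUC.
#' @export
auc_variance_delong <- function(scores, outcomes) {
  keep <- !is.na(scores)
  s <- as.numeric(scores[keep]); y <- as.numeric(outcomes[keep])
  pl <- .placements(s, y)
  stats::var(pl$v10) / length(pl$v10) + stats::var(pl$v01) / length(pl$v01)
}

#' DeLong comparison of two correlated AUCs
#'
#' Both scores are measured on the same patients; the test accounts for their
#' correlation through the empirical covariance of per-patient placement
#' values. The two-sided test statistic `(auc_a - auc_b)^2 / var(diff)` is
#' referred to a chi-square distribution with 1 degree of freedom (equivalent
#' to a z-test). Identical scores (zero variance of the difference) are
#' reported as non-comparable with statistic 0 and p = 1.
#'
#' @param scores_a,scores_b Numeric score vectors for the same patients.
#' @param outcomes 0/1 vector.
#' @return An object of class `"auc_comparison"`: `auc_a`, `auc_b`,
#'   `variance_a`, `variance_b`, `covariance`, `statistic`, `p_value`.
#' @export
delong_compare <- function(scores_a, scores_b, outcomes) {
  stopifnot(length(scores_a) == length(outcomes),
            length(scores_b) == length(outcomes))
  y <- as.numeric(outcomes)
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2L)
    stop("'outcomes' must be 0/1 with both classes present", call. = FALSE)
  pa <- .placements(as.numeric(scores_a), y)
  pb <- .placements(as.numeric(scores_b), y)
  m <- length(pa$v10); n <- length(pa$v01)
  var_a <- stats::var(pa$v10) / m + stats::var(pa$v01) / n
  var_b <- stats::var(pb$v10) / m + stats::var(pb$v01) / n
  cov_ab <- stats::cov(pa$v10, pb$v10) / m + stats::cov(pa$v01, pb$v01) / n
  var_diff <- var_a + var_b - 2 * cov_ab
  if (!is.finite(var_diff) || var_diff <= .Machine$double.eps) {
    stat <- 0; p <- 1
  } else {
    stat <- (pa$auc - pb$auc)^2 / var_diff
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc,
                 variance_a = var_a, variance_b = var_b, covariance = cov_ab,
                 statistic = stat, p_value = p),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("DeLong: AUC %.3f vs %.3f, chi-square = %.2f (1 df), p = %.3g\n",
              x$auc_a, x$auc_b, x$statistic, x$p_value))
  invisible(x)
}

#' Optimal cutoff by the Youden index
#'
#' Returns the threshold maximizing sensitivity + specificity. Ties are
#' broken toward the higher sensitivity, then toward the lower threshold
#' (the more inclusive rule).
#'
#' @param roc A [roc_curve()].
#' @return List with `threshold`, `sensitivity`, `specificity`, `youden`
#'   (sensitivity + specificity - 1).
#' @export
best_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  j <- roc$sensitivities + roc$specificities
  ord <- order(-j, -roc$sensitivities, roc$thresholds)
  i <- ord[1]
  list(threshold = roc$thresholds[i],
       sensitivity = roc$sensitivities[i],
       specificity = roc$specificities[i],
       youden = j[i] - 1)
}
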