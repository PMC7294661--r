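# The CIP-DUS itself: the cvAUC-to-weight rule, the canonical published
# weight schemes, per-patient scoring and classification at a cutoff.

#' Integer weight from a cross-validated AUC
#'
#' The score-construction rule: a feature is excluded (`NA`) when its
#' cvAUC is at most 0.6; it receives weight 1 for cvAUC in (0.6, 0.65],
#' weight 2 in (0.65, 0.7], and weight 3 above 0.7.
#'
#' @param cvauc Numeric vector of cross-validated AUCs in \[0, 1\].
#' @return Integer vector of weights; `NA` means excluded.
#' @export
#' @examples
#' weight_from_cvauc(c(0.60, 0.64, 0.67, 0.76))  # NA 1 2 3
weight_from_cvauc <- function(cvauc) {
  stopifnot(is.numeric(cvauc), all(is.na(cvauc) | (cvauc >= 0 & cvauc <= 1)))
  w <- ifelse(cvauc > 0.7, 3L,
              ifelse(cvauc > 0.65, 2L,
                     ifelse(cvauc > 0.6, 1L, NA_integer_)))
  as.integer(w)
}

.nc_pattern_weights <- c(normal = 0L, early = 1L, active = 2L, late = 3L)

#' The canonical published CIP-DUS weight scheme
#'
#' Returns the score exactly as published: diffuse subtype 1, mRSS > 8 2,
#' PAH 1, present ulcers/pitting scars 3, history of ulcers/pitting scars 3,
#' capillaroscopy pattern 1/2/3 for early/active/late, reduced capillary
#' density 1, FOI missing enhancement 1, CDUS pathologic vessels 1 — maximum
#' 16 points. The imaging-free variant drops the FOI and CDUS features
#' (maximum 14 points). Note that two published weights deliberately depart
#' from [weight_from_cvauc()] applied to the printed cvAUCs (see
#' [weight_rule_audit()]); this function is the source of truth for the
#' published instrument, the rule is for building new scores.
#'
#' @param includes_imaging Include the FOI and CDUS components (default
#'   `TRUE`).
#' @return An object of class `"weight_scheme"`: `weights` (named integer
#'   vector over binary features), `nc_pattern_weights`, `includes_imaging`,
#'   `max_score`.
#' @export
#' @examples
#' canonical_weights()$max_score        # 16
#' canonical_weights(FALSE)$max_score   # 14
canonical_weights <- function(includes_imaging = TRUE) {
  w <- c(diffuse_subtype = 1L, mrss_gt8 = 2L, pah = 1L,
         present_du_ps = 3L, history_du_ps = 3L,
         nc_density_reduced = 1L,
         foi_missing_enhancement = 1L, cdus_pathologic_gt35 = 1L)
  if (!includes_imaging)
    w <- w[setdiff(names(w), c("foi_missing_enhancement", "cdus_pathologic_gt35"))]
  weight_scheme(w, includes_imaging = includes_imaging)
}

#' Construct a weight scheme
#'
#' @param weights Named non-negative integer vector: one entry per binary
#'   feature.
#' @param nc_pattern_weights Named integer vector over the capillaroscopy
#'   levels `normal`, `early`, `active`, `late`; set to `NULL` for schemes
#'   without the pattern component.
#' @param includes_imaging Bookkeeping flag.
#' @return An object of class `"weight_scheme"`.
#' @export
weight_scheme <- function(weights, nc_pattern_weights = .nc_pattern_weights,
                          includes_imaging = TRUE) {
  stopifnot(is.numeric(weights), length(weights) >= 1,
            !is.null(names(weights)), all(nzchar(names(weights))),
            all(weights >= 0), all(weights == as.integer(weights)))
  if (!is.null(nc_pattern_weights)) {
    stopifnot(setequal(names(nc_pattern_weights), NC_LEVELS),
              all(nc_pattern_weights >= 0))
    nc_pattern_weights <-
      stats::setNames(as.integer(nc_pattern_weights[NC_LEVELS]), NC_LEVELS)
  }
  max_score <- sum(weights) + if (is.null(nc_pattern_weights)) 0L else
    max(nc_pattern_weights)
  structure(list(weights = stats::setNames(as.integer(weights), names(weights)),
                 nc_pattern_weights = nc_pattern_weights,
                 includes_imaging = isTRUE(includes_imaging),
                 max_score = as.integer(max_score)),
            class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat(sprintf("Additive weight scheme (max %d points%s)\n", x$max_score,
              if (x$includes_imaging) "" else ", imaging-free"))
  for (f in names(x$weights)) cat(sprintf("  %-26s %d\n", f, x$weights[[f]]))
  if (!is.null(x$nc_pattern_weights))
    cat(sprintf("  %-26s %s\n", "nc_pattern",
                paste(sprintf("%s=%d", names(x$nc_pattern_weights),
                              x$nc_pattern_weights), collapse = " ")))
  invisible(x)
}

#' Compute additive scores for a cohort
#'
#' Each patient's score is the sum of the weights of their positive binary
#' features plus the weight of their capillaroscopy pattern level. Missing
#' components contribute 0 points and are counted in
#' `n_missing_components`, so incomplete patients get a (lower-bound) score
#' rather than none.
#'
#' @param cohort Cohort data frame; must contain every feature named in the
#'   scheme.
#' @param scheme A [weight_scheme()].
#' @param cutoff Classification cutoff (default 10): positive when
#'   `score >= cutoff`.
#' @return A data frame with `patient_id`, `score`, `n_missing_components`,
#'   `predicted_positive`, and one `pts_<feature>` column per component.
#' @export
#' @examples
#' cohort <- generate_cohort(cipdus_config(seed = 7))
#' head(compute_scores(cohort, canonical_weights()))
compute_scores <- function(cohort, scheme, cutoff = 10L) {
  stopifnot(inherits(scheme, "weight_scheme"))
  need <- names(scheme$weights)
  if (!is.null(scheme$nc_pattern_weights)) need <- c(need, "nc_pattern")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks scheme feature(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  n <- nrow(cohort)
  score <- integer(n)
  n_miss <- integer(n)
  comps <- list()
  for (f in names(scheme$weights)) {
    v <- cohort[[f]]
    if (!all(is.na(v) | v %in% c(0, 1)))
      stop(sprintf("feature '%s' must be binary 0/1 (or NA)", f), call. = FALSE)
    pts <- ifelse(is.na(v), 0L, as.integer(v) * scheme$weights[[f]])
    n_miss <- n_miss + is.na(v)
    score <- score + pts
    comps[[paste0("pts_", f)]] <- pts
  }
  if (!is.null(scheme$nc_pattern_weights)) {
    v <- tolower(as.character(cohort$nc_pattern))
    bad <- !is.na(v) & !v %in% NC_LEVELS
    if (any(bad))
      stop("unknown nc_pattern level(s): ", paste(unique(v[bad]), collapse = ", "),
           call. = FALSE)
    pts <- ifelse(is.na(v), 0L, scheme$nc_pattern_weights[v])
    n_miss <- n_miss + is.na(v)
    score <- score + pts
    comps[["pts_nc_pattern"]] <- as.integer(pts)
  }
  out <- data.frame(
    patient_id = if ("patient_id" %in% names(cohort)) cohort$patient_id
                 else sprintf("P%05d", seq_len(n)),
    score = as.integer(score),
    n_missing_components = n_miss,
    predicted_positive = classify(score, cutoff),
    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(comps))
}

#' Classify a score at a cutoff
#'
#' @param score Numeric vector of scores.
#' @param cutoff Threshold; positive when `score >= cutoff` (default 10).
#' @return Logical vector.
#' @export
#' @examples
#' classify(c(9, 10, 16))  # FALSE TRUE TRUE
classify <- function(score, cutoff = 10L) {
  score >= cutoff
}

#' Audit the cvAUC rule against the published weights
#'
#' Applies [weight_from_cvauc()] to each published cross-validated AUC and
#' compares with the weight the instrument actually assigns. Two binary
#' features are known departures — mRSS > 8 (cvAUC 0.73, rule says 3,
#' published weight 2) and PAH (cvAUC 0.54, rule says exclude, published
#' weight 1) — as is the early capillaroscopy pattern (cvAUC 0.55, rule says
#' exclude, published weight 1, following the explicit published grading of
#' the pattern levels).
#'
#' @return Data frame with `feature`, `cv_auc`, `rule_weight`,
#'   `published_weight`, `consistent`.
#' @export
weight_rule_audit <- function() {
  pub <- .cipdus_published()
  pub <- pub[!is.na(pub$cv_auc), c("feature", "cv_auc", "weight")]
  nc <- data.frame(feature = paste0("nc_pattern_", names(.nc_pattern_cv_auc)),
                   cv_auc = unname(.nc_pattern_cv_auc),
                   weight = unname(.nc_pattern_weights[names(.nc_pattern_cv_auc)]),
                   stringsAsFactors = FALSE)
  all <- rbind(pub, nc)
  rule <- weight_from_cvauc(all$cv_auc)
  data.frame(feature = all$feature, cv_auc = all$cv_auc,
             rule_weight = rule, published_weight = as.integer(all$weight),
             consistent = !is.na(rule) & rule == all$weight,
             stringsAsFactors = FALSE)
}

#' Write / read a weight scheme as JSON
#'
#' @param scheme A [weight_scheme()].
#' @param path File path.
#' @return `write_weight_scheme` returns `path` invisibly;
#'   `read_weight_scheme` returns the scheme.
#' @export
write_weight_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "weight_scheme"))
  jsonlite::write_json(list(weights = as.list(scheme$weights),
                            nc_pattern_weights = as.list(scheme$nc_pattern_weights),
                            includes_imaging = scheme$includes_imaging),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_weight_scheme
#' @export
read_weight_scheme <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  weight_scheme(unlist(x$weights),
                nc_pattern_weights = if (length(x$nc_pattern_weights))
                  unlist(x$nc_pattern_weights) else NULL,
                includes_imaging = isTRUE(x$includes_imaging))
}
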