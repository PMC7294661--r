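# Published development-study summary statistics for the CIP-DUS.
# These printed values (sensitivity, specificity, cross-validated AUC, weight,
# odds ratio) are the fixed parameterization behind cipdus_config() and
# replicate_published_numbers(); they are data, not estimates made here.

.cipdus_published <- function() {
  df <- data.frame(
    feature = c("diffuse_subtype", "mrss_gt8", "pah", "present_du_ps",
                "history_du_ps", "nc_pattern_any", "nc_density_reduced",
                "foi_missing_enhancement", "cdus_pathologic_gt35"),
    label = c(
      "SSc diffuse subtype",
      "Modified Rodnan skin score > 8",
      "Pulmonary arterial hypertension",
      "Present digital ulcers or pitting scars at baseline",
      "History of digital ulcers or pitting scars",
      "NC scleroderma pattern (any of early/active/late)",
      "Reduced capillary density (<7/mm) digit III right hand",
      "Missing initial FOI enhancement digit III right hand",
      "Pathologic vessels > 35% in CDUS"
    ),
    sensitivity = c(0.591, 0.682, 0.273, 0.909, 1.000, 1.000, 0.947, 0.563, 0.682),
    specificity = c(0.741, 0.815, 0.926, 0.611, 0.444, 0.289, 0.333, 0.750, 0.667),
    # event / non-event denominators implied by the printed proportions
    n_events    = c(22L, 22L, 22L, 22L, 22L, 22L, 19L, 16L, 22L),
    n_nonevents = c(54L, 54L, 54L, 54L, 54L, 54L, 45L, 44L, 54L),
    cv_auc = c(0.65, 0.73, 0.54, 0.76, 0.77, NA, 0.61, 0.61, 0.64),
    weight = c(1L, 2L, 1L, 3L, 3L, NA, 1L, 1L, 1L),
    or_printed = c(4.1, 9.4, 4.7, 15.7, 36.2, 18.6, 9.0, 3.9, 4.3),
    stringsAsFactors = FALSE
  )
  df
}

# cvAUCs printed for the three scleroderma capillaroscopy pattern grades
.nc_pattern_cv_auc <- c(early = 0.55, active = 0.67, late = 0.76)

#' Published per-feature summary statistics of the CIP-DUS development cohort
#'
#' Returns the printed per-feature diagnostic statistics of the score's
#' development study (22 patients with new digital ulcers at ~12-month
#' follow-up, 54 without): sensitivity, specificity, the event/non-event
#' denominators implied by those proportions, the cross-validated AUC, the
#' published weight, and the published odds ratio. These values parameterize
#' [cipdus_config()] and are the reference for [replicate_published_numbers()]
#' and [weight_rule_audit()].
#'
#' @return A data frame with one row per candidate score feature.
#' @export
#' @examples
#' published_feature_stats()[, c("feature", "sensitivity", "specificity", "weight")]
published_feature_stats <- function() {
  .cipdus_published()
}
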