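# Descriptors consumed by the pattern search: total WML volume plus the
# four relative regional volumes (WMLr, % of the total).

#' Relative regional WML volumes
#'
#' Computes, from non-negative regional lesion volumes, the five
#' descriptors of the pattern search: the total WML volume (ml) and the
#' relative WML volume of each region,
#' `WMLr = 100 * region / total` (%). When the total volume is zero the
#' four WMLr values are defined as 0 and the `zero_total` flag is raised;
#' such subjects carry no spatial information and always fall below any
#' positive total-volume threshold.
#'
#' @param frontal,parietal,temporal,occipital regional WML volumes in ml
#'   (vectors of equal length).
#' @param total optional pre-computed total; when supplied it must equal
#'   the sum of the four regions within `1e-9` ml, otherwise it is an
#'   error. By default the total is the sum of the regions.
#' @return A data frame with columns `total_wml`, `frontal_wmlr`,
#'   `parietal_wmlr`, `temporal_wmlr`, `occipital_wmlr` (all WMLr in
#'   percent, summing to 100 whenever `total_wml > 0`) and the logical
#'   audit flag `zero_total`.
#' @examples
#' compute_wmlr(1, 1, 1, 1)        # each region 25%
#' compute_wmlr(1.15, 0.56, 0.05, 0.03)
#' @export
compute_wmlr <- function(frontal, parietal, temporal, occipital,
                         total = NULL) {
  vols <- cbind(frontal, parietal, temporal, occipital)
  if (anyNA(vols)) stop("missing regional volume", call. = FALSE)
  if (any(vols < 0)) stop("negative regional volume", call. = FALSE)
  sums <- rowSums(vols)
  if (is.null(total)) {
    total <- sums
  } else if (any(abs(total - sums) > ADDITIVITY_TOL)) {
    stop("total does not equal the sum of the regional volumes",
         call. = FALSE)
  }
  zero <- total == 0
  denom <- ifelse(zero, 1, total)
  data.frame(total_wml = total,
             frontal_wmlr = 100 * frontal / denom,
             parietal_wmlr = 100 * parietal / denom,
             temporal_wmlr = 100 * temporal / denom,
             occipital_wmlr = 100 * occipital / denom,
             zero_total = zero)
}

#' Feature table for a cohort
#'
#' Applies [compute_wmlr()] to every subject's baseline regional volumes.
#'
#' @param cohort a [wml_cohort].
#' @return Data frame with `subject_id`, the five descriptor columns and
#'   the `zero_total` flag, in baseline order (the exact input schema of
#'   the pattern-search stage).
#' @export
wml_features <- function(cohort) {
  b <- cohort$baseline
  f <- compute_wmlr(b$wml_frontal, b$wml_parietal, b$wml_temporal,
                    b$wml_occipital, total = b$wml_total)
  cbind(data.frame(subject_id = b$subject_id, stringsAsFactors = FALSE), f)
}
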