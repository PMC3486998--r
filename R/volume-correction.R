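#' Estimate the statistical lung-volume correction slope
#'
#' Ordinary least-squares slope (with intercept) of the per-subject
#' between-visit measure differences on the corresponding between-visit
#' volume differences. The slope expresses how much of the repeat-examination
#' change in an air-trapping measure is attributable to breath-hold volume
#' differences under a simple linear relation.
#'
#' @param delta_measure per-subject between-visit differences of the measure
#'   (baseline minus repeat).
#' @param delta_volume per-subject between-visit differences of the paired
#'   covariate volume, litres (expiratory volume for the low-attenuation
#'   fraction, exhaled volume for the E/I density ratio).
#' @return Slope in measure units per litre.
#' @export
#' @examples
#' estimate_correction_slope(c(2, 4, 6), c(1, 2, 3)) # 2
estimate_correction_slope <- function(delta_measure, delta_volume) {
  if (length(delta_measure) != length(delta_volume))
    stop("delta_measure and delta_volume must have equal length")
  if (length(delta_measure) < 3) stop("at least 3 subjects are required")
  if (stats::var(delta_volume) == 0)
    stop("degenerate fit: volume differences have zero variance")
  unname(stats::coef(stats::lm(delta_measure ~ delta_volume))[2])
}

#' Apply the linear lung-volume correction
#'
#' Shifts a measure to the value it would take at the subject's reference
#' volume: `corrected = measure - slope * (volume - ref_volume)`. The
#' reference is the mean of the subject's two visit volumes, so each
#' subject's pair mean is preserved. The output is deliberately not clamped:
#' the linear correction can push a percentage measure below zero, an
#' artefact worth surfacing rather than hiding.
#'
#' @param measure measure value(s).
#' @param volume covariate volume at acquisition, L.
#' @param ref_volume subject reference volume (pair mean), L.
#' @param slope correction slope from [estimate_correction_slope()].
#' @return Corrected measure value(s).
#' @export
#' @examples
#' apply_volume_correction(5, 4, 1, 2) # -1: negative values are possible
apply_volume_correction <- function(measure, volume, ref_volume, slope) {
  stopifnot(is.finite(slope))
  measure - slope * (volume - ref_volume)
}

#' Volume-correct the air-trapping measures of a cohort table
#'
#' Fits one correction slope per measure on the cohort's between-visit
#' differences (the low-attenuation fraction against expiratory volume, the
#' E/I density ratio against exhaled volume) and appends corrected columns
#' `exp856_volcorr_pct` and `ei_ratio_volcorr_pct`. The slope is estimated on
#' the same cohort it corrects; the fitted models are attached as
#' `attr(, "correction_models")` and logged in pipeline reports.
#'
#' @param measures data frame from [measure_cohort()], both visits present
#'   for every subject.
#' @return The input data frame with two extra columns and a
#'   `correction_models` attribute (list of per-measure model descriptors).
#' @export
correct_measures <- function(measures) {
  need <- c("subject_id", "visit", "v_exp_L", "v_exhaled_L",
            "exp856_pct", "ei_ratio_pct")
  if (!all(need %in% names(measures)))
    stop("`measures` lacks required columns: ",
         paste(setdiff(need, names(measures)), collapse = ", "))
  m1 <- measures[measures$visit == 1, ]
  m2 <- measures[measures$visit == 2, ]
  m2 <- m2[match(m1$subject_id, m2$subject_id), ]
  if (any(is.na(m2$subject_id)))
    stop("every subject needs both visits for volume correction")
  # identical visit volumes (e.g. zero-variation verification runs) leave the
  # slope unidentifiable; the correction then degrades to the identity
  safe_slope <- function(dm, dv) {
    if (stats::var(dv) == 0) list(slope = 0, degenerate = TRUE)
    else list(slope = estimate_correction_slope(dm, dv), degenerate = FALSE)
  }
  s_exp <- safe_slope(m1$exp856_pct - m2$exp856_pct, m1$v_exp_L - m2$v_exp_L)
  s_ei <- safe_slope(m1$ei_ratio_pct - m2$ei_ratio_pct,
                     m1$v_exhaled_L - m2$v_exhaled_L)
  models <- list(
    exp856 = list(measure = "exp856_pct", covariate = "v_exp_L",
                  slope = s_exp$slope, degenerate = s_exp$degenerate,
                  reference = "subject pair-mean expiratory volume"),
    ei_ratio = list(measure = "ei_ratio_pct", covariate = "v_exhaled_L",
                    slope = s_ei$slope, degenerate = s_ei$degenerate,
                    reference = "subject pair-mean exhaled volume"))
  ref_exp <- (m1$v_exp_L + m2$v_exp_L) / 2
  ref_exh <- (m1$v_exhaled_L + m2$v_exhaled_L) / 2
  i <- match(measures$subject_id, m1$subject_id)
  measures$exp856_volcorr_pct <- apply_volume_correction(
    measures$exp856_pct, measures$v_exp_L, ref_exp[i], models$exp856$slope)
  measures$ei_ratio_volcorr_pct <- apply_volume_correction(
    measures$ei_ratio_pct, measures$v_exhaled_L, ref_exh[i],
    models$ei_ratio$slope)
  attr(measures, "correction_models") <- models
  measures
}
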