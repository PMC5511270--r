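#' Clinical dichotomisation thresholds
#'
#' Cutoffs used to derive the binary clinical flags from raw admission
#' measurements. Defaults follow the standard paediatric HFMD criteria:
#' elevated white blood cell count at WBC >= 15 x 10^9/L (inclusive),
#' hyperglycemia at blood glucose > 8.3 mmol/L (strict), fever when body
#' temperature >= 37.5 degC, prolonged fever at >= 3 days, tachycardia over
#' 160/140/120 beats/min for infants (< 12 months), toddlers (12 to < 36
#' months) and children (>= 36 months) respectively, and hypertension when
#' systolic blood pressure exceeds the age-expected value by more than
#' 20 mmHg, with expected SBP = 2 x age(years) + 80 mmHg.
#'
#' @param wbc_cutoff elevated-WBC cutoff, x 10^9/L; inclusive (`>=`).
#' @param glucose_cutoff hyperglycemia cutoff, mmol/L; strict (`>`).
#' @param fever_temp_cutoff fever temperature cutoff, degC; inclusive.
#' @param fever_days_cutoff prolonged-fever cutoff, days; inclusive.
#' @param tachycardia_cutoffs named numeric vector of heart-rate cutoffs
#'   (beats/min, strict `>`) for age classes `infant`, `toddler`, `child`.
#' @param hypertension_excess mmHg above age-expected SBP; strict (`>`).
#' @param sbp_expected function of age in months returning the expected
#'   systolic blood pressure in mmHg.
#' @return An object of class `clinical_thresholds`.
#' @export
#' @examples
#' th <- clinical_thresholds()
#' derive_clinical_flags(list(age = 30, wbc = 15, glucose = 8.3,
#'                            fever_duration = 4, heart_rate = 130,
#'                            sbp = 100), th)
clinical_thresholds <- function(wbc_cutoff = 15,
                                glucose_cutoff = 8.3,
                                fever_temp_cutoff = 37.5,
                                fever_days_cutoff = 3,
                                tachycardia_cutoffs = c(infant = 160,
                                                        toddler = 140,
                                                        child = 120),
                                hypertension_excess = 20,
                                sbp_expected = function(age_months)
                                  (age_months / 12) * 2 + 80) {
  stopifnot(wbc_cutoff > 0, glucose_cutoff > 0, fever_temp_cutoff > 0,
            fever_days_cutoff > 0, all(tachycardia_cutoffs > 0),
            hypertension_excess > 0,
            all(c("infant", "toddler", "child") %in%
                  names(tachycardia_cutoffs)))
  structure(list(wbc_cutoff = wbc_cutoff,
                 glucose_cutoff = glucose_cutoff,
                 fever_temp_cutoff = fever_temp_cutoff,
                 fever_days_cutoff = fever_days_cutoff,
                 tachycardia_cutoffs = tachycardia_cutoffs,
                 hypertension_excess = hypertension_excess,
                 sbp_expected = sbp_expected),
            class = "clinical_thresholds")
}

# Age class for the tachycardia cutoff; boundaries: infant < 12 months,
# toddler 12 to < 36 months, child >= 36 months.
age_class <- function(age_months) {
  ifelse(age_months < 12, "infant",
         ifelse(age_months < 36, "toddler", "child"))
}

#' Derive binary clinical flags from raw measurements
#'
#' Applies the configured cutoffs to one patient record or, vectorised, to a
#' whole cohort. Boundary behaviour is exactly as configured: the WBC cutoff
#' is inclusive (15.0 is elevated), the glucose cutoff strict (8.3 is not
#' hyperglycemic), fever duration inclusive, tachycardia and hypertension
#' strict. A missing measurement yields a missing (`NA`) flag, never a
#' silent `FALSE`. The derivation is deterministic, idempotent and
#' per-record (order-independent across records).
#'
#' @param record a named list or single-row data frame with (any of) the
#'   fields `age` (months), `wbc`, `glucose`, `fever_duration`,
#'   `heart_rate`, `sbp`; absent fields are treated as missing. For
#'   cohort-level use see [cohort_model_frame()].
#' @param thresholds a [clinical_thresholds()] object.
#' @return Named logical vector (possibly `NA`) with elements
#'   `elevated_wbc`, `hyperglycemia`, `fever_ge_3_days`, `tachycardia`,
#'   `hypertension`.
#' @export
derive_clinical_flags <- function(record, thresholds = clinical_thresholds()) {
  stopifnot(inherits(thresholds, "clinical_thresholds"))
  gv <- function(f) {
    v <- record[[f]]
    if (is.null(v) || length(v) == 0) NA_real_ else as.numeric(v[[1]])
  }
  age <- gv("age")
  hr_cut <- if (is.na(age)) NA_real_ else
    unname(thresholds$tachycardia_cutoffs[age_class(age)])
  sbp_exp <- if (is.na(age)) NA_real_ else thresholds$sbp_expected(age)
  c(elevated_wbc   = gv("wbc") >= thresholds$wbc_cutoff,
    hyperglycemia  = gv("glucose") > thresholds$glucose_cutoff,
    fever_ge_3_days = gv("fever_duration") >= thresholds$fever_days_cutoff,
    tachycardia    = gv("heart_rate") > hr_cut,
    hypertension   = gv("sbp") > sbp_exp + thresholds$hypertension_excess)
}
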