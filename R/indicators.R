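# Derivation of the six analysis indicators from raw survey variables.
#
# Each derivation is a pure, vectorised function with missing-aware
# (three-valued) OR semantics: an indicator is 1 as soon as any observed
# criterion forces it, 0 only when every criterion is observed false, and
# missing otherwise, so that incompletely measured participants end up with
# imputable indicators instead of spurious zeros.

#' Clinical cut-offs defining the risk-factor indicators
#'
#' @param sbp_cut systolic blood pressure threshold, mmHg (default 140).
#' @param dbp_cut diastolic blood pressure threshold, mmHg (default 90).
#' @param tc_cut total cholesterol threshold, mmol/l (default 5).
#' @param hba1c_cut glycohemoglobin threshold, mmol/mol (default 48).
#' @param bmi_overweight,bmi_obese BMI category boundaries, kg/m^2
#'   (defaults 25 and 30; intervals are half-open, lower bound included).
#' @return an object of class `indicator_thresholds`.
#' @export
indicator_thresholds <- function(sbp_cut = 140, dbp_cut = 90, tc_cut = 5,
                                 hba1c_cut = 48, bmi_overweight = 25,
                                 bmi_obese = 30) {
  stopifnot(sbp_cut > 0, dbp_cut > 0, tc_cut > 0, hba1c_cut > 0,
            bmi_overweight > 0, bmi_overweight < bmi_obese)
  structure(list(sbp_cut = sbp_cut, dbp_cut = dbp_cut, tc_cut = tc_cut,
                 hba1c_cut = hba1c_cut, bmi_overweight = bmi_overweight,
                 bmi_obese = bmi_obese),
            class = "indicator_thresholds")
}

# Recency levels of the "when did you last smoke" item, most recent first.
SMOKING_RECENCY_LEVELS <- c("today", "past_30_days", "past_year", "over_a_year")

as_yesno <- function(x) {
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) return(as.integer(x))
  out <- rep(NA_integer_, length(x))
  out[x %in% c("yes", "Yes", "1", "TRUE")] <- 1L
  out[x %in% c("no", "No", "0", "FALSE")] <- 0L
  out
}

#' Derive current smoking
#'
#' Current smokers have ever smoked regularly and last smoked within the
#' recency window (by default within the past 30 days). Never-regular smokers
#' are 0 regardless of the recency item; regular ever-smokers with an
#' unobserved recency are missing, as are records with the ever-regular item
#' unobserved.
#'
#' @param ever_regular yes/no (character, logical or 0/1): ever smoked
#'   regularly.
#' @param last_smoked recency category, one of
#'   `r paste(SMOKING_RECENCY_LEVELS, collapse = ", ")`.
#' @param current_levels recency levels counted as current smoking.
#' @return integer vector of 0/1/NA.
#' @export
derive_smoking <- function(ever_regular, last_smoked,
                           current_levels = c("today", "past_30_days")) {
  ever <- as_yesno(ever_regular)
  last <- as.character(last_smoked)
  recent <- rep(NA_integer_, length(last))
  recent[!is.na(last) & last %in% current_levels] <- 1L
  recent[!is.na(last) & !(last %in% current_levels)] <- 0L
  out <- rep(NA_integer_, max(length(ever), length(recent)))
  ever <- rep_len(ever, length(out)); recent <- rep_len(recent, length(out))
  out[!is.na(ever) & ever == 0L] <- 0L
  out[!is.na(ever) & ever == 1L & !is.na(recent)] <- recent[
    !is.na(ever) & ever == 1L & !is.na(recent)]
  out
}

#' Derive leisure time sedentary lifestyle
#'
#' The four-level leisure-time physical activity item is dichotomised: only
#' the most inactive level (reading/TV/light household tasks) counts as a
#' sedentary lifestyle.
#'
#' @param leisure_activity integer 1-4 (1 = most inactive) or NA.
#' @param sedentary_level the level coded as sedentary (default 1).
#' @return integer vector of 0/1/NA.
#' @export
derive_sedentary <- function(leisure_activity, sedentary_level = 1L) {
  x <- as.integer(leisure_activity)
  out <- rep(NA_integer_, length(x))
  out[!is.na(x)] <- as.integer(x[!is.na(x)] == sedentary_level)
  out
}

#' Derive hypertension
#'
#' Hypertension is systolic pressure at or above the systolic cut-off, and/or
#' diastolic pressure at or above the diastolic cut-off, and/or reported use
#' of blood-pressure medication within the last seven days, combined with
#' missing-aware OR semantics.
#'
#' @param sbp,dbp blood pressures, mmHg.
#' @param bp_medication yes/no medication use in the last seven days.
#' @param thresholds an [indicator_thresholds()].
#' @return integer vector of 0/1/NA.
#' @export
derive_hypertension <- function(sbp, dbp, bp_medication,
                                thresholds = indicator_thresholds()) {
  check_positive(sbp, "sbp"); check_positive(dbp, "dbp")
  kleene_or(ge_or_na(sbp, thresholds$sbp_cut),
            ge_or_na(dbp, thresholds$dbp_cut),
            as_yesno(bp_medication))
}

#' Derive elevated total cholesterol
#'
#' Elevated if total cholesterol is at or above the cut-off (inclusive)
#' and/or the person currently uses cholesterol-lowering medication.
#'
#' @param total_cholesterol mmol/l.
#' @param lipid_medication yes/no.
#' @inheritParams derive_hypertension
#' @return integer vector of 0/1/NA.
#' @export
derive_elevated_cholesterol <- function(total_cholesterol, lipid_medication,
                                        thresholds = indicator_thresholds()) {
  check_positive(total_cholesterol, "total_cholesterol")
  kleene_or(ge_or_na(total_cholesterol, thresholds$tc_cut),
            as_yesno(lipid_medication))
}

#' Derive the three-level BMI category
#'
#' BMI = weight / height^2 with height in metres; categories are the
#' half-open intervals [0, 25) normal weight (underweight merged in),
#' [25, 30) overweight, and [30, Inf) obese. Missing height or weight yields
#' a missing category.
#'
#' @param height_cm height in centimetres.
#' @param weight_kg weight in kilograms.
#' @inheritParams derive_hypertension
#' @return factor with levels normal/overweight/obese (NA allowed).
#' @export
derive_bmi_category <- function(height_cm, weight_kg,
                                thresholds = indicator_thresholds()) {
  if (any(height_cm <= 0, na.rm = TRUE) || any(weight_kg <= 0, na.rm = TRUE))
    stop("height and weight must be positive")
  bmi <- weight_kg / (height_cm / 100)^2
  cut(bmi, breaks = c(0, thresholds$bmi_overweight, thresholds$bmi_obese, Inf),
      labels = BMI_LEVELS, right = FALSE)
}

#' Derive diabetes (any type)
#'
#' Diabetes is current use of diabetes medication and/or glycohemoglobin at
#' or above the HbA1c cut-off. In waves without an HbA1c assay the laboratory
#' criterion is undecidable, so non-medicated participants come out missing
#' (to be imputed) rather than 0 — coding them 0 would bias the trend.
#'
#' @param diabetes_medication yes/no.
#' @param hba1c glycohemoglobin, mmol/mol (NA where not assayed).
#' @param hba1c_available logical: set `FALSE` to force the laboratory
#'   criterion undecidable for a whole wave.
#' @inheritParams derive_hypertension
#' @return integer vector of 0/1/NA.
#' @export
derive_diabetes <- function(diabetes_medication, hba1c,
                            thresholds = indicator_thresholds(),
                            hba1c_available = TRUE) {
  check_positive(hba1c, "hba1c")
  lab <- ge_or_na(hba1c, thresholds$hba1c_cut)
  if (!isTRUE(hba1c_available)) lab <- rep(NA_integer_, length(lab))
  kleene_or(as_yesno(diabetes_medication), lab)
}

ge_or_na <- function(x, cut) {
  out <- rep(NA_integer_, length(x))
  out[!is.na(x)] <- as.integer(x[!is.na(x)] >= cut)
  out
}

check_positive <- function(x, name) {
  if (is.numeric(x) && any(x <= 0, na.rm = TRUE))
    stop("non-positive values in ", name)
  invisible(x)
}

#' Derive all indicators from a raw survey table
#'
#' Maps a raw table (one row per invited person) to the analysis indicator
#' frame used downstream. Expected raw columns: `year`, `sex`, `age`, `area`,
#' `marital`, `education`, `ever_smoked_regularly`, `last_smoked`,
#' `leisure_activity`, `sbp`, `dbp`, `bp_medication`, `total_cholesterol`,
#' `lipid_medication`, `height_cm`, `weight_kg`, `diabetes_medication`,
#' `hba1c`, `participation`; any value may be missing. Waves listed in
#' `hba1c_missing_years` have the HbA1c criterion treated as unavailable.
#'
#' @param raw data frame of raw records.
#' @param thresholds an [indicator_thresholds()].
#' @param hba1c_missing_years waves without an HbA1c assay
#'   (default 1997 and 2007).
#' @return a survey frame with the derived indicator columns.
#' @export
derive_indicators <- function(raw, thresholds = indicator_thresholds(),
                              hba1c_missing_years = c(1997, 2007)) {
  out <- new_survey_frame(nrow(raw))
  out$year <- as.integer(raw$year)
  out$sex <- factor(as.character(raw$sex), levels = SEX_LEVELS)
  out$age <- as.integer(raw$age)
  out$area <- factor(as.character(raw$area), levels = levels(out$area))
  out$marital <- as_yesno(raw$marital)
  out$education <- factor(as.character(raw$education),
                          levels = EDUCATION_LEVELS)
  out$smoking <- derive_smoking(raw$ever_smoked_regularly, raw$last_smoked)
  out$sedentary <- derive_sedentary(raw$leisure_activity)
  out$hypertension <- derive_hypertension(raw$sbp, raw$dbp, raw$bp_medication,
                                          thresholds)
  out$elevated_tc <- derive_elevated_cholesterol(raw$total_cholesterol,
                                                 raw$lipid_medication,
                                                 thresholds)
  out$bmi_cat <- derive_bmi_category(raw$height_cm, raw$weight_kg, thresholds)
  hba1c <- raw$hba1c
  avail <- !(out$year %in% hba1c_missing_years)
  hba1c[!avail] <- NA
  out$diabetes <- derive_diabetes(raw$diabetes_medication, hba1c, thresholds)
  out$participation <- if (!is.null(raw$participation))
    as.logical(raw$participation) else TRUE
  out
}
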