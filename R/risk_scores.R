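#' CHA2DS2-VASc stroke-risk score
#'
#' Additive stroke-risk score for atrial fibrillation: congestive heart
#' failure (1), hypertension (1), age 75+ (2) or 65--74 (1), diabetes (1),
#' prior stroke/TIA (2), vascular disease (1), female sex (1). Total range
#' 0--9. All arguments are vectorized and recycled by the usual rules.
#'
#' @param age Age in years, non-negative.
#' @param sex Character, \code{"male"} or \code{"female"}.
#' @param chf,hypertension,diabetes,stroke_tia_history,vascular_disease
#'   Logical component flags.
#' @return Integer vector of scores in 0..9.
#' @examples
#' cha2ds2_vasc(66, "male")   # 1 (age band only)
#' cha2ds2_vasc(80, "female") # 3
#' @export
cha2ds2_vasc <- function(age, sex, chf = FALSE, hypertension = FALSE,
                         diabetes = FALSE, stroke_tia_history = FALSE,
                         vascular_disease = FALSE) {
  if (anyNA(age) || any(age < 0)) tte_stop("'age' must be non-negative")
  if (!all(sex %in% c("male", "female"))) {
    tte_stop("'sex' must be 'male' or 'female'")
  }
  age_pts <- ifelse(age >= 75, 2L, ifelse(age >= 65, 1L, 0L))
  score <- age_pts +
    as.integer(chf) + as.integer(hypertension) + as.integer(diabetes) +
    2L * as.integer(stroke_tia_history) + as.integer(vascular_disease) +
    as.integer(sex == "female")
  as.integer(score)
}

#' HAS-BLED bleeding-risk score
#'
#' One point each for uncontrolled hypertension, renal disease, liver
#' disease, prior stroke, bleeding history, labile INR, age over 65,
#' antiplatelet/NSAID use, and alcohol use; capped at 9. The original
#' score's drug/alcohol item can contribute two points (one each); here the
#' two are scored as separate flags with the same cap.
#'
#' @param age Age in years.
#' @param uncontrolled_htn,renal_disease,liver_disease,stroke_tia_history,
#'   bleeding_history,labile_inr,antiplatelet_or_nsaid,alcohol_use Logical
#'   component flags (vectorized).
#' @return Integer vector of scores in 0..9.
#' @examples
#' has_bled(60)  # 0
#' has_bled(70)  # 1, age only
#' @export
has_bled <- function(age, uncontrolled_htn = FALSE, renal_disease = FALSE,
                     liver_disease = FALSE, stroke_tia_history = FALSE,
                     bleeding_history = FALSE, labile_inr = FALSE,
                     antiplatelet_or_nsaid = FALSE, alcohol_use = FALSE) {
  if (anyNA(age) || any(age < 0)) tte_stop("'age' must be non-negative")
  score <- as.integer(uncontrolled_htn) + as.integer(renal_disease) +
    as.integer(liver_disease) + as.integer(stroke_tia_history) +
    as.integer(bleeding_history) + as.integer(labile_inr) +
    as.integer(age > 65) + as.integer(antiplatelet_or_nsaid) +
    as.integer(alcohol_use)
  as.integer(pmin(score, 9L))
}
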