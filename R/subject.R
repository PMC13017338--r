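#' Construct a CPET subject record
#'
#' A subject is one maximal-effort CPET record: demographics, anthropometrics,
#' test modality and the measured peak oxygen uptake. Stored as a one-row
#' data frame so that single subjects and cohorts share the same schema.
#'
#' @param id Opaque subject label.
#' @param age Age in years (15-90).
#' @param sex `"male"` or `"female"`.
#' @param height Standing height in cm (120-220).
#' @param weight Body mass in kg (30-250).
#' @param mode Test modality, `"treadmill"` or `"cycle"`.
#' @param measured_vo2 Measured V̇O2peak in mL/min (> 0).
#' @param race Optional race label (`"white"`, `"black"`, `"asian"`,
#'   `"other"`); unknown values map to `"other"` at regression time.
#' @param ethnicity Optional ethnicity label.
#' @return One-row data frame with class `c("cpet_cohort", "data.frame")`.
#' @examples
#' s <- cpet_subject("case", 37, "male", 67 * 2.54, 280 * 0.453592,
#'                   "treadmill", 3560)
#' s$weight   # 127.00576 kg
#' @export
cpet_subject <- function(id, age, sex, height, weight, mode, measured_vo2,
                         race = NA_character_, ethnicity = NA_character_) {
  df <- data.frame(
    id = as.character(id), age = as.numeric(age), sex = as.character(sex),
    height = as.numeric(height), weight = as.numeric(weight),
    mode = as.character(mode), measured_vo2 = as.numeric(measured_vo2),
    race = as.character(race), ethnicity = as.character(ethnicity),
    stringsAsFactors = FALSE
  )
  validate_cohort(df)
}

#' Validate a cohort table
#'
#' Checks every subject against the record invariants (field presence, sex
#' and mode codes, age/height/weight bounds, positive measured V̇O2,
#' duplicate ids), accumulating all problems and reporting them with row
#' numbers rather than failing at the first.
#'
#' @param cohort Data frame with columns `id, age, sex, height, weight, mode,
#'   measured_vo2` and optionally `race, ethnicity`.
#' @return The cohort, with class `"cpet_cohort"` prepended, invisibly
#'   returned visible (so it can be piped).
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  required <- c("id", "age", "sex", "height", "weight", "mode", "measured_vo2")
  missing <- setdiff(required, names(cohort))
  if (length(missing)) {
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!"race" %in% names(cohort)) cohort$race <- NA_character_
  if (!"ethnicity" %in% names(cohort)) cohort$ethnicity <- NA_character_
  errs <- character(0)
  n <- nrow(cohort)
  if (n > 0) {
    bad <- function(cond, msg) {
      idx <- which(cond)
      if (length(idx)) {
        errs <<- c(errs, sprintf("row %d (id %s): %s", idx,
                                 cohort$id[idx], msg))
      }
    }
    bad(!cohort$sex %in% SEXES, "sex must be 'male' or 'female'")
    bad(!cohort$mode %in% MODES, "mode must be 'treadmill' or 'cycle'")
    bad(!is.finite(cohort$age) | cohort$age < SUBJECT_BOUNDS$age[1] |
          cohort$age > SUBJECT_BOUNDS$age[2],
        sprintf("age outside [%g, %g] years", SUBJECT_BOUNDS$age[1],
                SUBJECT_BOUNDS$age[2]))
    bad(!is.finite(cohort$height) | cohort$height < SUBJECT_BOUNDS$height[1] |
          cohort$height > SUBJECT_BOUNDS$height[2],
        sprintf("height outside [%g, %g] cm", SUBJECT_BOUNDS$height[1],
                SUBJECT_BOUNDS$height[2]))
    bad(!is.finite(cohort$weight) | cohort$weight < SUBJECT_BOUNDS$weight[1] |
          cohort$weight > SUBJECT_BOUNDS$weight[2],
        sprintf("weight outside [%g, %g] kg", SUBJECT_BOUNDS$weight[1],
                SUBJECT_BOUNDS$weight[2]))
    bad(!is.finite(cohort$measured_vo2) | cohort$measured_vo2 <= 0,
        "measured_vo2 must be positive (mL/min)")
    dup <- duplicated(cohort$id)
    if (any(dup)) {
      errs <- c(errs, sprintf("row %d: duplicate id '%s'", which(dup),
                              cohort$id[dup]))
    }
  }
  if (length(errs)) {
    stop("cohort validation failed:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  if (!inherits(cohort, "cpet_cohort")) {
    class(cohort) <- c("cpet_cohort", class(cohort))
  }
  cohort
}

#' Body mass index
#'
#' @param weight kg
#' @param height cm
#' @return kg/m^2
#' @export
bmi <- function(weight, height) weight / (height / 100)^2
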