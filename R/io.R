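#' Read a cohort from delimited text
#'
#' Expects the cohort schema
#' `id,age_years,sex,height_cm,weight_kg,mode,vo2peak_ml_min[,race,ethnicity]`
#' with `sex` coded `M`/`F` and `mode` in `treadmill`/`cycle`. All field
#' problems (unknown codes, non-numeric values, out-of-range values,
#' duplicate ids) are accumulated and reported together with their file line
#' numbers (header = line 1).
#'
#' @param path CSV file path.
#' @return A validated cohort data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("id", "age_years", "sex", "height_cm", "weight_kg", "mode",
                "vo2peak_ml_min")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("cohort header is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  errs <- character(0)
  line <- seq_len(nrow(raw)) + 1L  # header is line 1
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(v) & !is.na(raw[[col]])
    if (any(bad)) {
      errs <<- c(errs, sprintf("line %d: non-numeric %s '%s'", line[bad],
                               col, raw[[col]][bad]))
    }
    v
  }
  sex_raw <- toupper(trimws(raw$sex))
  bad_sex <- !sex_raw %in% c("M", "F")
  if (any(bad_sex)) {
    errs <- c(errs, sprintf("line %d: unknown sex code '%s'", line[bad_sex],
                            raw$sex[bad_sex]))
  }
  mode_raw <- tolower(trimws(raw$mode))
  bad_mode <- !mode_raw %in% MODES
  if (any(bad_mode)) {
    errs <- c(errs, sprintf("line %d: unknown mode '%s'", line[bad_mode],
                            raw$mode[bad_mode]))
  }
  cohort <- data.frame(
    id = raw$id, age = num("age_years"),
    sex = ifelse(sex_raw == "M", "male", "female"),
    height = num("height_cm"), weight = num("weight_kg"),
    mode = mode_raw, measured_vo2 = num("vo2peak_ml_min"),
    race = if ("race" %in% names(raw)) raw$race else NA_character_,
    ethnicity = if ("ethnicity" %in% names(raw)) raw$ethnicity
                else NA_character_,
    stringsAsFactors = FALSE
  )
  if (length(errs)) {
    stop("cohort file validation failed:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  }
  tryCatch(validate_cohort(cohort), error = function(e) {
    stop("cohort file validation failed (", path, "): ",
         conditionMessage(e), call. = FALSE)
  })
}

#' Write a cohort to delimited text
#'
#' Inverse of [read_cohort()]; round-trips exactly (up to numeric printing
#' at 15 significant digits, which reproduces doubles bit-for-bit for the
#' generator's values).
#'
#' @param cohort Validated cohort data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(as.data.frame(cohort))
  out <- data.frame(
    id = cohort$id,
    age_years = format(cohort$age, digits = 15, trim = TRUE),
    sex = ifelse(cohort$sex == "male", "M", "F"),
    height_cm = format(cohort$height, digits = 15, trim = TRUE),
    weight_kg = format(cohort$weight, digits = 15, trim = TRUE),
    mode = cohort$mode,
    vo2peak_ml_min = format(cohort$measured_vo2, digits = 15, trim = TRUE),
    race = cohort$race, ethnicity = cohort$ethnicity,
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0) {
    out <- out[0, , drop = FALSE]
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
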