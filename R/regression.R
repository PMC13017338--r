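#' Build the scaled covariate design for difference regression
#'
#' One row per subject with the covariates on the reporting scale used for
#' inter-equation difference models: age per decade (`age_decades = age/10`),
#' BMI per 5 kg/m^2 (`bmi_5units = bmi/5`), female indicator (reference
#' male), treadmill indicator (reference bike), and race indicators with
#' white as the reference; unknown or missing race maps to `"other"`.
#'
#' @param cohort A validated cohort data frame.
#' @return Data frame with columns `age_decades`, `bmi_5units`, `sex_female`,
#'   `mode_treadmill`, `race_black`, `race_asian`, `race_other`.
#' @export
build_design <- function(cohort) {
  cohort <- validate_cohort(as.data.frame(cohort))
  if (!nrow(cohort)) stop("cohort is empty")
  for (f in c("age", "height", "weight", "sex", "mode")) {
    miss <- is.na(cohort[[f]])
    if (any(miss)) {
      stop("missing covariate '", f, "' for subject(s): ",
           paste(cohort$id[miss], collapse = ", "))
    }
  }
  race <- ifelse(is.na(cohort$race) | !cohort$race %in% RACES,
                 "other", cohort$race)
  data.frame(
    age_decades = cohort$age / 10,
    bmi_5units = bmi(cohort$weight, cohort$height) / 5,
    sex_female = as.integer(cohort$sex == "female"),
    mode_treadmill = as.integer(cohort$mode == "treadmill"),
    race_black = as.integer(race == "black"),
    race_asian = as.integer(race == "asian"),
    race_other = as.integer(race == "other")
  )
}

#' Fit an inter-equation difference regression
#'
#' Ordinary least squares of the signed difference in continuous percent
#' predicted between a pair of equations on the scaled covariates from
#' [build_design()], with an intercept. Estimates are therefore read as
#' change in the percent-predicted difference per 10 years of age, per
#' 5 BMI units, etc.
#'
#' @param pp_diff Numeric response: signed percent-predicted difference
#'   (equation a minus equation b) per subject.
#' @param design Covariate data frame (numeric columns only).
#' @return List of class `"vo2_diff_model"`: `coefficients` (data frame with
#'   `term`, `estimate`, `se`, `p_value`), `sigma`, `n`, and the underlying
#'   `fit` (an `lm` object).
#' @export
fit_difference_model <- function(pp_diff, design) {
  stopifnot(is.numeric(pp_diff), is.data.frame(design))
  if (length(pp_diff) != nrow(design)) {
    stop("response and design have different lengths")
  }
  p <- ncol(design) + 1L
  if (length(pp_diff) <= p) {
    stop("need more observations (", length(pp_diff),
         ") than parameters (", p, ")")
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(design))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  dat <- cbind(.pp_diff = pp_diff, design)
  fit <- stats::lm(.pp_diff ~ ., data = dat)
  sm <- summary(fit)$coefficients
  structure(list(
    coefficients = data.frame(
      term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
      p_value = sm[, 4], row.names = NULL, stringsAsFactors = FALSE),
    sigma = summary(fit)$sigma, n = length(pp_diff), fit = fit
  ), class = "vo2_diff_model")
}

#' @export
print.vo2_diff_model <- function(x, ...) {
  cat("<vo2_diff_model> OLS on scaled covariates, n =", x$n, "\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}
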