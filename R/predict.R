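#' Ideal body weight
#'
#' Sex-specific linear function of height used by the Hansen ideal-weight
#' branching and by the weight-sweep curve annotation: men
#' `0.79 * height - 60.7`, women `0.65 * height - 42.8` (height in cm,
#' result in kg).
#'
#' @param sex `"male"` or `"female"` (vectorized).
#' @param height Height in cm.
#' @return Ideal body weight in kg.
#' @examples
#' ideal_body_weight("male", 170.18)   # 73.74
#' ideal_body_weight("female", 160)    # 61.2
#' @export
ideal_body_weight <- function(sex, height) {
  stopifnot(all(sex %in% SEXES), is.numeric(height))
  ibw <- ifelse(sex == "male", 0.79 * height - 60.7, 0.65 * height - 42.8)
  if (any(ibw <= 0)) {
    stop("ideal body weight non-positive for height(s) ",
         paste(height[ibw <= 0], collapse = ", "), " cm")
  }
  ibw
}

# ---- per-form evaluators: all return absolute mL/min in the native mode ----
# `mode` is the mode the equation is evaluated for (only consulted by the
# modality-specific forms).

eval_friend <- function(co, age, sex, height, weight, mode) {
  sex_code <- ifelse(sex == "male", 1, 2)
  mode_code <- ifelse(mode == "treadmill", 1, 2)
  wt_lb <- weight / KG_PER_LB
  ht_in <- height / CM_PER_IN
  rel <- co$intercept + co$age * age + co$sex * sex_code +
    co$weight * wt_lb + co$height * ht_in + co$mode * mode_code
  rel * weight
}

eval_wasserman <- function(co, age, sex, height, weight, mode) {
  rate <- function(s) co[[s]]$rate_intercept + co[[s]]$rate_age * age
  off <- function(s) co[[s]]$weight_offset
  ifelse(sex == "male",
         (weight + off("male")) * rate("male"),
         (weight + off("female")) * rate("female"))
}

# Ideal-weight-branched edition: at the ideal weight all branches coincide
# with the plain weight-based form; above it, excess mass contributes a flat
# `excess_slope` mL/min per kg; below it, the effective mass is the midpoint
# of actual and ideal weight.
eval_hansen_cycle <- function(co, age, sex, height, weight) {
  one_sex <- function(s) {
    c0 <- co[[s]]
    rate <- c0$rate_intercept + c0$rate_age * age
    ibw <- c0$ibw_slope * height + c0$ibw_intercept
    over <- (ibw + c0$weight_offset) * rate + c0$excess_slope * (weight - ibw)
    under <- ((weight + ibw) / 2 + c0$weight_offset) * rate
    ifelse(weight >= ibw, over, under)
  }
  ifelse(sex == "male", one_sex("male"), one_sex("female"))
}

eval_hansen <- function(co, age, sex, height, weight, mode) {
  base <- eval_hansen_cycle(co, age, sex, height, weight)
  ifelse(mode == "treadmill", base * co$treadmill_factor, base)
}

eval_per_kg_age <- function(co, age, sex, height, weight, mode) {
  rel <- ifelse(sex == "male",
                co$male$intercept + co$male$age * age,
                co$female$intercept + co$female$age * age)
  rel * weight
}

eval_height_age_sex <- function(co, age, sex, height, weight, mode) {
  l_min <- co$intercept + co$height * height + co$age * age +
    co$female * (sex == "female")
  l_min * 1000
}

eval_age_weight <- function(co, age, sex, height, weight, mode) {
  ifelse(sex == "male",
         co$male$intercept + co$male$age * age + co$male$weight * weight,
         co$female$intercept + co$female$age * age + co$female$weight * weight)
}

FORM_EVALUATORS <- list(
  friend = eval_friend, wasserman = eval_wasserman, hansen = eval_hansen,
  per_kg_age = eval_per_kg_age, height_age_sex = eval_height_age_sex,
  age_weight = eval_age_weight
)

#' Predict peak V̇O2 for one equation
#'
#' Evaluates an equation specification for a subject in the equation's native
#' mode: for the modality-specific equations (FRIEND, Hansen) the branch
#' matching the subject's test mode, for the others the single declared
#' native mode regardless of how the subject was tested (modality is then
#' reconciled by [apply_mode_correction()]). Unit conversions to the
#' equation's native pounds/inches are internal; the result is always
#' absolute mL/min.
#'
#' Subjects outside the equation's declared age/height/weight domain raise an
#' error; subjects outside the narrower age range of the equation's source
#' study are allowed but flagged with a warning, since in practice the
#' equations are applied beyond their derivation samples.
#'
#' @param spec An `equation_spec` from a registry, or an equation id string
#'   (resolved against `registry`).
#' @param subject A one-row cohort data frame (see [cpet_subject()]) or a
#'   cohort; vectorized over rows.
#' @param registry Registry used to resolve `spec` when given as an id.
#' @return Numeric vector of native predicted V̇O2peak in mL/min.
#' @examples
#' s <- cpet_subject("case", 37, "male", 170.18, 127.006, "treadmill", 3560)
#' predict_vo2("wasserman", s)   # 4693.6 (cycle-native)
#' @export
predict_vo2 <- function(spec, subject, registry = default_registry()) {
  if (is.character(spec)) {
    if (!spec %in% names(registry)) {
      stop("unknown equation id '", spec, "' (registry has: ",
           paste(names(registry), collapse = ", "), ")")
    }
    spec <- registry[[spec]]
  }
  stopifnot(inherits(spec, "equation_spec"))
  subject <- validate_cohort(as.data.frame(subject))
  dom <- spec$domain
  for (f in c("age", "height", "weight")) {
    v <- subject[[f]]
    out <- v < dom[[f]][1] | v > dom[[f]][2]
    if (any(out)) {
      stop("equation '", spec$id, "': subject(s) ",
           paste(subject$id[out], collapse = ", "), " outside ", f,
           " domain [", dom[[f]][1], ", ", dom[[f]][2], "]")
    }
  }
  sar <- spec$source_age_range
  if (!is.null(sar) && any(subject$age < sar[1] | subject$age > sar[2])) {
    warning("equation '", spec$id, "': ",
            sum(subject$age < sar[1] | subject$age > sar[2]),
            " subject(s) outside the source study age range [",
            sar[1], ", ", sar[2], "]; prediction extrapolates")
  }
  native_mode <- if (length(spec$native_modes) == 2L) {
    subject$mode
  } else {
    rep(spec$native_modes, nrow(subject))
  }
  FORM_EVALUATORS[[spec$form]](spec$coefficients, subject$age, subject$sex,
                               subject$height, subject$weight, native_mode)
}

#' Modality correction
#'
#' Reconciles an equation's native modality with the modality the subject was
#' actually tested on: a cycle-native prediction compared against a treadmill
#' test is multiplied by 1.11; a treadmill-native prediction against a cycle
#' test by 0.89; matching modes (and modality-specific equations, which never
#' reach this point with differing modes) are left unchanged.
#'
#' @param value Predicted V̇O2peak, mL/min (> 0).
#' @param native_mode Mode the prediction was computed in.
#' @param test_mode Mode of the subject's test.
#' @param factors Correction factors, see [mode_correction_factors()].
#' @return List with `corrected_value` and `correction_applied`.
#' @examples
#' apply_mode_correction(4693.6, "cycle", "treadmill")$corrected_value  # 5209.9
#' @export
apply_mode_correction <- function(value, native_mode, test_mode,
                                  factors = mode_correction_factors()) {
  stopifnot(all(value > 0), all(native_mode %in% MODES),
            all(test_mode %in% MODES))
  f <- ifelse(native_mode == test_mode, factors$none,
              ifelse(native_mode == "cycle", factors$cycle_to_treadmill,
                     factors$treadmill_to_cycle))
  list(corrected_value = value * f, correction_applied = f)
}

#' Predict peak V̇O2 with all registry equations
#'
#' Runs every equation in the registry for one subject and applies the
#' modality correction, yielding the full comparison dashboard input.
#'
#' @inheritParams predict_vo2
#' @param subject One-row cohort data frame.
#' @return Data frame with one row per equation: `equation`, `native_mode`,
#'   `native_value`, `corrected_value`, `correction_applied` (all values
#'   mL/min).
#' @export
predict_all <- function(registry, subject) {
  stopifnot(inherits(registry, "vo2_registry"))
  missing <- setdiff(EQUATION_IDS, names(registry))
  if (length(missing)) {
    stop("registry is missing required equation(s): ",
         paste(missing, collapse = ", "))
  }
  subject <- validate_cohort(as.data.frame(subject))
  stopifnot(nrow(subject) == 1L)
  rows <- lapply(EQUATION_IDS, function(id) {
    spec <- registry[[id]]
    native <- predict_vo2(spec, subject, registry)
    nm <- if (length(spec$native_modes) == 2L) subject$mode else spec$native_modes
    corr <- apply_mode_correction(native, nm, subject$mode)
    data.frame(equation = id, native_mode = nm, native_value = native,
               corrected_value = corr$corrected_value,
               correction_applied = corr$correction_applied,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Percent-predicted dashboard for one subject
#'
#' The calculator view: all six predictions for a subject with percent
#' predicted and capacity classification at the chosen threshold. Display
#' percents follow the calculator floor rule.
#'
#' @inheritParams predict_all
#' @param threshold Percent-predicted threshold for normal capacity
#'   (default 80).
#' @param correction If `FALSE`, the external modality correction is skipped
#'   and native values are used directly.
#' @return Data frame with columns `equation`, `predicted` (mL/min,
#'   corrected), `pp` (continuous percent), `pp_display` (floored integer),
#'   `class`.
#' @export
vo2_dashboard <- function(subject, registry = default_registry(),
                          threshold = 80, correction = TRUE) {
  pa <- predict_all(registry, subject)
  predicted <- if (correction) pa$corrected_value else pa$native_value
  pp <- percent_predicted(subject$measured_vo2, predicted)
  data.frame(
    equation = pa$equation,
    predicted = predicted,
    pp = pp,
    pp_display = display_percent(pp, "floor"),
    class = classify_capacity(pp, threshold),
    stringsAsFactors = FALSE
  )
}
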