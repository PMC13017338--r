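#' Metabolic equivalents from relative V̇O2
#'
#' One MET is 3.5 mL/kg/min of oxygen uptake by convention; the display
#' value is reported to one decimal (round half up).
#'
#' @param rel Relative V̇O2 in mL/kg/min (>= 0).
#' @return METs, rounded to 1 decimal.
#' @examples
#' mets_from_relative_vo2(26.8)  # 7.7
#' @export
mets_from_relative_vo2 <- function(rel) {
  stopifnot(is.numeric(rel))
  if (any(rel < 0)) stop("relative V̇O2 must be non-negative")
  round_half_up(rel / 3.5, 1)
}

#' Ventilatory equivalent
#'
#' Minute ventilation divided by a gas exchange rate (VE/V̇O2 or VE/V̇CO2).
#' The continuous ratio is retained; `display` carries the integer panel
#' value (round half up).
#'
#' @param ve Minute ventilation, L/min.
#' @param vgas Gas exchange rate (V̇O2 or V̇CO2), L/min (> 0).
#' @return List with `value` (continuous) and `display` (integer).
#' @examples
#' ventilatory_equivalent(112.5, 3.56)$display  # 32
#' @export
ventilatory_equivalent <- function(ve, vgas) {
  stopifnot(is.numeric(ve), is.numeric(vgas))
  if (any(vgas <= 0)) stop("gas exchange rate must be positive")
  val <- ve / vgas
  list(value = val, display = as.integer(round_half_up(val)))
}

#' Integer percent of predicted (panel convention)
#'
#' Derived-variable panels report percent of predicted rounded half up to an
#' integer — distinct from the equation calculator's floor rule (see
#' [display_percent()]).
#'
#' @param measured,predicted Same units; `predicted` > 0.
#' @return Integer percent.
#' @examples
#' percent_of_predicted(3.56, 3.42)  # 104
#' percent_of_predicted(174, 183)    # 95
#' @export
percent_of_predicted <- function(measured, predicted) {
  stopifnot(is.numeric(measured), is.numeric(predicted))
  if (any(predicted <= 0)) stop("predicted value must be positive")
  as.integer(round_half_up(measured / predicted * 100))
}

#' Oxygen pulse
#'
#' V̇O2 divided by heart rate — a surrogate for stroke volume times
#' arteriovenous O2 difference.
#'
#' @param vo2 V̇O2 in mL/min.
#' @param hr Heart rate, bpm (> 0).
#' @return mL/beat, 1 decimal.
#' @export
oxygen_pulse <- function(vo2, hr) {
  stopifnot(is.numeric(vo2), is.numeric(hr))
  if (any(hr <= 0)) stop("heart rate must be positive")
  round_half_up(vo2 / hr, 1)
}

#' Disability cut-off flags
#'
#' Two illustrative disability criteria: the New York state criterion based
#' on the Hansen equation (percent predicted below 85%) and the Department
#' of Veterans Affairs criterion on relative V̇O2peak (below 20 mL/kg/min).
#' Neither is used in isolation for an actual disability determination.
#'
#' @param relative_vo2 Relative V̇O2peak, mL/kg/min (> 0).
#' @param hansen_pp Continuous percent predicted under the Hansen equation.
#' @return List with logicals `ny_flag` (`hansen_pp < 85`) and `va_flag`
#'   (`relative_vo2 < 20`).
#' @examples
#' disability_flags(24.4, 84.9)  # ny TRUE, va FALSE
#' @export
disability_flags <- function(relative_vo2, hansen_pp) {
  stopifnot(all(relative_vo2 > 0), all(hansen_pp > 0))
  list(ny_flag = hansen_pp < 85, va_flag = relative_vo2 < 20)
}

#' Worked-example CPET case
#'
#' The illustrative clinical case bundled with the package: a 37-year-old
#' male tested on a treadmill (height 67 in = 170.18 cm, weight 280 lb =
#' 127.006 kg) who achieved a measured V̇O2peak of 3560 mL/min, together
#' with his full metabolic-cart derived-variable panel. The panel stores the
#' clinic printout verbatim, including its two internal inconsistencies
#' (peak O2 pulse printed 21 vs 3560/174 = 20.5; relative peak 26.8 vs
#' 3560/127.0 = 28.0); it is a fixture, not a recomputation.
#'
#' @return List with `subject` (a [cpet_subject()]) and `panel` (data frame
#'   of rest/AT/peak/predicted/percent-predicted values).
#' @examples
#' we <- worked_example()
#' vo2_dashboard(we$subject)
#' @export
worked_example <- function() {
  subject <- cpet_subject("case-1", age = 37, sex = "male",
                          height = 67 * CM_PER_IN, weight = 280 * KG_PER_LB,
                          mode = "treadmill", measured_vo2 = 3560)
  path <- system.file("extdata", "worked_example_panel.csv",
                      package = "vo2compare", mustWork = TRUE)
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  list(subject = subject, panel = panel)
}
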