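# Fixed unit conversions and modality correction factors shared across the
# package. Conversions are exact constants, not configurable.
KG_PER_LB <- 0.453592
CM_PER_IN <- 2.54

#' Modality correction factors
#'
#' Factors reconciling treadmill-derived and cycle-derived predicted V̇O2peak
#' for equations that do not provide modality-specific forms: a cycle-native
#' prediction applied to a treadmill test is raised by 11% (x1.11); a
#' treadmill-native prediction applied to a cycle test is lowered by 11%
#' (x0.89, the literal -11% reading rather than 1/1.11).
#'
#' @return Named list with elements `cycle_to_treadmill` (1.11),
#'   `treadmill_to_cycle` (0.89) and `none` (1).
#' @export
mode_correction_factors <- function() {
  list(cycle_to_treadmill = 1.11, treadmill_to_cycle = 0.89, none = 1)
}

#' Display rounding conventions
#'
#' Two integer display rules coexist in CPET reporting and both are kept as
#' named conventions: the equation-comparison calculator truncates percent
#' predicted toward zero (`"floor"`: 68.33 displays as 68, 114.64 as 114),
#' while metabolic-cart style derived-variable panels round half up
#' (`"half_up"`: 81.5 displays as 82, 31.6 as 32).
#'
#' @param x numeric vector of continuous values.
#' @param rule `"floor"` or `"half_up"`.
#' @return integer vector.
#' @examples
#' display_percent(c(68.33, 114.64))            # 68 114
#' display_percent(c(81.52, 31.6), "half_up")   # 82  32
#' @export
display_percent <- function(x, rule = c("floor", "half_up")) {
  rule <- match.arg(rule)
  stopifnot(is.numeric(x))
  out <- switch(rule, floor = floor(x), half_up = floor(x + 0.5))
  as.integer(out)
}

# round half up at `digits` decimals (base round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical sex / mode level sets
SEXES <- c("male", "female")
MODES <- c("treadmill", "cycle")
RACES <- c("white", "black", "asian", "other")

EQUATION_IDS <- c("friend", "wasserman", "hansen", "bruce", "jones", "neder")

# Subject-level validity bounds
SUBJECT_BOUNDS <- list(age = c(15, 90), height = c(120, 220), weight = c(30, 250))
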