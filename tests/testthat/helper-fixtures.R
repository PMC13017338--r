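# shared fixtures: the clinical case subject and small deterministic cohorts

case_subject <- function() {
  cpet_subject("case-1", age = 37, sex = "male", height = 67 * 2.54,
               weight = 280 * 0.453592, mode = "treadmill",
               measured_vo2 = 3560)
}

# small mixed cohort spanning sexes and modes, inside all source age ranges
tiny_cohort <- function() {
  validate_cohort(data.frame(
    id = paste0("s", 1:6),
    age = c(40, 52, 35, 61, 45, 38),
    sex = c("male", "male", "female", "male", "female", "male"),
    height = c(178, 170, 163, 182, 158, 175),
    weight = c(95, 110, 70, 88, 82, 101),
    mode = c("treadmill", "cycle", "treadmill", "cycle", "cycle", "treadmill"),
    measured_vo2 = c(2600, 2100, 1700, 2900, 1500, 2450),
    race = c("white", "black", "white", "other", "asian", "white"),
    ethnicity = NA_character_,
    stringsAsFactors = FALSE
  ))
}

# independent Friedman oracle: ranks from pairwise comparisons (not rank()),
# then the direct rank-sum formula
friedman_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  R <- matrix(0, n, k)
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      R[i, j] <- 1 + sum(m[i, ] < m[i, j]) +
        0.5 * (sum(m[i, ] == m[i, j]) - 1)
    }
  }
  Rj <- colSums(R)
  12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
}

# registry file in which all six equations are the same cycle-native
# weight-based specification (modality-specific ids keep both modes, whose
# branches coincide because the form ignores mode)
degenerate_registry_file <- function() {
  same <- function(modes) paste0(
    "  form: wasserman\n",
    "  native_modes: [", modes, "]\n",
    "  weight_units: kg\n  height_units: cm\n  output: ml_min\n",
    "  coefficients:\n",
    "    male:   {rate_intercept: 50.72, rate_age: -0.372, weight_offset: 0.0}\n",
    "    female: {rate_intercept: 22.78, rate_age: -0.17,  weight_offset: 43.0}\n")
  txt <- paste0(
    "friend:\n", same("treadmill, cycle"),
    "wasserman:\n", same("cycle"),
    "hansen:\n", same("treadmill, cycle"),
    "bruce:\n", same("cycle"),
    "jones:\n", same("cycle"),
    "neder:\n", same("cycle"))
  tf <- tempfile(fileext = ".yaml")
  writeLines(txt, tf)
  tf
}
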