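test_that("ideal body weight follows the sex-specific height formulas", {
  expect_equal(ideal_body_weight("male", 170.18), 0.79 * 170.18 - 60.7,
               tolerance = 1e-12)
  expect_equal(ideal_body_weight("male", 180), 81.5)
  expect_equal(ideal_body_weight("female", 160), 61.2)
  # vectorized over mixed sexes
  expect_equal(ideal_body_weight(c("male", "female"), c(180, 160)),
               c(81.5, 61.2))
  expect_error(ideal_body_weight("female", 60), "non-positive")
})

test_that("Wasserman and FRIEND reproduce the case-subject predictions", {
  s <- case_subject()
  expect_equal(predict_vo2("wasserman", s), 127.00576 * (50.72 - 0.372 * 37),
               tolerance = 1e-9)
  expect_equal(predict_vo2("wasserman", s), 4693.6, tolerance = 1e-4)
  # FRIEND: imperial-native, treadmill branch; 24.45 mL/kg/min x 127.006 kg
  rel <- 45.2 - 0.35 * 37 - 10.9 * 1 - 0.15 * 280 + 0.68 * 67 - 0.46 * 1
  expect_equal(predict_vo2("friend", s), rel * 127.00576, tolerance = 1e-9)
  expect_equal(predict_vo2("friend", s), 3105.3, tolerance = 1e-4)
})

test_that("Hansen collapses to Wasserman at the ideal weight and is continuous", {
  reg <- default_registry()
  for (sex in c("male", "female")) {
    h <- if (sex == "male") 178 else 164
    ibw <- ideal_body_weight(sex, h)
    at_ibw <- cpet_subject("x", 50, sex, h, ibw, "cycle", 2000)
    expect_equal(predict_vo2("hansen", at_ibw), predict_vo2("wasserman", at_ibw),
                 tolerance = 1e-9)
    # continuity across the branch point
    eps <- 1e-6
    lo <- cpet_subject("x", 50, sex, h, ibw - eps, "cycle", 2000)
    hi <- cpet_subject("x", 50, sex, h, ibw + eps, "cycle", 2000)
    expect_equal(predict_vo2("hansen", lo), predict_vo2("hansen", hi),
                 tolerance = 1e-3)
  }
})

test_that("modality correction applies the 1.11 / 0.89 / identity factors", {
  expect_equal(apply_mode_correction(4693.6, "cycle", "treadmill")$corrected_value,
               5209.896, tolerance = 1e-6)
  expect_equal(apply_mode_correction(1234, "cycle", "cycle")$corrected_value, 1234)
  expect_equal(apply_mode_correction(1000, "treadmill", "cycle")$corrected_value, 890)
  expect_equal(apply_mode_correction(1000, "treadmill", "cycle")$correction_applied,
               0.89)
  expect_error(apply_mode_correction(-5, "cycle", "cycle"))
})

test_that("predict_all yields six corrected deterministic entries", {
  s <- case_subject()
  pa <- predict_all(default_registry(), s)
  expect_equal(nrow(pa), 6L)
  expect_setequal(pa$equation,
                  c("friend", "wasserman", "hansen", "bruce", "jones", "neder"))
  expect_equal(pa$corrected_value[pa$equation == "wasserman"], 5209.9,
               tolerance = 1e-4)
  expect_true(all(pa$correction_applied %in% c(1, 1.11, 0.89)))
  # modality-specific equations never get the external correction
  expect_equal(pa$correction_applied[pa$equation %in% c("friend", "hansen")],
               c(1, 1))
  expect_identical(pa, predict_all(default_registry(), s))
  # registry missing an equation is a registry error
  partial <- load_equation_registry(allow_partial = TRUE)
  partial$neder <- NULL
  expect_error(predict_all(partial, s), "neder")
})

test_that("mode flip only rescales the non-modality-specific equations", {
  reg <- default_registry()
  s_tm <- tiny_cohort()[1, ]
  s_cy <- s_tm; s_cy$mode <- "cycle"
  pa_tm <- predict_all(reg, s_tm)
  pa_cy <- predict_all(reg, s_cy)
  for (id in c("wasserman", "jones", "neder")) {   # cycle-native
    expect_equal(pa_tm$corrected_value[pa_tm$equation == id],
                 pa_cy$corrected_value[pa_cy$equation == id] * 1.11,
                 tolerance = 1e-12, label = id)
  }
  expect_equal(pa_cy$corrected_value[pa_cy$equation == "bruce"],
               pa_tm$corrected_value[pa_tm$equation == "bruce"] * 0.89,
               tolerance = 1e-12)
})

test_that("all equations are monotone non-increasing in age, FRIEND strictly", {
  reg <- default_registry()
  ages <- seq(35, 65, by = 5)
  for (id in names(reg)) {
    preds <- vapply(ages, function(a) {
      s <- cpet_subject("x", a, "male", 176, 95, "treadmill", 2500)
      suppressWarnings(predict_vo2(id, s))
    }, numeric(1))
    expect_true(all(diff(preds) <= 0), label = paste(id, "non-increasing"))
    expect_true(all(preds > 0) && all(is.finite(preds)),
                label = paste(id, "positive finite"))
  }
  friend_preds <- vapply(ages, function(a) {
    predict_vo2("friend", cpet_subject("x", a, "male", 176, 95, "treadmill", 2500))
  }, numeric(1))
  expect_true(all(diff(friend_preds) < 0))
})

test_that("registry round-trips through YAML with bit-identical predictions", {
  reg <- default_registry()
  tf <- tempfile(fileext = ".yaml")
  write_equation_registry(reg, tf)
  reg2 <- load_equation_registry(tf)
  co <- tiny_cohort()
  p1 <- suppressWarnings(cohort_percent_predicted(co, reg))
  p2 <- suppressWarnings(cohort_percent_predicted(co, reg2))
  expect_identical(p1, p2)
  expect_identical(registry_hash(reg), registry_hash(reg2))
})

test_that("registry loading validates structure, units and overrides", {
  reg <- default_registry()
  # overriding one equation leaves the rest at defaults
  tf <- tempfile(fileext = ".yaml")
  writeLines(paste0(
    "bruce:\n  form: per_kg_age\n  native_modes: [treadmill]\n",
    "  weight_units: kg\n  height_units: cm\n  output: ml_kg_min\n",
    "  coefficients: {male: {intercept: 60.0, age: -0.5},",
    " female: {intercept: 44.0, age: -0.4}}\n"), tf)
  reg2 <- load_equation_registry(tf)
  s <- case_subject()
  expect_equal(predict_vo2("bruce", s, reg2), (60 - 0.5 * 37) * 127.00576,
               tolerance = 1e-9)
  expect_identical(reg2[["jones"]], reg[["jones"]])
  # unknown units rejected
  tf2 <- tempfile(fileext = ".yaml")
  writeLines(paste0(
    "bruce:\n  form: per_kg_age\n  native_modes: [treadmill]\n",
    "  weight_units: stone\n  height_units: cm\n",
    "  coefficients: {male: {intercept: 60.0, age: -0.5},",
    " female: {intercept: 44.0, age: -0.4}}\n"), tf2)
  expect_error(load_equation_registry(tf2), "stone")
  # malformed coefficients rejected
  tf3 <- tempfile(fileext = ".yaml")
  writeLines("bruce:\n  form: per_kg_age\n  native_modes: [treadmill]\n  coefficients: {male: {intercept: abc}}\n", tf3)
  expect_error(load_equation_registry(tf3), "coefficients")
  # unknown ids rejected
  tf4 <- tempfile(fileext = ".yaml")
  writeLines("storer:\n  form: per_kg_age\n  native_modes: [cycle]\n  coefficients: {male: {intercept: 1.0}}\n", tf4)
  expect_error(load_equation_registry(tf4), "unknown equation id")
})

test_that("subjects outside the equation domain or source range are handled", {
  reg <- default_registry()
  too_heavy <- data.frame(id = "x", age = 40, sex = "male", height = 180,
                          weight = 260, mode = "cycle", measured_vo2 = 2000)
  expect_error(validate_cohort(too_heavy), "weight")
  young <- cpet_subject("y", 25, "male", 180, 90, "cycle", 2500)
  expect_warning(predict_vo2("wasserman", young), "source study age range")
})
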