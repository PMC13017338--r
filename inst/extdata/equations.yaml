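# Default coefficient registry for the six peak-VO2 prediction equations.
# Edit and pass to load_equation_registry() to override any block without
# code changes. Units fields declare each equation's NATIVE units; subjects
# are always supplied in cm/kg and converted internally.
#
# Coefficient provenance: FRIEND (registry-wide equation with exercise-mode
# term, imperial units; sex coded male=1/female=2, mode treadmill=1/cycle=2);
# Wasserman/Hansen shipyard-worker cycle scheme (Hansen is the later,
# ideal-weight-branched edition); Bruce 1973 sedentary treadmill per-kg forms;
# Jones 1985 incremental cycle absolute form; Neder 1999 sedentary cycle
# age+weight forms (reconstructed from the original publication; editable
# here if a corrected set becomes available).
friend:
  label: FRIEND
  form: friend
  native_modes: [treadmill, cycle]
  weight_units: lb
  height_units: in
  output: ml_kg_min
  coefficients:
    intercept: 45.2
    age: -0.35
    sex: -10.9
    weight: -0.15
    height: 0.68
    mode: -0.46
  domain: {age: [15, 90], height: [120, 220], weight: [30, 250]}
  source_age_range: [20, 79]
wasserman:
  label: Wasserman
  form: wasserman
  native_modes: [cycle]
  weight_units: kg
  height_units: cm
  output: ml_min
  coefficients:
    male:   {rate_intercept: 50.72, rate_age: -0.372, weight_offset: 0.0}
    female: {rate_intercept: 22.78, rate_age: -0.17,  weight_offset: 43.0}
  domain: {age: [15, 90], height: [120, 220], weight: [30, 250]}
  source_age_range: [34, 74]
hansen:
  label: Hansen
  form: hansen
  native_modes: [treadmill, cycle]
  weight_units: kg
  height_units: cm
  output: ml_min
  coefficients:
    male:
      rate_intercept: 50.72
      rate_age: -0.372
      weight_offset: 0.0
      ibw_slope: 0.79
      ibw_intercept: -60.7
      excess_slope: 6.0
    female:
      rate_intercept: 22.78
      rate_age: -0.17
      weight_offset: 43.0
      ibw_slope: 0.65
      ibw_intercept: -42.8
      excess_slope: 6.0
    treadmill_factor: 1.11
  domain: {age: [15, 90], height: [120, 220], weight: [30, 250]}
  source_age_range: [34, 74]
bruce:
  label: Bruce
  form: per_kg_age
  native_modes: [treadmill]
  weight_units: kg
  height_units: cm
  output: ml_kg_min
  coefficients:
    male:   {intercept: 57.8, age: -0.445}
    female: {intercept: 42.3, age: -0.356}
  domain: {age: [15, 90], height: [120, 220], weight: [30, 250]}
  source_age_range: [29, 73]
jones:
  label: Jones
  form: height_age_sex
  native_modes: [cycle]
  weight_units: kg
  height_units: cm
  output: l_min
  coefficients:
    intercept: -4.31
    height: 0.046
    age: -0.021
    female: -0.62
  domain: {age: [15, 90], height: [120, 220], weight: [30, 250]}
  source_age_range: [15, 71]
neder:
  label: Neder
  form: age_weight
  native_modes: [cycle]
  weight_units: kg
  height_units: cm
  output: ml_min
  coefficients:
    male:   {intercept: 1351.0, age: -34.1, weight: 25.8}
    female: {intercept: 973.0,  age: -24.6, weight: 18.6}
  domain: {age: [15, 90], height: [120, 220], weight: [30, 250]}
  source_age_range: [20, 80]
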