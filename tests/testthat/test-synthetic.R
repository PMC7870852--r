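test_that("noiseless generation equals the closed-form sinusoid", {
  spec <- oscillation_spec(base_frequency = 1 / 480,
                           amplitude = c(oxCCO = 1, HbO2 = 1, HHb = 1),
                           phase_lag = c(oxCCO = 0, HbO2 = 0.4, HHb = -0.7),
                           duration = 1200, sampling_rate = 1)
  s <- generate_concentration_series(spec)
  t <- s$time
  for (ch in c("oxCCO", "HbO2", "HHb")) {
    expect_equal(ts_channel(s, ch),
                 sin(2 * pi * t / 480 + spec$phase_lag[[ch]]),
                 tolerance = 1e-12)
  }
  expect_identical(s$metadata$ground_truth, spec)
})

test_that("generation is deterministic given spec and seed", {
  spec <- clean_spec(jitter = 0.1, noise = 0.05, seed = 42)
  expect_identical(generate_concentration_series(spec)$channels,
                   generate_concentration_series(spec)$channels)
  spec2 <- clean_spec(jitter = 0.1, noise = 0.05, seed = 43)
  expect_false(identical(generate_concentration_series(spec)$channels,
                         generate_concentration_series(spec2)$channels))
})

test_that("invalid oscillation specs are rejected", {
  expect_error(oscillation_spec(base_frequency = -1), "positive")
  expect_error(oscillation_spec(1 / 480, duration = 0), "positive")
  expect_error(oscillation_spec(1 / 480, sampling_rate = -1), "positive")
  expect_error(oscillation_spec(0.4, sampling_rate = 0.5), "twice")
  expect_error(oscillation_spec(1 / 480, period_jitter_sd = -0.1), ">= 0")
  expect_error(oscillation_spec(1 / 480, duration = 2.5, sampling_rate = 1),
               "integer sample count")
  expect_error(
    oscillation_spec(1 / 480,
                     drift_coefficients = list(oxCCO = rep(1, 8))),
    "capped at 6")
})

test_that("peak-to-peak amplitude is conserved without noise/jitter/drift", {
  # period divisible by 4 samples so the grid hits the extremes exactly
  spec <- oscillation_spec(base_frequency = 1 / 480,
                           amplitude = c(oxCCO = 0.25, HbO2 = 0.6, HHb = 1.3),
                           phase_lag = c(oxCCO = 0, HbO2 = 0, HHb = 0),
                           duration = 3600, sampling_rate = 1)
  s <- generate_concentration_series(spec)
  for (ch in names(spec$amplitude)) {
    x <- ts_channel(s, ch)
    expect_equal(max(x) - min(x), 2 * spec$amplitude[[ch]], tolerance = 1e-9)
  }
})

test_that("generated phase lags match ground truth (quadrature oracle)", {
  lags <- c(oxCCO = 0, HbO2 = -pi / 3, HHb = 0.9)
  spec <- oscillation_spec(base_frequency = 1 / 480,
                           amplitude = c(oxCCO = 1, HbO2 = 1, HHb = 1),
                           phase_lag = lags, duration = 4800,
                           sampling_rate = 1)
  s <- generate_concentration_series(spec)
  ph <- vapply(names(lags), function(ch)
    quadrature_phase(ts_channel(s, ch), s$time, 1 / 480), numeric(1))
  for (ch in c("HbO2", "HHb")) {
    expect_equal(wrap_phase(ph[[ch]] - ph[["oxCCO"]]),
                 wrap_phase(lags[[ch]] - lags[["oxCCO"]]),
                 tolerance = 1e-6)
  }
})

test_that("drift polynomial and noise enter additively and reproducibly", {
  spec <- oscillation_spec(base_frequency = 1 / 480,
                           amplitude = c(oxCCO = 1, HbO2 = 1, HHb = 1),
                           phase_lag = c(oxCCO = 0, HbO2 = 0, HHb = 0),
                           drift_coefficients = list(oxCCO = c(2, -3, 1)),
                           duration = 1200, sampling_rate = 1)
  s <- generate_concentration_series(spec)
  tn <- s$time / s$time[length(s$time)]
  expect_equal(ts_channel(s, "oxCCO"),
               sin(2 * pi * s$time / 480) + 2 - 3 * tn + tn^2,
               tolerance = 1e-12)
  # drift-free channels untouched
  expect_equal(ts_channel(s, "HHb"), sin(2 * pi * s$time / 480),
               tolerance = 1e-12)
})

test_that("cohort presets encode the group phenotypes", {
  expect_equal(cohort_preset("young_C57")$spec$base_frequency, 1 / 480)
  expect_equal(cohort_preset("old_C57")$spec$base_frequency, 1 / 840)
  expect_equal(cohort_preset("young_CFH")$spec$base_frequency, 1 / 960)
  expect_equal(cohort_preset("old_CFH")$spec$base_frequency, 1 / 960)
  expect_error(cohort_preset("old_BALBc"), "unknown cohort")

  specs <- lapply(c("young_C57", "old_C57", "young_CFH", "old_CFH"),
                  function(g) cohort_preset(g)$spec)
  periods <- vapply(specs, function(s) 1 / s$base_frequency, numeric(1))
  jitters <- vapply(specs, function(s) s$period_jitter_sd, numeric(1))
  # periods ordered young_C57 < old_C57 <= CFH presets
  expect_lt(periods[1], periods[2])
  expect_true(all(periods[2] <= periods[3:4]))
  # young_C57 jitter below all others
  expect_true(all(jitters[1] < jitters[2:4]))
})

test_that("dominant frequency of a noisy synthetic record recovers the truth", {
  spec <- clean_spec(f = 1 / 480, noise = 0.1, seed = 5)
  s <- preprocess(derive_composites(generate_concentration_series(spec)))
  sp <- amplitude_spectrum(s, "oxCCO", 16L)
  f0 <- dominant_frequency(sp)
  expect_lt(abs(f0 - 1 / 480), sp$resolution + 1e-12)
})

test_that("forward attenuation model is linear and errors on name mismatch", {
  tbl <- synthetic_extinction_table(seq(780, 900, by = 5))
  pl <- pathlength_model(quiet = TRUE)
  zero <- chromophore_ts(0:299, matrix(0, 300, 3,
                                       dimnames = list(NULL, c("oxCCO", "HbO2", "HHb"))))
  att <- generate_attenuation_series(zero, tbl, pl)
  expect_true(all(att$values == 0))

  one_tbl <- extinction_table(800, matrix(1, 1, 1, dimnames = list(NULL, "X")))
  one <- chromophore_ts(0:9, matrix(500, 10, 1, dimnames = list(NULL, "X")))
  att1 <- generate_attenuation_series(one, one_tbl, pl)
  # eps = 1 mM^-1 cm^-1, pathlength 1 cm, dC = 500 uM = 0.5 mM -> dA = 0.5
  expect_equal(as.numeric(att1$values), rep(0.5, 10), tolerance = 1e-12)

  bad <- chromophore_ts(0:9, matrix(1, 10, 1, dimnames = list(NULL, "Y")))
  expect_error(generate_attenuation_series(bad, one_tbl, pl), "X")
})
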