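test_that("Morlet CWT modulus localizes a sinusoid and is linear", {
  s <- sinusoid_series(f = 1 / 480, lags = c(oxCCO = 0))
  cw <- morlet_cwt(s, "oxCCO")
  prof <- colMeans(Mod(cw$coefficients))
  f_hat <- cw$frequency[which.max(prof)]
  # within one voice of the true frequency (log-spaced grid)
  ratio <- cw$frequency[2] / cw$frequency[1]
  expect_lt(abs(log(f_hat / (1 / 480))), log(ratio) + 1e-12)

  zero <- chromophore_ts(s$time, cbind(oxCCO = rep(0, length(s$time))))
  expect_true(all(Mod(morlet_cwt(zero, "oxCCO")$coefficients) == 0))

  tripled <- s; tripled$channels <- 3 * s$channels
  expect_equal(Mod(morlet_cwt(tripled, "oxCCO")$coefficients),
               3 * Mod(cw$coefficients), tolerance = 1e-9)
})

test_that("wavelet frequencies above Nyquist are rejected", {
  s <- sinusoid_series(n = 600, lags = c(oxCCO = 0))
  cfg <- wavelet_config(frequencies = c(0.001, 0.6))
  expect_error(morlet_cwt(s, "oxCCO", cfg), "Nyquist")
  expect_error(wavelet_config(center_frequency_parameter = 3),
               "admissibility")
  expect_error(wavelet_config(frequencies = c(0.01, 0.001)), "increasing")
})

test_that("semblance hits the analytic identities", {
  f0 <- 1 / 480
  s <- sinusoid_series(f = f0, lags = c(oxCCO = 0, same = 0, anti = pi,
                                        quad = -pi / 2))
  m_same <- semblance_map(s, "same", "oxCCO")
  expect_true(all(abs(m_same$semblance - 1) < 1e-9, na.rm = TRUE))
  expect_equal(mean_semblance(m_same, f0)$mean_semblance, 1, tolerance = 1e-9)

  m_anti <- semblance_map(s, "anti", "oxCCO")
  expect_equal(mean_semblance(m_anti, f0)$mean_semblance, -1,
               tolerance = 1e-6)

  m_quad <- semblance_map(s, "quad", "oxCCO")
  expect_lt(abs(mean_semblance(m_quad, f0)$mean_semblance), 0.02)
})

test_that("semblance is bounded, symmetric, and NA below the power floor", {
  set.seed(6)
  n <- 1200
  ch <- cbind(oxCCO = stats::rnorm(n), HHb = stats::rnorm(n))
  s <- chromophore_ts(0:(n - 1), ch)
  ab <- semblance_map(s, "oxCCO", "HHb")
  ba <- semblance_map(s, "HHb", "oxCCO")
  expect_true(all(abs(ab$semblance) <= 1, na.rm = TRUE))
  expect_equal(ab$semblance, ba$semblance, tolerance = 1e-12)
  expect_error(mean_semblance(ab, 0.2), "outside the wavelet grid")
})

test_that("mean semblance follows the cosine of the imposed lag", {
  f0 <- 1 / 480
  for (lag in c(pi / 6, pi / 3, 2 * pi / 3)) {
    s <- sinusoid_series(f = f0, lags = c(oxCCO = 0, hb = -lag))
    m <- semblance_map(s, "hb", "oxCCO")
    expect_lt(abs(mean_semblance(m, f0)$mean_semblance - cos(lag)), 0.05)
  }
})

test_that("semblance resolves different lags at different frequencies", {
  n <- 3600; t <- 0:(n - 1)
  f1 <- 1 / 480; f2 <- 1 / 120
  a <- sin(2 * pi * f1 * t) + sin(2 * pi * f2 * t)
  b <- sin(2 * pi * f1 * t) + sin(2 * pi * f2 * t - pi)  # antiphase at f2 only
  s <- chromophore_ts(t, cbind(a = a, b = b))
  m <- semblance_map(s, "a", "b")
  expect_gt(mean_semblance(m, f1)$mean_semblance, 0.9)
  expect_lt(mean_semblance(m, f2)$mean_semblance, -0.9)
})

test_that("mean semblance is robust to voice density (+/- 1 octave)", {
  f0 <- 1 / 480
  s <- sinusoid_series(f = f0, lags = c(oxCCO = 0, hb = -pi / 3))
  vals <- vapply(c(32, 64, 128), function(nv) {
    cfg <- wavelet_config(frequencies = exp(seq(log(5e-4), log(0.01),
                                                length.out = nv)))
    mean_semblance(semblance_map(s, "hb", "oxCCO", cfg), f0)$mean_semblance
  }, numeric(1))
  expect_lt(max(abs(vals - cos(pi / 3))), 0.05)
  expect_lt(max(vals) - min(vals), 0.02)
})

test_that("the per-animal panel reproduces the generator's lag structure", {
  spec <- cohort_preset("young_C57", seed = 13)$spec
  s <- preprocess(derive_composites(generate_concentration_series(spec)))
  panel <- animal_semblance_panel(s, spec$base_frequency)
  expect_identical(panel$pair, c("HHb-oxCCO", "HbO2-oxCCO", "HbT-oxCCO",
                                 "HbDiff-oxCCO"))
  # young C57: HHb, HbO2, HbT in phase with oxCCO; HbDiff antiphase
  # (amplitude(HHb) > amplitude(HbO2) makes HbDiff = HbO2 - HHb negative)
  expect_true(all(panel$mean_semblance[1:3] > 0.9))
  expect_lt(panel$mean_semblance[4], -0.9)
  expect_equal(panel$display_period_hi_s - panel$display_period_lo_s,
               rep(100, 4))
})

test_that("channels identical to oxCCO give semblance +1 on every pair", {
  n <- 1800; t <- 0:(n - 1)
  x <- sin(2 * pi * t / 480)
  s <- chromophore_ts(t, cbind(oxCCO = x, HHb = x, HbO2 = x, HbT = x,
                               HbDiff = x))
  panel <- animal_semblance_panel(s, 1 / 480)
  expect_equal(panel$mean_semblance, rep(1, 4), tolerance = 1e-9)
})

test_that("phase-shuffled noise pairs center near zero semblance", {
  vals <- vapply(1:20, function(seed) {
    set.seed(seed)
    n <- 1800
    s <- chromophore_ts(0:(n - 1), cbind(a = stats::rnorm(n),
                                         b = stats::rnorm(n)))
    mean_semblance(semblance_map(s, "a", "b"), 1 / 480)$mean_semblance
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.25)
  expect_gt(stats::sd(vals), 0.05)
})
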