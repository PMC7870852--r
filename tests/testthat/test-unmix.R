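test_that("attenuation change is the element-wise base-10 log ratio", {
  lam <- seq(780, 800, by = 5)
  ref <- c(1000, 1200, 900, 1100, 1050)
  # identity: intensity == reference -> zero attenuation
  eq <- matrix(ref, 4, 5, byrow = TRUE, dimnames = list(NULL, lam))
  expect_true(all(attenuation_change(eq, ref)$values == 0))
  # log10 definition: one decade drop -> dA = 1
  one <- eq
  one[2, 3] <- ref[3] / 10
  expect_equal(unname(attenuation_change(one, ref)$values[2, 3]), 1,
               tolerance = 1e-15)
  # random positive spectra against direct recomputation
  set.seed(1)
  intens <- matrix(exp(stats::rnorm(200, log(1000), 0.3)), 40, 5,
                   dimnames = list(NULL, lam))
  da <- attenuation_change(intens, ref)
  oracle <- log10(matrix(ref, 40, 5, byrow = TRUE) / intens)
  expect_equal(unname(da$values), unname(oracle), tolerance = 1e-12)
})

test_that("non-positive intensities are rejected with their location", {
  lam <- c(780, 790)
  intens <- matrix(c(10, 10, -1, 10), 2, 2, dimnames = list(NULL, lam))
  expect_error(attenuation_change(intens, c(10, 10)),
               "time index 1, wavelength 790")
  expect_error(attenuation_change(matrix(1, 2, 2,
                                         dimnames = list(NULL, lam)),
                                  c(10, 0)), "reference")
})

test_that("unmixing solves a hand-invertible 3x3 system", {
  # eps chosen so the inverse is easy to verify by direct solve
  eps <- matrix(c(1, 0, 0,
                  1, 1, 0,
                  1, 1, 1), 3, 3, byrow = TRUE,
                dimnames = list(NULL, c("HbO2", "HHb", "oxCCO")))
  tbl <- extinction_table(c(780, 800, 820), eps)
  pl <- pathlength_model(geometric_distance = 1, dpf = 1, quiet = TRUE)
  truth <- c(HbO2 = 1, HHb = 2, oxCCO = 3)            # uM
  da <- as.numeric(eps %*% truth) * 1e-3              # mM-based design
  att <- attenuation_series(0:4, c(780, 800, 820),
                            matrix(da, 5, 3, byrow = TRUE))
  rec <- ucln_unmix(att, tbl, pl)
  expect_equal(rec$channels[1, ], truth, tolerance = 1e-10)

  zero <- attenuation_series(0:4, c(780, 800, 820), matrix(0, 5, 3))
  expect_true(all(ucln_unmix(zero, tbl, pl)$channels == 0))
})

test_that("noiseless forward model round-trips through unmixing", {
  tbl <- synthetic_extinction_table(seq(780, 899, by = 1))
  pl <- pathlength_model(geometric_distance = 2, dpf = 3.5, quiet = TRUE)
  spec <- oscillation_spec(base_frequency = 1 / 480,
                           amplitude = c(oxCCO = 0.2, HbO2 = 0.6, HHb = 1),
                           phase_lag = c(oxCCO = 0, HbO2 = 1, HHb = 2),
                           noise_sd = 0.02, duration = 600, seed = 3)
  conc <- generate_concentration_series(spec)
  att <- generate_attenuation_series(conc, tbl, pl)
  rec <- ucln_unmix(att, tbl, pl)
  err <- abs(rec$channels[, c("oxCCO", "HbO2", "HHb")] -
               conc$channels[, c("oxCCO", "HbO2", "HHb")])
  expect_lt(max(err), 1e-8)
})

test_that("unmixing is linear in the attenuation input", {
  tbl <- synthetic_extinction_table(seq(780, 900, by = 2))
  pl <- pathlength_model(quiet = TRUE)
  set.seed(2)
  n <- 20; w <- length(tbl$wavelengths)
  a1 <- attenuation_series(0:(n - 1), tbl$wavelengths,
                           matrix(stats::rnorm(n * w, 0, 0.01), n, w))
  a2 <- attenuation_series(0:(n - 1), tbl$wavelengths,
                           matrix(stats::rnorm(n * w, 0, 0.01), n, w))
  comb <- attenuation_series(0:(n - 1), tbl$wavelengths,
                             2.5 * a1$values - 1.25 * a2$values)
  lhs <- ucln_unmix(comb, tbl, pl)$channels
  rhs <- 2.5 * ucln_unmix(a1, tbl, pl)$channels -
    1.25 * ucln_unmix(a2, tbl, pl)$channels
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("wavelength mismatches and rank deficiency are reported", {
  tbl <- synthetic_extinction_table(seq(780, 900, by = 5))
  pl <- pathlength_model(quiet = TRUE)
  att <- attenuation_series(0:4, c(781, 786), matrix(0.1, 5, 2))
  expect_error(ucln_unmix(att, tbl, pl), "absent from extinction table")

  dup <- cbind(HbO2 = c(1, 2, 3), HHb = c(2, 4, 6), oxCCO = c(0, 1, 0))
  expect_error(extinction_table(c(780, 800, 820), dup), "rank deficient")
})

test_that("near-collinear designs raise a conditioning error", {
  # HbO2 and HHb differ only near 895 nm: the full table is well conditioned,
  # but unmixing a recording restricted to 780-850 nm is not
  lam <- seq(780, 900, by = 5)
  base <- 1 + (lam - 780) / 120
  coef <- cbind(HbO2 = base, HHb = base + exp(-((lam - 895) / 8)^2),
                oxCCO = 0.3 + exp(-((lam - 830) / 46)^2))
  tbl <- extinction_table(lam, coef)
  low <- lam[lam <= 850]
  att <- attenuation_series(0:4, low, matrix(0.1, 5, length(low)))
  expect_error(ucln_unmix(att, tbl, pathlength_model(quiet = TRUE)),
               "condition number")
})

test_that("extinction tables round-trip and natural-log tables convert", {
  tbl <- synthetic_extinction_table(seq(780, 800, by = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_extinction_table(tbl, path)
  back <- read_extinction_table(path)
  expect_equal(back$wavelengths, tbl$wavelengths)
  expect_equal(back$coefficients, tbl$coefficients, tolerance = 1e-15)

  # a table declared ln-based is divided by ln(10) on load
  lines <- readLines(path)
  lines[1] <- "# log_base: e"
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, path2)
  ln_back <- read_extinction_table(path2)
  expect_equal(ln_back$coefficients, tbl$coefficients / log(10),
               tolerance = 1e-12)
})

test_that("pathlength model validates and warns about the default DPF", {
  expect_error(pathlength_model(geometric_distance = 0), "positive")
  expect_error(pathlength_model(dpf = -2), "positive")
  expect_warning(pathlength_model(), "DPF")
  expect_silent(pathlength_model(dpf = 4.99, quiet = FALSE))
})
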