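#' Specification for a synthetic slow-wave oscillation recording
#'
#' Defines the ground truth for a simulated retinal bNIRS recording: a common
#' slow-wave oscillator shared by all chromophore channels, per-channel
#' amplitude and phase lag, cycle-to-cycle period jitter, slow polynomial
#' drift, and additive measurement noise. Slow-wave retinal oscillations sit
#' at roughly 0.001-0.002 Hz (periods of minutes), well below cardiac and
#' respiratory rhythms.
#'
#' Jitter follows a phase-random-walk model: the per-sample phase increment is
#' `2*pi*f*dt * (1 + e)` with `e` Gaussian, its SD scaled so that
#' `period_jitter_sd` is the fractional standard deviation of the
#' cycle-to-cycle period; the random walk broadens the spectral peak smoothly
#' as jitter grows. Drift is a polynomial in time
#' normalized to `[0, 1]` so coefficients are scale-free; the order is capped
#' at 6 so the default detrending step can remove it exactly.
#'
#' @param base_frequency Oscillation frequency in Hz (nominally 0.001-0.002).
#' @param amplitude Named numeric vector, oscillation amplitude in micromolar
#'   per generated channel (`oxCCO`, `HbO2`, `HHb`).
#' @param phase_lag Named numeric vector, phase lag in radians of each channel
#'   relative to `oxCCO`.
#' @param period_jitter_sd Fractional standard deviation of the cycle-to-cycle
#'   period (dimensionless, >= 0).
#' @param drift_coefficients Named list of per-channel polynomial coefficients
#'   (intercept first) over normalized time in `[0, 1]`; at most order 6.
#' @param noise_sd Additive i.i.d. Gaussian noise SD in micromolar.
#' @param duration Recording length in seconds.
#' @param sampling_rate Sampling rate in Hz.
#' @param seed Integer seed; one global seed from which the jitter stream and
#'   per-channel noise streams are split deterministically.
#'
#' @return An object of class `oscillation_spec`.
#' @export
#' @examples
#' spec <- oscillation_spec(base_frequency = 1 / 480, duration = 3600)
#' series <- generate_concentration_series(spec)
oscillation_spec <- function(base_frequency,
                             amplitude = c(oxCCO = 0.2, HbO2 = 0.6, HHb = 1.0),
                             phase_lag = c(oxCCO = 0, HbO2 = 0, HHb = 0),
                             period_jitter_sd = 0,
                             drift_coefficients = list(),
                             noise_sd = 0,
                             duration = 3600,
                             sampling_rate = 1,
                             seed = 1L) {
  if (!is.numeric(base_frequency) || base_frequency <= 0) {
    stop("base_frequency must be positive", call. = FALSE)
  }
  if (!is.numeric(duration) || duration <= 0) {
    stop("duration must be positive", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be positive", call. = FALSE)
  }
  if (sampling_rate <= 2 * base_frequency) {
    stop("sampling_rate must exceed twice the base frequency", call. = FALSE)
  }
  if (period_jitter_sd < 0) stop("period_jitter_sd must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  n <- duration * sampling_rate
  if (abs(n - round(n)) > 1e-9 || round(n) < 2) {
    stop("duration x sampling_rate must give an integer sample count >= 2",
         call. = FALSE)
  }
  chans <- names(amplitude)
  if (is.null(chans) || !setequal(names(phase_lag), chans)) {
    stop("amplitude and phase_lag must be named over the same channels",
         call. = FALSE)
  }
  if (length(drift_coefficients)) {
    if (!all(names(drift_coefficients) %in% chans)) {
      stop("drift_coefficients names must be channel names", call. = FALSE)
    }
    if (any(vapply(drift_coefficients, length, 1L) > 7L)) {
      stop("drift polynomial order is capped at 6", call. = FALSE)
    }
  }
  structure(
    list(base_frequency = base_frequency, amplitude = amplitude,
         phase_lag = phase_lag, period_jitter_sd = period_jitter_sd,
         drift_coefficients = drift_coefficients, noise_sd = noise_sd,
         duration = duration, sampling_rate = sampling_rate,
         seed = as.integer(seed)),
    class = "oscillation_spec"
  )
}

#' @export
print.oscillation_spec <- function(x, ...) {
  cat("<oscillation_spec> f0 = ", format(x$base_frequency), " Hz (period ",
      format(1 / x$base_frequency / 60, digits = 3), " min), jitter sd ",
      x$period_jitter_sd, ", noise sd ", x$noise_sd, " uM, ",
      x$duration, " s @ ", x$sampling_rate, " Hz, seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

polyval_norm <- function(coef, tnorm) {
  out <- numeric(length(tnorm))
  for (k in seq_along(coef)) out <- out + coef[k] * tnorm^(k - 1)
  out
}

#' Generate a synthetic chromophore concentration series
#'
#' Produces `oxCCO`, `HbO2` and `HHb` channels sharing one phase-jittered
#' slow-wave oscillator, with per-channel amplitude and phase lag, polynomial
#' drift, and additive Gaussian noise. Deterministic given the spec's seed;
#' the jitter stream is drawn first, then one noise stream per channel in
#' channel order, so all randomness splits reproducibly from the single seed.
#' Ground-truth parameters are echoed in the result's metadata.
#'
#' @param spec An [oscillation_spec()].
#' @return A [chromophore_ts()] with the generated channels; metadata element
#'   `ground_truth` holds the spec.
#' @export
generate_concentration_series <- function(spec) {
  stopifnot(inherits(spec, "oscillation_spec"))
  n <- round(spec$duration * spec$sampling_rate)
  dt <- 1 / spec$sampling_rate
  time <- (seq_len(n) - 1L) * dt
  tnorm <- if (n > 1) time / time[n] else time

  set.seed(spec$seed)
  base_inc <- 2 * pi * spec$base_frequency * dt
  if (spec$period_jitter_sd > 0) {
    # scale the per-sample increment SD by sqrt(samples per cycle) so that
    # period_jitter_sd is the fractional SD of the cycle-to-cycle period
    per_sample_sd <- spec$period_jitter_sd *
      sqrt(spec$sampling_rate / spec$base_frequency)
    eps <- stats::rnorm(n - 1L, 0, per_sample_sd)
  } else {
    eps <- numeric(n - 1L)
  }
  phase <- c(0, cumsum(base_inc * (1 + eps)))

  chans <- names(spec$amplitude)
  mat <- matrix(0, n, length(chans), dimnames = list(NULL, chans))
  for (ch in chans) {
    x <- spec$amplitude[[ch]] * sin(phase + spec$phase_lag[[ch]])
    dc <- spec$drift_coefficients[[ch]]
    if (!is.null(dc)) x <- x + polyval_norm(dc, tnorm)
    if (spec$noise_sd > 0) x <- x + stats::rnorm(n, 0, spec$noise_sd)
    mat[, ch] <- x
  }
  chromophore_ts(time, mat, metadata = list(ground_truth = spec))
}

#' Cohort presets for the four mouse groups
#'
#' Returns a fully parameterized [oscillation_spec()] for one of the four
#' cohorts: young and old C57 wild-type mice and young and old complement
#' factor H knockout (CFH-/-) mice, a model of age-related macular
#' degeneration. Presets encode the emulated group phenotypes: oscillation
#' period 480 s (8 min) in young C57, 840 s (14 min) in old C57 and 960 s
#' (16 min) in both CFH-/- groups, with period jitter lowest in young C57
#' and highest in young CFH-/- (which shows the least regular oscillations).
#' Old groups carry a small oxygenated-hemoglobin phase lag emulating the
#' age-related loss of phase synchrony between HbO2 and mitochondrial signals.
#'
#' @param name One of `"young_C57"`, `"old_C57"`, `"young_CFH"`, `"old_CFH"`.
#' @param seed Integer seed stored in the returned spec.
#' @return A list of class `cohort_preset` with elements `name` and `spec`.
#' @export
#' @examples
#' cohort_preset("young_C57")$spec$base_frequency  # 1/480 Hz
cohort_preset <- function(name, seed = 1L) {
  presets <- list(
    young_C57 = list(period = 480, jitter = 0.02, hbo2_lag = 0),
    old_C57   = list(period = 840, jitter = 0.10, hbo2_lag = -pi / 3),
    young_CFH = list(period = 960, jitter = 0.16, hbo2_lag = -pi / 6),
    old_CFH   = list(period = 960, jitter = 0.14, hbo2_lag = -pi / 3)
  )
  if (!is.character(name) || length(name) != 1L || !name %in% names(presets)) {
    stop("unknown cohort '", paste(name, collapse = ","), "'; must be one of ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  p <- presets[[name]]
  drift <- list(
    oxCCO = c(0, 0.5, -1.1, 0.6),
    HbO2  = c(0, 1.5, -3.2, 1.8),
    HHb   = c(0, -1.2, 2.6, -1.5)
  )
  spec <- oscillation_spec(
    base_frequency = 1 / p$period,
    amplitude = c(oxCCO = 0.2, HbO2 = 0.6, HHb = 1.0),
    phase_lag = c(oxCCO = 0, HbO2 = p$hbo2_lag, HHb = 0),
    period_jitter_sd = p$jitter,
    drift_coefficients = drift,
    noise_sd = 0.02,
    duration = 3600,
    sampling_rate = 1,
    seed = seed
  )
  structure(list(name = name, spec = spec), class = "cohort_preset")
}

#' @export
print.cohort_preset <- function(x, ...) {
  cat("<cohort_preset> ", x$name, "\n", sep = "")
  print(x$spec)
  invisible(x)
}

#' Synthetic NIR extinction-coefficient table
#'
#' Builds a smooth, full-rank extinction table over the 780-900 nm window used
#' for retinal bNIRS, with qualitatively NIR-plausible shapes: deoxyhemoglobin
#' decreasing from its ~760 nm peak, oxyhemoglobin rising toward 900 nm, and a
#' broad oxidized cytochrome-c-oxidase (CuA) band centred near 830 nm. The
#' values are synthetic stand-ins for a published extinction compilation (none
#' is bundled; real analyses must supply their own table) and are intended for
#' simulation and round-trip testing only.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly increasing.
#' @return An [extinction_table()] in mM^-1 cm^-1 (base-10 convention).
#' @export
synthetic_extinction_table <- function(wavelengths = seq(780, 900, by = 1)) {
  lam <- as.numeric(wavelengths)
  coef <- cbind(
    HbO2  = 0.55 + 0.9 * (lam - 780) / 120 + 0.25 * exp(-((lam - 880) / 35)^2),
    HHb   = 0.45 + 1.6 * exp(-((lam - 758) / 42)^2),
    oxCCO = 0.30 + 2.1 * exp(-((lam - 830) / 46)^2)
  )
  extinction_table(lam, coef, log_base = 10)
}

#' Forward-model broadband attenuation spectra from concentrations
#'
#' Applies the modified Beer-Lambert law in the forward direction: for each
#' time point, the attenuation change at wavelength `lambda` is
#' `pathlength(lambda) * sum_c eps_c(lambda) * dC_c(t)` (with concentrations
#' in micromolar and extinction coefficients in mM^-1 cm^-1), plus optional
#' i.i.d. Gaussian noise. The inverse operation is [ucln_unmix()]; the
#' noiseless round trip recovers the input concentrations to numerical
#' precision.
#'
#' @param conc A [chromophore_ts()] whose channel names match the table's
#'   chromophores.
#' @param table An [extinction_table()].
#' @param pathlength A [pathlength_model()].
#' @param noise_sd Additive noise SD in optical-density units.
#' @param seed Integer seed for the noise stream.
#' @return An [attenuation_series()] on the same time axis.
#' @export
generate_attenuation_series <- function(conc, table, pathlength,
                                        noise_sd = 0, seed = 1L) {
  stopifnot(inherits(conc, "chromophore_ts"),
            inherits(table, "extinction_table"),
            inherits(pathlength, "pathlength_model"))
  chroms <- colnames(table$coefficients)
  missing <- setdiff(chroms, colnames(conc$channels))
  if (length(missing)) {
    stop("concentration series lacks channel(s) required by the extinction ",
         "table: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  design <- unmix_design(table, pathlength)     # wavelength x chromophore
  vals <- conc$channels[, chroms, drop = FALSE] %*% t(design)
  if (noise_sd > 0) {
    set.seed(seed)
    vals <- vals + matrix(stats::rnorm(length(vals), 0, noise_sd),
                          nrow(vals), ncol(vals))
  }
  attenuation_series(conc$time, table$wavelengths, vals)
}
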