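#' Wavelet analysis configuration
#'
#' Settings for the complex-Morlet continuous wavelet transform used in
#' semblance analysis. The center-frequency parameter (omega0, default 6) is
#' the standard time-frequency trade-off and keeps the wavelet admissible in
#' practice (>= 5). The frequency grid is log-spaced across the slow-wave
#' neighbourhood, 0.0005-0.01 Hz in 64 voices by default.
#'
#' @param center_frequency_parameter Morlet omega0, >= 5.
#' @param frequencies Positive increasing frequency grid in Hz.
#' @param coi_handling `"include"` (default: full-record averages, matching
#'   whole-hour summaries) or `"mask"` (exclude cone-of-influence cells).
#' @return An object of class `wavelet_config`.
#' @export
wavelet_config <- function(center_frequency_parameter = 6,
                           frequencies = exp(seq(log(5e-4), log(0.01),
                                                 length.out = 64)),
                           coi_handling = c("include", "mask")) {
  coi_handling <- match.arg(coi_handling)
  if (center_frequency_parameter < 5) {
    stop("center_frequency_parameter must be >= 5 for practical ",
         "admissibility", call. = FALSE)
  }
  frequencies <- as.numeric(frequencies)
  if (any(frequencies <= 0) || is.unsorted(frequencies, strictly = TRUE)) {
    stop("frequencies must be positive and strictly increasing", call. = FALSE)
  }
  structure(list(center_frequency_parameter = center_frequency_parameter,
                 frequencies = frequencies, coi_handling = coi_handling),
            class = "wavelet_config")
}

#' Complex Morlet continuous wavelet transform
#'
#' FFT-based CWT of a mean-removed channel on the config's frequency grid.
#' The Morlet wavelet at angular frequency `omega0` maps frequency `f` to
#' scale via the Fourier factor `4*pi / (omega0 + sqrt(2 + omega0^2))`; the
#' transform is evaluated by multiplying the signal's FFT with the analytic
#' wavelet spectrum at each scale (zero-padded to the next power of two at
#' least twice the record length to limit wrap-around). The modulus of the
#' coefficients peaks at the frequency of a sinusoidal input; the argument is
#' the instantaneous phase used by semblance.
#'
#' @param series A [chromophore_ts()] with uniform sampling.
#' @param channel Channel name.
#' @param config A [wavelet_config()]; all frequencies must be below Nyquist.
#' @return A list of class `morlet_cwt` with `coefficients` (complex, time x
#'   frequency), `time`, `frequency`, and `coi_mask` (TRUE where the cell is
#'   inside the cone of influence, i.e. closer to an edge than the e-folding
#'   time `sqrt(2) * scale`).
#' @export
morlet_cwt <- function(series, channel, config = wavelet_config()) {
  stopifnot(inherits(series, "chromophore_ts"),
            inherits(config, "wavelet_config"))
  x <- ts_channel(series, channel)
  dt <- 1 / series$fs
  freqs <- config$frequencies
  if (max(freqs) >= series$fs / 2) {
    stop("wavelet frequencies must be below Nyquist (", series$fs / 2,
         " Hz)", call. = FALSE)
  }
  n <- length(x)
  np <- 2^ceiling(log2(2 * n))
  xf <- stats::fft(c(x - mean(x), rep(0, np - n)))
  w <- 2 * pi * (seq_len(np) - 1L) / (np * dt)
  w[w > pi / dt] <- w[w > pi / dt] - 2 * pi / dt
  omega0 <- config$center_frequency_parameter
  ff <- (4 * pi) / (omega0 + sqrt(2 + omega0^2))  # period = ff * scale
  W <- matrix(0 + 0i, n, length(freqs))
  coi <- matrix(FALSE, n, length(freqs))
  edge <- pmin(seq_len(n) - 1L, n - seq_len(n)) * dt
  pos <- w > 0
  for (j in seq_along(freqs)) {
    s <- 1 / (freqs[j] * ff)
    psi <- numeric(np)
    psi[pos] <- pi^(-0.25) * sqrt(2 * pi * s / dt) *
      exp(-(s * w[pos] - omega0)^2 / 2)
    W[, j] <- stats::fft(xf * psi, inverse = TRUE)[seq_len(n)] / np
    coi[, j] <- edge < sqrt(2) * s
  }
  structure(list(coefficients = W, time = series$time, frequency = freqs,
                 coi_mask = coi, channel = channel),
            class = "morlet_cwt")
}

#' Wavelet semblance map between two channels
#'
#' Semblance is the cosine of the instantaneous phase difference between two
#' signals, resolved over both time and frequency: from the cross-wavelet
#' field `C = W_a * conj(W_b)`, semblance is `cos(arg C) = Re(C)/|C|`. It is
#' +1 where the signals oscillate perfectly in phase, 0 at 90 degrees (no
#' phase correlation) and -1 in perfect antiphase. Cells whose cross-power
#' falls below `1e-12` of the maximum are flagged undefined (NA) rather than
#' returning noise-driven values.
#'
#' @param series A [chromophore_ts()] containing both channels.
#' @param a,b Channel names sharing the series' time axis.
#' @param config A [wavelet_config()].
#' @return A list of class `semblance_map` with `time`, `frequency`,
#'   `semblance` (in `[-1, 1]` or NA), `cross_power` (`|C|`), `coi_mask` and
#'   `pair`.
#' @export
semblance_map <- function(series, a, b, config = wavelet_config()) {
  wa <- morlet_cwt(series, a, config)
  wb <- morlet_cwt(series, b, config)
  cross <- wa$coefficients * Conj(wb$coefficients)
  pw <- Mod(cross)
  sem <- Re(cross) / pw
  sem[pw < 1e-12 * max(pw)] <- NA_real_
  sem[] <- pmin(1, pmax(-1, sem))
  structure(list(time = wa$time, frequency = wa$frequency, semblance = sem,
                 cross_power = pw, coi_mask = wa$coi_mask | wb$coi_mask,
                 pair = c(a, b)),
            class = "semblance_map")
}

#' @export
print.semblance_map <- function(x, ...) {
  cat("<semblance_map> ", x$pair[1L], " vs ", x$pair[2L], ": ",
      length(x$time), " time points x ", length(x$frequency),
      " frequencies\n", sep = "")
  invisible(x)
}

#' Mean semblance at an oscillation frequency
#'
#' Time-average of the semblance row at the grid frequency nearest
#' `at_frequency`, over the full record. Cells inside the cone of influence
#' are included by default (whole-record averaging); the COI-masked variant is
#' always reported alongside. At slow-wave frequencies the COI covers much of
#' a one-hour record, so masking can leave few cells.
#'
#' @param map A [semblance_map()].
#' @param at_frequency Target frequency in Hz, within the map's grid range
#'   (typically the animal's dominant oscillation frequency).
#' @param band_halfwidth_seconds Display-band half-width around the period,
#'   echoed for map rendering (default 50 s).
#' @return A list of class `semblance_summary` with the pair, the matched grid
#'   frequency, `mean_semblance`, and `mean_semblance_coi_masked`.
#' @export
mean_semblance <- function(map, at_frequency, band_halfwidth_seconds = 50) {
  stopifnot(inherits(map, "semblance_map"))
  fr <- range(map$frequency)
  if (at_frequency < fr[1L] || at_frequency > fr[2L]) {
    stop("frequency ", format(at_frequency), " Hz outside the wavelet grid [",
         format(fr[1L]), ", ", format(fr[2L]), "] Hz", call. = FALSE)
  }
  j <- which.min(abs(map$frequency - at_frequency))
  row <- map$semblance[, j]
  masked <- row
  masked[map$coi_mask[, j]] <- NA_real_
  structure(list(pair = map$pair,
                 at_frequency = map$frequency[j],
                 mean_semblance = mean(row, na.rm = TRUE),
                 mean_semblance_coi_masked =
                   if (all(is.na(masked))) NA_real_ else mean(masked, na.rm = TRUE),
                 band_halfwidth_seconds = band_halfwidth_seconds),
            class = "semblance_summary")
}

#' @export
print.semblance_summary <- function(x, ...) {
  cat("<semblance_summary> ", x$pair[1L], " vs ", x$pair[2L], " @ ",
      format(x$at_frequency), " Hz: mean semblance ",
      format(x$mean_semblance, digits = 4), " (COI-masked ",
      format(x$mean_semblance_coi_masked, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Per-animal semblance panel
#'
#' Mean semblance between each hemoglobin channel (`HHb`, `HbO2`, `HbT`,
#' `HbDiff`) and the mitochondrial `oxCCO` channel at the animal's dominant
#' oscillation frequency, averaged over the whole record. Also reports the
#' display band (period +/- 50 s) used for map rendering.
#'
#' @param series A preprocessed [chromophore_ts()] with all five channels
#'   (composites are derived if `HbO2`/`HHb` are present).
#' @param dominant_frequency The animal's slow-wave frequency in Hz, from
#'   [animal_metrics()].
#' @param config A [wavelet_config()].
#' @return A data frame with columns `pair`, `at_frequency_hz`,
#'   `mean_semblance`, `mean_semblance_coi_masked`, `display_period_lo_s`,
#'   `display_period_hi_s`.
#' @export
animal_semblance_panel <- function(series, dominant_frequency,
                                   config = wavelet_config()) {
  stopifnot(inherits(series, "chromophore_ts"))
  if (!all(c("HbT", "HbDiff") %in% ts_channels(series)) &&
      all(c("HbO2", "HHb") %in% ts_channels(series))) {
    series <- derive_composites(series)
  }
  pairs <- c("HHb", "HbO2", "HbT", "HbDiff")
  missing <- setdiff(c(pairs, "oxCCO"), ts_channels(series))
  if (length(missing)) {
    stop("missing channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  period <- 1 / dominant_frequency
  wcco <- morlet_cwt(series, "oxCCO", config)
  rows <- lapply(pairs, function(hb) {
    whb <- morlet_cwt(series, hb, config)
    cross <- whb$coefficients * Conj(wcco$coefficients)
    pw <- Mod(cross)
    sem <- Re(cross) / pw
    sem[pw < 1e-12 * max(pw)] <- NA_real_
    map <- structure(list(time = wcco$time, frequency = wcco$frequency,
                          semblance = sem, cross_power = pw,
                          coi_mask = wcco$coi_mask | whb$coi_mask,
                          pair = c(hb, "oxCCO")),
                     class = "semblance_map")
    s <- mean_semblance(map, dominant_frequency)
    data.frame(pair = paste0(hb, "-oxCCO"),
               at_frequency_hz = s$at_frequency,
               mean_semblance = s$mean_semblance,
               mean_semblance_coi_masked = s$mean_semblance_coi_masked,
               display_period_lo_s = period - 50,
               display_period_hi_s = period + 50)
  })
  do.call(rbind, rows)
}

#' Render a semblance map
#'
#' Image rendering of a time-frequency semblance field with a diverging color
#' scale anchored at -1 (antiphase), 0 and +1 (in phase), with the y-axis
#' restricted to the display band period +/- 50 s by default, the conventional
#' map layout for these analyses. Rendering is a side output for visual
#' inspection, never an analysis input.
#'
#' @param map A [semblance_map()].
#' @param period_band Length-2 numeric, y-axis limits in seconds of period;
#'   `NULL` shows the full grid.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the map.
#' @export
plot_semblance_map <- function(map, period_band = NULL, ...) {
  stopifnot(inherits(map, "semblance_map"))
  period <- 1 / map$frequency
  keep <- if (is.null(period_band)) {
    seq_along(period)
  } else {
    which(period >= min(period_band) & period <= max(period_band))
  }
  if (!length(keep)) stop("period band outside the wavelet grid", call. = FALSE)
  ord <- keep[order(period[keep])]
  pal <- grDevices::colorRampPalette(c("#21338f", "#3fa34d", "#ffffbf",
                                       "#f46d43", "#a50026"))(101)
  graphics::image(x = map$time, y = period[ord],
                  z = map$semblance[, ord, drop = FALSE],
                  zlim = c(-1, 1), col = pal,
                  xlab = "time (s)", ylab = "period (s)",
                  main = paste(map$pair[1L], "vs", map$pair[2L]), ...)
  invisible(map)
}
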