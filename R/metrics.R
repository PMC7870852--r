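#' One-sided amplitude spectrum
#'
#' FFT amplitude spectrum of a mean-removed channel, zero-padded by
#' `zero_padding_factor` to refine the frequency-bin spacing. For a 3600
#' sample, 1 Hz record the native bin spacing (~0.28 mHz) is too coarse to
#' separate 8 from 14 minute periods; padding interpolates the spectrum so the
#' peak can be localized (it does not add true resolution). No window is
#' applied by default (plain FFT); a Hann window is available.
#'
#' @param series A [chromophore_ts()] with at least 256 samples.
#' @param channel Channel name.
#' @param zero_padding_factor Integer >= 1.
#' @param window `"none"` (default) or `"hann"`.
#' @return An object of class `nirs_spectrum`: list with `frequency` (Hz),
#'   `magnitude` (amplitude units), `source_channel`, `resolution` (bin
#'   spacing, Hz) and `zero_padding_factor`.
#' @export
amplitude_spectrum <- function(series, channel, zero_padding_factor = 16L,
                               window = c("none", "hann")) {
  stopifnot(inherits(series, "chromophore_ts"))
  window <- match.arg(window)
  x <- ts_channel(series, channel)
  n <- length(x)
  if (n < 256L) stop("need >= 256 samples for spectral analysis", call. = FALSE)
  zpf <- max(1L, as.integer(zero_padding_factor))
  x <- x - mean(x)
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
    x <- x * w
  }
  nfft <- n * zpf
  xf <- stats::fft(c(x, rep(0, nfft - n)))
  nb <- floor(nfft / 2) + 1L
  mag <- (2 / n) * Mod(xf[seq_len(nb)])
  freq <- (seq_len(nb) - 1L) * series$fs / nfft
  structure(list(frequency = freq, magnitude = mag, source_channel = channel,
                 resolution = series$fs / nfft,
                 zero_padding_factor = zpf),
            class = "nirs_spectrum")
}

#' @export
print.nirs_spectrum <- function(x, ...) {
  cat("<nirs_spectrum> channel ", x$source_channel, ", ",
      length(x$frequency), " bins, resolution ", format(x$resolution),
      " Hz (zero-padding x", x$zero_padding_factor, ")\n", sep = "")
  invisible(x)
}

default_band <- c(0.0008, 0.004)

#' Dominant oscillation frequency
#'
#' Frequency of the maximum spectral magnitude within a search band. The band
#' default of 0.0008-0.004 Hz brackets the slow-wave range: group periods
#' of ~8 to ~16 minutes correspond to 2.1 down to 1.0 mHz. Ties are broken
#' toward the lower frequency.
#'
#' @param spec An `nirs_spectrum` from [amplitude_spectrum()].
#' @param band Length-2 numeric, `c(low, high)` in Hz, inside the spectrum's
#'   range.
#' @return Dominant frequency in Hz.
#' @export
dominant_frequency <- function(spec, band = default_band) {
  stopifnot(inherits(spec, "nirs_spectrum"))
  if (length(band) != 2L || band[1L] >= band[2L]) {
    stop("band must be c(low, high) with low < high", call. = FALSE)
  }
  sel <- which(spec$frequency >= band[1L] & spec$frequency <= band[2L])
  if (!length(sel)) {
    stop("search band [", band[1L], ", ", band[2L],
         "] Hz contains no spectral bins", call. = FALSE)
  }
  mag <- spec$magnitude[sel]
  if (all(mag == 0)) stop("no oscillatory power in the search band",
                          call. = FALSE)
  spec$frequency[sel[which.max(mag)]]  # which.max returns the first (lowest f)
}

#' Regularity index of slow-wave oscillations
#'
#' Peak FFT magnitude divided by the area under the curve of the full
#' one-sided magnitude spectrum, expressed as a percentage. The AUC is
#' trapezoidal over bin index (a dimensionless sum normalization), so the
#' ratio is scale-invariant: a spectrum concentrated in a single bin scores
#' 100, while broadened (irregular) oscillations spread power over many bins
#' and score lower. The peak is the dominant peak within `band`; the AUC is
#' over the whole spectrum by default (`band_limited_auc` restricts it).
#'
#' @inheritParams dominant_frequency
#' @param band_limited_auc Compute the AUC over the search band only.
#' @return Regularity index in percent.
#' @export
regularity_index <- function(spec, band = default_band,
                             band_limited_auc = FALSE) {
  f0 <- dominant_frequency(spec, band)
  peak <- spec$magnitude[which.min(abs(spec$frequency - f0))]
  mag <- if (band_limited_auc) {
    spec$magnitude[spec$frequency >= band[1L] & spec$frequency <= band[2L]]
  } else {
    spec$magnitude
  }
  auc <- sum(mag) - (mag[1L] + mag[length(mag)]) / 2  # trapezoid, unit spacing
  if (auc <= 0) stop("zero spectral area", call. = FALSE)
  100 * peak / auc
}

#' Per-animal oscillation metrics
#'
#' Computes the dominant frequency, period and regularity index for the three
#' summary channels (`oxCCO`, `HbT`, `HbDiff`) plus a pooled per-animal row:
#' the pooled period and regularity are the means across the three channels
#' (ratio-then-average), and the pooled dominant frequency is the reciprocal
#' of the pooled period, which downstream semblance analysis uses as the
#' animal's oscillation frequency. Composite channels are derived on the fly
#' when `HbO2`/`HHb` are present.
#'
#' @param series A preprocessed [chromophore_ts()].
#' @param band Search band in Hz.
#' @param zero_padding_factor Passed to [amplitude_spectrum()].
#' @return A data frame with columns `channel`, `dominant_frequency_hz`,
#'   `period_min`, `regularity_pct`; the last row is `pooled`.
#' @export
animal_metrics <- function(series, band = default_band,
                           zero_padding_factor = 16L) {
  stopifnot(inherits(series, "chromophore_ts"))
  if (!all(c("HbT", "HbDiff") %in% ts_channels(series)) &&
      all(c("HbO2", "HHb") %in% ts_channels(series))) {
    series <- derive_composites(series)
  }
  need <- c("oxCCO", "HbT", "HbDiff")
  missing <- setdiff(need, ts_channels(series))
  if (length(missing)) {
    stop("missing channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(need, function(ch) {
    sp <- amplitude_spectrum(series, ch, zero_padding_factor)
    f0 <- dominant_frequency(sp, band)
    data.frame(channel = ch, dominant_frequency_hz = f0,
               period_min = 1 / (60 * f0),
               regularity_pct = regularity_index(sp, band))
  })
  per <- do.call(rbind, rows)
  pooled_period <- mean(per$period_min)
  pooled <- data.frame(channel = "pooled",
                       dominant_frequency_hz = 1 / (60 * pooled_period),
                       period_min = pooled_period,
                       regularity_pct = mean(per$regularity_pct))
  rbind(per, pooled)
}
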