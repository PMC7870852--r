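#' Chromophore concentration time series
#'
#' Container for uniformly sampled multi-channel concentration-change series
#' measured (or simulated) by broadband NIRS: changes from baseline in
#' oxidized cytochrome-c-oxidase (`oxCCO`), oxygenated and deoxygenated
#' hemoglobin (`HbO2`, `HHb`), and the derived composites total hemoglobin
#' (`HbT = HHb + HbO2`, a blood-volume proxy) and hemoglobin difference
#' (`HbDiff = HbO2 - HHb`, an oxygenation proxy). All channels are in
#' micromolar change from baseline.
#'
#' @param time Numeric vector of sample times in seconds, uniformly spaced
#'   (deviation from uniformity at most 1e-6 s).
#' @param channels Named numeric matrix or data frame, one column per channel,
#'   `length(time)` rows. All values must be finite.
#' @param metadata Named list of provenance information; for synthetic series
#'   the generating parameters (ground truth) are stored here.
#'
#' @return An object of class `chromophore_ts` with elements `time`, `fs`
#'   (sampling rate in Hz), `channels` (numeric matrix) and `metadata`.
#' @export
#' @examples
#' t <- 0:599
#' x <- sin(2 * pi * t / 480)
#' ts <- chromophore_ts(t, cbind(oxCCO = x, HbO2 = 2 * x, HHb = 3 * x))
#' ts
chromophore_ts <- function(time, channels, metadata = list()) {
  time <- as.numeric(time)
  if (length(time) < 2L) {
    stop("a chromophore time series needs at least 2 samples", call. = FALSE)
  }
  channels <- as.matrix(channels)
  storage.mode(channels) <- "double"
  if (is.null(colnames(channels)) || any(!nzchar(colnames(channels)))) {
    stop("'channels' must have names", call. = FALSE)
  }
  if (nrow(channels) != length(time)) {
    stop("channel length (", nrow(channels), ") does not match time axis (",
         length(time), ")", call. = FALSE)
  }
  if (anyNA(channels) || any(!is.finite(channels))) {
    bad <- which(!is.finite(channels), arr.ind = TRUE)[1L, ]
    stop("non-finite sample in channel '", colnames(channels)[bad[2L]],
         "' at row ", bad[1L],
         "; recordings must be complete (no imputation is performed)",
         call. = FALSE)
  }
  dt <- diff(time)
  if (any(dt <= 0)) stop("time axis must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-6) {
    stop("non-uniform time axis: step deviates by ",
         format(max(dt) - min(dt)), " s (> 1e-6 s) first at row ",
         which.max(abs(dt - stats::median(dt))) + 1L, call. = FALSE)
  }
  structure(
    list(time = time, fs = 1 / stats::median(dt), channels = channels,
         metadata = metadata),
    class = "chromophore_ts"
  )
}

#' @export
print.chromophore_ts <- function(x, ...) {
  cat("<chromophore_ts> ", nrow(x$channels), " samples @ ",
      format(x$fs), " Hz (", format(diff(range(x$time))), " s)\n", sep = "")
  cat("  channels: ", paste(colnames(x$channels), collapse = ", "), "\n",
      sep = "")
  if (length(x$metadata)) {
    cat("  metadata: ", paste(names(x$metadata), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Extract a channel from a chromophore time series
#'
#' @param x A [chromophore_ts()] object.
#' @param channel Channel name.
#' @return Numeric vector of concentration changes.
#' @export
ts_channel <- function(x, channel) {
  stopifnot(inherits(x, "chromophore_ts"))
  if (!channel %in% colnames(x$channels)) {
    stop("unknown channel '", channel, "'; available: ",
         paste(colnames(x$channels), collapse = ", "), call. = FALSE)
  }
  x$channels[, channel]
}

#' Names of channels present in a chromophore time series
#' @param x A [chromophore_ts()] object.
#' @return Character vector.
#' @export
ts_channels <- function(x) {
  stopifnot(inherits(x, "chromophore_ts"))
  colnames(x$channels)
}

#' Derive composite hemoglobin channels
#'
#' Adds total hemoglobin `HbT = HHb + HbO2` (blood-volume proxy) and
#' hemoglobin difference `HbDiff = HbO2 - HHb` (oxygenation / oxygen-delivery
#' proxy) sample-wise. Composites are always recomputed from the hemoglobin
#' channels, so the operation is idempotent and the defining identities hold
#' exactly.
#'
#' @param conc A [chromophore_ts()] containing `HbO2` and `HHb` channels.
#' @return The series with `HbT` and `HbDiff` channels added (or refreshed).
#' @export
derive_composites <- function(conc) {
  stopifnot(inherits(conc, "chromophore_ts"))
  for (need in c("HbO2", "HHb")) {
    if (!need %in% colnames(conc$channels)) {
      stop("cannot derive composites: channel '", need, "' is missing",
           call. = FALSE)
    }
  }
  hbo2 <- conc$channels[, "HbO2"]
  hhb <- conc$channels[, "HHb"]
  keep <- setdiff(colnames(conc$channels), c("HbT", "HbDiff"))
  conc$channels <- cbind(conc$channels[, keep, drop = FALSE],
                         HbT = hhb + hbo2, HbDiff = hbo2 - hhb)
  conc
}
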