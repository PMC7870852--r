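# Steady-state initial conditions for an IIR filter (direct form II
# transposed), so forward-backward filtering starts from the filter's
# step-response equilibrium instead of zero state.
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b))) / a[1L]
  a <- c(a, rep(0, nf - length(a))) / a[1L]
  comp <- matrix(0, nf - 1L, nf - 1L)
  comp[1L, ] <- -a[2:nf]
  if (nf > 2L) comp[cbind(2:(nf - 1L), 1:(nf - 2L))] <- 1
  solve(diag(nf - 1L) - t(comp), b[2:nf] - a[2:nf] * b[1L])
}

# direct form II transposed with explicit initial state
df2t_filter <- function(b, a, x, zi) {
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b))) / a[1L]
  a <- c(a, rep(0, nf - length(a))) / a[1L]
  z <- c(zi, 0)
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1L] * xi + z[1L]
    for (k in seq_len(nf - 1L)) z[k] <- b[k + 1L] * xi + z[k + 1L] - a[k + 1L] * yi
    y[i] <- yi
  }
  y
}

# Zero-phase forward-backward filtering with odd-reflection padding and
# transient-matched initial conditions (the scipy/MATLAB filtfilt scheme).
filtfilt_zi <- function(b, a, x) {
  nf <- max(length(a), length(b))
  n <- length(x)
  npad <- min(3L * (nf - 1L), n - 1L)
  xe <- c(2 * x[1L] - x[(npad + 1L):2L], x,
          2 * x[n] - x[(n - 1L):(n - npad)])
  zi <- lfilter_zi(b, a)
  y <- df2t_filter(b, a, xe, zi * xe[1L])
  y <- rev(df2t_filter(b, a, rev(y), zi * y[length(y)]))
  y[(npad + 1L):(npad + n)]
}

#' Zero-phase low-pass filter
#'
#' Removes high-frequency content above the slow-wave band with a zero-phase
#' (forward-backward) Butterworth filter, default order 5 and cutoff 0.01 Hz.
#' Zero phase is essential here: every downstream result is a phase analysis,
#' so the filter must not shift the signals in time. The channel mean is
#' subtracted before filtering and restored afterwards, which keeps constant
#' offsets exact.
#'
#' @param series A [chromophore_ts()].
#' @param cutoff Cutoff frequency in Hz, strictly below Nyquist.
#' @param order Butterworth order.
#' @return The filtered series, same length and time axis; the processing step
#'   is appended to `metadata$processing`.
#' @export
lowpass <- function(series, cutoff = 0.01, order = 5L) {
  stopifnot(inherits(series, "chromophore_ts"))
  nyq <- series$fs / 2
  if (cutoff <= 0 || cutoff >= nyq) {
    stop("cutoff must lie in (0, Nyquist = ", format(nyq), " Hz)",
         call. = FALSE)
  }
  bt <- signal::butter(order, cutoff / nyq, type = "low")
  out <- series
  for (j in seq_len(ncol(series$channels))) {
    x <- series$channels[, j]
    m <- mean(x)
    out$channels[, j] <- filtfilt_zi(bt$b, bt$a, x - m) + m
  }
  out$metadata$processing <- c(series$metadata$processing,
                               sprintf("lowpass(butterworth order %d, cutoff %g Hz, zero-phase)",
                                       order, cutoff))
  out
}

#' Polynomial detrending
#'
#' Removes slow instrumental drift by subtracting, per channel, the
#' least-squares polynomial of the given order (default 6) in time. The fit
#' uses an orthogonal-polynomial basis on time normalized to `[-1, 1]` for
#' conditioning; any input that is itself a polynomial of degree `<= order`
#' is removed to numerical precision, and the operation is idempotent. The
#' subtracted trend is kept for inspection in `metadata$detrend_trend`.
#'
#' @param series A [chromophore_ts()] with more than `order + 1` samples.
#' @param order Polynomial order, 0 (mean subtraction) to 10.
#' @return The detrended series.
#' @export
detrend_polynomial <- function(series, order = 6L) {
  stopifnot(inherits(series, "chromophore_ts"))
  order <- as.integer(order)
  if (order < 0L || order > 10L) stop("order must be in 0..10", call. = FALSE)
  n <- nrow(series$channels)
  if (n < order + 2L) {
    stop("series too short (", n, " samples) for order-", order,
         " detrending", call. = FALSE)
  }
  tn <- 2 * (series$time - series$time[1L]) / (series$time[n] - series$time[1L]) - 1
  basis <- if (order == 0L) {
    matrix(1, n, 1L)
  } else {
    cbind(1, stats::poly(tn, degree = order))
  }
  out <- series
  trend <- series$channels
  for (j in seq_len(ncol(series$channels))) {
    fit <- stats::lm.fit(basis, series$channels[, j])
    trend[, j] <- series$channels[, j] - fit$residuals
    out$channels[, j] <- fit$residuals
  }
  out$metadata$detrend_trend <- trend
  out$metadata$processing <- c(series$metadata$processing,
                               sprintf("detrend_polynomial(order %d)", order))
  out
}

#' Slow-wave preprocessing configuration and pipeline step
#'
#' Applies the two-step slow-wave isolation: zero-phase low-pass filtering at
#' `lowpass_cutoff` followed by polynomial detrending of order
#' `detrend_order`. Filter-then-detrend is the default order; the reverse is
#' available via `detrend_first`.
#'
#' @param series A [chromophore_ts()].
#' @param lowpass_cutoff Low-pass cutoff in Hz.
#' @param detrend_order Detrending polynomial order.
#' @param detrend_first Apply detrending before filtering.
#' @return The preprocessed series with both steps recorded in
#'   `metadata$processing`.
#' @export
preprocess <- function(series, lowpass_cutoff = 0.01, detrend_order = 6L,
                       detrend_first = FALSE) {
  if (detrend_first) {
    lowpass(detrend_polynomial(series, detrend_order), lowpass_cutoff)
  } else {
    detrend_polynomial(lowpass(series, lowpass_cutoff), detrend_order)
  }
}
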