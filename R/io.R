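#' Write a chromophore time series as delimited text
#'
#' Tab-separated file with a `time_s` column and one column per channel,
#' preceded by `#`-prefixed header lines recording the sampling rate and
#' units. Values are written at full double precision so a read/write round
#' trip is exact to 1e-12.
#'
#' @param series A [chromophore_ts()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_timeseries <- function(series, path) {
  stopifnot(inherits(series, "chromophore_ts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# retiwave chromophore time series",
               sprintf("# sampling_rate_hz: %.17g", series$fs),
               "# units: micromolar_change"), con)
  cols <- cbind(time_s = series$time, series$channels)
  writeLines(paste(colnames(cols), collapse = "\t"), con)
  writeLines(apply(cols, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
  invisible(path)
}

#' Read a chromophore time series from delimited text
#'
#' Expects the schema written by [write_timeseries()]: optional `#` header
#' lines, then a `time_s` column and named channel columns. The time axis
#' must be uniform to within 1e-6 s and all values finite; violations are
#' rejected with the offending row.
#'
#' @param path Input file path.
#' @return A [chromophore_ts()].
#' @export
read_timeseries <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          check.names = FALSE)
  if (!"time_s" %in% names(df)) {
    stop("file lacks required 'time_s' column: ", path, call. = FALSE)
  }
  tm <- df$time_s
  dt <- diff(tm)
  if (length(dt) && (any(dt <= 0) || max(dt) - min(dt) > 1e-6)) {
    bad <- which.max(abs(dt - stats::median(dt))) + 1L
    stop("non-uniform time axis at row ", bad, " of ", path, call. = FALSE)
  }
  ch <- as.matrix(df[setdiff(names(df), "time_s")])
  if (anyNA(ch) || any(!is.finite(ch))) {
    bad <- which(!is.finite(ch), arr.ind = TRUE)[1L, 1L]
    stop("non-finite value at row ", bad, " of ", path, call. = FALSE)
  }
  units <- grep("^#\\s*units:", lines, value = TRUE)
  meta <- list(source = path)
  if (length(units)) meta$units <- trimws(sub("^#\\s*units:", "", units[1L]))
  chromophore_ts(tm, ch, metadata = meta)
}
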