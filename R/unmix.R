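#' Extinction-coefficient table
#'
#' Wavelength-indexed specific extinction coefficients for the three
#' chromophores resolved by broadband NIRS (`HbO2`, `HHb`, `oxCCO`). The table
#' defines the design matrix of the multiwavelength modified Beer-Lambert
#' least-squares fit. Coefficients are stored in the base-10 (optical density)
#' convention in mM^-1 cm^-1; tables supplied in the natural-log convention
#' are converted on load (division by `ln 10`).
#'
#' @param wavelengths Strictly increasing wavelengths in nm, no duplicates.
#' @param coefficients Numeric matrix, one row per wavelength, named columns
#'   (one per chromophore), no missing values, full column rank, at least as
#'   many wavelengths as chromophores.
#' @param log_base Either `10` (optical density, stored as-is) or `"e"`
#'   (converted to base 10).
#' @return An object of class `extinction_table`.
#' @export
extinction_table <- function(wavelengths, coefficients, log_base = 10) {
  lam <- round(as.numeric(wavelengths), 2)  # exact matching at 0.01 nm
  coefficients <- as.matrix(coefficients)
  storage.mode(coefficients) <- "double"
  if (anyDuplicated(lam)) stop("duplicate wavelengths", call. = FALSE)
  if (is.unsorted(lam, strictly = TRUE)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (nrow(coefficients) != length(lam)) {
    stop("coefficient rows must match wavelengths", call. = FALSE)
  }
  if (anyNA(coefficients)) stop("missing extinction values", call. = FALSE)
  if (is.null(colnames(coefficients))) {
    stop("coefficient columns must be named by chromophore", call. = FALSE)
  }
  if (nrow(coefficients) < ncol(coefficients)) {
    stop("need at least as many wavelengths as chromophores", call. = FALSE)
  }
  if (identical(log_base, "e")) {
    coefficients <- coefficients / log(10)
  } else if (!identical(as.numeric(log_base), 10)) {
    stop("log_base must be 10 or \"e\"", call. = FALSE)
  }
  if (qr(coefficients)$rank < ncol(coefficients)) {
    stop("extinction matrix is rank deficient", call. = FALSE)
  }
  structure(list(wavelengths = lam, coefficients = coefficients),
            class = "extinction_table")
}

#' @export
print.extinction_table <- function(x, ...) {
  cat("<extinction_table> ", length(x$wavelengths), " wavelengths (",
      min(x$wavelengths), "-", max(x$wavelengths), " nm) x ",
      ncol(x$coefficients), " chromophores: ",
      paste(colnames(x$coefficients), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Optical pathlength model
#'
#' Effective optical pathlength for the modified Beer-Lambert law: geometric
#' source-detector distance times a differential pathlength factor (DPF),
#' which may be scalar or per-wavelength. No mouse-eye DPF is established, so
#' the default DPF of 1 is conventional: absolute micromolar scaling is then
#' nominal, and a warning says so. All downstream oscillation and phase
#' metrics are invariant to this overall scale.
#'
#' @param geometric_distance Source-detector distance in cm (> 0).
#' @param dpf Dimensionless differential pathlength factor, scalar or one
#'   value per wavelength (> 0).
#' @param quiet Suppress the default-DPF warning.
#' @return An object of class `pathlength_model`.
#' @export
pathlength_model <- function(geometric_distance = 1, dpf = 1, quiet = FALSE) {
  if (any(geometric_distance <= 0) || any(dpf <= 0)) {
    stop("geometric_distance and dpf must be strictly positive", call. = FALSE)
  }
  if (!quiet && all(dpf == 1)) {
    warning("DPF = 1 (no established mouse-eye value): concentration scaling ",
            "is conventional, not absolute; oscillation metrics are ",
            "unaffected", call. = FALSE)
  }
  structure(list(geometric_distance = geometric_distance, dpf = dpf),
            class = "pathlength_model")
}

#' Attenuation-change spectra series
#'
#' Per-time-point attenuation changes (base-10 optical density) across the
#' NIR wavelength grid.
#'
#' @param time Uniform time axis in seconds.
#' @param wavelengths Wavelengths in nm.
#' @param values Numeric matrix, time x wavelength.
#' @return An object of class `attenuation_series`.
#' @export
attenuation_series <- function(time, wavelengths, values) {
  time <- as.numeric(time)
  values <- as.matrix(values)
  if (nrow(values) != length(time) || ncol(values) != length(wavelengths)) {
    stop("values must be time x wavelength", call. = FALSE)
  }
  dt <- diff(time)
  if (length(dt) && (any(dt <= 0) || max(dt) - min(dt) > 1e-6)) {
    stop("time axis must be uniform (within 1e-6 s)", call. = FALSE)
  }
  structure(list(time = time, wavelengths = round(as.numeric(wavelengths), 2),
                 values = values),
            class = "attenuation_series")
}

#' @export
print.attenuation_series <- function(x, ...) {
  cat("<attenuation_series> ", length(x$time), " time points x ",
      length(x$wavelengths), " wavelengths (", min(x$wavelengths), "-",
      max(x$wavelengths), " nm)\n", sep = "")
  invisible(x)
}

#' Attenuation change from reflected-intensity spectra
#'
#' Converts measured reflected intensities to attenuation changes relative to
#' a reference spectrum: `dA(lambda, t) = log10(reference(lambda) /
#' intensity(lambda, t))`, the base-10 optical-density convention of the
#' modified Beer-Lambert law.
#'
#' @param intensity Numeric matrix of strictly positive counts, time x
#'   wavelength, with wavelengths as column names or given via `wavelengths`.
#' @param reference Strictly positive reference spectrum, one value per
#'   wavelength.
#' @param time Time axis in seconds (default: sample index at 1 Hz).
#' @param wavelengths Wavelength axis in nm.
#' @return An [attenuation_series()].
#' @export
attenuation_change <- function(intensity, reference, time = NULL,
                               wavelengths = NULL) {
  intensity <- as.matrix(intensity)
  if (is.null(wavelengths)) wavelengths <- as.numeric(colnames(intensity))
  if (length(reference) != ncol(intensity)) {
    stop("reference length must match the wavelength axis", call. = FALSE)
  }
  if (any(reference <= 0)) {
    stop("non-positive reference intensity at wavelength ",
         wavelengths[which(reference <= 0)[1L]], " nm", call. = FALSE)
  }
  bad <- which(intensity <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-positive intensity at time index ", bad[1L, 1L],
         ", wavelength ", wavelengths[bad[1L, 2L]], " nm", call. = FALSE)
  }
  if (is.null(time)) time <- seq_len(nrow(intensity)) - 1
  da <- log10(matrix(reference, nrow(intensity), ncol(intensity),
                     byrow = TRUE) / intensity)
  attenuation_series(time, wavelengths, da)
}

# design matrix in uM^-1: eps [mM^-1 cm^-1] * distance [cm] * DPF * 1e-3
unmix_design <- function(table, path) {
  pl <- path$geometric_distance * path$dpf
  if (length(pl) != 1L && length(pl) != length(table$wavelengths)) {
    stop("per-wavelength DPF length must match the wavelength grid",
         call. = FALSE)
  }
  table$coefficients * pl * 1e-3
}

#' Multiwavelength modified Beer-Lambert unmixing
#'
#' Recovers chromophore concentration changes from broadband attenuation
#' spectra by ordinary least squares over all wavelengths: per time point,
#' `dC = argmin || (eps * d * DPF) dC - dA ||_2`. Using the full >100
#' wavelength grid resolves the small, broad oxidized cytochrome-c-oxidase
#' signal without crosstalk from the much more concentrated hemoglobins. The
#' solve uses a QR (orthogonal) decomposition of the tall design matrix, not
#' normal equations.
#'
#' @param atten An [attenuation_series()]; its wavelengths must all be present
#'   in the table (exact match after rounding to 0.01 nm).
#' @param table An [extinction_table()].
#' @param path A [pathlength_model()].
#' @return A [chromophore_ts()] with one channel per table chromophore, in
#'   micromolar change.
#' @export
ucln_unmix <- function(atten, table, path = pathlength_model(quiet = TRUE)) {
  stopifnot(inherits(atten, "attenuation_series"),
            inherits(table, "extinction_table"),
            inherits(path, "pathlength_model"))
  idx <- match(atten$wavelengths, table$wavelengths)
  if (anyNA(idx)) {
    stop("wavelengths absent from extinction table: ",
         paste(utils::head(atten$wavelengths[is.na(idx)], 5), collapse = ", "),
         " nm", call. = FALSE)
  }
  sub <- extinction_subset(table, idx)
  design <- unmix_design(sub, path)
  sv <- svd(design, nu = 0, nv = 0)$d
  kappa <- sv[1L] / sv[length(sv)]
  if (!is.finite(kappa) || kappa > 1e8) {
    stop("ill-conditioned unmixing design (condition number ",
         format(kappa, digits = 3), ")", call. = FALSE)
  }
  qrd <- qr(design)
  conc <- t(qr.coef(qrd, t(atten$values)))
  colnames(conc) <- colnames(table$coefficients)
  chromophore_ts(atten$time, conc,
                 metadata = list(unmix = list(n_wavelengths = length(idx),
                                              condition_number = kappa)))
}

extinction_subset <- function(table, idx) {
  structure(list(wavelengths = table$wavelengths[idx],
                 coefficients = table$coefficients[idx, , drop = FALSE]),
            class = "extinction_table")
}

#' Read / write extinction tables as delimited text
#'
#' The file format is tab-separated with columns `wavelength_nm` then one per
#' chromophore, preceded by a header comment line declaring the logarithm
#' convention, e.g. `# log_base: 10`. Natural-log tables are converted to the
#' base-10 convention on load.
#'
#' @param path File path.
#' @return For `read_extinction_table`, an [extinction_table()].
#' @export
read_extinction_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#\\s*log_base:", lines, value = TRUE)
  log_base <- 10
  if (length(hdr)) {
    val <- trimws(sub("^#\\s*log_base:", "", hdr[1L]))
    log_base <- if (identical(val, "e")) "e" else as.numeric(val)
  }
  df <- utils::read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                          sep = "\t", check.names = FALSE)
  if (!"wavelength_nm" %in% names(df)) {
    stop("extinction table must have a 'wavelength_nm' column", call. = FALSE)
  }
  coef <- as.matrix(df[setdiff(names(df), "wavelength_nm")])
  extinction_table(df$wavelength_nm, coef, log_base = log_base)
}

#' @rdname read_extinction_table
#' @param table An [extinction_table()] to write (always written base 10).
#' @export
write_extinction_table <- function(table, path) {
  stopifnot(inherits(table, "extinction_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# log_base: 10", con)
  df <- data.frame(wavelength_nm = table$wavelengths, table$coefficients,
                   check.names = FALSE)
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(apply(df, 1L, function(r)
    paste(sprintf("%.17g", as.numeric(r)), collapse = "\t")), con)
  invisible(path)
}
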