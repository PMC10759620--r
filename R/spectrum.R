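#' Single absorbance scan
#'
#' A `spectrum` is one spectrophotometer scan: a strictly increasing
#' wavelength grid (nm) with one absorbance value (AU) per point, labelled
#' with its measurement condition and an optional replicate number.
#'
#' @param wavelengths strictly increasing numeric vector, nm.
#' @param absorbances numeric vector of equal length, absorbance units.
#' @param condition one of `"dark"`, `"light"`, `"difference"`.
#' @param replicate_id optional 1-based replicate integer.
#' @return an object of class `spectrum`.
#' @export
spectrum <- function(wavelengths, absorbances,
                     condition = c("dark", "light", "difference"),
                     replicate_id = NULL) {
  condition <- match.arg(condition)
  if (!is.numeric(wavelengths) || !is.numeric(absorbances))
    stop_input("wavelengths and absorbances must be numeric")
  if (length(wavelengths) != length(absorbances))
    stop_input("wavelengths and absorbances must have equal length")
  if (length(wavelengths) < 2L)
    stop_input("a spectrum needs at least 2 points")
  if (anyNA(wavelengths) || anyNA(absorbances))
    stop_input("spectra must not contain missing values")
  if (any(diff(wavelengths) <= 0))
    stop_input("wavelengths must be strictly increasing")
  if (!is.null(replicate_id)) {
    replicate_id <- as.integer(replicate_id)
    stopifnot(length(replicate_id) == 1L, replicate_id >= 1L)
  }
  structure(
    list(wavelengths = as.numeric(wavelengths),
         absorbances = as.numeric(absorbances),
         condition = condition, replicate_id = replicate_id),
    class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s%s: %d points, %.0f-%.0f nm\n",
              x$condition,
              if (is.null(x$replicate_id)) "" else
                sprintf(" (replicate %d)", x$replicate_id),
              length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelengths, absorbance = x$absorbances,
             condition = x$condition,
             replicate = x$replicate_id %||% NA_integer_)
}

same_grid <- function(a, b) {
  length(a$wavelengths) == length(b$wavelengths) &&
    all(a$wavelengths == b$wavelengths)
}

#' Replicated dark/light measurement of one pigment
#'
#' Container for the replicated scans of one reconstructed pigment: at least
#' one dark scan, and optionally post-bleach ("light") scans, all on one
#' shared wavelength grid.
#'
#' @param pigment_label free-text label for the pigment.
#' @param dark_scans list of `spectrum` objects with condition `"dark"`.
#' @param light_scans list of `spectrum` objects with condition `"light"`;
#'   may be empty for dark-only analysis.
#' @return an object of class `spectral_measurement`.
#' @export
spectral_measurement <- function(pigment_label, dark_scans,
                                 light_scans = list()) {
  stopifnot(is.character(pigment_label), length(pigment_label) == 1L)
  if (!is.list(dark_scans) || length(dark_scans) < 1L)
    stop_input("at least one dark scan is required")
  all_scans <- c(dark_scans, light_scans)
  if (!all(vapply(all_scans, inherits, logical(1), "spectrum")))
    stop_input("dark_scans and light_scans must be lists of spectrum objects")
  if (!all(vapply(dark_scans, function(s) s$condition == "dark", logical(1))))
    stop_input("all dark_scans must have condition 'dark'")
  if (length(light_scans) &&
      !all(vapply(light_scans, function(s) s$condition == "light", logical(1))))
    stop_input("all light_scans must have condition 'light'")
  ref <- all_scans[[1L]]
  if (!all(vapply(all_scans, same_grid, logical(1), ref)))
    stop_input("all scans must share one wavelength grid")
  structure(list(pigment_label = pigment_label,
                 dark_scans = dark_scans, light_scans = light_scans),
            class = "spectral_measurement")
}

#' @export
print.spectral_measurement <- function(x, ...) {
  cat(sprintf("<spectral_measurement> '%s': %d dark, %d light scan(s)\n",
              x$pigment_label, length(x$dark_scans), length(x$light_scans)))
  invisible(x)
}

#' Read and write measurement CSV files
#'
#' The on-disk dialect has columns `wavelength_nm`, `absorbance`,
#' `condition` (`dark`/`light`) and `replicate` (1-based). A bare
#' two-column `wavelength,absorbance` file can be read by supplying the
#' condition and replicate through arguments.
#'
#' @param measurement a `spectral_measurement`.
#' @param path file path.
#' @rdname measurement_csv
#' @export
write_measurement_csv <- function(measurement, path) {
  stopifnot(inherits(measurement, "spectral_measurement"))
  rows <- do.call(rbind, lapply(c(measurement$dark_scans,
                                  measurement$light_scans),
                                as.data.frame))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param pigment_label label for the measurement read back.
#' @param condition,replicate_id used only when the file is a bare
#'   two-column `wavelength,absorbance` table.
#' @rdname measurement_csv
#' @export
read_measurement_csv <- function(path, pigment_label = basename(path),
                                 condition = "dark", replicate_id = 1L) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (ncol(d) == 2L) {
    names(d) <- c("wavelength_nm", "absorbance")
    d$condition <- condition
    d$replicate <- replicate_id
  }
  need <- c("wavelength_nm", "absorbance", "condition", "replicate")
  if (!all(need %in% names(d)))
    stop_input("CSV must have columns ", paste(need, collapse = ", "),
               " (or exactly two columns wavelength,absorbance)")
  mk <- function(cond) {
    sub <- d[d$condition == cond, , drop = FALSE]
    lapply(sort(unique(sub$replicate)), function(r) {
      s <- sub[sub$replicate == r, ]
      s <- s[order(s$wavelength_nm), ]
      spectrum(s$wavelength_nm, s$absorbance, cond, r)
    })
  }
  spectral_measurement(pigment_label, mk("dark"), mk("light"))
}
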