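#' Plot a measurement with its fitted curve and lambda-max marker
#'
#' Draws the mean spectrum for the requested method (dark or difference),
#' overlays the smoothing-spline fit, and marks the estimated lambda-max.
#' If `file` is given the plot is written as SVG or PNG by extension.
#'
#' @param measurement a [spectral_measurement()].
#' @param estimate optional [estimate_lambda_max()] result; computed from
#'   `measurement` when omitted (then `search_window` is required).
#' @param method,search_window,smoothness passed to
#'   [estimate_lambda_max()] when `estimate` is missing.
#' @param file optional `.svg` or `.png` output path.
#' @return the estimate, invisibly.
#' @export
plot_spectrum_fit <- function(measurement, estimate = NULL,
                              method = "dark_spectrum", search_window = NULL,
                              smoothness = 0.9, file = NULL) {
  stopifnot(inherits(measurement, "spectral_measurement"))
  if (is.null(estimate))
    estimate <- estimate_lambda_max(measurement, method,
                                    search_window = search_window,
                                    smoothness = smoothness)
  method <- estimate$method
  scans <- if (method == "dark_spectrum") measurement$dark_scans
  else lapply(seq_len(min(length(measurement$dark_scans),
                          length(measurement$light_scans))), function(i)
    difference_spectrum(measurement$dark_scans[[i]],
                        measurement$light_scans[[i]]))
  avg <- average_spectra(scans)
  fit <- fit_smoothing_spline(avg, estimate$smoothness)
  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) grDevices::svg(file)
    else if (grepl("\\.png$", file)) grDevices::png(file, 800, 600)
    else stop_input("file must end in .svg or .png")
    on.exit(grDevices::dev.off())
  }
  plot(avg$wavelengths, avg$absorbances, type = "p", pch = 16, cex = 0.3,
       col = "grey50", xlab = "wavelength (nm)", ylab = "absorbance (AU)",
       main = sprintf("%s (%s)", measurement$pigment_label, method))
  lines(avg$wavelengths, predict(fit, avg$wavelengths), lwd = 2,
        col = "firebrick")
  abline(v = estimate$mean_nm, lty = 2)
  graphics::mtext(sprintf("lambda-max %.1f +/- %.1f nm", estimate$mean_nm,
                          if (is.na(estimate$sd_nm)) 0 else estimate$sd_nm),
                  side = 3, line = 0.2, cex = 0.8)
  invisible(estimate)
}

#' 24-h activity histogram for one individual
#'
#' Mirrors the standard 24-h activity profile: active-minute counts per
#' hourly (or custom) bin summed over the recording, with the light span
#' shaded.
#'
#' @param table an `activity_table`.
#' @param individual id to plot; default the first present.
#' @param bin_minutes bin width in minutes (default 60).
#' @param schedule a [light_schedule()] used for shading.
#' @param file optional `.svg` or `.png` output path.
#' @return the per-bin counts, invisibly.
#' @export
plot_activity_profile <- function(table, individual = NULL,
                                  bin_minutes = 60L,
                                  schedule = light_schedule(),
                                  file = NULL) {
  d <- as_activity_table(table)
  if (is.null(individual)) individual <- d$individual[1L]
  d <- d[d$individual == individual & d$active == 1, , drop = FALSE]
  lt <- as.POSIXlt(d$timestamp, tz = "UTC")
  mod <- lt$hour * 60L + lt$min
  bins <- factor(mod %/% bin_minutes, levels = 0:(1440 %/% bin_minutes - 1))
  counts <- table(bins)
  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) grDevices::svg(file)
    else if (grepl("\\.png$", file)) grDevices::png(file, 800, 600)
    else stop_input("file must end in .svg or .png")
    on.exit(grDevices::dev.off())
  }
  mids <- (as.integer(levels(bins)) + 0.5) * bin_minutes / 60
  graphics::barplot(as.integer(counts), names.arg = sprintf("%02d", floor(mids)),
                    xlab = "hour of day", ylab = "active minutes",
                    main = sprintf("24-h activity: %s", individual),
                    col = ifelse(is_light_minute(mids * 60, schedule),
                                 "khaki", "grey40"))
  invisible(counts)
}
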