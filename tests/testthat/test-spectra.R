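# Spectrum processing: averaging, differences, spline fits, lambda-max,
# Welch's t-test.

make_spec <- function(values, wl = seq(400, 500, by = 1), cond = "dark",
                      rep_id = NULL) {
  spectrum(wl, values, cond, rep_id)
}

test_that("average_spectra is the pointwise mean and validates grids", {
  wl <- seq(400, 500, 5)
  s1 <- spectrum(wl, sin(wl / 50), "dark")
  expect_equal(average_spectra(list(s1))$absorbances, s1$absorbances)

  s2 <- spectrum(wl, -sin(wl / 50), "dark")
  expect_equal(average_spectra(list(s1, s2))$absorbances, rep(0, length(wl)))

  # 8 noise-free simulated scans average to the single noise-free scan
  p <- pigment_template_params(443, noise_sd = 0, n_replicates = 8)
  m <- simulate_measurement(p)
  avg <- average_spectra(m$dark_scans)
  expect_equal(avg$absorbances, m$dark_scans[[1]]$absorbances)

  s3 <- spectrum(wl + 1, sin(wl / 50), "dark")
  expect_error(average_spectra(list(s1, s3)), "grid")
  s4 <- spectrum(wl, sin(wl / 50), "light")
  expect_error(average_spectra(list(s1, s4)), "condition")
  expect_error(average_spectra(list()), "non-empty")
})

test_that("difference_spectrum subtracts pointwise and is linear over replicates", {
  wl <- seq(400, 500, 2)
  d <- spectrum(wl, rep(0.5, length(wl)), "dark")
  l <- spectrum(wl, rep(0.5, length(wl)), "light")
  expect_equal(difference_spectrum(d, l)$absorbances, rep(0, length(wl)))
  expect_equal(difference_spectrum(d, l)$condition, "difference")
  expect_error(difference_spectrum(l, d), "dark and a light")

  p <- pigment_template_params(443, noise_sd = 0.002, bleach_fraction = 1,
                               n_replicates = 4, seed = 9)
  m <- simulate_measurement(p)
  per_rep <- lapply(1:4, function(i)
    difference_spectrum(m$dark_scans[[i]], m$light_scans[[i]]))
  mean_of_diffs <- average_spectra(per_rep)
  diff_of_means <- spectrum(
    m$dark_scans[[1]]$wavelengths,
    average_spectra(m$dark_scans)$absorbances -
      average_spectra(m$light_scans)$absorbances,
    "difference")
  expect_equal(mean_of_diffs$absorbances, diff_of_means$absorbances)
})

test_that("smoothing spline reproduces penalty-null-space data and orders RSS", {
  wl <- seq(400, 500, 1)
  # linear data lie in the roughness-penalty null space and are reproduced
  # at every smoothness; a cubic has nonzero second derivative, so it is
  # reproduced only at light smoothing and shrunk toward linearity beyond
  lin <- spectrum(wl, 0.001 * wl + 0.2, "dark")
  for (sm in c(0, 0.3, 0.6, 0.9, 1)) {
    f <- fit_smoothing_spline(lin, sm)
    expect_equal(predict(f, wl), lin$absorbances, tolerance = 1e-6)
  }
  # a cubic is reproduced at low smoothness
  cub <- spectrum(wl, 1e-6 * (wl - 450)^3 + 0.1, "dark")
  f <- fit_smoothing_spline(cub, 0.1)
  expect_equal(predict(f, wl), cub$absorbances, tolerance = 1e-4)

  # noise-free template at moderate smoothness: residuals < 1% of amplitude
  grid <- seq(250, 700, 1)
  tmpl <- spectrum(grid, govardovskii_template(443, grid), "dark")
  f <- fit_smoothing_spline(tmpl, 0.8)
  expect_lt(max(abs(predict(f, grid) - tmpl$absorbances)), 0.01)

  # RSS non-decreasing in the smoothness control
  noisy <- spectrum(grid, govardovskii_template(443, grid) +
                      sin(grid / 3) * 0.02, "dark")
  rss <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9, 0.99),
                function(sm) fit_smoothing_spline(noisy, sm)$rss, numeric(1))
  expect_true(all(diff(rss) >= -1e-10))

  expect_error(fit_smoothing_spline(make_spec(1:5, wl = 1:5)), "10 points")
  expect_error(fit_smoothing_spline(lin, 2), "smoothness")
  expect_error(predict(fit_smoothing_spline(lin, 0.5), 600), "range")
})

test_that("estimate_lambda_max recovers simulated truth", {
  # noise-free: within 1 nm of a 443-nm pigment
  p <- pigment_template_params(443, noise_sd = 0, n_replicates = 3)
  m <- simulate_measurement(p)
  e <- estimate_lambda_max(m, "dark_spectrum", c(380, 520))
  expect_lt(abs(e$mean_nm - 443), 1)
  expect_equal(e$sd_nm, 0)          # identical replicates
  expect_equal(e$n, 3)
  expect_identical(e$status, "ok")

  # noisy, fixed seed: sd > 0 and mean within 3 nm
  p2 <- pigment_template_params(443, seed = 101)
  e2 <- estimate_lambda_max(simulate_measurement(p2), "dark_spectrum",
                            c(380, 520))
  expect_gt(e2$sd_nm, 0)
  expect_lt(abs(e2$mean_nm - 443), 3)

  # mean/sd always recomputable from the per-replicate peaks
  expect_equal(e2$mean_nm, mean(e2$per_replicate_peaks))
  expect_equal(e2$sd_nm, sd(e2$per_replicate_peaks))
  expect_true(all(e2$per_replicate_peaks >= 380 &
                    e2$per_replicate_peaks <= 520))
})

test_that("difference-spectrum lambda-max exceeds dark-spectrum for a 443-nm pigment", {
  # full bleach with a 380-nm product distorts the short-wave flank: the
  # indirect (difference) estimate overshoots the direct (dark) one
  p <- pigment_template_params(443, noise_sd = 0, bleach_fraction = 1,
                               n_replicates = 2)
  m <- simulate_measurement(p)
  dark <- estimate_lambda_max(m, "dark_spectrum", c(380, 520))
  diff <- estimate_lambda_max(m, "difference_spectrum", c(380, 520))
  expect_gte(diff$mean_nm - dark$mean_nm, 2)
})

test_that("estimate_lambda_max flags and errors as specified", {
  p <- pigment_template_params(443, noise_sd = 0, n_replicates = 1)
  m <- simulate_measurement(p)
  m_dark_only <- spectral_measurement("x", m$dark_scans)
  expect_error(estimate_lambda_max(m_dark_only, "difference_spectrum",
                                   c(380, 520)), "light scans")
  expect_error(estimate_lambda_max(m, "dark_spectrum", c(100, 520)),
               "inside the grid")
  # a window on the monotone flank has no interior peak: flagged
  expect_warning(
    e <- estimate_lambda_max(m, "dark_spectrum", c(500, 600)),
    "no interior peak")
  expect_identical(e$status, "boundary_peak")
})

test_that("welch_t_test matches stats::t.test and its own summary route", {
  set.seed(42)
  x <- rnorm(8, 570, 14)
  y <- rnorm(8, 560, 9)
  w <- welch_t_test(x, y)
  ref <- t.test(x, y, var.equal = FALSE)
  expect_equal(w$t_statistic, unname(ref$statistic))
  expect_equal(w$df, unname(ref$parameter))
  expect_equal(w$p_value, ref$p.value)

  ws <- welch_t_test(c(mean = mean(x), sd = sd(x), n = 8),
                     c(mean = mean(y), sd = sd(y), n = 8))
  expect_equal(ws$p_value, w$p_value)

  # identical groups: t = 0, p = 1
  w0 <- welch_t_test(x, x)
  expect_equal(w0$t_statistic, 0)
  expect_equal(w0$p_value, 1)

  expect_error(welch_t_test(c(1), c(1, 2)), "n >= 2")
  expect_error(welch_t_test(c(mean = 1, sd = 0, n = 8),
                            c(mean = 2, sd = 0, n = 8)), "zero sd")
})

test_that("welch_t_test accepts lambda_max_estimate objects symmetrically", {
  p <- pigment_template_params(443, seed = 11)
  e1 <- estimate_lambda_max(simulate_measurement(p), "dark_spectrum",
                            c(380, 520))
  p2 <- pigment_template_params(460, seed = 12)
  e2 <- estimate_lambda_max(simulate_measurement(p2), "dark_spectrum",
                            c(380, 520))
  w <- welch_t_test(e1, e2)
  w_raw <- welch_t_test(e1$per_replicate_peaks, e2$per_replicate_peaks)
  expect_equal(w$p_value, w_raw$p_value)
  expect_lt(w$p_value, 0.05)
})

test_that("lambda-max estimates round-trip through JSON", {
  p <- pigment_template_params(443, seed = 101)
  e <- estimate_lambda_max(simulate_measurement(p), "dark_spectrum",
                           c(380, 520))
  f <- tempfile(fileext = ".json")
  write_lambda_max_json(e, f)
  e2 <- read_lambda_max_json(f)
  expect_equal(e2$mean_nm, e$mean_nm)
  expect_equal(e2$per_replicate_peaks, e$per_replicate_peaks)
  expect_equal(welch_t_test(e, e)$t_statistic, 0)
})
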