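#' Build a conductance spectrum
#'
#' A conductance spectrum is one sweep of the sensor admittance analyser:
#' conductance sampled on a strictly increasing frequency grid around the
#' resonance, at one timestamp. It is stored as a plain tibble so sweeps can
#' be stacked, filtered and plotted with ordinary tidyverse verbs.
#'
#' @param frequency_hz Strictly increasing numeric vector of swept
#'   frequencies (Hz), length >= 8.
#' @param conductance Non-negative conductance values (arbitrary units), same
#'   length as `frequency_hz`.
#' @param timestamp_s Time of the sweep, seconds since activation.
#'
#' @return A tibble with columns `timestamp_s`, `frequency_hz`, `conductance`.
#' @examples
#' sp <- conductance_spectrum(seq(4.9997e6, 5.0003e6, by = 1),
#'                            lorentzian(seq(4.9997e6, 5.0003e6, by = 1),
#'                                       f = 5e6, gamma = 30, amplitude = 1))
#' fit_resonance(sp)
#' @export
conductance_spectrum <- function(frequency_hz, conductance, timestamp_s = 0) {
  if (length(frequency_hz) != length(conductance))
    abort("`frequency_hz` and `conductance` must have the same length.")
  if (length(frequency_hz) < 8L)
    abort("A conductance spectrum needs at least 8 points.")
  check_strictly_increasing(frequency_hz, "frequency_hz")
  if (any(!is.finite(conductance)) || any(conductance < 0))
    abort("`conductance` must be finite and non-negative.")
  stopifnot_scalar_number(timestamp_s, "timestamp_s")
  tibble(timestamp_s = timestamp_s,
         frequency_hz = as.numeric(frequency_hz),
         conductance = as.numeric(conductance))
}

#' Lorentzian conductance peak
#'
#' Canonical model of the conductance resonance of a shear-mode quartz
#' resonator: `G(x) = baseline + amplitude * gamma^2 / ((x - f)^2 + gamma^2)`,
#' where `f` is the resonant frequency and `gamma` the half width at half
#' maximum (the bandwidth).
#'
#' @param x Frequencies (Hz).
#' @param f Resonant frequency (Hz).
#' @param gamma Half width at half maximum (Hz), > 0.
#' @param amplitude Peak conductance above baseline.
#' @param baseline Offset conductance.
#' @return Conductance values, same length as `x`.
#' @export
lorentzian <- function(x, f, gamma, amplitude = 1, baseline = 0) {
  baseline + amplitude * gamma^2 / ((x - f)^2 + gamma^2)
}

# data-driven starting values: smoothed argmax, half-max crossings, median
# baseline. Errors with "flat spectrum" when there is no usable interior peak.
resonance_start <- function(x, y) {
  n <- length(y)
  if (diff(range(y)) <= 0) abort("flat spectrum: conductance has no peak.")
  k <- min(5L, if (n %% 2L == 0L) n - 1L else n)
  ys <- if (k >= 3L) as.numeric(stats::filter(y, rep(1 / k, k), sides = 2)) else y
  ys[is.na(ys)] <- -Inf
  i0 <- which.max(ys)
  if (i0 <= 1L || i0 >= n)
    abort("flat spectrum: no interior conductance maximum.")
  if (max(y[2:(n - 1L)]) < max(y[1], y[n]))
    abort("flat spectrum: conductance maximum sits at the sweep edge.")
  baseline0 <- median(y)
  amp0 <- y[i0] - baseline0
  if (amp0 <= 0) abort("flat spectrum: peak does not rise above the baseline.")
  half <- baseline0 + amp0 / 2
  left <- x[1]
  for (i in seq(i0, 2L)) {
    if (y[i - 1L] < half && y[i] >= half) {
      left <- approx(y[(i - 1L):i], x[(i - 1L):i], xout = half)$y
      break
    }
  }
  right <- x[n]
  for (i in seq(i0, n - 1L)) {
    if (y[i] >= half && y[i + 1L] < half) {
      right <- approx(y[(i + 1L):i], x[(i + 1L):i], xout = half)$y
      break
    }
  }
  gamma0 <- max((right - left) / 2, diff(range(x)) / n)
  list(f = x[i0], gamma = gamma0, amplitude = amp0, baseline = baseline0)
}

#' Fit a Lorentzian resonance to a conductance spectrum
#'
#' Extracts the resonant frequency `f` and half bandwidth `gamma` (half width
#' at half maximum) by bounded Levenberg-Marquardt least squares on the
#' four-parameter Lorentzian [lorentzian()]. Starting values are derived from
#' the data (smoothed peak position, half-maximum crossings) unless supplied.
#'
#' @param spectrum Data frame with columns `frequency_hz` and `conductance`
#'   (one sweep; see [conductance_spectrum()]).
#' @param initial_guess Optional named list with any of `f`, `gamma`,
#'   `amplitude`, `baseline` to override the data-driven starting values.
#'
#' @return An object of class `resonance_fit`: a list with elements `f`,
#'   `gamma`, `amplitude`, `baseline` (the fitted parameters), `fit_rss`
#'   (residual sum of squares), `n_points`, `iterations`, `timestamp_s`, and
#'   `data` (the input sweep with fitted values). Use [tidy()] / [glance()] /
#'   [autoplot()] on it.
#' @examples
#' x <- seq(4.9e6, 5.1e6, length.out = 401)
#' sp <- conductance_spectrum(x, lorentzian(x, 4.9985e6, 2000, 1, 0.05))
#' glance(fit_resonance(sp))
#' @export
fit_resonance <- function(spectrum, initial_guess = NULL) {
  if (!is.data.frame(spectrum) ||
      !all(c("frequency_hz", "conductance") %in% names(spectrum)))
    abort("`spectrum` must have columns `frequency_hz` and `conductance`.")
  x <- spectrum$frequency_hz
  y <- spectrum$conductance
  if (length(x) < 8L) abort("A conductance spectrum needs at least 8 points.")
  check_strictly_increasing(x, "frequency_hz")

  start <- resonance_start(x, y)
  if (!is.null(initial_guess)) {
    bad <- setdiff(names(initial_guess), names(start))
    if (length(bad)) abort(paste0("Unknown initial_guess fields: ",
                                  paste(bad, collapse = ", ")))
    start[names(initial_guess)] <- initial_guess
  }

  # centre frequencies on the initial peak estimate so all parameters are on
  # comparable scales; fit with analytic Jacobian under parameter bounds
  span <- diff(range(x))
  x_ref <- start$f
  xc <- x - x_ref
  residual <- function(p) y - (p[1] + p[2] * p[4]^2 / ((xc - p[3])^2 + p[4]^2))
  jacobian <- function(p) {
    D <- (xc - p[3])^2 + p[4]^2
    L <- p[4]^2 / D
    cbind(-1, -L,
          -p[2] * p[4]^2 * 2 * (xc - p[3]) / D^2,
          -2 * p[2] * p[4] * (xc - p[3])^2 / D^2)
  }
  p0 <- c(start$baseline, start$amplitude, 0, start$gamma)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = p0, fn = residual, jac = jacobian,
      lower = c(-Inf, 0, min(x) - x_ref, span * 1e-9),
      upper = c(Inf, Inf, max(x) - x_ref, Inf),
      control = minpack.lm::nls.lm.control(
        maxiter = 500, ftol = 1e-10, ptol = 1e-10)),
    error = function(e) abort(paste0("fit failed: ", conditionMessage(e))))
  if (fit$info == 5L || fit$info == 0L)
    abort(sprintf("fit failed: no convergence after %d iterations (%s).",
                  fit$niter, fit$message))

  p <- list(b0 = fit$par[1], A = fit$par[2],
            f = fit$par[3] + x_ref, g = fit$par[4])
  fitted_y <- lorentzian(x, p$f, p$g, p$A, p$b0)
  rss <- sum((y - fitted_y)^2)
  if (p$A <= 0 || p$g <= 0)
    abort("fit failed: degenerate peak (non-positive amplitude or bandwidth).")

  structure(
    list(f = p$f, gamma = p$g, amplitude = p$A, baseline = p$b0,
         fit_rss = rss, n_points = length(x),
         iterations = fit$niter,
         timestamp_s = if ("timestamp_s" %in% names(spectrum))
           spectrum$timestamp_s[1] else NA_real_,
         data = tibble(frequency_hz = x, conductance = y,
                       .fitted = fitted_y)),
    class = "resonance_fit")
}

#' @export
print.resonance_fit <- function(x, ...) {
  cat("<resonance_fit>\n")
  cat(sprintf("  f        : %.3f Hz\n", x$f))
  cat(sprintf("  gamma    : %.3f Hz (HWHM)\n", x$gamma))
  cat(sprintf("  amplitude: %.4g   baseline: %.4g\n", x$amplitude, x$baseline))
  cat(sprintf("  RSS %.3g over %d points\n", x$fit_rss, x$n_points))
  invisible(x)
}

#' Track resonance across a time series of sweeps
#'
#' Fits every sweep with [fit_resonance()] and converts the fitted `(f, gamma)`
#' trajectory to shift time courses relative to the unloaded (in-air) sensor:
#' `dF(t) = f_air - f(t)` (down-shift magnitude, so mass loading is positive)
#' and `dG(t) = gamma(t) - gamma_air`. The result is baseline-referenced at
#' the sample-loading snapshot via [baseline_reference()].
#'
#' @param spectra Data frame of stacked sweeps with columns `timestamp_s`,
#'   `frequency_hz`, `conductance`; timestamps must be strictly increasing
#'   across sweeps.
#' @param f_air,gamma_air In-air resonant frequency and half bandwidth (Hz);
#'   `gamma_air` must be > 0.
#' @param z_index Index (1-based, in sweep order) of the sample-loading
#'   snapshot used as the starred-baseline reference.
#'
#' @return A `shift_series` tibble (see [baseline_reference()]) with extra
#'   columns `f_hz`, `gamma_hz`, `fit_rss` carrying the per-sweep fit.
#' @export
track_resonance <- function(spectra, f_air, gamma_air, z_index = 1L) {
  stopifnot_scalar_number(f_air, "f_air", positive = TRUE)
  stopifnot_scalar_number(gamma_air, "gamma_air", positive = TRUE)
  if (!is.data.frame(spectra) ||
      !all(c("timestamp_s", "frequency_hz", "conductance") %in% names(spectra)))
    abort("`spectra` must have columns timestamp_s, frequency_hz, conductance.")
  ts <- unique(spectra$timestamp_s)
  check_strictly_increasing(ts, "timestamp_s")

  fits <- lapply(ts, function(t0) {
    sweep <- spectra[spectra$timestamp_s == t0, , drop = FALSE]
    tryCatch(fit_resonance(sweep),
             error = function(e) abort(sprintf(
               "resonance fit failed at timestamp %.6g s: %s",
               t0, conditionMessage(e))))
  })
  shifts <- tibble(
    time_s = ts,
    dF_hz = f_air - purrr::map_dbl(fits, "f"),
    dG_hz = purrr::map_dbl(fits, "gamma") - gamma_air)
  out <- baseline_reference(shifts, z_index = z_index)
  out$f_hz <- purrr::map_dbl(fits, "f")
  out$gamma_hz <- purrr::map_dbl(fits, "gamma")
  out$fit_rss <- purrr::map_dbl(fits, "fit_rss")
  attr(out, "f_air") <- f_air
  attr(out, "gamma_air") <- gamma_air
  out
}

#' Read stacked conductance sweeps from delimited text
#'
#' Expects columns `timestamp_s`, `frequency_hz`, `conductance`; one block of
#' rows per sweep.
#'
#' @param path CSV/TSV file path (delimiter inferred from extension; `.tsv`
#'   is tab-separated).
#' @return Tibble of stacked sweeps.
#' @export
read_spectra <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- as_tibble(read.csv(path, sep = sep))
  need <- c("timestamp_s", "frequency_hz", "conductance")
  if (!all(need %in% names(df)))
    abort(paste0("Spectrum file must have columns ",
                 paste(need, collapse = ", "), "."))
  df
}

#' @rdname tidy.resonance_fit
#' @export
glance.resonance_fit <- function(x, ...) {
  tibble(f = x$f, gamma = x$gamma, amplitude = x$amplitude,
         baseline = x$baseline, fit_rss = x$fit_rss,
         n_points = x$n_points, iterations = x$iterations,
         timestamp_s = x$timestamp_s)
}

#' Tidiers for resonance fits
#'
#' `tidy()` returns one row per fitted parameter; `glance()` one row per fit;
#' `augment()` the sweep with fitted values and residuals.
#'
#' @param x A `resonance_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.resonance_fit <- function(x, ...) {
  tibble(term = c("f", "gamma", "amplitude", "baseline"),
         estimate = c(x$f, x$gamma, x$amplitude, x$baseline))
}

#' @rdname tidy.resonance_fit
#' @export
augment.resonance_fit <- function(x, ...) {
  dplyr::mutate(x$data, .resid = .data$conductance - .data$.fitted)
}
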