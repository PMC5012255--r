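#' Baseline-reference a shift series at the sample-loading snapshot
#'
#' Clot time courses are analysed relative to the moment the plasma sample is
#' deposited on the sensor, before coagulation starts (the "z-snapshot").
#' This subtracts the snapshot values from the in-air-referenced shifts:
#' `dF_star(t) = dF(t) - dF_z`, `dG_star(t) = dG(t) - dG_z`.
#'
#' @param data Data frame with columns `time_s` (strictly increasing seconds
#'   since activation), `dF_hz` (frequency down-shift vs in-air, Hz) and
#'   `dG_hz` (half-bandwidth shift vs in-air, Hz).
#' @param z_index 1-based index of the sample-loading snapshot (default:
#'   first sample).
#'
#' @return A `shift_series` tibble: `data` plus `dF_star`, `dG_star` columns,
#'   with the snapshot stored in attributes `z_index`, `dF_z`, `dG_z`.
#' @examples
#' s <- baseline_reference(tibble::tibble(
#'   time_s = 0:2, dF_hz = c(700, 700, 1500), dG_hz = c(1000, 1000, 2200)))
#' s$dF_star   # 0 0 800
#' @export
baseline_reference <- function(data, z_index = 1L) {
  need <- c("time_s", "dF_hz", "dG_hz")
  if (!is.data.frame(data) || !all(need %in% names(data)))
    abort(paste0("`data` must have columns ", paste(need, collapse = ", "), "."))
  n <- nrow(data)
  if (n < 1L) abort("`data` is empty.")
  check_strictly_increasing(data$time_s, "time_s")
  z_index <- as.integer(z_index)
  if (is.na(z_index) || z_index < 1L || z_index > n)
    abort(sprintf("`z_index` must be in 1..%d.", n))
  out <- as_tibble(data)
  dF_z <- out$dF_hz[z_index]
  dG_z <- out$dG_hz[z_index]
  out$dF_star <- out$dF_hz - dF_z
  out$dG_star <- out$dG_hz - dG_z
  new_shift_series(out, z_index = z_index, dF_z = dF_z, dG_z = dG_z)
}

new_shift_series <- function(data, z_index, dF_z, dG_z) {
  structure(data,
            z_index = z_index, dF_z = dF_z, dG_z = dG_z,
            class = c("shift_series", class(tibble())))
}

#' @export
print.shift_series <- function(x, ...) {
  cat(sprintf("<shift_series> %d samples, z-snapshot at index %d (dF_z = %.4g Hz, dG_z = %.4g Hz)\n",
              nrow(x), attr(x, "z_index"), attr(x, "dF_z"), attr(x, "dG_z")))
  NextMethod()
}

# starred channel vector restricted to t >= t[z]
starred_channel <- function(series, channel = c("frequency", "bandwidth")) {
  channel <- match.arg(channel)
  if (!inherits(series, "shift_series"))
    abort("`series` must be a shift_series (see baseline_reference()).")
  z <- attr(series, "z_index")
  idx <- seq(z, nrow(series))
  y <- if (channel == "frequency") series$dF_star else series$dG_star
  list(t = series$time_s[idx], y = y[idx], channel = channel)
}

sgolay_smooth <- function(y, window, deriv = 0L, dt = 1) {
  n <- length(y)
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (n >= window && window >= 5L) {
    out <- signal::sgolayfilt(y, p = 2, n = window, m = deriv)
    if (deriv > 0L) out <- out / dt^deriv
    return(out)
  }
  if (deriv == 0L) return(y)
  if (n < 5L) abort("Series too short for derivative estimation (need >= 5 samples).")
  # central differences fallback for series shorter than the window
  d <- c(y[2] - y[1], (y[3:n] - y[1:(n - 2)]) / 2, y[n] - y[n - 1]) / dt
  d
}

#' Maximum starred response
#'
#' Maximum of the baseline-referenced shift (`dF_star` or `dG_star`) over
#' times at or after the sample-loading snapshot.
#'
#' @inheritParams clot_kinetics
#' @return Maximum response in Hz (scalar).
#' @export
max_response <- function(series, channel = c("frequency", "bandwidth"),
                         smooth_window = NULL) {
  s <- starred_channel(series, channel)
  y <- s$y
  if (!is.null(smooth_window) && length(y) >= 5L)
    y <- sgolay_smooth(y, smooth_window)
  m <- max(y)
  if (!is.finite(m) || m <= 0)
    abort(sprintf("no response: the starred %s channel never rises above zero.",
                  s$channel))
  m
}

#' Clotting time (R-QCM)
#'
#' Time from the start of activation until the starred shift first reaches a
#' fraction (default 10 %) of its maximum, located by linear interpolation
#' between samples.
#'
#' @inheritParams clot_kinetics
#' @param threshold Fraction of the maximum response defining the clotting
#'   time (default 0.10).
#' @return Clotting time in seconds.
#' @export
clotting_time <- function(series, channel = c("frequency", "bandwidth"),
                          threshold = 0.10, smooth_window = NULL) {
  stopifnot_scalar_number(threshold, "threshold", positive = TRUE)
  s <- starred_channel(series, channel)
  y <- s$y
  if (!is.null(smooth_window) && length(y) >= 5L)
    y <- sgolay_smooth(y, smooth_window)
  thr <- threshold * max(y)
  if (max(y) <= 0)
    abort(sprintf("no response: the starred %s channel never rises above zero.",
                  s$channel))
  i <- which(y >= thr)[1]
  if (is.na(i)) abort("clotting-time threshold never crossed.")
  if (i == 1L) return(s$t[1])
  s$t[i - 1L] + (thr - y[i - 1L]) / (y[i] - y[i - 1L]) * (s$t[i] - s$t[i - 1L])
}

#' Maximum rate of clot formation and its time (MRCF, TMRCF)
#'
#' Estimates the first derivative of the starred shift by local quadratic
#' (Savitzky-Golay) differentiation and reports its maximum (MRCF, Hz/s) and
#' the earliest time at which it is attained (TMRCF, s). Series shorter than
#' the window fall back to central differences.
#'
#' @inheritParams clot_kinetics
#' @return Named list with elements `MRCF` (Hz/s) and `TMRCF` (s).
#' @export
rate_parameters <- function(series, channel = c("frequency", "bandwidth"),
                            smooth_window = 11L) {
  s <- starred_channel(series, channel)
  if (length(s$y) < 5L)
    abort("Series too short for derivative estimation (need >= 5 samples).")
  dt <- sampling_interval(s$t)
  d <- sgolay_smooth(s$y, smooth_window, deriv = 1L, dt = dt)
  # earliest maximum, tolerant to float jitter on exactly-flat derivatives
  tol <- 1e-8 * max(abs(d), 1)
  i <- which(d >= max(d) - tol)[1]
  list(MRCF = max(d[i], 0), TMRCF = s$t[i])
}

#' Extract clot-formation kinetic parameters
#'
#' One call for the full kinetic readout of a clot time course: maximum
#' response, clotting time (R-QCM, 10 % threshold), maximum rate of clot
#' formation (MRCF) and its time (TMRCF), per channel.
#'
#' For noisy traces set `smooth_series = TRUE`: the starred channel is then
#' Savitzky-Golay smoothed with `smooth_window` before the maximum and the
#' threshold crossing are located (the derivative is always Savitzky-Golay
#' estimated). A practical window for logistic-like traces is about one third
#' of the expected width of the rate peak, `2*log(3 + 2*sqrt(2))/k` seconds
#' for growth rate `k`.
#'
#' @param series A `shift_series` from [baseline_reference()] or
#'   [track_resonance()].
#' @param channel `"frequency"` (dF_star) or `"bandwidth"` (dG_star); the
#'   default computes both.
#' @param smooth_window Savitzky-Golay window in samples (odd; default 11).
#' @param smooth_series Also smooth the series itself before max/threshold
#'   extraction (default FALSE).
#'
#' @return A tibble with one row per channel: `channel`, `max_shift_hz`,
#'   `r_qcm_s`, `mrcf_hz_per_s`, `tmrcf_s`, `smooth_window`.
#' @examples
#' sim <- simulate_shift_series(noise_sd = 0)
#' clot_kinetics(sim$series)
#' @export
clot_kinetics <- function(series, channel = c("frequency", "bandwidth"),
                          smooth_window = 11L, smooth_series = FALSE) {
  channel <- match.arg(channel, several.ok = TRUE)
  sw <- if (smooth_series) smooth_window else NULL
  purrr::map_dfr(channel, function(ch) {
    rp <- rate_parameters(series, ch, smooth_window = smooth_window)
    tibble(channel = ch,
           max_shift_hz = max_response(series, ch, smooth_window = sw),
           r_qcm_s = clotting_time(series, ch, smooth_window = sw),
           mrcf_hz_per_s = rp$MRCF,
           tmrcf_s = rp$TMRCF,
           smooth_window = as.integer(smooth_window))
  })
}

#' Read a pre-fitted shift series from CSV
#'
#' Expects columns `time_s`, `dF_hz`, `dG_hz` (shifts vs the in-air sensor)
#' and applies [baseline_reference()].
#'
#' @param path CSV file path.
#' @inheritParams baseline_reference
#' @return A `shift_series` tibble.
#' @export
read_shift_series <- function(path, z_index = 1L) {
  df <- as_tibble(read.csv(path))
  baseline_reference(df, z_index = z_index)
}

#' Plot a clot-formation shift series
#'
#' Starred frequency and bandwidth shifts against time, with the z-snapshot
#' marked.
#'
#' @param object A `shift_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shift_series <- function(object, ...) {
  z <- attr(object, "z_index")
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("time_s", "dF_star", "dG_star")],
    -"time_s", names_to = "channel", values_to = "shift_hz")
  long$channel <- factor(long$channel, c("dF_star", "dG_star"),
                         c("frequency shift Δf* (Hz)",
                           "bandwidth shift ΔΓ* (Hz)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$shift_hz)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$time_s[z], linetype = 3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time since activation (s)", y = NULL)
}

#' Plot a fitted resonance peak
#'
#' @param object A `resonance_fit`.
#' @param ... Unused.
#' @return A ggplot of the sweep with the fitted Lorentzian overlaid.
#' @export
autoplot.resonance_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$frequency_hz)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$conductance), size = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), colour = "red3") +
    ggplot2::labs(x = "frequency (Hz)", y = "conductance (a.u.)",
                  title = sprintf("f = %.1f Hz, Γ = %.1f Hz",
                                  object$f, object$gamma))
}
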