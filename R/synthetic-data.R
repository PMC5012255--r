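# Seeded generators for every input the pipeline reads, with closed-form
# ground truth: clot shift time courses, conductance-sweep series, and
# crossed-grating fibre-network images.

logistic_curve <- function(t, k, t0) 1 / (1 + exp(-k * (t - t0)))
gompertz_curve <- function(t, k, t0) exp(-exp(-k * (t - t0)))

#' Simulate a clot-formation shift series
#'
#' Generates sigmoidal frequency and bandwidth shift time courses emulating
#' plasma coagulation on a QCM: a pre-clot liquid-loading plateau (`dF_z`,
#' `dG_z`, the viscous-plasma snapshot) plus a logistic (default) or Gompertz
#' clot component with plateau amplitudes `A_f`, `A_g`, growth rate `k` and
#' midpoint `t0`, with optional additive Gaussian noise.
#'
#' Ground-truth kinetic parameters come from the closed forms of the clot
#' curve: maximum response `A`; clotting time `t0 - log(9)/k` (logistic) or
#' `t0 - log(-log(0.1))/k` (Gompertz); maximum rate `A*k/4` at `t0`
#' (logistic) or `A*k/e` at `t0` (Gompertz).
#'
#' @param dF_z,dG_z Liquid-loading shifts vs the in-air sensor (Hz);
#'   `dG_z > 0`. Defaults 700 and 1000 Hz, typical of an aqueous sample on a
#'   5 MHz crystal.
#' @param A_f,A_g Clot plateau amplitudes (Hz) of the frequency and bandwidth
#'   channels.
#' @param k Growth rate (1/s). @param t0 Curve midpoint (s).
#' @param duration Trace length (s), must exceed `t0`. @param dt Sampling
#'   interval (s).
#' @param noise_sd Additive Gaussian noise standard deviation (Hz).
#' @param seed Integer seed; the global RNG state is restored afterwards.
#' @param curve `"logistic"` (default) or `"gompertz"`.
#'
#' @return List with `series` (a `shift_series`) and `truth` (tibble of
#'   closed-form kinetic parameters per channel).
#' @examples
#' sim <- simulate_shift_series(noise_sd = 20, seed = 7)
#' sim$truth
#' @export
simulate_shift_series <- function(dF_z = 700, dG_z = 1000,
                                  A_f = 2000, A_g = 1500,
                                  k = 0.02, t0 = 400,
                                  duration = 800, dt = 1,
                                  noise_sd = 0, seed = NULL,
                                  curve = c("logistic", "gompertz")) {
  curve <- match.arg(curve)
  stopifnot_scalar_number(dG_z, "dG_z", positive = TRUE)
  stopifnot_scalar_number(k, "k", positive = TRUE)
  stopifnot_scalar_number(dt, "dt", positive = TRUE)
  if (A_f < 0 || A_g < 0) abort("`A_f` and `A_g` must be >= 0.")
  if (duration <= t0) abort("`duration` must exceed the midpoint `t0`.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")

  t <- seq(0, duration, by = dt)
  g <- switch(curve,
              logistic = logistic_curve(t, k, t0),
              gompertz = gompertz_curve(t, k, t0))
  noise <- with_seed(seed, list(f = rnorm(length(t), 0, noise_sd),
                                g = rnorm(length(t), 0, noise_sd)))
  dF <- dF_z + A_f * g + noise$f
  dG <- dG_z + A_g * g + noise$g
  # pin the z-snapshot to its noiseless value so the starred reference is the
  # liquid-loading plateau, not one noisy sample
  dF[1] <- dF_z + A_f * g[1]
  dG[1] <- dG_z + A_g * g[1]
  series <- baseline_reference(tibble(time_s = t, dF_hz = dF, dG_hz = dG),
                               z_index = 1L)
  r_frac <- switch(curve,
                   logistic = t0 - log(9) / k,
                   gompertz = t0 - log(-log(0.1)) / k)
  mr <- switch(curve, logistic = k / 4, gompertz = k / exp(1))
  truth <- tibble(channel = c("frequency", "bandwidth"),
                  max_shift_hz = c(A_f, A_g),
                  r_qcm_s = r_frac,
                  mrcf_hz_per_s = c(A_f, A_g) * mr,
                  tmrcf_s = t0)
  list(series = series, truth = truth)
}

#' Simulate conductance sweeps for a shift series
#'
#' Renders every time point of a shift series as a Lorentzian conductance
#' sweep: resonant frequency `f(t) = f_air - dF(t)`, half bandwidth
#' `gamma(t) = gamma_air + dG(t)`, unit amplitude and zero baseline, plus
#' optional Gaussian noise. The sweep window is common to all time points and
#' must cover the full excursion of `f(t)` with room for the broadened peak.
#'
#' @param series A `shift_series` (e.g. from [simulate_shift_series()]).
#' @param f_air,gamma_air In-air reference values (Hz).
#' @param sweep_span Width of the common sweep window (Hz); default is the
#'   `f(t)` range plus eight times the largest bandwidth. An error is raised
#'   when the span cannot contain the peaks.
#' @param n_points Samples per sweep (>= 8; default 201).
#' @param noise_sd Additive conductance noise (fraction of unit amplitude).
#' @param seed Integer seed.
#' @return Tibble of stacked sweeps (`timestamp_s`, `frequency_hz`,
#'   `conductance`) ready for [track_resonance()].
#' @export
simulate_spectra <- function(series, f_air = 5e6, gamma_air = 25,
                             sweep_span = NULL, n_points = 201L,
                             noise_sd = 0, seed = NULL) {
  if (!inherits(series, "shift_series"))
    abort("`series` must be a shift_series.")
  stopifnot_scalar_number(f_air, "f_air", positive = TRUE)
  stopifnot_scalar_number(gamma_air, "gamma_air", positive = TRUE)
  if (n_points < 8L)
    abort("`n_points` must be at least 8 (minimum fittable sweep).")
  f_t <- f_air - series$dF_hz
  g_t <- gamma_air + series$dG_hz
  if (any(g_t <= 0)) abort("Simulated bandwidth must stay positive.")
  need <- diff(range(f_t)) + 4 * max(g_t)
  if (is.null(sweep_span)) sweep_span <- diff(range(f_t)) + 8 * max(g_t)
  if (sweep_span < need)
    abort(sprintf("sweep span too small: need at least %.4g Hz to cover the peaks.",
                  need))
  centre <- mean(range(f_t))
  x <- seq(centre - sweep_span / 2, centre + sweep_span / 2,
           length.out = n_points)
  with_seed(seed, purrr::map_dfr(seq_along(f_t), function(i) {
    y <- lorentzian(x, f_t[i], g_t[i]) + rnorm(n_points, 0, noise_sd)
    tibble(timestamp_s = series$time_s[i], frequency_hz = x,
           conductance = pmax(y, 0))
  }))
}

#' Simulate a fibrin-network SEM image as crossed gratings
#'
#' Ideal crossed rectangular gratings: two orthogonal sets of bright bars of
#' width `width_px` repeating every `period_px` pixels, optionally rotated,
#' Gaussian-blurred and corrupted with noise. This is exactly the geometric
#' idealisation behind the fibre-diameter formula, so the ground truth is
#' closed form: porosity `(1 - w/P)^2`, density `(1/P)/pixel_size`, diameter
#' `w * pixel_size`.
#'
#' @param width_px Fibre (bar) width in pixels, `1 <= width_px < period_px`.
#' @param period_px Grating period in pixels.
#' @param angle_deg Grating orientation (degrees).
#' @param pixel_size_nm Pixel size (nm).
#' @param image_size_px Image side length (>= 64; default 192).
#' @param noise_sd Additive Gaussian noise, in units of the 0-1 dynamic range.
#' @param blur_px Gaussian blur standard deviation in pixels (0 = none).
#' @param seed Integer seed.
#' @return List with `image` (matrix, grey levels in roughly 0..1) and
#'   `truth` (one-row tibble `F_Por`, `F_Dens_um`, `F_Diam_nm`,
#'   `peak_freq_px`).
#' @examples
#' sim <- simulate_network_image(width_px = 3, period_px = 10)
#' sim$truth
#' @export
simulate_network_image <- function(width_px = 3, period_px = 10,
                                   angle_deg = 0, pixel_size_nm = 25,
                                   image_size_px = 192L,
                                   noise_sd = 0, blur_px = 0, seed = NULL) {
  if (width_px < 1 || width_px >= period_px)
    abort("Require 1 <= width_px < period_px.")
  if (image_size_px < 64L) abort("`image_size_px` must be at least 64.")
  stopifnot_scalar_number(pixel_size_nm, "pixel_size_nm", positive = TRUE)
  if (noise_sd < 0 || blur_px < 0) abort("`noise_sd` and `blur_px` must be >= 0.")

  n <- as.integer(image_size_px)
  th <- angle_deg * pi / 180
  ij <- expand.grid(i = 0:(n - 1), j = 0:(n - 1))
  u <- ij$i * cos(th) + ij$j * sin(th)
  v <- -ij$i * sin(th) + ij$j * cos(th)
  bar <- function(w) (w %% period_px) < width_px
  img <- matrix(as.numeric(bar(u) | bar(v)), n, n)
  if (blur_px > 0) img <- gaussian_blur_fft(img, blur_px)
  if (noise_sd > 0)
    img <- img + with_seed(seed, matrix(rnorm(n * n, 0, noise_sd), n, n))
  truth <- tibble(F_Por = (1 - width_px / period_px)^2,
                  F_Dens_um = (1 / period_px) / pixel_size_nm * 1000,
                  F_Diam_nm = width_px * pixel_size_nm,
                  peak_freq_px = 1 / period_px)
  list(image = img, truth = truth)
}

# periodic Gaussian blur via the FFT (transfer function of a Gaussian kernel)
gaussian_blur_fft <- function(img, sigma) {
  fu <- fft_freq(nrow(img))
  fv <- fft_freq(ncol(img))
  H <- exp(-2 * pi^2 * sigma^2 * outer(fu^2, fv^2, "+"))
  Re(fft(fft(img) * H, inverse = TRUE)) / length(img)
}

#' Write a grey-level image to PNG or TIFF
#'
#' Rescales to the 0-1 range expected by the writers. Intended for feeding
#' simulated networks to the file-based image pipeline.
#'
#' @param img Numeric matrix.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_fibre_image <- function(img, path) {
  rng <- range(img)
  scaled <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      abort("Writing PNG images requires the 'png' package.")
    png::writePNG(scaled, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      abort("Writing TIFF images requires the 'tiff' package.")
    tiff::writeTIFF(scaled, path)
  } else abort(sprintf("Unsupported image format: .%s", ext))
  invisible(path)
}
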