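# Fibrin-network SEM image quantification: structure filtering, mean-threshold
# binarization, porosity, radially averaged 2-D power spectrum, fibre density
# and the rectangular-grating fibre-diameter estimate.

# radial spatial frequency (cycles/pixel) for every FFT coefficient
radial_freq_matrix <- function(nr, nc) {
  fu <- fft_freq(nr)
  fv <- fft_freq(nc)
  sqrt(outer(fu^2, fv^2, "+"))
}

check_image <- function(img, min_dim = 32L) {
  if (!is.matrix(img) || !is.numeric(img))
    abort("`img` must be a numeric matrix of grey levels.")
  if (min(dim(img)) < min_dim)
    abort(sprintf("Image dimensions must be at least %d pixels.", min_dim))
  if (any(!is.finite(img))) abort("`img` must be finite everywhere.")
  invisible(img)
}

#' Remove sub-resolution structure from an SEM image
#'
#' Suppresses high-spatial-frequency structure (noise) smaller than
#' `min_size_px` pixels before binarization. The default implementation is a
#' sharp Fourier low-pass: every coefficient whose wavelength is shorter than
#' `min_size_px` pixels (radial frequency above `1/min_size_px` cycles/pixel)
#' is zeroed; the mean intensity (DC component) is untouched. A real-space
#' alternative (`method = "median"`, 3x3 median filter) is available for
#' images with strong salt-and-pepper noise.
#'
#' @param img Numeric matrix of grey levels, both dimensions >= 32.
#' @param min_size_px Structure size cutoff in pixels (default 2, i.e. remove
#'   wavelengths below two pixels); must be >= 1 and smaller than the image.
#' @param method `"fourier"` (default) or `"median"`.
#' @return Filtered image matrix, same dimensions.
#' @export
structure_filter <- function(img, min_size_px = 2, method = c("fourier", "median")) {
  method <- match.arg(method)
  check_image(img)
  if (min_size_px < 1) abort("`min_size_px` must be >= 1.")
  if (min_size_px >= min(dim(img)))
    abort("`min_size_px` must be smaller than the image dimensions.")
  if (method == "median") return(median_filter3(img))
  F <- fft(img)
  r <- radial_freq_matrix(nrow(img), ncol(img))
  F[r > 1 / min_size_px] <- 0
  Re(fft(F, inverse = TRUE)) / length(img)
}

# 3x3 median filter with edge replication
median_filter3 <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- img[c(1, 1:nr, nr), c(1, 1:nc, nc)]
  stack <- vapply(1:9, function(k) {
    di <- (k - 1) %% 3; dj <- (k - 1) %/% 3
    pad[di + 1:nr, dj + 1:nc]
  }, matrix(0, nr, nc))
  matrix(apply(stack, c(1, 2), median), nr, nc)
}

#' Binarize an image at its mean intensity
#'
#' Pixels below the mean intensity become -1 ("dark", pore space); pixels at
#' or above the mean become +1 ("bright", fibre). Errors on a constant image,
#' where the threshold is degenerate.
#'
#' @param img Numeric matrix of grey levels.
#' @return Matrix of -1 / +1 values, same dimensions.
#' @export
binarize_mean <- function(img) {
  check_image(img, min_dim = 1L)
  m <- mean(img)
  if (diff(range(img)) == 0)
    abort("degenerate threshold: image is constant.")
  ifelse(img >= m, 1, -1)
}

#' Fibre-network porosity
#'
#' Fraction of dark (-1) pixels in a binarized image.
#'
#' @param bin_img Matrix of -1 / +1 values from [binarize_mean()].
#' @return Porosity in \[0, 1\].
#' @export
porosity <- function(bin_img) {
  if (!all(bin_img %in% c(-1, 1)))
    abort("`bin_img` must contain only -1 and +1 (see binarize_mean()).")
  mean(bin_img < 0)
}

#' Radially averaged 2-D power spectrum
#'
#' Squared magnitude of the 2-D FFT, averaged over annular bins of radial
#' spatial frequency `r = sqrt(u^2 + v^2)` (cycles/pixel). Bin width is
#' `1/max(dim(img))`; every non-DC coefficient is assigned to exactly one bin
#' (the nearest bin centre), so per-bin mean power times bin count partitions
#' the total non-DC power.
#'
#' @param img Numeric matrix (typically the binarized image), both
#'   dimensions >= 32.
#' @return A `radial_spectrum` tibble: `freq_cpp` (bin centre, cycles/pixel),
#'   `power` (mean power), `n_coef` (coefficients per bin). The total non-DC
#'   power is kept in attribute `total_power`.
#' @export
radial_power_spectrum <- function(img) {
  check_image(img)
  P <- Mod(fft(img))^2
  r <- radial_freq_matrix(nrow(img), ncol(img))
  width <- 1 / max(dim(img))
  bin <- as.integer(round(r / width))
  keep <- !(r == 0)  # drop DC only
  bin <- bin[keep]; pw <- P[keep]
  power <- tapply(pw, bin, mean)
  n_coef <- tapply(pw, bin, length)
  bins <- as.integer(names(power))
  structure(
    tibble(freq_cpp = bins * width,
           power = as.numeric(power),
           n_coef = as.integer(n_coef)),
    bin_width = width, total_power = sum(pw),
    class = c("radial_spectrum", class(tibble())))
}

#' Fibre density from the spectral peak
#'
#' The average fibre density is read from the radial frequency of maximal
#' mean power: one fibre per spatial period is assumed, so the peak frequency
#' in cycles/pixel divided by the pixel size gives fibres per micrometre.
#' The DC bin is never searched, and by default the first radial bin is also
#' excluded (it holds large-scale illumination gradients).
#'
#' @param spectrum A `radial_spectrum` from [radial_power_spectrum()].
#' @param pixel_size_nm Pixel size in nanometres.
#' @param exclude_bins Number of leading low-frequency bins excluded from the
#'   peak search (default 1).
#' @return One-row tibble: `peak_freq_px` (cycles/pixel), `f_dens_um`
#'   (fibres per micrometre), `flags` (comma-separated; `"unresolved"` when
#'   the maximum sits in the highest bin, `"weak_peak"` when the peak power
#'   is less than five times the median bin power).
#' @export
fibre_density <- function(spectrum, pixel_size_nm, exclude_bins = 1L) {
  if (!inherits(spectrum, "radial_spectrum"))
    abort("`spectrum` must come from radial_power_spectrum().")
  stopifnot_scalar_number(pixel_size_nm, "pixel_size_nm", positive = TRUE)
  width <- attr(spectrum, "bin_width")
  s <- spectrum[spectrum$freq_cpp > (exclude_bins + 0.5) * width, , drop = FALSE]
  if (nrow(s) == 0L) abort("Spectrum is empty after excluding leading bins.")
  i <- which.max(s$power)
  flags <- character()
  if (i == nrow(s)) {
    flags <- c(flags, "unresolved")
    warn("Spectral maximum is in the highest bin: structure unresolved at this pixel size.")
  }
  if (s$power[i] < 5 * median(s$power)) flags <- c(flags, "weak_peak")
  peak <- s$freq_cpp[i]
  tibble(peak_freq_px = peak,
         f_dens_um = peak / pixel_size_nm * 1000,
         flags = paste(flags, collapse = ","))
}

#' Fibre diameter from porosity and density
#'
#' Under the idealisation of the fibre network as crossed rectangular
#' gratings (two orthogonal bar sets of width `w` and period `P`, porosity
#' `(1 - w/P)^2`, density `1/P`), the average fibre diameter is
#' `F.Diam = (1 - sqrt(F.Por)) / F.Dens`.
#'
#' @param f_por Porosity in \[0, 1\].
#' @param f_dens_um Fibre density in fibres per micrometre.
#' @return Fibre diameter in nanometres.
#' @examples
#' fibre_diameter(0.518, 1.72)  # ~163 nm
#' @export
fibre_diameter <- function(f_por, f_dens_um) {
  if (any(f_por < 0 | f_por > 1)) abort("`f_por` must be in [0, 1].")
  if (any(f_dens_um <= 0)) abort("`f_dens_um` must be > 0.")
  (1 - sqrt(f_por)) / f_dens_um * 1000
}

#' Quantify a fibrin-network SEM image
#'
#' Full image chain: [structure_filter()] (sub-2-pixel noise removal) then
#' [binarize_mean()]; porosity from the dark-pixel fraction; fibre density
#' from the radially averaged power spectrum of the binary image; fibre
#' diameter from the grating identity [fibre_diameter()].
#'
#' @param img Numeric matrix of grey levels, both dimensions >= 32.
#' @param pixel_size_nm Pixel size in nanometres (SEM calibration; required).
#' @param cutoff_px Structure-filter cutoff in pixels (default 2).
#' @param filter_method `"fourier"` (default) or `"median"`; see
#'   [structure_filter()].
#' @param exclude_bins Leading radial bins excluded from the peak search.
#' @return One-row tibble: `F_Por`, `F_Dens_um`, `F_Diam_nm`, `peak_freq_px`,
#'   `flags`.
#' @examples
#' sim <- simulate_network_image(width_px = 3, period_px = 10)
#' fibre_metrics(sim$image, pixel_size_nm = 25)
#' @export
fibre_metrics <- function(img, pixel_size_nm, cutoff_px = 2,
                          filter_method = c("fourier", "median"),
                          exclude_bins = 1L) {
  stopifnot_scalar_number(pixel_size_nm, "pixel_size_nm", positive = TRUE)
  filtered <- structure_filter(img, min_size_px = cutoff_px,
                               method = filter_method)
  bin <- binarize_mean(filtered)
  f_por <- porosity(bin)
  dens <- fibre_density(radial_power_spectrum(bin), pixel_size_nm,
                        exclude_bins = exclude_bins)
  tibble(F_Por = f_por,
         F_Dens_um = dens$f_dens_um,
         F_Diam_nm = fibre_diameter(f_por, dens$f_dens_um),
         peak_freq_px = dens$peak_freq_px,
         flags = dens$flags)
}

#' Read a grey-level SEM image
#'
#' Reads a TIFF or PNG image as a numeric matrix; RGB images are averaged to
#' grey. Pixel size is never parsed from the file — SEM scale bars are not
#' machine-readable — so it must accompany the image through the analysis.
#'
#' @param path Image file path (`.tif`, `.tiff` or `.png`).
#' @return Numeric matrix of grey levels.
#' @export
read_fibre_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("Image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  px <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      abort("Reading TIFF images requires the 'tiff' package.")
    tiff::readTIFF(path)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      abort("Reading PNG images requires the 'png' package.")
    png::readPNG(path)
  } else abort(sprintf("Unsupported image format: .%s", ext))
  if (length(dim(px)) == 3L) px <- apply(px[, , 1:min(3, dim(px)[3]), drop = FALSE],
                                         c(1, 2), mean)
  as.matrix(px)
}

#' Plot a radially averaged power spectrum
#'
#' @param object A `radial_spectrum`.
#' @param ... Unused.
#' @return A ggplot with log-scaled power.
#' @export
autoplot.radial_spectrum <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$freq_cpp, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "radial spatial frequency (cycles/pixel)",
                  y = "mean power (a.u.)")
}
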