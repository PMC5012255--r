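test_that("structure filter keeps the passband and removes sub-cutoff structure", {
  n <- 64
  const <- matrix(0.5, n, n)
  expect_equal(structure_filter(const), const, tolerance = 1e-12)

  # single-pixel checkerboard lives beyond the 2-px cutoff (diagonal Nyquist)
  cb <- outer(1:n, 1:n, function(i, j) (-1)^(i + j))
  img <- 0.5 + 0.1 * cb
  filt <- structure_filter(img, min_size_px = 2)
  expect_lt(max(abs(filt - 0.5)), 1e-10)
  expect_equal(mean(filt), 0.5, tolerance = 1e-12)

  # wavelength-10 sinusoid passes unchanged
  sin10 <- 0.5 + 0.2 * outer(rep(1, n), sin(2 * pi * (1:n) / 10))
  expect_lt(max(abs(structure_filter(sin10) - sin10)), 1e-6)

  expect_error(structure_filter(const, min_size_px = 64), "smaller than")
  expect_error(structure_filter(const, min_size_px = 0.5), ">= 1")
})

test_that("median variant of the structure filter removes salt-and-pepper noise", {
  n <- 64
  img <- matrix(0.5, n, n)
  img[cbind(sample(2:(n - 1), 20), sample(2:(n - 1), 20))] <- 1
  filt <- structure_filter(img, method = "median")
  expect_lt(max(abs(filt - 0.5)), 1e-12)
})

test_that("mean-threshold binarization splits at the mean with +1/-1 codomain", {
  half <- matrix(rep(c(0, 1), each = 32), 8, 8)
  b <- binarize_mean(half)
  expect_true(all(b %in% c(-1, 1)))
  expect_equal(b[half == 0], rep(-1, 32))
  expect_equal(b[half == 1], rep(1, 32))

  ramp <- matrix(seq(0, 255, length.out = 64 * 64), 64, 64)
  expect_equal(porosity(binarize_mean(ramp)), 0.5, tolerance = 1 / 64)

  expect_error(binarize_mean(matrix(3, 8, 8)), "degenerate threshold")
})

test_that("porosity counts dark pixels", {
  allb <- matrix(1, 8, 8)
  expect_equal(porosity(allb), 0)
  cb <- outer(1:32, 1:32, function(i, j) ifelse((i + j) %% 2 == 0, 1, -1))
  expect_equal(porosity(cb), 0.5)
  g <- simulate_network_image(width_px = 3, period_px = 10, image_size_px = 200)
  expect_equal(porosity(binarize_mean(g$image)), 0.49, tolerance = 0.01)
  expect_error(porosity(matrix(0.5, 8, 8)), "-1 and \\+1")
})

test_that("porosity and bright fraction partition the image exactly", {
  set.seed(3)
  img <- matrix(stats::runif(64 * 64), 64, 64)
  b <- binarize_mean(img)
  expect_identical(porosity(b) + mean(b > 0), 1)
})

test_that("radial power spectrum localises a pure sinusoid and partitions power", {
  n <- 64
  s8 <- outer(rep(1, n), sin(2 * pi * (1:n) / 8))
  sp <- radial_power_spectrum(s8)
  expect_equal(sp$freq_cpp[which.max(sp$power)], 0.125, tolerance = 1e-9)

  # Parseval partition: per-bin mean times count sums to total non-DC power
  set.seed(11)
  img <- matrix(stats::runif(n * n), n, n)
  sp <- radial_power_spectrum(img)
  expect_equal(sum(sp$power * sp$n_coef), attr(sp, "total_power"),
               tolerance = 1e-10)
  # white noise: no bin towers over the rest
  expect_lt(max(sp$power) / stats::median(sp$power), 5)
})

test_that("fibre density reads the grating fundamental and scales with pixel size", {
  g <- simulate_network_image(width_px = 3, period_px = 10, image_size_px = 200)
  sp <- radial_power_spectrum(binarize_mean(g$image))
  d25 <- fibre_density(sp, pixel_size_nm = 25)
  expect_equal(d25$peak_freq_px, 0.1, tolerance = 0.5 / 200 / 0.1)
  expect_equal(d25$f_dens_um, 4, tolerance = 0.03)
  d50 <- fibre_density(sp, pixel_size_nm = 50)
  expect_equal(d50$f_dens_um, d25$f_dens_um / 2)

  set.seed(5)
  noise <- matrix(stats::rnorm(128 * 128), 128, 128)
  dn <- suppressWarnings(
    fibre_density(radial_power_spectrum(binarize_mean(noise)), 25))
  expect_match(dn$flags, "weak_peak")
})

test_that("fibre diameter identity matches hand evaluation", {
  expect_equal(fibre_diameter(0.49, 4), 75, tolerance = 1e-9)
  expect_error(fibre_diameter(1.2, 4), "\\[0, 1\\]")
  expect_error(fibre_diameter(0.5, -1), "> 0")
})

test_that("the full chain recovers a known grating and ignores intensity scaling", {
  g <- simulate_network_image(width_px = 3, period_px = 10,
                              pixel_size_nm = 25, image_size_px = 200)
  m <- fibre_metrics(g$image, pixel_size_nm = 25)
  expect_equal(m$F_Diam_nm, 75, tolerance = 8 / 75)
  expect_equal(m$F_Por, 0.49, tolerance = 0.02)
  expect_equal(m$F_Diam_nm, (1 - sqrt(m$F_Por)) / m$F_Dens_um * 1000)

  m2 <- fibre_metrics(40 + 180 * g$image, pixel_size_nm = 25)
  expect_equal(m2$F_Por, m$F_Por)
  expect_equal(m2$F_Dens_um, m$F_Dens_um)
})

test_that("grating recovery holds over widths and periods, density falls with period", {
  dens <- c()
  for (P in c(8, 16, 24)) {
    for (w in c(2, 4, 6)) {
      if (w >= P) next
      g <- simulate_network_image(width_px = w, period_px = P,
                                  pixel_size_nm = 25, image_size_px = 192)
      m <- fibre_metrics(g$image, pixel_size_nm = 25)
      expect_lt(abs(m$F_Diam_nm / 25 - w), 1)
      expect_lt(abs(m$peak_freq_px - 1 / P), 1 / 192 + 1e-9)
    }
    dens <- c(dens, fibre_metrics(
      simulate_network_image(width_px = 3, period_px = P,
                             image_size_px = 192)$image, 25)$F_Dens_um)
  }
  expect_true(all(diff(dens) < 0))
})
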