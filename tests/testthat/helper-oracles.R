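# Independent oracles and small fixture builders used across the suite.

# Brute-force Lorentzian fit: exhaustive (f, gamma) grid with baseline and
# amplitude solved in closed form per grid point. Independent of the
# Levenberg-Marquardt path in fit_resonance().
lorentz_grid_oracle <- function(x, y, f_grid, g_grid) {
  n <- length(y)
  Sy <- sum(y)
  best <- list(rss = Inf)
  for (f in f_grid) {
    d2 <- (x - f)^2
    for (g in g_grid) {
      L <- g^2 / (d2 + g^2)
      SL <- sum(L); SLL <- sum(L * L); SLy <- sum(L * y)
      det <- n * SLL - SL^2
      A <- (n * SLy - SL * Sy) / det
      b0 <- (Sy - A * SL) / n
      rss <- sum((y - b0 - A * L)^2)
      if (rss < best$rss)
        best <- list(f = f, gamma = g, amplitude = A, baseline = b0, rss = rss)
    }
  }
  best
}

# one noiseless Lorentzian sweep as a plain tibble
make_sweep <- function(f, gamma, amplitude = 1, baseline = 0,
                       span = 20 * gamma, by = span / 600, timestamp_s = 0) {
  x <- seq(f - span / 2, f + span / 2, by = by)
  tibble::tibble(timestamp_s = timestamp_s, frequency_hz = x,
                 conductance = lorentzian(x, f, gamma, amplitude, baseline))
}

# closed-form kinetic truth of a logistic clot curve
logistic_truth <- function(A, k, t0) {
  list(max = A, R = t0 - log(9) / k, MRCF = A * k / 4, TMRCF = t0)
}

# shift series carrying a pure logistic clot component, no noise
make_logistic_series <- function(A_f = 2000, A_g = 1500, k = 0.02, t0 = 400,
                                 dF_z = 700, dG_z = 1000,
                                 duration = 800, dt = 1) {
  t <- seq(0, duration, by = dt)
  s <- 1 / (1 + exp(-k * (t - t0)))
  baseline_reference(tibble::tibble(time_s = t,
                                    dF_hz = dF_z + A_f * s,
                                    dG_hz = dG_z + A_g * s))
}
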