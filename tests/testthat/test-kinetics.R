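test_that("baseline referencing subtracts the z-snapshot", {
  s <- baseline_reference(tibble::tibble(
    time_s = 0:2, dF_hz = c(700, 700, 1500), dG_hz = c(1000, 1000, 2200)))
  expect_equal(s$dF_star, c(0, 0, 800))
  expect_equal(s$dG_star, c(0, 0, 1200))
  expect_equal(attr(s, "dF_z"), 700)
  expect_equal(attr(s, "dG_z"), 1000)

  const <- baseline_reference(tibble::tibble(
    time_s = 0:9, dF_hz = rep(700, 10), dG_hz = rep(1000, 10)))
  expect_true(all(const$dF_star == 0) && all(const$dG_star == 0))

  expect_error(baseline_reference(tibble::tibble(
    time_s = 0:2, dF_hz = 1:3, dG_hz = 1:3), z_index = 9), "z_index")
  expect_error(baseline_reference(tibble::tibble(
    time_s = c(0, 0, 1), dF_hz = 1:3, dG_hz = 1:3)), "strictly increasing")
})

test_that("maximum response finds the plateau and rejects flat traces", {
  s <- make_logistic_series(A_f = 2000, k = 0.02, t0 = 400, duration = 900)
  expect_equal(max_response(s, "frequency"), 2000, tolerance = 1e-3)

  ramp <- baseline_reference(tibble::tibble(
    time_s = 0:1000, dF_hz = 700 + seq(0, 500, length.out = 1001),
    dG_hz = rep(1000, 1001)))
  expect_equal(max_response(ramp, "frequency"), 500)

  flat <- baseline_reference(tibble::tibble(
    time_s = 0:10, dF_hz = rep(700, 11), dG_hz = rep(1000, 11)))
  expect_error(max_response(flat, "frequency"), "no response")
})

test_that("clotting time matches closed forms for logistic, ramp and step traces", {
  s <- make_logistic_series(A_f = 2000, k = 0.02, t0 = 400)
  expect_equal(clotting_time(s, "frequency"), 400 - log(9) / 0.02,
               tolerance = 0.5 / 290)

  ramp <- baseline_reference(tibble::tibble(
    time_s = 0:1000, dF_hz = 700 + seq(0, 1000, length.out = 1001),
    dG_hz = rep(1000, 1001)))
  expect_equal(clotting_time(ramp, "frequency"), 100, tolerance = 1e-6)

  step <- baseline_reference(tibble::tibble(
    time_s = 0:100, dF_hz = 700 + c(rep(0, 50), rep(2000, 51)),
    dG_hz = rep(1000, 101)))
  expect_equal(clotting_time(step, "frequency"), 50, tolerance = 2e-2)
})

test_that("clotting time is invariant to uniform rescaling of the response", {
  s1 <- make_logistic_series(A_f = 2000, A_g = 1500)
  s2 <- make_logistic_series(A_f = 200, A_g = 150)
  expect_equal(clotting_time(s1, "frequency"), clotting_time(s2, "frequency"),
               tolerance = 1e-9)
  expect_equal(clotting_time(s1, "bandwidth"), clotting_time(s2, "bandwidth"),
               tolerance = 1e-9)
})

test_that("rate parameters match the logistic derivative closed form", {
  s <- make_logistic_series(A_f = 2000, k = 0.02, t0 = 400)
  rp <- rate_parameters(s, "frequency")
  expect_equal(rp$MRCF, 10, tolerance = 0.02)
  expect_equal(rp$TMRCF, 400, tolerance = 2 / 400)

  ramp <- baseline_reference(tibble::tibble(
    time_s = 0:100, dF_hz = 700 + 3 * (0:100), dG_hz = rep(1000, 101)))
  rr <- rate_parameters(ramp, "frequency")
  expect_equal(rr$MRCF, 3, tolerance = 1e-9)
  expect_equal(rr$TMRCF, 0)  # tie broken to the earliest time

  const <- baseline_reference(tibble::tibble(
    time_s = 0:100, dF_hz = rep(700, 101), dG_hz = rep(1000, 101)))
  expect_equal(rate_parameters(const, "frequency")$MRCF, 0)
  expect_error(rate_parameters(baseline_reference(tibble::tibble(
    time_s = 0:2, dF_hz = 1:3, dG_hz = 1:3)), "frequency"), "too short")
})

test_that("TMRCF of a logistic is its midpoint independent of amplitude", {
  for (A in c(200, 2000, 8000)) {
    s <- make_logistic_series(A_f = A, k = 0.02, t0 = 350)
    expect_equal(rate_parameters(s, "frequency")$TMRCF, 350, tolerance = 2 / 350)
  }
})

test_that("kinetic parameters are recovered within 5% over a logistic grid with mild noise", {
  # k*t0 >= 7 so the pre-activation tail of the logistic is negligible and the
  # closed forms apply
  grid <- expand.grid(A = c(1000, 2500), k = c(0.02, 0.05), t0 = c(350, 500))
  for (i in seq_len(nrow(grid))) {
    A <- grid$A[i]; k <- grid$k[i]; t0 <- grid$t0[i]
    sim <- simulate_shift_series(A_f = A, A_g = A, k = k, t0 = t0,
                                 duration = t0 + 6 / k, dt = 1,
                                 noise_sd = 0.01 * A, seed = 100 + i)
    w <- 2 * floor(2 * log(3 + 2 * sqrt(2)) / k / 3 / 2) + 1  # ~FWHM/3 rule
    kin <- clot_kinetics(sim$series, channel = "frequency",
                         smooth_window = w, smooth_series = TRUE)
    truth <- logistic_truth(A, k, t0)
    expect_lt(abs(kin$max_shift_hz - truth$max) / truth$max, 0.05)
    expect_lt(abs(kin$r_qcm_s - truth$R) / truth$R, 0.05)
    expect_lt(abs(kin$mrcf_hz_per_s - truth$MRCF) / truth$MRCF, 0.05)
    expect_lt(abs(kin$tmrcf_s - truth$TMRCF) / truth$TMRCF, 0.05)
  }
})

test_that("clot_kinetics reports both channels with their own maxima", {
  s <- make_logistic_series(A_f = 2000, A_g = 1500)
  kin <- clot_kinetics(s)
  expect_equal(kin$channel, c("frequency", "bandwidth"))
  expect_equal(kin$max_shift_hz, c(2000, 1500), tolerance = 1e-3)
  expect_equal(kin$mrcf_hz_per_s, c(10, 7.5), tolerance = 0.02)
})
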