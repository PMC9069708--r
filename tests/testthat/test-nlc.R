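# small protocols keep the simulator fast in unit tests
quick_protocol <- function(dc_levels = seq(-150, 90, by = 40), ...) {
  two_sine_protocol(dc_levels = dc_levels, ...)
}

test_that("Fourier admittance obeys Ohm's law and recovers synthesized admittances", {
  fs <- 50000; f <- 390.625
  n <- round(10 * fs / f)
  t_s <- (seq_len(n) - 1) / fs
  v <- 10 * sin(2 * pi * f * t_s)
  # pure 100 MOhm resistor
  y <- fourier_admittance(v, v / 100, f, fs)
  expect_equal(Re(y), 0.01, tolerance = 1e-10)
  expect_equal(Im(y), 0, tolerance = 1e-10)

  # forward synthesis at a chosen complex admittance
  y0 <- complex(real = 0.004, imaginary = 0.019)
  i <- Mod(y0) * 10 * sin(2 * pi * f * t_s + Arg(y0))
  expect_equal(fourier_admittance(v, i, f, fs), y0, tolerance = 1e-9)

  # amplitude invariance of a linear segment
  expect_equal(fourier_admittance(2 * v, 2 * v / 100, f, fs), y,
               tolerance = 1e-12)

  # non-integer period count is a leakage error
  expect_error(fourier_admittance(v[1:100], v[1:100], f, fs),
               class = "leakage_error")
})

test_that("circuit solve: closed form at Rs = 0, exact round trips, solver errors", {
  f1 <- 390.625; f2 <- 781.25
  y1 <- rc_admittance(f1, 0, 250, 12)
  y2 <- rc_admittance(f2, 0, 250, 12)
  # Rs = 0 oracle: Y = 1/Rm + jwC
  expect_equal(1e6 * Im(y1) / (2 * pi * f1), 12, tolerance = 1e-9)
  expect_equal(1 / Re(rc_admittance(1e-3, 0, 250, 12)), 250,
               tolerance = 1e-6)
  sol0 <- solve_rc_from_admittance(y1, y2, f1, f2)
  expect_equal(sol0$cm, 12, tolerance = 1e-6)
  expect_equal(sol0$rm, 250, tolerance = 1e-6)

  truth <- c(10, 500, 25)
  sol <- solve_rc_from_admittance(rc_admittance(f1, 10, 500, 25),
                                  rc_admittance(f2, 10, 500, 25),
                                  f1, f2)
  expect_equal(c(sol$rs, sol$rm, sol$cm), truth, tolerance = 1e-6)

  # an inconsistent pair raises a model-mismatch error
  expect_error(
    solve_rc_from_admittance(complex(real = 1, imaginary = 1),
                             complex(real = 1, imaginary = -1),
                             f1, f2),
    class = "model_mismatch")
  expect_error(solve_rc_from_admittance(y1, y2, f1, f1),
               class = "config_error")
})

test_that("simulated currents follow the passive circuit physics", {
  # resistive divider at rest: Qmax = 0, amplitude = 0
  proto0 <- two_sine_protocol(amplitude = 0, dc_levels = -60,
                              phase_cycle = FALSE)
  rec <- simulate_voltage_clamp(circuit_params(rs = 10, rm = 490),
                                boltzmann_params(qmax = 0), proto0)
  seg <- attr(rec, "segments")
  expect_equal(mean(rec$current_nA[seg$start[1]:seg$end[1]]),
               -60 / (10 + 490), tolerance = 1e-6)

  # ideal clamp: I = Vc/Rm + Clin dVc/dt
  proto <- quick_protocol(dc_levels = c(-70, -30))
  rec0 <- simulate_voltage_clamp(circuit_params(rs = 0, rm = 500,
                                                clin = 7),
                                 boltzmann_params(qmax = 0), proto)
  w1 <- 2 * pi * proto$f1 / 1000; w2 <- 2 * pi * proto$f2 / 1000
  n_block <- round((proto$settle_periods + proto$periods_per_level) *
                     proto$sample_rate / proto$f1)
  i <- attr(rec0, "segments")$start[1] + 5
  tl <- ((i - 1) %% n_block) * 1000 / proto$sample_rate
  dvc <- 10 * (w1 * cos(w1 * tl) + w2 * cos(w2 * tl))
  expect_equal(rec0$current_nA[i],
               rec0$vcmd_mV[i] / 500 + 1e-3 * 7 * dvc,
               tolerance = 1e-9)

  # linearity: with Qmax = 0, doubling the command doubles the current
  protoA <- quick_protocol(dc_levels = c(-50))
  protoB <- quick_protocol(dc_levels = c(-100), amplitude = 20)
  recA <- simulate_voltage_clamp(circuit_params(), NULL, protoA)
  recB <- simulate_voltage_clamp(circuit_params(), NULL, protoB)
  expect_equal(recB$current_nA, 2 * recA$current_nA, tolerance = 1e-8)

  # admittance of the simulated passive cell matches the closed form
  pts_rec <- simulate_voltage_clamp(circuit_params(rs = 10, rm = 500,
                                                   clin = 7),
                                    NULL, quick_protocol())
  segs <- attr(pts_rec, "segments")
  idx <- segs$start[1]:segs$end[1]
  y1 <- fourier_admittance(pts_rec$vcmd_mV[idx],
                           pts_rec$current_nA[idx], 390.625, 50000)
  y1_true <- rc_admittance(390.625, 10, 500, 7)
  expect_lt(Mod(y1 - y1_true) / Mod(y1_true), 0.005)
})

test_that("capacitance-voltage series reads Clin for a linear cell and peaks at Vpk", {
  rec_lin <- simulate_voltage_clamp(circuit_params(rs = 10, rm = 500,
                                                   clin = 7),
                                    NULL, quick_protocol())
  pts <- cm_voltage_series(rec_lin)
  expect_true(all(pts$ok))
  expect_true(all(abs(pts$cm_pF - 7) / 7 < 0.01))

  rec_rs0 <- simulate_voltage_clamp(circuit_params(rs = 0),
                                    NULL, quick_protocol())
  pts0 <- cm_voltage_series(rec_rs0)
  # rs_hat is estimated, not assumed, so the dc correction is only
  # numerically zero
  expect_equal(pts0$v_mV, pts0$dc_mV, tolerance = 1e-4)

  rec_nlc <- simulate_voltage_clamp(
    circuit_params(), boltzmann_params(qmax = 800, alpha = 33,
                                       vpk = -70),
    two_sine_protocol(dc_levels = seq(-150, 90, 20)))
  pts_nlc <- cm_voltage_series(rec_nlc)
  expect_equal(pts_nlc$dc_mV[which.max(pts_nlc$cm_pF)], -70)
})

test_that("the fitted Boltzmann model has the analytic peak, symmetry and integral", {
  q <- 640; a <- 28; vp <- -55; cl <- 6.5
  expect_equal(nlc_capacitance(vp, q, a, vp, cl) - cl, q / (4 * a))
  x <- seq(0, 120, by = 7)
  expect_equal(nlc_capacitance(vp + x, q, a, vp, cl),
               nlc_capacitance(vp - x, q, a, vp, cl))
  grid <- seq(vp - 1500, vp + 1500, by = 0.05)
  expect_equal(sum(nlc_capacitance(grid, q, a, vp, cl) - cl) * 0.05, q,
               tolerance = 1e-6)
  # charge density is invariant to joint scaling of Qmax and Clin
  pts <- tibble::tibble(v_mV = seq(-150, 50, 10),
                        cm_pF = nlc_capacitance(seq(-150, 50, 10),
                                                q, a, vp, cl))
  pts2 <- dplyr::mutate(pts, cm_pF = 2 * .data$cm_pF)
  f1 <- fit_boltzmann(pts); f2 <- fit_boltzmann(pts2)
  expect_equal(f1$charge_density, f2$charge_density, tolerance = 1e-6)
})

test_that("noise-free synthetic capacitance points refit to <0.5% on all four parameters", {
  v <- seq(-150, 90, 20)
  pts <- tibble::tibble(v_mV = v,
                        cm_pF = nlc_capacitance(v, 800, 33, -70, 7))
  fit <- fit_boltzmann(pts)
  expect_lt(abs(fit$qmax - 800) / 800, 0.005)
  expect_lt(abs(fit$alpha - 33) / 33, 0.005)
  expect_lt(abs(fit$vpk + 70), 0.5)
  expect_lt(abs(fit$clin - 7) / 7, 0.005)
  expect_equal(fit$charge_density, fit$qmax / fit$clin)

  expect_error(fit_boltzmann(pts[1:3, ]), class = "fit_error")
  expect_warning(
    fit_boltzmann(tibble::tibble(
      v_mV = seq(20, 120, 20),
      cm_pF = nlc_capacitance(seq(20, 120, 20), 800, 33, -70, 7))),
    class = "cochleaging_warning")
})

test_that("recording CSV round trip preserves traces and segment metadata", {
  path <- withr::local_tempfile(fileext = ".csv")
  rec <- simulate_voltage_clamp(circuit_params(), boltzmann_params(),
                                quick_protocol(dc_levels = c(-90, -50)),
                                noise_rms_pA = 5, seed = 2)
  write_vc_recording(rec, path)
  back <- read_vc_recording(path)
  expect_equal(back$current_nA, rec$current_nA, tolerance = 1e-9)
  expect_equal(attr(back, "segments")$start, attr(rec, "segments")$start)
  pts_a <- cm_voltage_series(rec); pts_b <- cm_voltage_series(back)
  expect_equal(pts_a$cm_pF, pts_b$cm_pF, tolerance = 1e-6)
})
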