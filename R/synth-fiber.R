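#' Simulate free and loaded fiber-motion traces
#'
#' Inverts the series-spring relation behind the axial-stiffness
#' measurement: the free fiber tip moves as a sinusoid of amplitude
#' `lf_amp`; resting against a cell of stiffness `true_kc`, the loaded
#' amplitude is `kf * lf_amp / (kf + true_kc)`. Gaussian noise of the
#' stated RMS is added to both traces.
#'
#' @param kf Fiber stiffness (opaque but consistent stiffness unit).
#' @param true_kc Ground-truth cell axial stiffness (same unit).
#' @param lf_amp Free-fiber amplitude (nm).
#' @param drive_freq Drive frequency, Hz.
#' @param noise_rms RMS of additive displacement noise (nm).
#' @param duration_periods Trace length in drive periods.
#' @param sample_rate Sampling rate, Hz.
#' @param seed RNG seed.
#' @return A `fiber_traces` tibble (`time_ms`, `free_nm`, `loaded_nm`)
#'   with `kf`, `drive_freq`, `sample_rate` and `true_kc` attributes.
#' @export
#' @examples
#' tr <- simulate_fiber_traces(kf = 2, true_kc = 2, lf_amp = 50)
#' fiber_stiffness(tr)  # recovers kc ~ 2; loaded amplitude is 25 nm
simulate_fiber_traces <- function(kf, true_kc, lf_amp = 50,
                                  drive_freq = 100, noise_rms = 0,
                                  duration_periods = 10,
                                  sample_rate = 10000, seed = NULL) {
  check_number(kf, "kf", min = 0, strict_min = TRUE)
  check_number(true_kc, "true_kc", min = 0)
  check_number(lf_amp, "lf_amp", min = 0, strict_min = TRUE)
  check_number(noise_rms, "noise_rms", min = 0)
  check_number(duration_periods, "duration_periods", min = 1)
  n <- round(duration_periods * sample_rate / drive_freq)
  t_ms <- (seq_len(n) - 1) * 1000 / sample_rate
  w <- 2 * pi * drive_freq / 1000              # rad per ms
  lc_amp <- kf * lf_amp / (kf + true_kc)
  free <- lf_amp * sin(w * t_ms)
  loaded <- lc_amp * sin(w * t_ms)
  if (noise_rms > 0) {
    noise <- with_seed(seed, rnorm(2 * n, sd = noise_rms))
    free <- free + noise[seq_len(n)]
    loaded <- loaded + noise[n + seq_len(n)]
  }
  structure(tibble(time_ms = t_ms, free_nm = free, loaded_nm = loaded),
            kf = kf, drive_freq = drive_freq, sample_rate = sample_rate,
            true_kc = true_kc,
            class = c("fiber_traces", class(tibble())))
}
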