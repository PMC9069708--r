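#' Two-state Boltzmann nonlinear capacitance model
#'
#' Membrane capacitance of an outer hair cell as a function of membrane
#' potential: a voltage-independent (linear, cell-size) term plus the
#' bell-shaped nonlinear component generated by prestin charge movement,
#'
#' \deqn{C_m(v) = C_{lin} + \frac{Q_{max}}{\alpha}\,
#'       \frac{e^x}{(1+e^x)^2}, \qquad x = \frac{v - V_{pk}}{\alpha}}
#'
#' The peak of the nonlinear component sits at \eqn{V_{pk}} with height
#' \eqn{Q_{max}/(4\alpha)}, and its integral over all voltages equals
#' \eqn{Q_{max}}.
#'
#' @param v Membrane potential (mV); vectorized.
#' @param qmax Maximum nonlinear charge (fC).
#' @param alpha Slope factor of the voltage dependence (mV).
#' @param vpk Voltage at peak capacitance (mV).
#' @param clin Linear capacitance (pF).
#' @return Capacitance (pF), same length as `v`.
#' @export
#' @examples
#' nlc_capacitance(-70, qmax = 800, alpha = 33, vpk = -70, clin = 7)
nlc_capacitance <- function(v, qmax, alpha, vpk, clin) {
  check_number(qmax, "qmax", min = 0)
  check_number(alpha, "alpha", min = 0, strict_min = TRUE)
  x <- (v - vpk) / alpha
  clin + (qmax / alpha) * boltz_g(x)
}

# logistic-derivative kernel and its derivatives, numerically stable
boltz_g <- function(x) 0.25 / cosh(x / 2)^2

boltz_g2 <- function(x) {
  s <- stats::plogis(x)
  g <- s * (1 - s)
  g * ((1 - 2 * s)^2 - 2 * g)
}

#' Patch-circuit, Boltzmann and stimulus parameter bundles
#'
#' Constructors for the three parameter sets that define a simulated
#' whole-cell recording: the passive recording circuit (series resistance,
#' membrane resistance, linear capacitance), the two-state Boltzmann
#' nonlinear-capacitance parameters, and the dual-sine command protocol.
#'
#' The dual-sine protocol superimposes two small sinusoids, the second at
#' twice the frequency of the first, on a series of holding (dc) levels.
#' The complex admittance measured at both frequencies over-determines the
#' three-element circuit (Rs, Rm, Cm), which is what makes single-segment
#' capacitance estimates possible. Default frequencies are the hardware
#' rates 390.625 and 781.25 Hz; each dc segment spans an exact integer
#' number of periods of both tones so that Fourier projections are
#' leakage-free.
#'
#' @param rs Series (pipette access) resistance, MOhm.
#' @param rm Membrane resistance, MOhm.
#' @param clin Linear membrane capacitance, pF.
#' @return A validated list with class `circuit_params`,
#'   `boltzmann_params` or `two_sine_protocol`.
#' @export
circuit_params <- function(rs = 10, rm = 500, clin = 7) {
  check_number(rs, "rs", min = 0)
  check_number(rm, "rm", min = 0, strict_min = TRUE)
  check_number(clin, "clin", min = 0, strict_min = TRUE)
  structure(list(rs = rs, rm = rm, clin = clin), class = "circuit_params")
}

#' @rdname circuit_params
#' @param qmax Maximum nonlinear charge, fC.
#' @param alpha Slope factor, mV.
#' @param vpk Voltage at peak capacitance, mV.
#' @export
boltzmann_params <- function(qmax = 800, alpha = 33, vpk = -70) {
  check_number(qmax, "qmax", min = 0)
  check_number(alpha, "alpha", min = 0, strict_min = TRUE)
  check_number(vpk, "vpk")
  structure(list(qmax = qmax, alpha = alpha, vpk = vpk),
            class = "boltzmann_params")
}

#' @rdname circuit_params
#' @param f1,f2 Stimulus frequencies, Hz; `f2` must equal `2 * f1` to
#'   within 0.1%.
#' @param amplitude Peak amplitude of each sine, mV.
#' @param dc_levels Holding potentials (mV) stepped through in order.
#' @param periods_per_level Analysed periods of `f1` per dc level.
#' @param settle_periods Periods of `f1` discarded at the start of each
#'   level while the membrane settles after the dc step.
#' @param sample_rate Sampling rate, Hz; must be at least `20 * f2`.
#' @param phase_cycle If `TRUE` (default) every dc level is recorded
#'   twice, with the sign of the `f2` tone inverted on the second pass.
#'   Averaging the admittances over the pair cancels all intermodulation
#'   products odd in the `f2` tone — the leading systematic error of the
#'   dual-sine method on a voltage-dependent capacitance.
#' @export
two_sine_protocol <- function(f1 = 390.625, f2 = 2 * f1, amplitude = 10,
                              dc_levels = seq(-150, 90, by = 20),
                              periods_per_level = 10, settle_periods = 2,
                              sample_rate = 50000, phase_cycle = TRUE) {
  check_number(f1, "f1", min = 0, strict_min = TRUE)
  check_number(f2, "f2", min = 0, strict_min = TRUE)
  if (abs(f2 - 2 * f1) > 1e-3 * f1) {
    stop_cochle("`f2` must be twice `f1` (dual-sine protocol assumption)",
                "protocol_error")
  }
  check_number(amplitude, "amplitude", min = 0)
  check_number(dc_levels, "dc_levels", len = length(dc_levels))
  if (length(dc_levels) < 1) stop_cochle("need at least one dc level",
                                         "protocol_error")
  check_number(periods_per_level, "periods_per_level", min = 1)
  check_number(settle_periods, "settle_periods", min = 0)
  check_number(sample_rate, "sample_rate", min = 0, strict_min = TRUE)
  if (sample_rate < 20 * f2) {
    stop_cochle("`sample_rate` must be at least 20 * f2", "protocol_error")
  }
  if (!is.logical(phase_cycle) || length(phase_cycle) != 1 ||
      is.na(phase_cycle)) {
    stop_cochle("`phase_cycle` must be TRUE or FALSE", "protocol_error")
  }
  structure(list(f1 = f1, f2 = f2, amplitude = amplitude,
                 dc_levels = dc_levels,
                 periods_per_level = periods_per_level,
                 settle_periods = settle_periods,
                 sample_rate = sample_rate, phase_cycle = phase_cycle),
            class = "two_sine_protocol")
}
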