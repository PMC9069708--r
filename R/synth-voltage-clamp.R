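#' Simulate a dual-sine whole-cell voltage-clamp recording
#'
#' Integrates the single-compartment patch-circuit ODE
#' \deqn{C(V_m)\,\frac{dV_m}{dt} = \frac{V_c - V_m}{R_s} - \frac{V_m}{R_m}}
#' with total capacitance \eqn{C(V) = C_{lin} + NLC(V)} (see
#' [nlc_capacitance()]) under the dual-sine command
#' \eqn{V_c(t) = V_{dc} + A[\sin 2\pi f_1 t + \sin 2\pi f_2 t]},
#' stepped through the protocol's dc levels. The recorded current is the
#' pipette current \eqn{I = (V_c - V_m)/R_s}, or the total membrane current
#' \eqn{V_c/R_m + C(V_c)\,dV_c/dt} in the ideal-clamp limit `rs = 0`.
#' Integration is fixed-step fourth-order Runge-Kutta at the sample rate.
#'
#' @param circuit A [circuit_params()] bundle (Rs, Rm, Clin).
#' @param boltzmann A [boltzmann_params()] bundle (Qmax, alpha, Vpk), or
#'   `NULL` for a purely linear cell (`qmax = 0`).
#' @param protocol A [two_sine_protocol()] bundle.
#' @param noise_rms_pA RMS of additive Gaussian current noise, pA.
#' @param seed RNG seed for the noise stream; each call uses its own
#'   stream and leaves the global RNG untouched.
#' @return A tibble of class `vc_recording` with columns `time_ms`,
#'   `vcmd_mV`, `current_nA`, carrying as attributes the protocol, the
#'   analysis `segments` table (one row per dc level: `dc_mV`, `start`,
#'   `end` sample indices, settle excluded) and the generating `truth`.
#' @export
#' @examples
#' rec <- simulate_voltage_clamp(circuit_params(), boltzmann_params(),
#'                               two_sine_protocol(dc_levels = c(-90, -70)))
#' head(rec)
simulate_voltage_clamp <- function(circuit, boltzmann = NULL,
                                   protocol = two_sine_protocol(),
                                   noise_rms_pA = 0, seed = NULL) {
  stopifnot(inherits(circuit, "circuit_params"),
            inherits(protocol, "two_sine_protocol"))
  if (is.null(boltzmann)) boltzmann <- boltzmann_params(qmax = 0)
  stopifnot(inherits(boltzmann, "boltzmann_params"))
  check_number(noise_rms_pA, "noise_rms_pA", min = 0)

  fs <- protocol$sample_rate
  dt <- 1000 / fs                              # ms per sample
  n_settle <- round(protocol$settle_periods * fs / protocol$f1)
  n_seg <- round(protocol$periods_per_level * fs / protocol$f1)
  n_block <- n_settle + n_seg
  phases <- if (protocol$phase_cycle) c(1, -1) else 1
  # one block per (dc level, f2 phase sign); command phase restarts at
  # each block so every analysis window begins at phase zero of f1
  blocks <- tidyr::expand_grid(dc_mV = protocol$dc_levels, phase = phases)
  n_tot <- n_block * nrow(blocks)

  cap <- function(v) nlc_capacitance(v, boltzmann$qmax, boltzmann$alpha,
                                     boltzmann$vpk, circuit$clin)
  w1 <- 2 * pi * protocol$f1 / 1000            # rad per ms
  w2 <- 2 * pi * protocol$f2 / 1000
  cmd_at <- function(dc, ph, tm) {
    dc + protocol$amplitude * (sin(w1 * tm) + ph * sin(w2 * tm))
  }

  t_block <- (seq_len(n_block) - 1) * dt
  vcmd <- unlist(purrr::map2(blocks$dc_mV, blocks$phase,
                             function(dc, ph) cmd_at(dc, ph, t_block)),
                 use.names = FALSE)

  if (circuit$rs == 0) {
    # ideal clamp: membrane potential follows the command exactly
    dvc <- unlist(purrr::map(blocks$phase, function(ph) {
      protocol$amplitude *
        (w1 * cos(w1 * t_block) + ph * w2 * cos(w2 * t_block))
    }), use.names = FALSE)
    current <- vcmd / circuit$rm + 1e-3 * cap(vcmd) * dvc   # nA
  } else {
    rs <- circuit$rs; rm <- circuit$rm
    # dV/dt in mV/ms; pF * mV/ms = pA, hence the 1e3 on the nA drive
    deriv <- function(vc, vm) 1e3 * ((vc - vm) / rs - vm / rm) / cap(vm)
    vm <- numeric(n_tot)
    v <- blocks$dc_mV[1] * rm / (rs + rm)      # start at dc steady state
    half <- dt / 2
    for (i in seq_len(n_tot)) {
      vm[i] <- v
      blk <- (i - 1) %/% n_block + 1
      tl <- ((i - 1) %% n_block) * dt
      dc <- blocks$dc_mV[blk]; ph <- blocks$phase[blk]
      # command evaluated analytically at the RK4 half-step
      vc0 <- vcmd[i]
      vch <- cmd_at(dc, ph, tl + half)
      vc1 <- cmd_at(dc, ph, tl + dt)
      k1 <- deriv(vc0, v)
      k2 <- deriv(vch, v + half * k1)
      k3 <- deriv(vch, v + half * k2)
      k4 <- deriv(vc1, v + dt * k3)
      v <- v + dt * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    }
    current <- (vcmd - vm) / rs                # nA
  }

  if (noise_rms_pA > 0) {
    current <- current +
      with_seed(seed, rnorm(n_tot, sd = noise_rms_pA * 1e-3))
  }

  segments <- mutate(blocks,
    start = (seq_len(nrow(blocks)) - 1) * n_block + n_settle + 1L,
    end = seq_len(nrow(blocks)) * n_block
  )
  new_vc_recording(
    tibble(time_ms = (seq_len(n_tot) - 1) * dt,
           vcmd_mV = vcmd, current_nA = current),
    protocol = protocol, segments = segments,
    truth = list(circuit = circuit, boltzmann = boltzmann)
  )
}

new_vc_recording <- function(data, protocol, segments, truth = NULL) {
  structure(data, protocol = protocol, segments = segments, truth = truth,
            class = c("vc_recording", class(data)))
}

#' Write or read a voltage-clamp trace as CSV
#'
#' The CSV carries the unit-bearing column names `time_ms`, `vcmd_mV`,
#' `current_nA`; segment boundaries and the protocol travel in a JSON
#' sidecar (`<path>.json`) so a recording round-trips losslessly.
#'
#' @param recording A `vc_recording`.
#' @param path Output CSV path.
#' @return `write_vc_recording()` returns `path` invisibly;
#'   `read_vc_recording()` returns a `vc_recording`.
#' @export
write_vc_recording <- function(recording, path) {
  stopifnot(inherits(recording, "vc_recording"))
  readr::write_csv(as_tibble(recording), path)
  proto <- attr(recording, "protocol")
  side <- list(protocol = unclass(proto),
               segments = attr(recording, "segments"))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_vc_recording
#' @export
read_vc_recording <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time_ms", "vcmd_mV", "current_nA")
  if (!all(need %in% names(data))) {
    stop_cochle("trace CSV must have columns time_ms, vcmd_mV, current_nA",
                "format_error")
  }
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) {
    stop_cochle("missing protocol sidecar JSON for trace", "format_error")
  }
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  proto <- do.call(two_sine_protocol, side$protocol[
    c("f1", "f2", "amplitude", "dc_levels", "periods_per_level",
      "settle_periods", "sample_rate")])
  new_vc_recording(data, protocol = proto,
                   segments = as_tibble(side$segments))
}
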