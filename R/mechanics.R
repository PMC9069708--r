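#' Sinusoidal amplitude of a displacement trace at the drive frequency
#'
#' `2 * |Fourier coefficient at drive_freq| / N` on the mean-removed
#' trace: extracts the motion at the stimulus frequency only, rejecting
#' DC offset and broadband noise.
#'
#' @param trace Displacement samples (nm).
#' @param drive_freq Drive frequency, Hz.
#' @param sample_rate Sampling rate, Hz.
#' @return Amplitude (nm).
#' @export
trace_amplitude <- function(trace, drive_freq, sample_rate) {
  check_number(drive_freq, "drive_freq", min = 0, strict_min = TRUE)
  check_number(sample_rate, "sample_rate", min = 0, strict_min = TRUE)
  if (drive_freq >= sample_rate / 2) {
    stop_cochle("drive frequency at or above Nyquist", "protocol_error")
  }
  if (length(trace) < 3 * sample_rate / drive_freq) {
    stop_cochle("trace must span at least 3 periods of the drive",
                "protocol_error")
  }
  Mod(fourier_coefficient(trace, drive_freq, sample_rate))
}

#' Axial stiffness of an outer hair cell from fiber amplitudes
#'
#' A calibrated glass fiber of stiffness `kf` is driven against the cell:
#' comparing the free motion of its tip (`Lf`) with the loaded motion
#' (`Lc`) gives the cell's axial stiffness
#' \deqn{k_c = k_f (L_f - L_c) / L_c} (two springs in series sharing
#' displacement). `Lf < Lc` is physically impossible for a passive load
#' and is reported with a `physical = FALSE` flag rather than hidden.
#'
#' @param kf Fiber stiffness (any consistent stiffness unit).
#' @param lf Free-fiber tip amplitude.
#' @param lc Loaded-fiber tip amplitude (> 0).
#' @return One-row tibble: `kf`, `lf`, `lc`, `kc`, `physical`.
#' @export
#' @examples
#' axial_stiffness(kf = 2, lf = 3, lc = 1)  # kc = 4
axial_stiffness <- function(kf, lf, lc) {
  check_number(kf, "kf", min = 0, strict_min = TRUE)
  check_number(lf, "lf", min = 0, strict_min = TRUE)
  check_number(lc, "lc", min = 0)
  if (lc == 0) {
    stop_cochle("loaded amplitude is zero: stiffness unbounded",
                "undefined_value")
  }
  kc <- kf * (lf - lc) / lc
  physical <- lf >= lc
  if (!physical) {
    warn("loaded amplitude exceeds free amplitude; reporting negative (non-physical) stiffness",
         class = "cochleaging_warning")
  }
  tibble(kf = kf, lf = lf, lc = lc, kc = kc, physical = physical)
}

#' Axial stiffness from a pair of fiber traces
#'
#' Convenience wrapper: extracts both amplitudes at the drive frequency
#' with [trace_amplitude()] and applies [axial_stiffness()].
#'
#' @param traces A `fiber_traces` object (see [simulate_fiber_traces()])
#'   or a data frame with columns `time_ms`, `free_nm`, `loaded_nm`.
#' @param kf Fiber stiffness; defaults to the value carried by `traces`.
#' @param drive_freq,sample_rate Drive frequency and sampling rate (Hz);
#'   default to the values carried by `traces`.
#' @export
fiber_stiffness <- function(traces, kf = attr(traces, "kf"),
                            drive_freq = attr(traces, "drive_freq"),
                            sample_rate = attr(traces, "sample_rate")) {
  stopifnot(all(c("free_nm", "loaded_nm") %in% names(traces)))
  lf <- trace_amplitude(traces$free_nm, drive_freq, sample_rate)
  lc <- trace_amplitude(traces$loaded_nm, drive_freq, sample_rate)
  axial_stiffness(kf, lf, lc)
}
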