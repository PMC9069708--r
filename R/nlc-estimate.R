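#' Complex admittance of a trace segment at one stimulus frequency
#'
#' Projects the detrended command and current onto the complex exponential
#' at `f` and returns the ratio of current to voltage coefficients,
#' \eqn{Y(f) = I(f)/V(f)}. With current in nA and command in mV the
#' admittance is in microsiemens (equivalently 1/MOhm). The window must
#' span an integer number of periods of `f`; otherwise the projection
#' leaks across frequencies and an error is raised.
#'
#' @param vcmd,current Command (mV) and current (nA) vectors over one
#'   analysis window.
#' @param f Frequency, Hz.
#' @param sample_rate Sampling rate, Hz.
#' @return A complex scalar admittance (uS).
#' @export
fourier_admittance <- function(vcmd, current, f, sample_rate) {
  vc <- fourier_coefficient(vcmd, f, sample_rate)
  ic <- fourier_coefficient(current, f, sample_rate)
  if (Mod(vc) == 0) {
    stop_cochle("command has no component at the requested frequency",
                "protocol_error")
  }
  ic / vc
}

# complex amplitude of x at f: x(t) ~ Re(coef * exp(2i pi f t));
# exact when the window holds an integer number of periods
fourier_coefficient <- function(x, f, sample_rate) {
  n <- length(x)
  periods <- n * f / sample_rate
  if (abs(periods - round(periods)) > 1e-3) {
    stop_cochle(sprintf(
      "window of %d samples spans %.4f periods of %.4g Hz; integer count required (spectral leakage)",
      n, periods, f), "leakage_error")
  }
  x <- x - mean(x)
  t_s <- (seq_len(n) - 1) / sample_rate
  (2 / n) * sum(x * exp(-2i * pi * f * t_s))
}

#' Solve the three-element patch circuit from two admittances
#'
#' The dual-sine protocol yields the complex admittance of the recording
#' circuit at two frequencies; the model
#' \deqn{Y(\omega) = \frac{1}{R_s + R_m/(1 + j\omega R_m C_m)}}
#' has three real parameters, so the pair (four real numbers)
#' over-determines it. The solver root-finds the series resistance on the
#' identity \eqn{Re\{1/(Z-R_s)\}} being frequency-independent, recovers
#' \eqn{R_m} and \eqn{C_m} in closed form, then polishes all three by
#' Levenberg-Marquardt least squares on the complex residuals. The
#' relative residual norm is reported; a pair no RC model fits within
#' `tol` raises a model-mismatch error.
#'
#' @param y1,y2 Complex admittances (uS) at `f1` and `f2`.
#' @param f1,f2 The two frequencies, Hz.
#' @param tol Maximum tolerated relative residual before the pair is
#'   declared inconsistent with any RC circuit.
#' @param mode `"full"` fits all four real numbers; `"resym"` fits the
#'   two imaginary parts plus the sum of the real parts, which rejects
#'   the conductance-like intermodulation contamination that a
#'   voltage-dependent capacitance adds with opposite signs at the two
#'   harmonically related frequencies. Both modes agree on data an RC
#'   circuit fits exactly.
#' @return A list with `rs`, `rm` (MOhm), `cm` (pF) and `residual`.
#' @export
#' @examples
#' y <- function(f, rs, rm, cm) {
#'   w <- 2 * pi * f
#'   1 / (rs + rm / (1 + 1i * w * rm * cm * 1e-6))
#' }
#' solve_rc_from_admittance(y(390.625, 10, 500, 25),
#'                          y(781.25, 10, 500, 25), 390.625, 781.25)
solve_rc_from_admittance <- function(y1, y2, f1, f2, tol = 0.2,
                                     mode = c("full", "resym")) {
  mode <- match.arg(mode)
  if (!is.complex(c(y1, y2)) || anyNA(c(y1, y2)) ||
      !all(is.finite(c(Re(y1), Im(y1), Re(y2), Im(y2))))) {
    stop_cochle("admittances must be finite complex numbers", "config_error")
  }
  if (f1 == f2) stop_cochle("f1 and f2 must differ", "config_error")
  w1 <- 2 * pi * f1; w2 <- 2 * pi * f2       # rad/s; MOhm*pF = 1e-6 s
  z1 <- 1 / y1; z2 <- 1 / y2

  invz <- function(z, rs) 1 / (z - rs)
  gap <- function(rs) Re(invz(z1, rs)) - Re(invz(z2, rs))
  rs_max <- min(Re(z1), Re(z2))
  start <- NULL
  if (rs_max > 0) {
    eps <- rs_max * 1e-6
    g0 <- gap(0); g1 <- gap(rs_max - eps)
    if (is.finite(g0) && is.finite(g1) && g0 * g1 <= 0) {
      rs0 <- uniroot(gap, c(0, rs_max - eps), tol = 1e-12)$root
      w1h <- invz(z1, rs0); w2h <- invz(z2, rs0)
      rm0 <- 2 / (Re(w1h) + Re(w2h))
      cm0 <- 1e6 * (Im(w1h) / w1 + Im(w2h) / w2) / 2
      if (is.finite(rm0) && rm0 > 0 && is.finite(cm0) && cm0 > 0) {
        start <- c(rs0, rm0, cm0)
      }
    }
  }
  if (is.null(start)) {
    # fallback start: ideal-clamp reading of the low-frequency admittance
    cm0 <- max(1e6 * Im(y1) / w1, 1e-3)
    rm0 <- if (Re(y1) > 0) 1 / Re(y1) else 1e3
    start <- c(max(rs_max / 2, 1e-3), rm0, cm0)
  }

  model <- function(p) {
    zm1 <- p[2] / (1 + 1i * w1 * p[2] * p[3] * 1e-6)
    zm2 <- p[2] / (1 + 1i * w2 * p[2] * p[3] * 1e-6)
    c(1 / (p[1] + zm1), 1 / (p[1] + zm2))
  }
  resid <- function(p) {
    d <- model(p) - c(y1, y2)
    if (mode == "resym") {
      # quadratic intermodulation of the harmonically related tones
      # contaminates Re(Y) with opposite signs at f1 and f2; fitting only
      # the symmetric (sum) real part rejects it
      c(Im(d), Re(d[1]) + Re(d[2]))
    } else {
      c(Re(d), Im(d))
    }
  }
  fit <- minpack.lm::nls.lm(
    par = start, lower = c(0, 1e-9, 1e-9), fn = resid,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                         ptol = 1e-15))
  p <- fit$par
  rel <- sqrt(sum(resid(p)^2) / sum(Mod(c(y1, y2))^2))
  if (rel > tol) {
    stop_cochle(sprintf(
      "no RC circuit reproduces the admittance pair (relative residual %.3g)",
      rel), "model_mismatch")
  }
  list(rs = unname(p[1]), rm = unname(p[2]), cm = unname(p[3]),
       residual = rel)
}

#' Per-voltage membrane capacitance from a dual-sine recording
#'
#' For each dc segment of the recording, measures the complex admittance
#' at both stimulus frequencies, solves the three-element circuit
#' ([solve_rc_from_admittance()]), and reports the capacitance against the
#' series-resistance-corrected membrane potential
#' \eqn{v = V_{dc} - I_{dc}\hat R_s} (first-order dc correction). Failed
#' segments are flagged (`ok = FALSE`) rather than aborting the series.
#'
#' The column `kappa_mV2` carries the second-moment of the stimulus seen
#' by the membrane at each dc level, attenuated through the fitted circuit;
#' [fit_boltzmann()] can use it to undo the smoothing a finite sine
#' excursion applies to the capacitance-voltage curve.
#'
#' @param recording A `vc_recording` (see [simulate_voltage_clamp()] /
#'   [read_vc_recording()]).
#' @param tol Residual tolerance forwarded to the circuit solver.
#' @return A tibble with one row per dc level: `dc_mV`, `v_mV`, `cm_pF`,
#'   `rs_MOhm`, `rm_MOhm`, `residual`, `kappa_mV2`, `ok`.
#' @export
cm_voltage_series <- function(recording, tol = 0.2) {
  stopifnot(inherits(recording, "vc_recording"))
  proto <- attr(recording, "protocol")
  segs <- attr(recording, "segments")
  if (is.null(proto) || is.null(segs)) {
    stop_cochle("recording carries no protocol/segment metadata",
                "config_error")
  }
  fs <- proto$sample_rate
  a <- proto$amplitude
  w1 <- 2 * pi * proto$f1; w2 <- 2 * pi * proto$f2
  if (!"phase" %in% names(segs)) segs$phase <- 1

  by_level <- split(segs, factor(segs$dc_mV, levels = unique(segs$dc_mV)))
  rows <- purrr::map(by_level, function(seg) {
    dc <- seg$dc_mV[1]
    out <- tibble(dc_mV = dc, v_mV = NA_real_, cm_pF = NA_real_,
                  rs_MOhm = NA_real_, rm_MOhm = NA_real_,
                  residual = NA_real_, kappa_mV2 = NA_real_, ok = FALSE)
    fit <- tryCatch({
      # admittances averaged over the phase-cycled pair: intermodulation
      # terms odd in the f2 tone cancel in the average
      ys <- purrr::pmap(seg[c("start", "end")], function(start, end) {
        idx <- start:end
        c(fourier_admittance(recording$vcmd_mV[idx],
                             recording$current_nA[idx], proto$f1, fs),
          fourier_admittance(recording$vcmd_mV[idx],
                             recording$current_nA[idx], proto$f2, fs))
      })
      y <- Reduce(`+`, ys) / length(ys)
      solve_rc_from_admittance(y[1], y[2], proto$f1, proto$f2, tol = tol,
                               mode = "resym")
    }, cochleaging_error = function(e) NULL)
    if (is.null(fit)) return(out)
    i_dc <- mean(recording$current_nA[
      unlist(purrr::map2(seg$start, seg$end, seq))])
    # membrane-level sine amplitudes, attenuated by the pipette RC divider
    att <- function(w) {
      zm <- fit$rm / (1 + 1i * w * fit$rm * fit$cm * 1e-6)
      Mod(zm / (fit$rs + zm))
    }
    a1m <- a * att(w1); a2m <- a * att(w2)
    out$v_mV <- dc - i_dc * fit$rs
    out$cm_pF <- fit$cm
    out$rs_MOhm <- fit$rs
    out$rm_MOhm <- fit$rm
    out$residual <- fit$residual
    # averaged over the two measurement frequencies (see vignette)
    out$kappa_mV2 <- 3 * (a1m^2 + a2m^2) / 16
    out$ok <- TRUE
    out
  })
  bind_rows(rows)
}

#' Fit the two-state Boltzmann NLC model to capacitance-voltage points
#'
#' Least-squares fit of [nlc_capacitance()] to a capacitance-voltage
#' series, returning the four parameters (Qmax, alpha, Vpk, Clin) and the
#' charge density Qmax/Clin. Initialization is multi-start over slope
#' factors 20, 33 and 50 mV with Clin started at the minimum capacitance,
#' Vpk at the voltage of the maximum, and Qmax at 4*alpha*(max - min);
#' the best converged start (lowest RSS) wins.
#'
#' When `kappa` is supplied (scalar, or the `kappa_mV2` column produced by
#' [cm_voltage_series()]), the fitted model is
#' \eqn{C(v) + \kappa\,C''(v)}: the second-order correction for the
#' smoothing that a finite dual-sine excursion (second moment
#' \eqn{\kappa}, in mV^2) applies to the measured curve. Without it the
#' fitted slope factor absorbs the stimulus width and is biased wide by
#' roughly \eqn{3\kappa/(\pi^2\alpha^2)}.
#'
#' @param points A data frame with columns `v_mV` and `cm_pF` (the output
#'   of [cm_voltage_series()] works directly; rows with `ok == FALSE` are
#'   dropped).
#' @param kappa Stimulus second moment (mV^2): `NULL` for the plain model,
#'   a scalar, or a vector matching `points` rows. If `points` has a
#'   `kappa_mV2` column and `kappa = "auto"`, that column is used.
#' @param alpha_starts Slope-factor starting values (mV).
#' @return An object of class `nlc_fit`; see [tidy.nlc_fit()],
#'   [glance.nlc_fit()], [autoplot.nlc_fit()].
#' @export
#' @examples
#' pts <- tibble::tibble(v_mV = seq(-150, 90, 20),
#'                       cm_pF = nlc_capacitance(seq(-150, 90, 20),
#'                                               800, 33, -70, 7))
#' fit <- fit_boltzmann(pts)
#' glance(fit)
fit_boltzmann <- function(points, kappa = "auto",
                          alpha_starts = c(20, 33, 50)) {
  pts <- as_tibble(points)
  if (!all(c("v_mV", "cm_pF") %in% names(pts))) {
    stop_cochle("`points` needs columns v_mV and cm_pF", "config_error")
  }
  if ("ok" %in% names(pts)) pts <- filter(pts, .data$ok)
  pts <- filter(pts, is.finite(.data$v_mV), is.finite(.data$cm_pF))
  if (nrow(pts) < 5) {
    stop_cochle("need at least 5 capacitance-voltage points", "fit_error")
  }
  if (identical(kappa, "auto")) {
    kappa <- if ("kappa_mV2" %in% names(pts)) pts$kappa_mV2 else NULL
  }
  if (!is.null(kappa)) {
    check_number(kappa, "kappa", min = 0, len = length(kappa))
    if (!length(kappa) %in% c(1L, nrow(pts))) {
      stop_cochle("`kappa` must be scalar or one value per point",
                  "config_error")
    }
  }
  v <- pts$v_mV; cm <- pts$cm_pF
  model <- function(p, vv, kk) {
    x <- (vv - p[3]) / p[2]
    out <- p[4] + (p[1] / p[2]) * boltz_g(x)
    if (!is.null(kk)) out <- out + kk * (p[1] / p[2]^3) * boltz_g2(x)
    out
  }
  resid <- function(p) model(p, v, kappa) - cm

  cmin <- min(cm); cmax <- max(cm)
  fits <- lapply(alpha_starts, function(a0) {
    start <- c(max(4 * a0 * (cmax - cmin), 1), a0, v[which.max(cm)],
               max(cmin, 1e-3))
    tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid,
                         lower = c(0, 1e-3, -Inf, 1e-6),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  if (!length(fits)) stop_cochle("Boltzmann fit failed to converge",
                                 "fit_error")
  rss <- vapply(fits, function(f) sum(f$fvec^2), numeric(1))
  best <- fits[[which.min(rss)]]
  p <- best$par
  bracketed <- p[3] >= min(v) && p[3] <= max(v)
  if (!bracketed) {
    warn("fitted peak voltage lies outside the sampled range; parameter estimates are poorly constrained",
         class = "cochleaging_warning")
  }
  structure(list(
    qmax = p[1], alpha = p[2], vpk = p[3], clin = p[4],
    charge_density = p[1] / p[4],
    rss = min(rss), converged = best$info %in% 1:4,
    bracketed = bracketed, kappa = kappa,
    data = tibble(v_mV = v, cm_pF = cm,
                  fitted_pF = model(p, v, kappa))
  ), class = "nlc_fit")
}

#' @export
print.nlc_fit <- function(x, ...) {
  cat("Two-state Boltzmann NLC fit\n")
  cat(sprintf("  Qmax  %8.2f fC\n  alpha %8.2f mV\n  Vpk   %8.2f mV\n",
              x$qmax, x$alpha, x$vpk))
  cat(sprintf("  Clin  %8.3f pF\n  charge density %.2f fC/pF\n",
              x$clin, x$charge_density))
  cat(sprintf("  RSS %.3g over %d points%s\n", x$rss, nrow(x$data),
              if (x$bracketed) "" else " (peak not bracketed!)"))
  invisible(x)
}

#' Tidiers and plot for Boltzmann NLC fits
#'
#' @param x,object An `nlc_fit` from [fit_boltzmann()].
#' @param ... Unused.
#' @return `tidy()` a tibble of parameter estimates; `glance()` a one-row
#'   fit summary; `autoplot()` a ggplot of the points and fitted curve.
#' @method tidy nlc_fit
#' @export
tidy.nlc_fit <- function(x, ...) {
  tibble(term = c("qmax_fC", "alpha_mV", "vpk_mV", "clin_pF",
                  "charge_density_fC_pF"),
         estimate = c(x$qmax, x$alpha, x$vpk, x$clin, x$charge_density))
}

#' @rdname tidy.nlc_fit
#' @method glance nlc_fit
#' @export
glance.nlc_fit <- function(x, ...) {
  tibble(qmax_fC = x$qmax, alpha_mV = x$alpha, vpk_mV = x$vpk,
         clin_pF = x$clin, charge_density_fC_pF = x$charge_density,
         rss = x$rss, n = nrow(x$data), converged = x$converged,
         peak_bracketed = x$bracketed)
}

#' Evaluate a fitted NLC curve on a voltage grid
#'
#' Returns the underlying (stimulus-free) Boltzmann capacitance, i.e. the
#' de-smoothed curve when a stimulus correction was fitted.
#'
#' @param object An `nlc_fit`.
#' @param v_mV Voltage grid (mV); defaults to a fine grid over the data.
#' @param ... Unused.
#' @export
predict.nlc_fit <- function(object, v_mV = NULL, ...) {
  if (is.null(v_mV)) {
    v_mV <- seq(min(object$data$v_mV), max(object$data$v_mV),
                length.out = 200)
  }
  tibble(v_mV = v_mV,
         cm_pF = nlc_capacitance(v_mV, object$qmax, object$alpha,
                                 object$vpk, object$clin))
}

#' @rdname tidy.nlc_fit
#' @method autoplot nlc_fit
#' @export
autoplot.nlc_fit <- function(object, ...) {
  curve <- predict(object)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$v_mV,
                                            y = .data$cm_pF)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, linewidth = 0.8,
                       colour = "firebrick") +
    ggplot2::labs(x = "Membrane potential (mV)", y = "Cm (pF)",
                  title = sprintf(
                    "Qmax %.0f fC, alpha %.1f mV, Vpk %.1f mV, Clin %.2f pF",
                    object$qmax, object$alpha, object$vpk, object$clin)) +
    ggplot2::theme_minimal()
}
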