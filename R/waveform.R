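# Flow waveforms: construction, sampling and the parametric systolic shape
# used by the synthetic generator.

#' Flow waveform container
#'
#' One cardiac cycle of volumetric flow rate at a named cross-section.
#' Times are in ms and cover `[0, period)` on a uniform grid; flow is in
#' mL s^-1. The waveform is interpreted as periodic, so the trapezoidal
#' cycle mean equals the plain mean of the samples.
#'
#' @param time numeric vector of sample times (ms), uniform, starting at 0.
#' @param flow numeric vector of flow rates (mL s^-1).
#' @param period cycle length (ms); default extrapolates the uniform grid.
#' @param name optional plane name.
#' @return object of class `flow_waveform`.
#' @export
flow_waveform <- function(time, flow, period = NULL, name = "inlet") {
  if (length(time) != length(flow)) stop("time and flow lengths differ")
  if (length(time) < 2L) stop("need at least 2 samples")
  dt <- diff(time)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(flow))) stop("flow must be finite")
  if (is.null(period)) period <- time[length(time)] - time[1L] + dt[1L]
  structure(list(time = time, flow = flow, period = period, name = name),
            class = "flow_waveform")
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf("flow_waveform '%s': %d frames, period %.0f ms, mean %.1f mL/s, peak %.1f mL/s\n",
              x$name, length(x$time), x$period, waveform_mean(x), max(x$flow)))
  invisible(x)
}

#' Cycle-mean flow of a periodic waveform (trapezoidal rule)
#' @param w a `flow_waveform`.
#' @return mean flow (mL s^-1).
#' @export
waveform_mean <- function(w) {
  # uniform periodic sampling: trapezoid over the closed cycle = sample mean
  mean(w$flow)
}

#' Periodic interpolant of a waveform
#' @param w a `flow_waveform`.
#' @param method "linear" or "spline" (periodic cubic).
#' @return function of time (ms) returning flow (mL s^-1).
#' @export
waveform_fun <- function(w, method = c("spline", "linear")) {
  method <- match.arg(method)
  tt <- c(w$time, w$time[1L] + w$period)
  qq <- c(w$flow, w$flow[1L])
  if (method == "spline") {
    f <- stats::splinefun(tt, qq, method = "periodic")
  } else {
    f <- stats::approxfun(tt, qq)
  }
  function(t) f(t %% w$period)
}

#' Flow and fluid parameter set for the synthetic generator
#'
#' Encodes the pulsatile inflow shape and the jet/swirl structure of the
#' synthetic velocity fields. Fluid constants default to whole blood treated
#' as an incompressible Newtonian fluid: density 1050 kg m^-3 and dynamic
#' viscosity 0.035 kg (m s)^-1.
#'
#' @param mean_flow cycle-mean flow (mL s^-1). Default 83 mL s^-1
#'   (about 5 L min^-1 cardiac output).
#' @param systolic_fraction fraction of the cycle occupied by systolic
#'   ejection (default 0.35).
#' @param peak_mean_ratio peak flow over mean flow (default 4).
#' @param jet_offset eccentric displacement of the systolic jet core from the
#'   centerline (mm).
#' @param jet_angle tilt of the jet axis away from the centerline tangent
#'   (degrees).
#' @param jet_azimuth in-plane direction (degrees, in the section frame) of
#'   both the offset and the tilt.
#' @param helical_strength swirl strength k (s^-1 m^-1): the secondary
#'   velocity is `k * rho * (R - rho)` (SI units), which vanishes at the wall
#'   (no slip) and at the jet core and exerts a circumferential wall shear
#'   stress of magnitude `mu * k * R` on a centred jet.
#' @param helical_window optional arc-length-fraction interval `c(lo, hi)`
#'   inside which the swirl acts at full strength (smoothly windowed);
#'   `NULL` applies it everywhere.
#' @param womersley_harmonics number of oscillatory Womersley harmonics to
#'   superpose on the quasi-steady parabolic profile (0 = quasi-steady).
#' @param density fluid density (kg m^-3).
#' @param viscosity dynamic viscosity (kg m^-1 s^-1).
#' @return object of class `flow_params`.
#' @export
flow_params <- function(mean_flow = 83, systolic_fraction = 0.35,
                        peak_mean_ratio = 4, jet_offset = 0, jet_angle = 0,
                        jet_azimuth = 0, helical_strength = 0,
                        helical_window = NULL, womersley_harmonics = 0L,
                        density = 1050, viscosity = 0.035) {
  if (mean_flow <= 0) stop("mean_flow must be positive")
  if (peak_mean_ratio < 1) stop("peak/mean ratio must be >= 1")
  if (systolic_fraction <= 0 || systolic_fraction >= 1)
    stop("systolic_fraction must be in (0, 1)")
  if (jet_offset < 0) stop("jet_offset must be >= 0")
  if (jet_angle < 0 || jet_angle >= 90) stop("jet_angle must be in [0, 90)")
  structure(list(mean_flow = mean_flow, systolic_fraction = systolic_fraction,
                 peak_mean_ratio = peak_mean_ratio, jet_offset = jet_offset,
                 jet_angle = jet_angle, jet_azimuth = jet_azimuth,
                 helical_strength = helical_strength,
                 helical_window = helical_window,
                 womersley_harmonics = as.integer(womersley_harmonics),
                 density = density, viscosity = viscosity),
            class = "flow_params")
}

# Closed-form systolic waveform: Q(t) = base + amp * sin^2(pi t / t_sys) during
# systole, base flow in diastole. Continuous-time mean is exactly mean_flow.
systolic_q_coef <- function(params, period) {
  fs <- params$systolic_fraction
  g <- params$peak_mean_ratio
  qm <- params$mean_flow
  amp <- (g - 1) * qm / (1 - fs / 2)
  base <- g * qm - amp
  if (base < -1e-9 * qm)
    stop("peak/mean ratio too large for this systolic fraction (negative diastolic flow)")
  list(base = max(base, 0), amp = amp, t_sys = fs * period)
}

#' Closed-form inflow function Q(t)
#'
#' @param params a `flow_params`.
#' @param period cycle length (ms).
#' @return function of time (ms, periodic) returning flow (mL s^-1).
#' @export
systolic_q_fun <- function(params, period = 1000) {
  cf <- systolic_q_coef(params, period)
  function(t) {
    tm <- t %% period
    q <- rep(cf$base, length(tm))
    s <- tm < cf$t_sys
    q[s] <- cf$base + cf$amp * sin(pi * tm[s] / cf$t_sys)^2
    q
  }
}

#' Generate a pulsatile flow waveform
#'
#' Samples the parametric systolic-dominant shape (squared-sine ejection over
#' the systolic fraction, constant diastolic base flow) on a uniform frame
#' grid and rescales so that the discrete trapezoidal cycle mean equals
#' `mean_flow` exactly.
#'
#' @param params a `flow_params`.
#' @param n_frames number of frames per cycle (>= 8).
#' @param period cycle length (ms).
#' @return a `flow_waveform`.
#' @examples
#' w <- generate_waveform(flow_params(mean_flow = 100), n_frames = 40)
#' waveform_mean(w)
#' @export
generate_waveform <- function(params, n_frames = 100L, period = 1000) {
  if (period <= 0) stop("period must be positive")
  n_frames <- as.integer(n_frames)
  if (n_frames < 8L) stop("need at least 8 frames per cycle")
  tt <- seq(0, period, length.out = n_frames + 1L)[seq_len(n_frames)]
  q <- systolic_q_fun(params, period)(tt)
  q <- q * params$mean_flow / mean(q)   # exact discrete cycle mean
  flow_waveform(tt, q, period = period)
}
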