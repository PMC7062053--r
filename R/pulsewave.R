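# Reduced-order pulse-wave propagation: two-element Windkessel ODE and a
# 1D elastic-tube solver (compiled core) used by the stiffness and
# flow-split calibration loops.

MMHG_PER_PA <- 1 / 133.322

#' Two-element Windkessel parameters
#'
#' Lumped outlet model `Q(t) = P(t)/R + C dP(t)/dt`: peripheral resistance R
#' (a resistor) and arterial compliance C (a capacitor).
#'
#' @param R peripheral resistance (Pa s m^-3), > 0.
#' @param C compliance (m^3 Pa^-1), > 0.
#' @return object of class `windkessel_params`.
#' @export
windkessel_params <- function(R, C) {
  if (R <= 0 || C <= 0) stop("Windkessel R and C must be positive")
  structure(list(R = R, C = C), class = "windkessel_params")
}

#' @export
print.windkessel_params <- function(x, ...) {
  cat(sprintf("windkessel_params: R = %.3g Pa s/m^3, C = %.3g m^3/Pa (tau = %.2f s)\n",
              x$R, x$C, x$R * x$C))
  invisible(x)
}

#' Pressure waveform container
#' @param time times (ms).
#' @param pressure pressures (Pa).
#' @return object of class `pressure_waveform`.
#' @export
pressure_waveform <- function(time, pressure) {
  if (length(time) != length(pressure)) stop("time and pressure lengths differ")
  if (any(!is.finite(pressure))) stop("pressure must be finite")
  structure(list(time = time, pressure = pressure), class = "pressure_waveform")
}

#' @export
print.pressure_waveform <- function(x, ...) {
  cat(sprintf("pressure_waveform: %d samples, %.1f-%.1f mmHg\n",
              length(x$time), min(x$pressure) * MMHG_PER_PA,
              max(x$pressure) * MMHG_PER_PA))
  invisible(x)
}

#' Solve the two-element Windkessel ODE for a periodic inflow
#'
#' Integrates `C dP/dt = Q(t) - P/R` with classical RK4 at a fine fixed step,
#' repeating cycles until the cycle-to-cycle relative L2 pressure change
#' drops below `cycle_tol` (default 0.1%), and returns the last cycle.
#'
#' @param Q a `flow_waveform` (mL s^-1, ms).
#' @param params a `windkessel_params`.
#' @param P0 initial pressure (Pa); defaults to `R * mean(Q)`.
#' @param n_cycles maximum number of cycles.
#' @param n_steps RK4 steps per cycle.
#' @param cycle_tol relative cycle-to-cycle convergence tolerance.
#' @return a `pressure_waveform` over one cycle, with attributes
#'   `cycles_run` and `converged`.
#' @export
solve_windkessel <- function(Q, params, P0 = NULL, n_cycles = 50L,
                             n_steps = 2000L, cycle_tol = 1e-3) {
  qfun_ml <- waveform_fun(Q, method = "linear")
  period_s <- Q$period / 1000
  qfun <- function(ts) qfun_ml(ts * 1000) * 1e-6        # m^3/s
  if (is.null(P0)) P0 <- params$R * waveform_mean(Q) * 1e-6
  h <- period_s / n_steps
  dPdt <- function(ts, p) (qfun(ts) - p / params$R) / params$C
  p <- P0
  prev <- NULL
  converged <- FALSE
  cycles <- 0L
  tgrid <- (0:n_steps) * h
  for (cyc in seq_len(n_cycles)) {
    trace <- numeric(n_steps + 1L)
    trace[1L] <- p
    t0 <- 0
    for (s in seq_len(n_steps)) {
      ts <- t0 + (s - 1L) * h
      k1 <- dPdt(ts, p)
      k2 <- dPdt(ts + h / 2, p + h / 2 * k1)
      k3 <- dPdt(ts + h / 2, p + h / 2 * k2)
      k4 <- dPdt(ts + h, p + h * k3)
      p <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      trace[s + 1L] <- p
    }
    cycles <- cyc
    if (!is.null(prev)) {
      err <- sqrt(sum((trace - prev)^2) / (sum(prev^2) + 1e-30))
      if (err < cycle_tol) { converged <- TRUE; prev <- trace; break }
    }
    prev <- trace
  }
  out <- pressure_waveform(tgrid[-(n_steps + 1L)] * 1000,
                           prev[-(n_steps + 1L)])
  attr(out, "cycles_run") <- cycles
  attr(out, "converged") <- converged
  out
}

#' Moens-Korteweg wave speed
#'
#' `c0 = sqrt(E h / (2 rho r))`: the linearized pulse wave speed of a thin
#' elastic tube; the tube law of the 1D solver is calibrated so that its
#' linearized wave speed equals this expression exactly.
#'
#' @param E Young's modulus (Pa).
#' @param r lumen radius (m).
#' @param h wall thickness (m).
#' @param rho fluid density (kg m^-3).
#' @return wave speed (m s^-1).
#' @export
mk_wave_speed <- function(E, r, h, rho = 1050) sqrt(E * h / (2 * rho * r))

#' 1D elastic tube model
#'
#' Uniform thin-walled elastic tube for the pulse-wave surrogate. The wall
#' density and Poisson ratio are carried as metadata (they do not enter the
#' tube law, which is calibrated to the Moens-Korteweg wave speed).
#'
#' @param length tube length (m).
#' @param radius reference lumen radius (m).
#' @param thickness wall thickness (m).
#' @param E Young's modulus (Pa).
#' @param rho_fluid fluid density (kg m^-3), default 1050.
#' @param viscosity dynamic viscosity (kg m^-1 s^-1), default 0.035.
#' @param rho_wall wall density (kg m^-3), metadata, default 1100.
#' @param poisson wall Poisson ratio, metadata, default 0.45.
#' @param wall_viscosity Voigt wall viscosity phi (Pa s), default 500. The
#'   viscoelastic tube law damps the short standing waves an elastic tube
#'   truncated by a lumped outlet would otherwise ring with, while leaving
#'   the pulse transit speed essentially unchanged; 0 disables it.
#' @param n_nodes number of grid nodes (default 200).
#' @param dt explicit time step (s); `NULL` picks `cfl * dx / (c0 + u_max)`.
#' @param cfl Courant number used when `dt` is automatic.
#' @param sink optional distributed outflow: `list(x0, x1, G)` with `x0 < x1`
#'   arc-length fractions and total conductance `G` (m^3 Pa^-1 s^-1),
#'   emulating branch outflow between the ascending and descending aorta.
#' @return object of class `tube_model_1d`.
#' @export
tube_model_1d <- function(length = 0.3, radius = 0.0125, thickness = 0.00125,
                          E = 1.25e6, rho_fluid = 1050, viscosity = 0.035,
                          rho_wall = 1100, poisson = 0.45,
                          wall_viscosity = 500, n_nodes = 200L,
                          dt = NULL, cfl = 0.8, sink = NULL) {
  if (length <= 0 || radius <= 0 || thickness <= 0 || E <= 0)
    stop("length, radius, thickness and E must be positive")
  if (!is.null(sink)) {
    if (!all(c("x0", "x1", "G") %in% names(sink)) || sink$x0 >= sink$x1 ||
        sink$x0 < 0 || sink$x1 > 1 || sink$G < 0)
      stop("sink must be list(x0, x1, G) with 0 <= x0 < x1 <= 1 and G >= 0")
  }
  structure(list(length = length, radius = radius, thickness = thickness,
                 E = E, rho_fluid = rho_fluid, viscosity = viscosity,
                 rho_wall = rho_wall, poisson = poisson,
                 wall_viscosity = wall_viscosity,
                 n_nodes = as.integer(n_nodes), dt = dt, cfl = cfl,
                 sink = sink,
                 c0 = mk_wave_speed(E, radius, thickness, rho_fluid)),
            class = "tube_model_1d")
}

#' @export
print.tube_model_1d <- function(x, ...) {
  cat(sprintf("tube_model_1d: L = %.2f m, r = %.1f mm, h = %.2f mm, E = %.3g Pa\n",
              x$length, x$radius * 1000, x$thickness * 1000, x$E))
  cat(sprintf("  c0 = %.2f m/s, %d nodes%s\n", x$c0, x$n_nodes,
              if (!is.null(x$sink)) sprintf(", sink G = %.3g over [%.2f, %.2f]",
                                            x$sink$G, x$sink$x0, x$sink$x1) else ""))
  invisible(x)
}

#' Simulate pulse-wave propagation through the 1D tube
#'
#' Advances the area-flow equations (mass and momentum with Poiseuille
#' friction) with a two-step Lax-Wendroff scheme; the inlet is driven by the
#' prescribed flow waveform through the backward characteristic and the
#' outlet couples into the two-element Windkessel through the forward
#' characteristic. Cycles repeat until the outlet pressure is periodic
#' (relative L2 cycle change below `cycle_tol`), then one further cycle is
#' recorded.
#'
#' @param model a `tube_model_1d`.
#' @param inlet a `flow_waveform` (mL s^-1).
#' @param outlet a `windkessel_params`.
#' @param n_cycles maximum number of cycles (default 12).
#' @param cycle_tol relative cycle-to-cycle L2 tolerance (default 0.005).
#' @param snap_nt number of stored space-time snapshots of Q, P, A.
#' @param arrival_frac threshold fraction of the systolic flow rise used for
#'   first-arrival wavefront detection (see [pwv_from_arrival()]);
#'   default 0.01.
#' @return object of class `pulsewave_result` with inlet/outlet flow and
#'   pressure waveforms, cycle-mean balances, snapshots and solver metadata.
#' @export
simulate_pulsewave <- function(model, inlet, outlet, n_cycles = 12L,
                               cycle_tol = 0.005, snap_nt = 50L,
                               arrival_frac = 0.01) {
  period_s <- inlet$period / 1000
  sink <- model$sink
  res <- solve_tube_1d_cpp(
    n_nodes = model$n_nodes, L = model$length, r0 = model$radius,
    h = model$thickness, E = model$E, rho = model$rho_fluid,
    mu = model$viscosity, inlet_t = inlet$time / 1000,
    inlet_q = inlet$flow * 1e-6, period = period_s,
    Rwk = outlet$R, Cwk = outlet$C,
    P_init = 0,
    max_cycles = as.integer(n_cycles), cycle_tol = cycle_tol,
    cfl = model$cfl, dt_user = if (is.null(model$dt)) -1 else model$dt,
    sink_x0 = if (is.null(sink)) 0 else sink$x0,
    sink_x1 = if (is.null(sink)) 0 else sink$x1,
    sink_G = if (is.null(sink)) 0 else sink$G,
    visc_D = (2 / 3) * sqrt(pi) * model$wall_viscosity * model$thickness /
      (model$rho_fluid * sqrt(pi * model$radius^2)),
    arr_frac = arrival_frac, snap_nt = as.integer(snap_nt))
  tms <- res$time * 1000
  structure(list(
    q_in = flow_waveform(tms, res$q_in * 1e6, period = inlet$period,
                         name = "inlet"),
    q_out = flow_waveform(tms, res$q_out * 1e6, period = inlet$period,
                          name = "outlet"),
    p_in = pressure_waveform(tms, res$p_in),
    p_out = pressure_waveform(tms, res$p_out),
    qmean_in = res$qmean_in * 1e6, qmean_out = res$qmean_out * 1e6,
    qmean_sink = res$qmean_sink * 1e6,
    snapshots = list(x = res$snap_x, t = res$snap_t * 1000,
                     Q = res$snap_Q * 1e6, P = res$snap_P, A = res$snap_A),
    arrival = list(x = res$snap_x,
                   t = ifelse(res$arrival_t < 0, NA_real_,
                              res$arrival_t * 1000),
                   threshold = res$arrival_thresh * 1e6),
    c0 = res$c0, dt = res$dt, cycles_run = res$cycles_run,
    converged = res$converged, model = model
  ), class = "pulsewave_result")
}

#' @export
print.pulsewave_result <- function(x, ...) {
  cat(sprintf("pulsewave_result: %d cycles (%s), dt = %.3g ms\n",
              x$cycles_run, if (x$converged) "periodic" else "NOT periodic",
              x$dt * 1000))
  cat(sprintf("  cycle means: in %.1f, out %.1f, sink %.1f mL/s; c0 = %.2f m/s\n",
              x$qmean_in, x$qmean_out, x$qmean_sink, x$c0))
  invisible(x)
}

# discrete peak with parabolic sub-sample refinement; periodic neighbours
peak_time_parabolic <- function(time, value, period = NULL) {
  n <- length(value)
  rng <- max(value) - min(value)
  if (rng <= 1e-12 * max(abs(value), 1e-300)) {
    return(structure(time[1L], flat = TRUE))
  }
  m <- which.max(value)
  if (!is.null(period)) {
    ym <- value[m]
    yl <- value[if (m == 1L) n else m - 1L]
    yr <- value[if (m == n) 1L else m + 1L]
  } else {
    if (m == 1L || m == n) return(structure(time[m], flat = FALSE))
    ym <- value[m]; yl <- value[m - 1L]; yr <- value[m + 1L]
  }
  dt <- if (n >= 2L) time[2L] - time[1L] else 0
  den <- yl - 2 * ym + yr
  off <- if (abs(den) < 1e-300) 0 else 0.5 * (yl - yr) / den
  off <- max(min(off, 0.5), -0.5)
  structure(time[m] + off * dt, flat = FALSE)
}


#' Pulse wave velocity from the cold-start wavefront transit
#'
#' The simulation starts from a quiescent tube and a discharged Windkessel,
#' so during the first cycle the systolic wavefront sweeps the tube exactly
#' once before any reflection exists: the time at which the flow first
#' crosses a low threshold is recorded at every grid node, and the wave
#' speed is the inverse slope of the regression of arrival time on distance.
#' Being strictly causal, this transit measurement is immune to the waveform
#' reshaping and standing waves that a lumped compliant outlet superimposes
#' on the periodic-steady-state waveforms (which make peak-to-peak timing on
#' an electrically short tube ill-posed; see [measure_pwv()]).
#'
#' @param sim a `pulsewave_result`.
#' @param x_range fraction of the tube length used for the fit. The default
#'   keeps the proximal half: distal arrivals are advanced by the wavefront's
#'   own reflection off the outlet, which reaches a point at distance x from
#'   the inlet a time 2(L - x)/c after the front and so contaminates the
#'   distal threshold crossings of a finite-rise-time upstroke first.
#' @return PWV (m s^-1).
#' @export
pwv_from_arrival <- function(sim, x_range = c(0.05, 0.5)) {
  x <- sim$arrival$x
  t <- sim$arrival$t
  L <- max(x)
  keep <- is.finite(t) & x >= x_range[1L] * L & x <= x_range[2L] * L
  if (sum(keep) < 10L)
    stop("wavefront arrival was not detected across the tube")
  fit <- stats::lm.fit(cbind(1, t[keep] / 1000), x[keep])
  speed <- fit$coefficients[2L]
  if (!is.finite(speed) || speed <= 0)
    stop("non-physical wavefront transit (non-positive speed)")
  unname(speed)
}

# systolic foot by the intersecting-tangent method: the tangent at the point
# of maximum upstroke slope is intersected with the pre-upstroke baseline.
# The foot is the first causal arrival of the wave, so unlike the peak it is
# immune to the waveform reshaping of a lumped compliant termination.
foot_time_tangent <- function(time, value, period) {
  n <- length(value)
  rng <- max(value) - min(value)
  if (rng <= 1e-12 * max(abs(value), 1e-300))
    return(structure(time[1L], flat = TRUE))
  m <- which.max(value)
  # rotate so the peak sits at the end of the window
  rot <- function(i) ((i - 1L) %% n) + 1L
  idx <- rot(seq(m - n + 1L, m))
  v <- value[idx]
  dtv <- time[2L] - time[1L]
  i_min <- which.min(v)
  if (i_min >= n - 1L) i_min <- 1L
  up <- i_min:(n - 1L)
  sl <- (v[up + 1L] - v[up]) / dtv
  i_s <- up[which.max(sl)]
  slope <- max(sl)
  if (slope <= 0) return(structure(time[m], flat = FALSE))
  t_rel <- (i_s - 0.5) * dtv  # time from window start to mid upstroke sample
  t_star <- t_rel + 0.5 * dtv
  v_star <- (v[i_s] + v[i_s + 1L]) / 2
  foot_rel <- t_star - (v_star - v[i_min]) / slope
  t0 <- time[1L] + (m - n) * dtv  # absolute time of the window start
  structure((t0 + foot_rel) %% period, flat = FALSE)
}

#' Pulse wave velocity from two flow waveforms
#'
#' `PWV = dx / dt` with `dt` the wave travel time between the two planes,
#' taken modulo the cycle so that adding the same constant delay to both
#' waveforms leaves the PWV unchanged.
#'
#' Two timing conventions are available. `method = "peak"` measures between
#' systolic peaks with parabolic sub-sample refinement around the discrete
#' maximum (frame intervals of 25 ms are too coarse for a raw argmax).
#' `method = "foot"` measures between the systolic feet located by the
#' intersecting-tangent construction; because the foot is the first causal
#' arrival of the wavefront it remains well defined when a lumped compliant
#' outlet reshapes the waveform and shifts its peak, and it is the
#' convention used by the stiffness-calibration loop on the 1D surrogate.
#'
#' @param wave_in upstream `flow_waveform`.
#' @param wave_out downstream `flow_waveform`.
#' @param dx distance between the planes (m).
#' @param method `"peak"` or `"foot"`.
#' @return PWV (m s^-1).
#' @export
measure_pwv <- function(wave_in, wave_out, dx, method = c("peak", "foot")) {
  method <- match.arg(method)
  if (dx <= 0) stop("dx must be positive")
  timer <- if (method == "peak") peak_time_parabolic else foot_time_tangent
  t_in <- timer(wave_in$time, wave_in$flow, wave_in$period)
  t_out <- timer(wave_out$time, wave_out$flow, wave_out$period)
  if (isTRUE(attr(t_in, "flat")) || isTRUE(attr(t_out, "flat")))
    stop("flat waveform: systolic timing undefined")
  dt_ms <- (as.numeric(t_out) - as.numeric(t_in)) %% wave_in$period
  if (dt_ms <= 1e-9)
    stop("non-physical wave timing: outlet does not lag the inlet (infinite PWV)")
  dx / (dt_ms / 1000)
}
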