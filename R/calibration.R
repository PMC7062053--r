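# Iterative matching loops: wall stiffness from a target pulse wave velocity
# (Moens-Korteweg) and Windkessel resistance from a target flow split.

#' Young's modulus from pulse wave velocity (Moens-Korteweg)
#'
#' `E = 2 PWV^2 r rho / h`. The density is the fluid density (classical
#' Moens-Korteweg form); all arguments SI.
#'
#' @param pwv pulse wave velocity (m s^-1), >= 0.
#' @param r lumen radius (m).
#' @param h wall thickness (m), > 0.
#' @param rho density (kg m^-3), default blood 1050.
#' @return Young's modulus (Pa).
#' @examples
#' mk_young_modulus(7.7, r = 0.0125, h = 0.00125)  # ~1.25 MPa
#' @export
mk_young_modulus <- function(pwv, r, h, rho = 1050) {
  if (h <= 0) stop("wall thickness h must be positive")
  if (pwv < 0 || r < 0 || rho < 0) stop("inputs must be non-negative")
  2 * pwv^2 * r * rho / h
}

#' Calibrate wall stiffness to a target pulse wave velocity
#'
#' Implements the iterative stiffness-matching loop: the initial Young's
#' modulus comes from the Moens-Korteweg formula applied to the target PWV;
#' each iteration simulates the pulse wave through the 1D tube, measures the
#' transit-time PWV between the inlet and outlet, and computes the relative
#' error `eps_i = (PWV_i - PWV_target) / PWV_target`. The loop stops when
#' `|eps_i| <= tolerance` (default +/- 5%) or after `max_iter` iterations.
#'
#' The default update is multiplicative, `E_{i+1} = E_i (PWV_target /
#' PWV_i)^2`, whose fixed point is `PWV_i = PWV_target`; it reduces to
#' re-applying the Moens-Korteweg formula to the measured PWV (`update =
#' "printed"`, available for comparison) whenever the simulator obeys
#' Moens-Korteweg exactly. If the error oscillates in sign without
#' shrinking, the log-E step is damped by `damping`.
#'
#' @param target_pwv target PWV (m s^-1), > 0.
#' @param model a `tube_model_1d` (its `E` is overwritten per iteration).
#' @param inlet a `flow_waveform`.
#' @param outlet a `windkessel_params`.
#' @param tolerance relative stopping tolerance (default 0.05).
#' @param max_iter maximum iterations (default 20).
#' @param update `"ratio"` (default) or `"printed"`.
#' @param damping damping factor applied to the log-E step on oscillation.
#' @param pwv_method `"arrival"` (default) measures the transit of the
#'   cold-start wavefront with [pwv_from_arrival()], which stays well posed
#'   under the lumped Windkessel termination of the 1D surrogate; `"peak"`
#'   and `"foot"` time the periodic waveforms with [measure_pwv()].
#' @param ... passed to [simulate_pulsewave()].
#' @return object of class `calibration_result`: data frame of iterations
#'   `(E, pwv, eps)`, `converged`, `tolerance`, `target_pwv`, final `model`.
#' @export
calibrate_stiffness <- function(target_pwv, model, inlet, outlet,
                                tolerance = 0.05, max_iter = 20L,
                                update = c("ratio", "printed"),
                                damping = 0.7, pwv_method = "arrival", ...) {
  if (target_pwv <= 0) stop("target_pwv must be positive")
  update <- match.arg(update)
  E <- mk_young_modulus(target_pwv, model$radius, model$thickness,
                        model$rho_fluid)
  iters <- data.frame(E = numeric(0), pwv = numeric(0), eps = numeric(0))
  converged <- FALSE
  prev_eps <- NA_real_
  for (i in seq_len(max_iter)) {
    model$E <- E
    model$c0 <- mk_wave_speed(E, model$radius, model$thickness, model$rho_fluid)
    sim <- simulate_pulsewave(model, inlet, outlet, ...)
    pwv_i <- if (pwv_method == "arrival") pwv_from_arrival(sim) else
      measure_pwv(sim$q_in, sim$q_out, model$length, method = pwv_method)
    eps_i <- (pwv_i - target_pwv) / target_pwv
    iters <- rbind(iters, data.frame(E = E, pwv = pwv_i, eps = eps_i))
    if (abs(eps_i) <= tolerance) { converged <- TRUE; break }
    if (update == "printed") {
      E_next <- mk_young_modulus(pwv_i, model$radius, model$thickness,
                                 model$rho_fluid)
    } else {
      step <- 2 * log(target_pwv / pwv_i)
      if (!is.na(prev_eps) && sign(eps_i) != sign(prev_eps) &&
          abs(eps_i) >= abs(prev_eps)) {
        step <- step * damping
      }
      E_next <- E * exp(step)
    }
    prev_eps <- eps_i
    E <- E_next
  }
  structure(list(iterations = iters, converged = converged,
                 tolerance = tolerance, target_pwv = target_pwv,
                 model = model),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration_result: target PWV %.2f m/s, %d iteration(s), %s\n",
              x$target_pwv, nrow(x$iterations),
              if (x$converged) sprintf("converged (|eps| <= %.0f%%)",
                                       100 * x$tolerance) else "NOT converged"))
  print(transform(x$iterations, eps_pct = 100 * eps))
  invisible(x)
}

#' Flow-split target for Windkessel tuning
#'
#' @param true_ratio target descending/ascending cycle-mean flow ratio, in
#'   (0, 1].
#' @param tolerance relative tolerance on the achieved ratio (default 0.05).
#' @return object of class `flow_split_target`.
#' @export
flow_split_target <- function(true_ratio, tolerance = 0.05) {
  if (true_ratio <= 0 || true_ratio > 1)
    stop("true_ratio must be in (0, 1]")
  structure(list(true_ratio = true_ratio, tolerance = tolerance),
            class = "flow_split_target")
}

#' Flow-ratio functions for Windkessel tuning
#'
#' `windkessel_ratio_fn` builds, from a branch-sink tube model, the map from
#' outlet resistance R to the achieved cycle-mean outlet/inlet flow ratio
#' (the descending/ascending split): raising R diverts more flow through the
#' distributed sink, so the ratio decreases monotonically in R. The
#' compliance is closed by a fixed time constant, `R C = cycle_fraction *
#' period` (C is not identifiable from a flow ratio alone).
#'
#' `two_outlet_split_fn` is a steady two-outlet toy: the tuned outlet of
#' resistance R in parallel with a fixed outlet `R_other` receives the flow
#' fraction `(1/R) / (1/R + 1/R_other)`.
#'
#' @param model a `tube_model_1d` with a configured `sink`.
#' @param inlet a `flow_waveform`.
#' @param cycle_fraction Windkessel time constant as a fraction of the cycle.
#' @param ... passed to [simulate_pulsewave()].
#' @return function mapping R (Pa s m^-3) to the achieved flow ratio; for
#'   `windkessel_ratio_fn` the returned function carries the last simulation
#'   in attribute `"sim"`.
#' @export
windkessel_ratio_fn <- function(model, inlet, cycle_fraction = 1 / 3, ...) {
  period_s <- inlet$period / 1000
  function(R) {
    wk <- windkessel_params(R, cycle_fraction * period_s / R)
    sim <- simulate_pulsewave(model, inlet, wk, ...)
    structure(sim$qmean_out / sim$qmean_in, sim = sim)
  }
}

#' @rdname windkessel_ratio_fn
#' @param R_other fixed resistance of the other outlet (Pa s m^-3).
#' @export
two_outlet_split_fn <- function(R_other) {
  function(R) (1 / R) / (1 / R + 1 / R_other)
}

#' Tune Windkessel resistance to a target flow split
#'
#' Replaces manual trial-and-error tuning with secant iteration on log R:
#' the outlet resistance is adjusted until the achieved flow ratio is within
#' the target's tolerance (default +/- 5%) of the prescribed ratio.
#'
#' @param target a `flow_split_target` (or a plain ratio in (0, 1]).
#' @param ratio_fn function R -> achieved ratio, e.g. from
#'   [windkessel_ratio_fn()].
#' @param R_init initial resistance guess (Pa s m^-3).
#' @param max_iter maximum ratio evaluations (default 30).
#' @param cycle_fraction time constant fraction used to report the final
#'   compliance.
#' @param period_s cycle length (s) used for the final compliance.
#' @return list with `params` (a `windkessel_params`), `achieved_ratio`,
#'   `converged`, and the iteration `trace` data frame.
#' @export
calibrate_windkessel <- function(target, ratio_fn, R_init = 1.5e8,
                                 max_iter = 30L, cycle_fraction = 1 / 3,
                                 period_s = 1) {
  if (!inherits(target, "flow_split_target")) target <- flow_split_target(target)
  tol <- target$tolerance
  goal <- target$true_ratio
  trace <- data.frame(R = numeric(0), ratio = numeric(0))
  eval_r <- function(R) {
    r <- as.numeric(ratio_fn(R))
    trace <<- rbind(trace, data.frame(R = R, ratio = r))
    r
  }
  x0 <- log(R_init)
  f0 <- eval_r(exp(x0)) - goal
  converged <- abs(f0 / goal) <= tol
  if (!converged) {
    # second point: step in the direction that should reduce the error
    # (ratio decreases with R for the branch-sink model)
    x1 <- x0 + if (f0 > 0) log(2) else -log(2)
    f1 <- eval_r(exp(x1)) - goal
    converged <- abs(f1 / goal) <= tol
    while (!converged && nrow(trace) < max_iter) {
      if (abs(f1 - f0) < 1e-14) {
        x2 <- x1 + if (f1 > 0) log(2) else -log(2)  # flat: keep stepping
      } else {
        x2 <- x1 - f1 * (x1 - x0) / (f1 - f0)
        x2 <- max(min(x2, x1 + log(10)), x1 - log(10))
      }
      f2 <- eval_r(exp(x2)) - goal
      x0 <- x1; f0 <- f1; x1 <- x2; f1 <- f2
      converged <- abs(f1 / goal) <= tol
    }
  }
  best <- which.min(abs(trace$ratio - goal))
  R_best <- trace$R[best]
  list(params = windkessel_params(R_best, cycle_fraction * period_s / R_best),
       achieved_ratio = trace$ratio[best], converged = converged,
       trace = trace)
}
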