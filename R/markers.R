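# Haemodynamic marker extraction: flow rate, peak systole, flow
# displacement, jet angle, maximum velocity, wall shear stress decomposition
# and the shear stress ratio (SSR).

#' In-plane sample grid of a section plane
#'
#' Uniform grid of points on the plane covering the lumen disc.
#'
#' @param plane a `section_plane`.
#' @param spacing sample spacing (mm).
#' @param margin extra radius beyond the lumen (mm).
#' @return list with `points` (n x 3, mm), in-plane offsets `a`, `b`, and
#'   the cell area `dA` (mm^2).
#' @keywords internal
plane_samples <- function(plane, spacing, margin = 0) {
  r <- plane$lumen_radius + margin
  g <- seq(-r, r, by = spacing)
  ab <- expand.grid(a = g, b = g)
  keep <- ab$a^2 + ab$b^2 <= r^2
  ab <- ab[keep, ]
  pts <- matrix(plane$origin, nrow(ab), 3L, byrow = TRUE) +
    outer(ab$a, plane$axes[1L, ]) + outer(ab$b, plane$axes[2L, ])
  list(points = pts, a = ab$a, b = ab$b, dA = spacing^2)
}

#' Volumetric flow rate through a section plane
#'
#' `Q(t) = sum (v . tangent) dA` over in-plane lumen samples of the velocity
#' field (midpoint quadrature on a uniform in-plane grid, which for a
#' periodic-in-angle integrand is equivalent to the trapezoidal rule).
#'
#' @param field a `velocity_field`.
#' @param plane a `section_plane`.
#' @param spacing in-plane sample spacing (mm); default half the smallest
#'   voxel edge.
#' @return a `flow_waveform` (mL s^-1) sampled at the field's frame times.
#' @export
flow_rate <- function(field, plane, spacing = NULL) {
  if (is.null(spacing)) spacing <- min(field$spacing) / 2
  ps <- plane_samples(plane, spacing)
  nt <- length(field$times)
  q <- numeric(nt)
  any_in <- FALSE
  for (k in seq_len(nt)) {
    v <- interp_frame(field, ps$points, k)
    any_in <- any_in || any(attr(v, "in_grid"))
    q[k] <- sum(v %*% plane$tangent) * ps$dA   # m/s * mm^2 = mL/s
  }
  if (!any_in) stop("section plane lies outside the field grid")
  if (nt == 1L)
    return(flow_waveform(c(field$times, field$times + 1), c(q, q), name = "plane"))
  flow_waveform(field$times, q, name = "plane")
}

#' Time of peak systole
#'
#' Argmax of the flow waveform with parabolic sub-sample refinement. A flat
#' waveform returns its first sample flagged with attribute `flat = TRUE`.
#'
#' @param Q a `flow_waveform` covering one cycle.
#' @return peak time (ms) with attribute `flat`.
#' @export
peak_systole <- function(Q) {
  res <- peak_time_parabolic(Q$time, Q$flow, Q$period)
  if (isTRUE(attr(res, "flat")))
    warning("flat waveform: peak systole undefined, returning first frame")
  res
}

# locate the forward-flow maximum-velocity sample in a plane
forward_peak <- function(field, plane, t, spacing = NULL) {
  if (is.null(spacing)) spacing <- min(field$spacing) / 4
  ps <- plane_samples(plane, spacing)
  v <- interp_velocity(field, ps$points, t)
  ax <- as.numeric(v %*% plane$tangent)
  fwd <- ax > 0
  if (!any(fwd)) stop("no forward flow in plane at t = ", t, " ms")
  speed <- sqrt(rowSums(v^2))
  speed[!fwd] <- -Inf
  i <- which.max(speed)
  list(a = ps$a[i], b = ps$b[i], point = ps$points[i, ], v = v[i, ],
       speed = speed[i])
}

#' Flow displacement at peak systole
#'
#' In-plane distance (mm) between the centerline and the location of the
#' maximum velocity of the forward flow (`v . tangent > 0`). With
#' `reference = "centroid"` the distance is measured from the in-plane lumen
#' centroid instead of the centerline point.
#'
#' @param field a `velocity_field`.
#' @param plane a `section_plane` (its origin is the centerline point).
#' @param t_peak evaluation time (ms), normally from [peak_systole()].
#' @param reference `"centerline"` (default) or `"centroid"`.
#' @param spacing search-grid spacing (mm); default a quarter voxel.
#' @return displacement (mm).
#' @export
flow_displacement <- function(field, plane, t_peak,
                              reference = c("centerline", "centroid"),
                              spacing = NULL) {
  reference <- match.arg(reference)
  pk <- forward_peak(field, plane, t_peak, spacing)
  if (reference == "centerline") return(sqrt(pk$a^2 + pk$b^2))
  # lumen centroid from the field mask sampled in-plane
  ps <- plane_samples(plane, min(field$spacing) / 2)
  v <- interp_velocity(field, ps$points, t_peak)
  inl <- rowSums(v^2) > 0
  if (!any(inl)) stop("no lumen samples in plane")
  sqrt((pk$a - mean(ps$a[inl]))^2 + (pk$b - mean(ps$b[inl]))^2)
}

#' Jet angle at peak systole
#'
#' Angle (degrees) between the centerline tangent and the velocity vector at
#' the forward-flow maximum: `acos(|v . tangent| / |v|)`, in `[0, 90]`.
#'
#' @inheritParams flow_displacement
#' @return angle (degrees).
#' @export
jet_angle <- function(field, plane, t_peak, spacing = NULL) {
  pk <- forward_peak(field, plane, t_peak, spacing)
  nv <- sqrt(sum(pk$v^2))
  if (nv < 1e-12) stop("zero velocity vector at forward-flow maximum")
  acos(min(abs(sum(pk$v * plane$tangent)) / nv, 1)) * 180 / pi
}

#' Maximum forward velocity at peak systole
#'
#' @inheritParams flow_displacement
#' @return maximum speed among forward-flow samples (m s^-1).
#' @export
max_velocity <- function(field, plane, t_peak, spacing = NULL) {
  forward_peak(field, plane, t_peak, spacing)$speed
}

#' Wall shear stress decomposition on the vessel surface
#'
#' Image-based WSS estimator: at every surface vertex the wall-tangential
#' velocity is sampled along the inward normal at depths `delta, 2 delta,
#' 3 delta`, and the wall velocity gradient is estimated by least squares
#' anchored at zero wall velocity (no slip). The default `fit = "quadratic"`
#' solves for a linear + quadratic depth dependence and reports the linear
#' (wall) slope, which is exact for parabolic near-wall profiles; `fit =
#' "linear"` is the plain anchored straight-line slope, which carries an
#' O(delta/R) bias on curved profiles. The WSS vector `mu * dv_t/dn` is
#' projected onto the axial direction (centerline tangent projected into the
#' local tangent plane; positive downstream) and the circumferential
#' direction (`normal x axial`; positive counter-clockwise viewed
#' downstream).
#'
#' @param field a `velocity_field`.
#' @param geometry a `vessel_geometry`.
#' @param mu dynamic viscosity (Pa s), default 0.035.
#' @param frames frame indices to process (default all).
#' @param delta sample depth unit (mm); default one (smallest) voxel.
#' @param fit `"quadratic"` (default) or `"linear"`.
#' @return object of class `wall_shear_field`: matrices `wss_axial`,
#'   `wss_circ` (Pa, vertices x frames), `valid`, frame `times`, and the
#'   sampling metadata. SSR is added by [ssr()].
#' @export
wall_shear <- function(field, geometry, mu = 0.035, frames = NULL,
                       delta = NULL, fit = c("quadratic", "linear")) {
  fit <- match.arg(fit)
  if (is.null(frames)) frames <- seq_along(field$times)
  if (is.null(delta)) delta <- min(field$spacing)
  depths <- delta * (1:3)
  vtx <- geometry$surface$vertices
  nrm <- geometry$surface$normals
  V <- nrow(vtx)

  # axial/circumferential unit directions in each vertex's tangent plane
  Tm <- geometry$frames$tangent[geometry$surface$station, , drop = FALSE]
  adir <- Tm - rowSums(Tm * nrm) * nrm
  adir <- adir / sqrt(rowSums(adir^2))
  cdir <- cbind(nrm[, 2L] * adir[, 3L] - nrm[, 3L] * adir[, 2L],
                nrm[, 3L] * adir[, 1L] - nrm[, 1L] * adir[, 3L],
                nrm[, 1L] * adir[, 2L] - nrm[, 2L] * adir[, 1L])

  nt <- length(frames)
  wss_ax <- matrix(NA_real_, V, nt)
  wss_ci <- matrix(NA_real_, V, nt)
  valid <- matrix(FALSE, V, nt)

  d <- depths
  if (fit == "quadratic") {
    # anchored LS for v = a d + b d^2: normal equations in (a, b)
    M <- matrix(c(sum(d^2), sum(d^3), sum(d^3), sum(d^4)), 2L)
    Minv <- solve(M)
  } else {
    sdd <- sum(d^2)
  }

  for (j in seq_len(nt)) {
    fr <- frames[j]
    va <- matrix(0, V, 3L)  # axial-projected velocity at the 3 depths
    vc <- matrix(0, V, 3L)
    ok <- rep(TRUE, V)
    for (q in 1:3) {
      pts <- vtx - d[q] * nrm
      v <- interp_frame(field, pts, fr)
      ok <- ok & attr(v, "in_grid")
      vt <- v - rowSums(v * nrm) * nrm
      va[, q] <- rowSums(vt * adir)
      vc[, q] <- rowSums(vt * cdir)
    }
    if (fit == "quadratic") {
      sa1 <- va %*% d; sa2 <- va %*% d^2
      sc1 <- vc %*% d; sc2 <- vc %*% d^2
      slope_a <- Minv[1L, 1L] * sa1 + Minv[1L, 2L] * sa2
      slope_c <- Minv[1L, 1L] * sc1 + Minv[1L, 2L] * sc2
    } else {
      slope_a <- (va %*% d) / sdd
      slope_c <- (vc %*% d) / sdd
    }
    # slope in (m/s)/mm -> 1000 / s; WSS in Pa
    wss_ax[, j] <- mu * as.numeric(slope_a) * 1000
    wss_ci[, j] <- mu * as.numeric(slope_c) * 1000
    valid[, j] <- ok & is.finite(wss_ax[, j]) & is.finite(wss_ci[, j])
    wss_ax[!ok, j] <- NA_real_
    wss_ci[!ok, j] <- NA_real_
  }
  structure(list(wss_axial = wss_ax, wss_circ = wss_ci, valid = valid,
                 times = field$times[frames], delta = delta, fit = fit,
                 mu = mu, n_vertices = V,
                 n_invalid = sum(!valid)),
            class = "wall_shear_field")
}

#' @export
print.wall_shear_field <- function(x, ...) {
  cat(sprintf("wall_shear_field: %d vertices x %d frame(s), delta = %.2f mm (%s fit)\n",
              x$n_vertices, length(x$times), x$delta, x$fit))
  cat(sprintf("  invalid vertex-frames: %d; axial WSS range %.2f to %.2f Pa\n",
              x$n_invalid, min(x$wss_axial, na.rm = TRUE),
              max(x$wss_axial, na.rm = TRUE)))
  if (!is.null(x$ssr))
    cat(sprintf("  SSR: median %.2f, flagged (|axial| < %g Pa): %d\n",
                stats::median(x$ssr, na.rm = TRUE), x$eps_floor,
                sum(x$flagged, na.rm = TRUE)))
  invisible(x)
}

#' Shear stress ratio (SSR)
#'
#' `SSR = |WSS_circ| / max(|WSS_axial|, eps_floor)`: the dimensionless ratio
#' of circumferential to axial wall shear stress, quantifying how much the
#' near-wall flow rotates in-plane relative to how much it progresses along
#' the vessel. The ratio is undefined where the axial shear vanishes (e.g.
#' at flow reversal), so vertices with `|WSS_axial| < eps_floor` are flagged
#' and excluded from regional statistics. Magnitudes are used, making SSR
#' invariant to the axial sign convention and to uniform velocity scaling.
#'
#' @param wss a `wall_shear_field`.
#' @param eps_floor axial-shear floor (Pa), default 1e-3.
#' @param signed if TRUE, keep the sign of `WSS_circ / WSS_axial`.
#' @return the `wall_shear_field` with `ssr` and `flagged` matrices added.
#' @export
ssr <- function(wss, eps_floor = 1e-3, signed = FALSE) {
  den <- pmax(abs(wss$wss_axial), eps_floor)
  val <- if (signed) {
    sgn <- ifelse(wss$wss_axial < 0, -1, 1)
    wss$wss_circ / (sgn * den)
  } else {
    abs(wss$wss_circ) / den
  }
  wss$ssr <- val
  wss$flagged <- abs(wss$wss_axial) < eps_floor
  wss$eps_floor <- eps_floor
  wss
}

#' Percentage error between simulated and reference marker values
#'
#' `"relative"`: `|sim - ref| / |ref| * 100` (%); `"absolute"`: `|sim -
#' ref|` in the marker's own units (used for jet angles, whose errors are
#' reported in degrees).
#'
#' @param sim simulated value(s).
#' @param ref reference value(s); nonzero in relative mode.
#' @param mode `"relative"` or `"absolute"`.
#' @return error value(s).
#' @export
percentage_error <- function(sim, ref, mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  if (mode == "relative") {
    if (any(ref == 0)) stop("reference value is zero: relative error undefined")
    abs(sim - ref) / abs(ref) * 100
  } else {
    abs(sim - ref)
  }
}

#' Check invariance of markers under uniform velocity scaling
#'
#' Multiplying every velocity by `c > 0` must leave flow displacement, jet
#' angle and SSR unchanged while scaling the maximum velocity and both WSS
#' components by `c` exactly (the shear estimator is linear in the data).
#'
#' @param field a `velocity_field`.
#' @param geometry a `vessel_geometry`.
#' @param plane a `section_plane`.
#' @param t_peak evaluation time (ms).
#' @param c_scale positive scale factor.
#' @return data frame with the original value, scaled value and the absolute
#'   deviation from the expected behaviour for each marker.
#' @export
scale_invariance_check <- function(field, geometry, plane, t_peak,
                                   c_scale = 2) {
  if (c_scale <= 0) stop("c_scale must be positive")
  scaled <- field
  scaled$v <- field$v * c_scale
  m1 <- c(displacement = flow_displacement(field, plane, t_peak),
          angle = jet_angle(field, plane, t_peak),
          vmax = max_velocity(field, plane, t_peak))
  m2 <- c(displacement = flow_displacement(scaled, plane, t_peak),
          angle = jet_angle(scaled, plane, t_peak),
          vmax = max_velocity(scaled, plane, t_peak))
  w1 <- ssr(wall_shear(field, geometry, frames = 1L))
  w2 <- ssr(wall_shear(scaled, geometry, frames = 1L))
  ok <- w1$valid[, 1L] & !w1$flagged[, 1L] & w2$valid[, 1L] & !w2$flagged[, 1L]
  data.frame(
    marker = c("flow_displacement", "jet_angle", "max_velocity",
               "ssr_max_dev", "wss_axial_scale_dev"),
    original = c(m1, NA, NA),
    scaled = c(m2, NA, NA),
    deviation = c(abs(m2["displacement"] - m1["displacement"]),
                  abs(m2["angle"] - m1["angle"]),
                  abs(m2["vmax"] - c_scale * m1["vmax"]),
                  max(abs(w2$ssr[ok, 1L] - w1$ssr[ok, 1L])),
                  max(abs(w2$wss_axial[ok, 1L] -
                            c_scale * w1$wss_axial[ok, 1L])))
  )
}
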