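# Synthetic 4D-flow-like velocity fields: analytic pulsatile tube flow with
# eccentric/tilted systolic jets and helical secondary flow, voxel-grid
# sampling, and phase-contrast-MRI-like degradation.

#' Time-resolved 3D velocity field on a regular voxel grid
#'
#' Voxel centres sit at `origin + (i - 1/2) * spacing` along each axis
#' (mm); velocities are in m s^-1 and are exactly zero outside the lumen
#' mask.
#'
#' @param origin grid corner (mm), length 3.
#' @param spacing voxel edge lengths (mm), length 3 (scalar recycled).
#' @param times frame times (ms), strictly increasing.
#' @param v 5-D array `[nx, ny, nz, 3, nt]` of velocity components (m s^-1).
#' @param mask logical 3-D array `[nx, ny, nz]`, TRUE inside the lumen.
#' @return object of class `velocity_field`.
#' @export
velocity_field <- function(origin, spacing, times, v, mask) {
  spacing <- rep_len(spacing, 3L)
  if (any(spacing <= 0)) stop("grid spacing must be positive")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  dv <- dim(v)
  if (length(dv) != 5L || dv[4L] != 3L || dv[5L] != length(times))
    stop("v must be an [nx, ny, nz, 3, nt] array matching times")
  if (!identical(dim(mask), dv[1:3])) stop("mask dimensions must match v")
  if (any(!is.finite(v))) stop("velocities must be finite")
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = dv[1:3], times = as.numeric(times), v = v,
                 mask = mask),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("velocity_field: %d x %d x %d voxels at %.2f x %.2f x %.2f mm, %d frame(s)\n",
              x$dims[1L], x$dims[2L], x$dims[3L],
              x$spacing[1L], x$spacing[2L], x$spacing[3L], length(x$times)))
  cat(sprintf("  lumen voxels: %d (%.1f%%), max |component| %.2f m/s\n",
              sum(x$mask), 100 * mean(x$mask), max(abs(x$v))))
  invisible(x)
}

#' Voxel centre coordinates of a velocity field
#' @param field a `velocity_field`.
#' @return n x 3 matrix (mm), x fastest.
#' @keywords internal
voxel_centers <- function(field) {
  d <- field$dims
  gx <- field$origin[1L] + (seq_len(d[1L]) - 0.5) * field$spacing[1L]
  gy <- field$origin[2L] + (seq_len(d[2L]) - 0.5) * field$spacing[2L]
  gz <- field$origin[3L] + (seq_len(d[3L]) - 0.5) * field$spacing[3L]
  cbind(rep(gx, times = d[2L] * d[3L]),
        rep(rep(gy, each = d[1L]), times = d[3L]),
        rep(gz, each = d[1L] * d[2L]))
}

# ---- projection onto tube coordinates ---------------------------------------

#' Project points into tube coordinates
#'
#' Nearest-station projection into the local rotation-minimizing frame:
#' arc length, in-plane coordinates, radial distance and lumen membership.
#'
#' @param geometry a `vessel_geometry`.
#' @param points n x 3 matrix (mm).
#' @return list with `station`, `s`, `x1`, `x2`, `rho`, `r_local`, `inside`.
#' @export
project_to_tube <- function(geometry, points) {
  points <- if (is.matrix(points)) points else matrix(points, ncol = 3L)
  project_to_tube_cpp(points, geometry$centerline, geometry$frames$tangent,
                      geometry$frames$normal, geometry$frames$binormal,
                      geometry$arclength, geometry$radius)
}

# ---- Womersley machinery -----------------------------------------------------

# complex Bessel J0/J1 by ascending series; adequate for |z| up to ~30
besselJ0c <- function(z) {
  term <- rep(1 + 0i, length(z))
  tot <- term
  z24 <- -z * z / 4
  for (k in 1:80) {
    term <- term * z24 / (k * k)
    tot <- tot + term
    if (all(Mod(term) < 1e-18 * pmax(Mod(tot), 1))) break
  }
  tot
}

besselJ1c <- function(z) {
  term <- z / 2
  tot <- term
  z24 <- -z * z / 4
  for (k in 1:80) {
    term <- term * z24 / (k * (k + 1))
    tot <- tot + term
    if (all(Mod(term) < 1e-18 * pmax(Mod(tot), 1))) break
  }
  tot
}

#' Flow-normalized Womersley velocity profile factor
#'
#' Complex profile `phi(y)` of an oscillatory harmonic in a rigid tube such
#' that the cross-section average of `phi` is 1: a harmonic with complex
#' flow amplitude `q` contributes `Re(q / (pi R^2) * phi(y) * exp(i w t))`
#' to the axial velocity.
#'
#' @param y radial position ratio rho/R in `[0, 1]`.
#' @param alpha Womersley number `R * sqrt(w / nu)` (dimensionless, SI).
#' @return complex vector of profile values.
#' @export
womersley_profile <- function(y, alpha) {
  lam <- alpha * complex(real = -sqrt(2) / 2, imaginary = sqrt(2) / 2)
  j0l <- besselJ0c(lam)
  denom <- 1 - 2 * besselJ1c(lam) / (lam * j0l)
  (1 - besselJ0c(lam * y) / j0l) / denom
}

# one-sided Fourier coefficients of the closed-form waveform (mL/s)
waveform_harmonic_coefs <- function(params, period, n_harm, n_dense = 1024L) {
  tt <- seq(0, period, length.out = n_dense + 1L)[seq_len(n_dense)]
  q <- systolic_q_fun(params, period)(tt)
  cf <- stats::fft(q) / n_dense
  list(q0 = Re(cf[1L]), a = 2 * cf[seq_len(n_harm) + 1L],
       omega = 2 * pi * seq_len(n_harm) / (period / 1000))   # rad/s
}

# smooth 0->1->0 arc-length window with raised-cosine ramps
helical_window_fun <- function(window, ramp = 0.08) {
  if (is.null(window)) return(function(frac) rep(1, length(frac)))
  lo <- window[1L]; hi <- window[2L]
  function(frac) {
    w <- numeric(length(frac))
    up <- frac >= lo & frac < lo + ramp
    w[up] <- 0.5 - 0.5 * cos(pi * (frac[up] - lo) / ramp)
    w[frac >= lo + ramp & frac <= hi - ramp] <- 1
    dn <- frac > hi - ramp & frac <= hi
    w[dn] <- 0.5 - 0.5 * cos(pi * (hi - frac[dn]) / ramp)
    w
  }
}

# ---- analytic velocity -------------------------------------------------------

velocity_from_projection <- function(geometry, flow, proj, t, period = 1000) {
  m <- length(proj$s)
  out <- matrix(0, m, 3L)
  ins <- which(proj$inside)
  if (length(ins) == 0L) return(out)

  st <- proj$station[ins]
  Tm <- geometry$frames$tangent[st, , drop = FALSE]
  Nm <- geometry$frames$normal[st, , drop = FALSE]
  Bm <- geometry$frames$binormal[st, , drop = FALSE]

  az <- flow$jet_azimuth * pi / 180
  d1 <- flow$jet_offset * cos(az)
  d2 <- flow$jet_offset * sin(az)
  Rj <- proj$r_local[ins] - flow$jet_offset          # mm
  if (any(Rj <= 0)) stop("jet_offset must be smaller than the lumen radius")
  dx1 <- proj$x1[ins] - d1
  dx2 <- proj$x2[ins] - d2
  rhoj <- sqrt(dx1^2 + dx2^2)                        # mm
  y <- pmin(rhoj / Rj, 1)

  # axial speed profile, m/s (mL/s over mm^2)
  nh <- flow$womersley_harmonics
  if (nh > 0L) {
    hc <- waveform_harmonic_coefs(flow, period, nh)
    S_ax <- hc$q0 * 2 / (pi * Rj^2) * (1 - y^2)
    nu <- flow$viscosity / flow$density              # m^2/s
    for (n in seq_len(nh)) {
      alpha <- (Rj / 1000) * sqrt(hc$omega[n] / nu)
      phi <- womersley_profile(y, alpha)
      S_ax <- S_ax + Re(hc$a[n] / (pi * Rj^2) * phi *
                          exp(1i * hc$omega[n] * (t / 1000)))
    }
  } else {
    qt <- systolic_q_fun(flow, period)(t)
    S_ax <- qt * 2 / (pi * Rj^2) * (1 - y^2)
  }
  S_ax <- S_ax * (rhoj < Rj)                         # zero outside jet support

  th <- flow$jet_angle * pi / 180
  S <- S_ax / cos(th)
  wdir1 <- cos(az); wdir2 <- sin(az)                 # tilt direction in-plane
  udir <- cos(th) * Tm + sin(th) * (wdir1 * Nm + wdir2 * Bm)

  # helical secondary flow about the jet core, no-slip at the jet boundary
  k <- flow$helical_strength
  if (k != 0) {
    L <- max(geometry$arclength)
    wfun <- helical_window_fun(flow$helical_window)
    keff <- k * wfun(pmin(pmax(proj$s[ins] / L, 0), 1))
    rho_m <- rhoj / 1000
    Rj_m <- Rj / 1000
    wmag <- keff * rho_m * pmax(Rj_m - rho_m, 0)     # m/s
    esw1 <- ifelse(rhoj > 1e-12, -dx2 / rhoj, 0)
    esw2 <- ifelse(rhoj > 1e-12, dx1 / rhoj, 0)
    swirl <- wmag * (esw1 * Nm + esw2 * Bm)
  } else {
    swirl <- 0
  }
  out[ins, ] <- S * udir + swirl
  out
}

#' Analytic velocity of the synthetic pulsatile jet flow
#'
#' Evaluates the generator's closed-form velocity at arbitrary points: a
#' quasi-steady parabolic (optionally Womersley-harmonic) axial jet of
#' effective radius `R - jet_offset`, recentred at the jet offset and tilted
#' by the jet angle, plus a helical secondary flow about the jet core with
#' azimuthal speed `k * rho * (R_jet - rho)` (SI), which vanishes at the jet
#' core and at the wall. Points outside the lumen get a zero vector.
#'
#' Ground-truth markers are available in closed form: the maximum forward
#' speed sits at the jet core (offset `jet_offset` from the centerline, angle
#' `jet_angle` to it) and equals `2 Q(t) / (pi R_jet^2 cos(jet_angle))`.
#'
#' @param geometry a `vessel_geometry`.
#' @param flow a `flow_params`.
#' @param points n x 3 matrix of positions (mm).
#' @param t time (ms).
#' @param period cycle length (ms).
#' @return n x 3 matrix of velocities (m s^-1).
#' @export
analytic_velocity <- function(geometry, flow, points, t, period = 1000) {
  points <- if (is.matrix(points)) points else matrix(points, ncol = 3L)
  proj <- project_to_tube(geometry, points)
  velocity_from_projection(geometry, flow, proj, t, period)
}

#' Sample the analytic flow onto a voxel grid
#'
#' @param geometry a `vessel_geometry`.
#' @param flow a `flow_params`.
#' @param spacing voxel size (mm), scalar or length 3.
#' @param frame_times frame times (ms).
#' @param period cycle length (ms).
#' @param padding margin added around the surface bounding box (mm).
#' @param origin,dims optional explicit grid; default fits the geometry.
#' @return a `velocity_field` whose lumen mask marks voxel centres inside the
#'   tube.
#' @export
sample_field <- function(geometry, flow, spacing = 0.8,
                         frame_times = seq(0, 990, by = 10), period = 1000,
                         padding = NULL, origin = NULL, dims = NULL) {
  spacing <- rep_len(spacing, 3L)
  if (any(spacing <= 0)) stop("grid spacing must be positive")
  if (is.null(padding)) padding <- 2 * max(spacing)
  vtx <- geometry$surface$vertices
  if (is.null(origin)) origin <- apply(vtx, 2L, min) - padding
  if (is.null(dims))
    dims <- as.integer(ceiling((apply(vtx, 2L, max) + padding - origin) / spacing))
  nt <- length(frame_times)
  v <- array(0, dim = c(dims, 3L, nt))
  mask_field <- velocity_field(origin, spacing, times = c(0),
                               v = array(0, dim = c(dims, 3L, 1L)),
                               mask = array(TRUE, dim = dims))
  pts <- voxel_centers(mask_field)
  proj <- project_to_tube(geometry, pts)
  mask <- array(proj$inside, dim = dims)
  for (k in seq_len(nt)) {
    vk <- velocity_from_projection(geometry, flow, proj, frame_times[k], period)
    v[, , , , k] <- array(vk, dim = c(dims, 3L))
  }
  velocity_field(origin, spacing, frame_times, v, mask)
}

# ---- interpolation -----------------------------------------------------------

# trilinear interpolation of one frame index; returns m x 3 matrix plus
# attribute "in_grid"
interp_frame <- function(field, points, frame) {
  d <- field$dims
  m <- nrow(points)
  u <- sweep(sweep(points, 2L, field$origin), 2L, field$spacing, "/") + 0.5
  in_grid <- u[, 1L] >= 0.5 & u[, 1L] <= d[1L] + 0.5 &
    u[, 2L] >= 0.5 & u[, 2L] <= d[2L] + 0.5 &
    u[, 3L] >= 0.5 & u[, 3L] <= d[3L] + 0.5
  i0 <- pmin(pmax(floor(u[, 1L]), 1L), d[1L] - 1L)
  j0 <- pmin(pmax(floor(u[, 2L]), 1L), d[2L] - 1L)
  k0 <- pmin(pmax(floor(u[, 3L]), 1L), d[3L] - 1L)
  wx <- pmin(pmax(u[, 1L] - i0, 0), 1)
  wy <- pmin(pmax(u[, 2L] - j0, 0), 1)
  wz <- pmin(pmax(u[, 3L] - k0, 0), 1)
  nxy <- d[1L] * d[2L]
  base_frame <- (frame - 1L) * d[1L] * d[2L] * d[3L] * 3L
  out <- matrix(0, m, 3L)
  for (comp in 1:3) {
    base <- base_frame + (comp - 1L) * d[1L] * d[2L] * d[3L]
    acc <- numeric(m)
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      idx <- base + (i0 + dx) + d[1L] * (j0 + dy - 1L) + nxy * (k0 + dz - 1L)
      w <- (if (dx == 1) wx else 1 - wx) *
        (if (dy == 1) wy else 1 - wy) *
        (if (dz == 1) wz else 1 - wz)
      acc <- acc + w * field$v[idx]
    }
    out[, comp] <- acc
  }
  out[!in_grid, ] <- 0
  attr(out, "in_grid") <- in_grid
  out
}

#' Interpolate field velocities at arbitrary points and time
#'
#' Trilinear in space, linear between the two bracketing frames in time.
#' Points outside the grid return zero (flagged in the `"in_grid"`
#' attribute).
#'
#' @param field a `velocity_field`.
#' @param points n x 3 matrix (mm).
#' @param t time (ms), within the field's frame range.
#' @return n x 3 velocity matrix (m s^-1) with attribute `in_grid`.
#' @export
interp_velocity <- function(field, points, t) {
  points <- if (is.matrix(points)) points else matrix(points, ncol = 3L)
  tms <- field$times
  if (t < tms[1L] - 1e-6 || t > tms[length(tms)] + 1e-6)
    stop(sprintf("t = %g ms outside field frame range [%g, %g]",
                 t, tms[1L], tms[length(tms)]))
  if (length(tms) == 1L) return(interp_frame(field, points, 1L))
  k <- findInterval(t, tms, rightmost.closed = TRUE)
  k <- min(max(k, 1L), length(tms) - 1L)
  if (abs(t - tms[k]) < 1e-9) return(interp_frame(field, points, k))
  w <- (t - tms[k]) / (tms[k + 1L] - tms[k])
  if (w < 1e-12) return(interp_frame(field, points, k))
  if (w > 1 - 1e-12) return(interp_frame(field, points, k + 1L))
  a <- interp_frame(field, points, k)
  b <- interp_frame(field, points, k + 1L)
  out <- (1 - w) * a + w * b
  attr(out, "in_grid") <- attr(a, "in_grid") & attr(b, "in_grid")
  out
}

# ---- MRI-like degradation ----------------------------------------------------

#' Degrade a fine velocity field to phase-contrast-MRI-like resolution
#'
#' Box-averages the field down to a coarser voxel size and frame interval,
#' then adds independent Gaussian velocity noise per component with the
#' standard phase-contrast propagation `sigma = venc * sqrt(2) / (pi * SNR)`.
#' Optionally wraps velocities beyond the velocity-encoding limit (aliasing).
#' The coarse lumen mask keeps voxels whose fine-mask fill fraction exceeds
#' one half; velocities outside the coarse mask are zero.
#'
#' @param field a fine-resolution `velocity_field`.
#' @param voxel target isotropic voxel size (mm), default 2.5.
#' @param dt target frame interval (ms), default 25.
#' @param venc velocity encoding (cm s^-1), default 200; sets the noise scale
#'   and the aliasing threshold.
#' @param snr signal-to-noise ratio; `Inf` disables noise.
#' @param seed optional integer seed for the noise (restores the caller's RNG
#'   state afterwards).
#' @param wrap if TRUE, velocities beyond `+/- venc` alias back into range.
#' @return a coarser `velocity_field`.
#' @export
degrade_to_mri <- function(field, voxel = 2.5, dt = 25, venc = 200, snr = 20,
                           seed = NULL, wrap = FALSE) {
  if (venc <= 0) stop("venc must be positive")
  if (any(voxel < field$spacing - 1e-9))
    stop("target voxel must be coarser than the source spacing")
  nt <- length(field$times)
  if (nt > 1L) {
    dt_src <- field$times[2L] - field$times[1L]
    if (dt < dt_src - 1e-9)
      stop("target frame interval must be coarser than the source")
  }

  d <- field$dims
  # spatial bin index per fine voxel along each axis
  nb <- pmax(1L, as.integer(floor(d * field$spacing / voxel)))
  bin1 <- pmin(((seq_len(d[1L]) - 0.5) * field$spacing[1L]) %/% voxel + 1L, nb[1L])
  bin2 <- pmin(((seq_len(d[2L]) - 0.5) * field$spacing[2L]) %/% voxel + 1L, nb[2L])
  bin3 <- pmin(((seq_len(d[3L]) - 0.5) * field$spacing[3L]) %/% voxel + 1L, nb[3L])
  lin <- as.integer(bin1[rep(seq_len(d[1L]), times = d[2L] * d[3L])]) +
    nb[1L] * (as.integer(bin2[rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L])]) - 1L) +
    nb[1L] * nb[2L] * (as.integer(bin3[rep(seq_len(d[3L]), each = d[1L] * d[2L])]) - 1L)
  nbin <- prod(nb)
  counts <- tabulate(lin, nbins = nbin)

  # temporal bins
  if (nt > 1L) {
    tb <- pmax(1L, as.integer((field$times - field$times[1L]) %/% dt + 1L))
    ntb <- max(tb)
  } else {
    tb <- 1L
    ntb <- 1L
  }
  t_out <- as.numeric(tapply(field$times, tb, mean))

  vsz <- prod(d)
  ugrp <- sort(unique(lin))
  bin_sum <- function(vals) {
    dense <- numeric(nbin)
    dense[ugrp] <- as.numeric(rowsum(vals, lin, reorder = TRUE))
    dense
  }
  vout <- array(0, dim = c(nb, 3L, ntb))
  for (jt in seq_len(ntb)) {
    frames <- which(tb == jt)
    for (comp in 1:3) {
      acc <- numeric(nbin)
      for (fr in frames) {
        off <- ((fr - 1L) * 3L + (comp - 1L)) * vsz
        acc <- acc + bin_sum(field$v[off + seq_len(vsz)])
      }
      vout[, , , comp, jt] <- array(acc / pmax(counts, 1L) / length(frames),
                                    dim = nb)
    }
  }
  mask_out <- array(bin_sum(as.numeric(field$mask)) / pmax(counts, 1L) > 0.5,
                    dim = nb)

  venc_ms <- venc / 100                       # m/s
  if (is.finite(snr)) {
    if (!is.null(seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
      }
      set.seed(seed)
    }
    sigma <- venc_ms * sqrt(2) / (pi * snr)
    nin <- sum(mask_out)
    for (jt in seq_len(ntb)) for (comp in 1:3) {
      sl <- vout[, , , comp, jt]
      sl[mask_out] <- sl[mask_out] + stats::rnorm(nin, sd = sigma)
      vout[, , , comp, jt] <- sl
    }
  }
  if (wrap) {
    vout <- ((vout + venc_ms) %% (2 * venc_ms)) - venc_ms
  }
  # enforce zero outside the coarse mask
  for (jt in seq_len(ntb)) for (comp in 1:3) {
    sl <- vout[, , , comp, jt]
    sl[!mask_out] <- 0
    vout[, , , comp, jt] <- sl
  }
  velocity_field(field$origin, rep(voxel, 3L), t_out, vout, mask_out)
}
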