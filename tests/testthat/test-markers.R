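test_that("flow rate integrates uniform, reversed and Poiseuille fields", {
  g <- straight_tube(length = 24, r = 10, h = 1, n = 7L)
  pl <- local_frame(g, 12)

  # uniform axial 1 m/s in an r = 10 mm tube: Q = pi * 1e-4 m^3/s
  f <- sample_field(g, steady_flow(50), spacing = 0.5, frame_times = 0)
  fu <- f
  for (comp in 1:2) fu$v[, , , comp, 1L][fu$mask] <- 0
  fu$v[, , , 3L, 1L][fu$mask] <- 1
  q <- flow_rate(fu, pl)$flow[1L]
  expect_equal(q, pi * 100, tolerance = 0.02)   # mL/s = m/s * mm^2

  # linearity: reversed field negates exactly
  fr <- fu
  fr$v <- -fu$v
  expect_equal(flow_rate(fr, pl)$flow[1L], -q, tolerance = 1e-12)

  # Poiseuille with known Q0, 0.25 mm in-plane sampling: within 1%
  qpois <- flow_rate(f, pl, spacing = 0.25)$flow[1L]
  expect_equal(qpois, 50, tolerance = 0.01)

  far <- local_frame(g, 12)
  far$origin <- far$origin + c(500, 0, 0)
  expect_error(flow_rate(f, far), "outside")
})

test_that("peak systole timing refines a coarse argmax", {
  tt <- seq(0, 975, by = 25)
  w <- flow_waveform(tt, rep(3, length(tt)))
  expect_warning(tp <- peak_systole(w), "flat")
  expect_true(attr(tp, "flat"))
  expect_equal(as.numeric(tp), 0)

  t10 <- seq(0, 990, by = 10)
  tri <- flow_waveform(t10, pmax(0, 1 - abs(t10 - 120) / 100))
  expect_equal(as.numeric(peak_systole(tri)), 120, tolerance = 1e-9)

  # smooth peak at 133 ms sampled every 25 ms: within 5 ms of dense argmax
  smooth <- flow_waveform(tt, exp(-((tt - 133) / 90)^2))
  td <- seq(0, 999.9, by = 0.1)
  t_true <- td[which.max(exp(-((td - 133) / 90)^2))]
  expect_lt(abs(as.numeric(peak_systole(smooth)) - t_true), 5)
})

test_that("jet markers recover the generator ground truth on fine grids", {
  g <- straight_tube()
  fp <- flow_params(mean_flow = 83, jet_offset = 3, jet_angle = 15)
  tp <- 175
  f <- sample_field(g, fp, spacing = 0.8, frame_times = tp)
  pl <- local_frame(g, 20)

  expect_lt(abs(flow_displacement(f, pl, tp) - 3), 0.4)    # half a voxel
  expect_lt(abs(jet_angle(f, pl, tp) - 15), 1)
  truth_v <- 2 * systolic_q_fun(fp, 1000)(tp) /
    (pi * (12.5 - 3)^2 * cos(15 * pi / 180))
  expect_equal(max_velocity(f, pl, tp), truth_v, tolerance = 0.02)

  # axisymmetric parabolic profile: displacement 0, angle 0
  f0 <- sample_field(g, steady_flow(), spacing = 0.8, frame_times = 0)
  expect_lt(flow_displacement(f0, pl, 0), 0.2)
  expect_lt(jet_angle(f0, pl, 0), 0.5)
  expect_equal(max_velocity(f0, pl, 0), 2 * 100 / (pi * 12.5^2),
               tolerance = 0.02)

  # homogeneity: scaling velocities scales the maximum exactly
  f2 <- f
  f2$v <- f$v * 2
  expect_equal(max_velocity(f2, pl, tp), 2 * max_velocity(f, pl, tp),
               tolerance = 1e-12)

  # retrograde-only plane is an error
  fneg <- f
  fneg$v <- -f$v
  expect_error(flow_displacement(fneg, pl, tp), "no forward flow")
})

test_that("MRI-degraded fields bias markers one-sidedly and lose accuracy", {
  g <- straight_tube()
  fp <- flow_params(mean_flow = 83, jet_offset = 3, jet_angle = 15)
  tp <- 175
  f <- sample_field(g, fp, spacing = 0.8, frame_times = tp)
  pl <- local_frame(g, 20)
  vmax_fine <- max_velocity(f, pl, tp)
  disp_fine <- flow_displacement(f, pl, tp)

  # averaging alone (noise off) never overestimates the peak velocity
  d0 <- degrade_to_mri(f, snr = Inf)
  expect_lt(max_velocity(d0, pl, tp), vmax_fine)

  # seeded noisy sweep: displacement error within half a coarse voxel, and
  # degradation only removes information (mean errors >= fine-grid errors)
  errs_d <- errs_v <- numeric(10L)
  for (s in 1:10) {
    dm <- degrade_to_mri(f, snr = 20, seed = s)
    errs_d[s] <- abs(flow_displacement(dm, pl, tp) - 3)
    errs_v[s] <- abs(max_velocity(dm, pl, tp) - vmax_fine)
  }
  expect_lte(max(errs_d), 1.25)
  expect_gte(mean(errs_d), abs(disp_fine - 3))
  expect_gt(mean(errs_v), 0)
})

test_that("wall shear decomposition reproduces the Poiseuille and swirl closed forms", {
  g <- straight_tube(n = 9L)
  core <- core_stations(g)

  # Poiseuille: WSS_ax = 4 mu Q / (pi R^3), WSS_circ = 0
  f <- sample_field(g, steady_flow(Q = 100), spacing = 0.4, frame_times = 0)
  w <- ssr(wall_shear(f, g, frames = 1L))
  ok <- w$valid[, 1L] & core
  expect_gt(mean(ok), 0.4)
  wss_ax <- mean(w$wss_axial[ok, 1L])
  expect_equal(wss_ax, 4 * 0.035 * 1e-4 / (pi * 0.0125^3), tolerance = 0.05)
  expect_lt(mean(abs(w$wss_circ[ok, 1L])), 0.05 * wss_ax)
  expect_true(all(w$wss_axial[ok, 1L] > 0))   # positive = downstream

  # swirl u_theta = k rho (R - rho): WSS_circ = mu k R, and the combined
  # SSR matches k pi R^4 / (4 Q)
  k <- 5000
  f2 <- sample_field(g, steady_flow(Q = 100, helical_strength = k),
                     spacing = 0.4, frame_times = 0)
  w2 <- ssr(wall_shear(f2, g, frames = 1L))
  ok2 <- w2$valid[, 1L] & core
  expect_equal(mean(abs(w2$wss_circ[ok2, 1L])), 0.035 * k * 0.0125,
               tolerance = 0.05)
  ssr_true <- k * pi * 0.0125^4 / (4 * 1e-4)
  expect_equal(mean(w2$ssr[ok2, 1L]), ssr_true, tolerance = 0.05)

  # oracle errors shrink under refinement (3 levels)
  target <- 4 * 0.035 * 1e-4 / (pi * 0.0125^3)
  errs <- sapply(c(1.0, 0.6, 0.35), function(sp) {
    fs <- sample_field(g, steady_flow(Q = 100), spacing = sp, frame_times = 0)
    ws <- wall_shear(fs, g, frames = 1L)
    oks <- ws$valid[, 1L] & core
    abs(mean(ws$wss_axial[oks, 1L]) - target) / target
  })
  expect_true(all(diff(errs) < 0))
})

test_that("SSR definition, flooring and flagging behave as specified", {
  fake <- structure(list(
    wss_axial = matrix(c(2, 1, 1e-6, -2), 4L),
    wss_circ = matrix(c(0, 1, 0.5, 1), 4L),
    valid = matrix(TRUE, 4L), times = 0), class = "wall_shear_field")
  s <- ssr(fake)
  expect_equal(s$ssr[1L, 1L], 0)
  expect_equal(s$ssr[2L, 1L], 1)
  expect_equal(s$ssr[3L, 1L], 0.5 / 1e-3)      # floored denominator
  expect_true(s$flagged[3L, 1L])
  expect_false(any(s$flagged[c(1L, 2L, 4L), 1L]))
  expect_equal(s$ssr[4L, 1L], 0.5)             # magnitudes: sign-free
  ssg <- ssr(fake, signed = TRUE)
  expect_equal(ssg$ssr[4L, 1L], -0.5)
})

test_that("percentage errors follow the relative/absolute conventions", {
  expect_equal(percentage_error(10, 10), 0)
  expect_equal(percentage_error(8.5, 10), 15)
  expect_equal(percentage_error(16, 15, mode = "absolute"), 1)
  expect_error(percentage_error(1, 0), "zero")
  # error-reduction arithmetic used in cohort tables
  expect_equal((18.5 - 10.0) / 18.5 * 100, 45.9, tolerance = 0.01)
})

test_that("markers and SSR are invariant under uniform velocity scaling", {
  g <- straight_tube(n = 7L, length = 30)
  fp <- flow_params(mean_flow = 83, jet_offset = 2, helical_strength = 2000)
  f <- sample_field(g, fp, spacing = 0.8, frame_times = 175)
  pl <- local_frame(g, 15)
  chk <- scale_invariance_check(f, g, pl, 175, c_scale = 2)
  expect_equal(chk$deviation[chk$marker == "flow_displacement"], 0)
  expect_equal(chk$deviation[chk$marker == "jet_angle"], 0, tolerance = 1e-10)
  expect_equal(chk$deviation[chk$marker == "max_velocity"], 0,
               tolerance = 1e-12)
  expect_lt(chk$deviation[chk$marker == "ssr_max_dev"], 1e-12)
  expect_lt(chk$deviation[chk$marker == "wss_axial_scale_dev"], 1e-12)

  # c = 0.5 halves the shear exactly
  half <- f
  half$v <- f$v * 0.5
  w1 <- wall_shear(f, g, frames = 1L)
  w2 <- wall_shear(half, g, frames = 1L)
  ok <- w1$valid[, 1L]
  expect_equal(w2$wss_axial[ok, 1L], 0.5 * w1$wss_axial[ok, 1L],
               tolerance = 1e-12)
})

test_that("forward-flow restriction shields markers from retrograde wall flow", {
  g <- straight_tube()
  fp <- flow_params(mean_flow = 83, jet_offset = 3)
  f <- sample_field(g, fp, spacing = 0.8, frame_times = 175)
  pl <- local_frame(g, 20)
  base <- c(flow_displacement(f, pl, 175), jet_angle(f, pl, 175),
            max_velocity(f, pl, 175))

  # superpose retrograde flow confined to the wall region opposite the jet
  fmod <- f
  ctr <- voxel_centers(f)
  rad <- sqrt(ctr[, 1L]^2 + ctr[, 2L]^2)
  wallzone <- as.vector(f$mask) & rad > 10 & ctr[, 1L] < -5
  vz <- fmod$v[, , , 3L, 1L]
  vz[array(wallzone, dim = f$dims)] <- -0.3
  fmod$v[, , , 3L, 1L] <- vz
  after <- c(flow_displacement(fmod, pl, 175), jet_angle(fmod, pl, 175),
             max_velocity(fmod, pl, 175))
  expect_equal(after, base, tolerance = 1e-12)
})
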