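test_that("waveform generator honors mean, shape and degenerate cases", {
  w <- generate_waveform(flow_params(mean_flow = 100, peak_mean_ratio = 1),
                         n_frames = 40L)
  expect_equal(w$flow, rep(100, 40L), tolerance = 1e-12)

  w2 <- generate_waveform(flow_params(mean_flow = 100), n_frames = 64L)
  expect_equal(waveform_mean(w2), 100, tolerance = 1e-3)
  expect_true(all(w2$flow >= 0))

  # argmax in the first 35% of the cycle, against dense-grid evaluation
  fp <- flow_params(systolic_fraction = 0.35)
  qf <- systolic_q_fun(fp, 1000)
  td <- seq(0, 999.9, by = 0.1)
  t_dense <- td[which.max(qf(td))]
  expect_lt(t_dense, 350)
  w3 <- generate_waveform(fp, n_frames = 50L)
  expect_lt(abs(w3$time[which.max(w3$flow)] - t_dense), 1000 / 50)

  expect_error(flow_params(peak_mean_ratio = 0.5), "ratio")
  expect_error(generate_waveform(flow_params(), n_frames = 4L), "at least 8")
})

test_that("analytic velocity reproduces Poiseuille and no-slip", {
  g <- straight_tube()
  fp <- steady_flow(Q = 100)
  # axis velocity = 2Q/(pi R^2): Q = 100 mL/s, R = 12.5 mm
  v_axis <- analytic_velocity(g, fp, c(0, 0, 20), t = 0)
  expect_equal(v_axis[3L], 2 * 100 / (pi * 12.5^2), tolerance = 1e-9)
  expect_equal(v_axis[1:2], c(0, 0), tolerance = 1e-12)
  # no-slip at the wall and zero outside the lumen (contract, not error)
  v_wall <- analytic_velocity(g, fp, c(12.4999, 0, 20), t = 0)
  expect_lt(abs(v_wall[3L]), 1e-4)
  v_out <- analytic_velocity(g, fp, c(20, 0, 20), t = 0)
  expect_equal(as.numeric(v_out), c(0, 0, 0))
})

test_that("Womersley harmonic profile matches an independent finite-difference oracle", {
  alpha <- 10
  R <- 0.0125
  nu <- 0.035 / 1050
  om <- alpha^2 * nu / R^2
  # oracle: complex radial BVP  i w u = K + nu (u'' + u'/r), u(R) = 0,
  # on a staggered grid (second order at the axis), self-convergence checked
  solve_bvp <- function(N) {
    h <- R / N
    r <- (seq_len(N) - 0.5) * h                 # staggered: no axis node
    lower <- -nu / h^2 + nu / (2 * r * h)
    upper <- -nu / h^2 - nu / (2 * r * h)
    diagm <- rep(complex(real = 0, imaginary = om) + 2 * nu / h^2, N)
    diagm[1L] <- diagm[1L] + lower[1L]          # mirror symmetry across r = 0
    diagm[N] <- diagm[N] - upper[N]             # u = 0 at the wall midpoint

    b <- rep(1 + 0i, N)
    cp <- complex(length.out = N); dp <- complex(length.out = N)
    cp[1L] <- upper[1L] / diagm[1L]; dp[1L] <- b[1L] / diagm[1L]
    for (i in 2:N) {
      m <- diagm[i] - lower[i] * cp[i - 1L]
      cp[i] <- upper[i] / m
      dp[i] <- (b[i] - lower[i] * dp[i - 1L]) / m
    }
    u <- complex(length.out = N); u[N] <- dp[N]
    for (i in (N - 1L):1L) u[i] <- dp[i] - cp[i] * u[i + 1L]
    num <- sum(u * 2 * pi * r * h) / (pi * R^2)
    list(r = r, phi = u / num)
  }
  sol <- solve_bvp(4000L)
  sol2 <- solve_bvp(8000L)
  ys <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  at <- function(s, y) {                       # linear interpolation in r
    i <- findInterval(y * R, s$r)
    w <- (y * R - s$r[i]) / (s$r[i + 1L] - s$r[i])
    (1 - w) * s$phi[i] + w * s$phi[i + 1L]
  }
  o1 <- sapply(ys, at, s = sol)
  o2 <- sapply(ys, at, s = sol2)
  expect_lt(max(Mod(o2 - o1)), 5e-5)           # oracle self-convergence
  pkg <- womersley_profile(ys, alpha)
  # profile is flow-normalized (order 1); velocities scale as q/(pi R^2)
  expect_lt(max(Mod(pkg - o2)), 1e-4)
})

test_that("sampled fields integrate to the prescribed flow and refine monotonically", {
  g <- straight_tube(length = 30, n = 7L)
  fp <- flow_params(mean_flow = 83)
  pl <- local_frame(g, 15)
  qf <- systolic_q_fun(fp, 1000)
  errs <- sapply(c(1.6, 0.8, 0.4), function(sp) {
    f <- sample_field(g, fp, spacing = sp, frame_times = 175)
    q <- flow_rate(f, pl)$flow[1L]
    abs(q - qf(175)) / qf(175)
  })
  expect_lt(errs[2L], 0.02)          # 2% at 0.8 mm
  expect_true(all(diff(errs) < 0))   # monotone refinement

  f <- sample_field(g, fp, spacing = 1.6, frame_times = c(100, 175))
  outside <- !as.vector(f$mask)
  for (k in 1:2) for (comp in 1:3)
    expect_true(all(f$v[, , , comp, k][outside] == 0))
  expect_error(sample_field(g, fp, spacing = -1), "positive")
})

test_that("MRI degradation averages, preserves constants, and is seed-deterministic", {
  # uniform field with full mask: box averaging must be exact
  dims <- c(20L, 20L, 8L)
  v <- array(0.7, dim = c(dims, 3L, 2L))
  f <- velocity_field(c(0, 0, 0), 0.5, c(0, 25), v, array(TRUE, dims))
  d <- degrade_to_mri(f, voxel = 2.5, dt = 50, snr = Inf)
  expect_true(all(abs(d$v - 0.7) < 1e-12))
  expect_equal(d$dims, c(4L, 4L, 1L))

  # 400 mm extent at 2.5 mm voxels -> 160 samples along that axis
  big <- velocity_field(c(-200, 0, 0), c(0.625, 2.5, 2.5), 0,
                        array(0, dim = c(640L, 4L, 4L, 3L, 1L)),
                        array(TRUE, c(640L, 4L, 4L)))
  expect_equal(degrade_to_mri(big, voxel = 2.5, snr = Inf)$dims[1L], 160L)

  # determinism contract
  g <- straight_tube(length = 20, n = 5L)
  ff <- sample_field(g, flow_params(), spacing = 1.25, frame_times = 175)
  d1 <- degrade_to_mri(ff, snr = 20, seed = 11L)
  d2 <- degrade_to_mri(ff, snr = 20, seed = 11L)
  d3 <- degrade_to_mri(ff, snr = 20, seed = 12L)
  expect_identical(d1$v, d2$v)
  expect_false(identical(d1$v, d3$v))
  expect_error(degrade_to_mri(ff, venc = -1), "venc")

  # aliasing wrap folds out-of-range velocities back into +/- venc
  vv <- array(3.1, dim = c(4L, 4L, 4L, 3L, 1L))    # above venc = 2 m/s
  fw <- velocity_field(c(0, 0, 0), 2.5, 0, vv, array(TRUE, c(4L, 4L, 4L)))
  dw <- degrade_to_mri(fw, voxel = 2.5, venc = 200, snr = Inf, wrap = TRUE)
  expect_true(all(abs(dw$v - (3.1 - 4)) < 1e-12))
})

test_that("cohort generation is reproducible with the specified structure", {
  ch <- generate_cohort(cohort_spec(4L, 4L, 4L), seed = 1L)
  expect_equal(nrow(ch$manifest), 12L)
  expect_equal(as.vector(table(ch$manifest$group)[c("control", "stable", "dilating")]),
               c(4L, 4L, 4L))
  expect_true(all(ch$manifest$target_pwv >= 6.2 & ch$manifest$target_pwv <= 20.7))

  ch2 <- generate_cohort(cohort_spec(4L, 4L, 4L), seed = 1L)
  expect_identical(ch$manifest, ch2$manifest)

  solo <- generate_cohort(cohort_spec(1L, 0L, 0L), seed = 3L)
  expect_equal(nrow(solo$manifest), 1L)
  expect_equal(solo$manifest$group, "control")
  expect_lte(solo$manifest$helical_strength, 800 * 1.15)

  expect_error(cohort_spec(0L, 0L, 0L), "empty")
})
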