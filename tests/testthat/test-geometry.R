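test_that("tube construction places vertices on the prescribed radius", {
  g <- straight_tube(length = 100, r = 12.5, n = 10L)
  d <- sqrt(g$surface$vertices[, 1L]^2 + g$surface$vertices[, 2L]^2)
  expect_lt(max(abs(d - 12.5)), 1e-9)

  # semicircular arc: construction size contract
  a <- seq(0, pi, length.out = 20L)
  arc <- cbind(50 * cos(a), 50 * sin(a), 0)
  g2 <- build_tube_geometry(arc, 10, 1, circumferential_resolution = 24L,
                            segment_bounds = c(0, 1), segment_names = "arch")
  expect_equal(nrow(g2$surface$vertices), 20L * 24L)

  # linear taper 15 -> 10 mm: per-station max distance vs brute force
  n <- 12L
  prof <- seq(15, 10, length.out = n)
  g3 <- build_tube_geometry(cbind(0, 0, seq(0, 60, length.out = n)), prof, 1)
  dist <- sqrt(g3$surface$vertices[, 1L]^2 + g3$surface$vertices[, 2L]^2)
  per_station <- as.numeric(tapply(dist, g3$surface$station, max))
  expect_equal(per_station, prof, tolerance = 1e-10)
})

test_that("degenerate and self-intersecting centerlines are rejected", {
  expect_error(build_tube_geometry(cbind(0, 0, 0), 10, 1), "at least 2")
  expect_error(straight_tube(r = -1), "positive")
  expect_error(straight_tube(h = 0), "positive")
  # duplicate points: non-monotone arc length
  cl <- rbind(c(0, 0, 0), c(0, 0, 10), c(0, 0, 10), c(0, 0, 20))
  expect_error(build_tube_geometry(cl, 5, 1),
               "strictly increasing|coincident")
  # tube radius exceeding the local radius of curvature
  a <- seq(0, pi / 2, length.out = 20L)
  tight <- cbind(8 * cos(a), 8 * sin(a), 0)
  expect_error(build_tube_geometry(tight, 10, 1), "self-intersect")
})

test_that("rotation-minimizing frames are orthonormal, continuous, and match a dense transport oracle", {
  # helix centerline
  t <- seq(0, 4 * pi, length.out = 200L)
  helix <- cbind(20 * cos(t), 20 * sin(t), 8 * t)
  fr <- rmf_frames(helix)
  for (i in c(1L, 100L, 200L)) {
    M <- rbind(fr$tangent[i, ], fr$normal[i, ], fr$binormal[i, ])
    expect_lt(max(abs(M %*% t(M) - diag(3))), 1e-10)
  }
  ang <- sapply(seq_len(199L), function(i)
    acos(min(1, sum(fr$normal[i, ] * fr$normal[i + 1L, ]))) * 180 / pi)
  expect_lt(max(ang), 5)

  # oracle: dense stepwise parallel transport at 100x resolution
  td <- seq(0, 4 * pi, length.out = 19901L)
  hd <- cbind(20 * cos(td), 20 * sin(td), 8 * td)
  seg <- hd[-1L, ] - hd[-nrow(hd), ]
  tgd <- seg / sqrt(rowSums(seg^2))
  nref <- fr$normal[1L, ]
  nref <- nref - sum(nref * tgd[1L, ]) * tgd[1L, ]
  nref <- nref / sqrt(sum(nref^2))
  oracle <- matrix(NA_real_, 200L, 3L)
  oracle[1L, ] <- nref
  k <- 2L
  for (i in 2:nrow(tgd)) {
    nref <- nref - sum(nref * tgd[i, ]) * tgd[i, ]
    nref <- nref / sqrt(sum(nref^2))
    if ((i %% 100L) == 0L) { oracle[k, ] <- nref; k <- k + 1L }
  }
  dev <- sapply(2:199, function(i)
    acos(min(1, abs(sum(fr$normal[i, ] * oracle[i, ])))) * 180 / pi)
  expect_lt(max(dev), 0.5)
})

test_that("local_frame interpolates position and stays orthogonal", {
  g <- straight_tube(length = 100, n = 11L)
  for (s in c(0, 13.7, 50, 100)) {
    pl <- local_frame(g, s)
    expect_equal(unname(pl$tangent), c(0, 0, 1), tolerance = 1e-12)
    expect_equal(unname(pl$origin[3L]), s, tolerance = 1e-9)
    expect_lt(abs(sum(pl$axes[1L, ] * pl$tangent)), 1e-12)
    expect_lt(abs(sum(pl$axes[1L, ] * pl$axes[2L, ])), 1e-12)
  }
  expect_error(local_frame(g, 101), "outside")

  # planar arc: tangent orthogonal to the radial direction
  a <- seq(0, pi / 2, length.out = 30L)
  arc <- cbind(60 * (1 - cos(a)), 0, 60 * sin(a))
  ga <- build_tube_geometry(arc, 10, 1, segment_bounds = c(0, 1),
                            segment_names = "arch")
  pl <- local_frame(ga, max(ga$arclength) / 2)
  radial <- pl$origin - c(60, 0, 0)
  expect_lt(abs(sum(pl$tangent * radial) / sqrt(sum(radial^2))), 0.02)
})

test_that("quadrant labels form a partition matching direct angle arithmetic", {
  g <- straight_tube(circ = 100L, n = 10L)
  q <- quadrant_labels(g, "anatomical", anterior = c(1, 0, 0))
  expect_equal(length(q), nrow(g$surface$vertices))
  expect_false(any(is.na(q)))
  expect_equal(sum(table(q)), nrow(g$surface$vertices))

  # theta = 0 sits on the reference axis -> first label
  expect_equal(as.character(q[g$surface$theta == 0][1L]), "anterior")

  # sector centres 45/135/225/315 relative to anterior = +x (the frame normal)
  v45 <- which.min(abs(g$surface$theta - 45))
  v135 <- which.min(abs(g$surface$theta - 135))
  v225 <- which.min(abs(g$surface$theta - 225))
  v315 <- which.min(abs(g$surface$theta - 315))
  expect_equal(length(unique(as.character(q[c(v45, v135, v225, v315)]))), 4L)

  # brute force: vertex angle from +x axis must lie within [c-45, c+45)
  ang <- atan2(g$surface$vertices[, 2L], g$surface$vertices[, 1L]) * 180 / pi
  ang <- ang %% 360
  centers <- c(anterior = 0, left = 90, posterior = 180, right = 270)
  rel <- (ang - centers[as.character(q)] + 180) %% 360 - 180
  expect_true(all(rel >= -45 - 1e-9 & rel < 45 + 1e-9))

  q2 <- quadrant_labels(g, "interior-exterior", anterior = c(1, 0, 0))
  expect_setequal(levels(q2), c("anterior", "interior", "posterior", "exterior"))
  expect_error(quadrant_labels(g, "bogus"), "unknown quadrant convention")
  expect_error(quadrant_labels(g, "anatomical", anterior = c(0, 0, 1)),
               "parallel")
})

test_that("segment split partitions the surface and splits the ascending segment", {
  g <- build_tube_geometry(cbind(0, 0, seq(0, 100, length.out = 21L)), 10, 1,
                           segment_bounds = c(0, 0.25, 0.5, 0.75, 1),
                           segment_names = c("a", "b", "c", "d"))
  s <- segment_split(g)
  expect_false(any(is.na(s)))
  tb <- table(s)
  expect_equal(length(tb), 4L)
  expect_lt(diff(range(tb)) / max(tb), 0.35)   # near-equal bands on a uniform tube

  # ascending [0, 0.3] split at its arithmetic midpoint 0.15
  g2 <- build_tube_geometry(cbind(0, 0, seq(0, 100, length.out = 21L)), 10, 1,
                            segment_bounds = c(0, 0.3, 1),
                            segment_names = c("ascending", "rest"))
  s2 <- segment_split(g2)
  frac <- g2$arclength[g2$surface$station] / max(g2$arclength)
  v <- which(abs(frac - 0.10) < 0.02)[1L]
  expect_equal(as.character(s2[v]), "ascending-proximal")
  v2 <- which(abs(frac - 0.22) < 0.02)[1L]
  expect_equal(as.character(s2[v2]), "ascending-distal")

  # random bounds: partition property
  set.seed(42)
  b <- sort(runif(3))
  g3 <- build_tube_geometry(cbind(0, 0, seq(0, 50, length.out = 11L)), 8, 1,
                            segment_bounds = c(0, b, 1),
                            segment_names = paste0("s", 1:4))
  s3 <- segment_split(g3)
  expect_equal(sum(table(s3)), nrow(g3$surface$vertices))
  expect_error(build_tube_geometry(cbind(0, 0, 0:5), 5, 1,
                                   segment_bounds = c(0, 0.8, 0.4, 1),
                                   segment_names = paste0("s", 1:3)),
               "increasing")
})

test_that("cylinder surface area matches 2 pi r L within 1%", {
  g <- straight_tube(length = 80, r = 10, n = 30L, circ = 48L)
  expect_equal(surface_area(g), 2 * pi * 10 * 80, tolerance = 0.01)
})
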