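fake_wss <- function(ssr_values, valid = NULL) {
  n <- length(ssr_values)
  if (is.null(valid)) valid <- rep(TRUE, n)
  ssr(structure(list(wss_axial = matrix(1, n), wss_circ = matrix(ssr_values, n),
                     valid = matrix(valid, n), times = 0),
                class = "wall_shear_field"))
}

test_that("quadrant means match brute-force masked averaging", {
  g <- straight_tube(circ = 40L, n = 6L)
  quad <- quadrant_labels(g, "anatomical", anterior = c(1, 0, 0))
  seg <- segment_split(g)
  V <- nrow(g$surface$vertices)

  w1 <- fake_wss(rep(1, V))
  expect_equal(unname(quadrant_mean_ssr(w1, quad)), rep(1, 4L))

  ind <- as.numeric(quad == "left")
  w2 <- fake_wss(ind)
  m2 <- quadrant_mean_ssr(w2, quad)
  expect_equal(unname(m2["left"]), 1)
  expect_equal(unname(m2[c("anterior", "posterior", "right")]), rep(0, 3L))

  set.seed(9)
  vals <- runif(V)
  valid <- runif(V) > 0.1
  w3 <- fake_wss(vals, valid)
  m3 <- quadrant_mean_ssr(w3, quad, segments = seg,
                          segment = "ascending-distal")
  for (qv in levels(quad)) {
    sel <- valid & quad == qv & seg == "ascending-distal"
    expect_equal(unname(m3[qv]), mean(vals[sel]))
  }

  # empty quadrant after filtering -> NA
  w4 <- fake_wss(vals, quad != "left")
  expect_true(is.na(quadrant_mean_ssr(w4, quad)["left"]))
})

test_that("SSR profiles localize an elevated distal-ascending swirl", {
  g <- straight_tube(length = 60, n = 13L)
  seg <- segment_split(g)
  fp <- flow_params(mean_flow = 83, helical_strength = 3000,
                    helical_window = c(0.5, 1))
  f <- sample_field(g, fp, spacing = 0.8, frame_times = 175)
  w <- ssr(wall_shear(f, g, frames = 1L))
  prof <- ssr_profile(w, g)
  expect_true(all(diff(prof$station) > 0))
  peak_frac <- prof$arclength[which.max(prof$ssr_mean)] / max(g$arclength)
  expect_gt(peak_frac, 0.5)                       # generator localization

  # uniform SSR -> flat profile; station bookkeeping is plumbing-exact
  wu <- fake_wss(rep(2, nrow(g$surface$vertices)))
  pu <- ssr_profile(wu, g)
  expect_equal(pu$ssr_mean, rep(2, nrow(pu)))
  expect_equal(nrow(pu), length(unique(g$surface$station)))
})

test_that("cumulative frequency and percentiles agree with sorting oracles", {
  cf <- cumulative_frequency(rep(3.3, 7L))
  expect_equal(cf$percentile(90), 3.3)
  expect_equal(cf$ecdf(3.3), 1)

  cf2 <- cumulative_frequency(sample(1:100))
  expect_equal(cf2$percentile(90), 90.1)          # closest-ranks interpolation
  expect_equal(cf2$ecdf(max(cf2$sorted)), 1)

  set.seed(4)
  x <- rlnorm(257)
  cf3 <- cumulative_frequency(x)
  s <- sort(x)
  for (q in c(0, 10, 50, 90, 100)) {
    h <- (length(s) - 1) * q / 100 + 1
    manual <- s[floor(h)] + (h - floor(h)) * (s[ceiling(h)] - s[floor(h)])
    expect_equal(cf3$percentile(q), manual, tolerance = 1e-12)
  }
  expect_true(all(diff(cf3$ecdf(s)) >= 0))
  expect_error(cumulative_frequency(numeric(0)), "no finite")
})

test_that("Kruskal-Wallis H matches hand computation and the rank-sum oracle", {
  r0 <- kruskal_wallis(list(c(2, 2, 2), c(2, 2, 2), c(2, 2, 2)))
  expect_equal(r0$H, 0)
  expect_equal(r0$p, 1)

  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  res <- kruskal_wallis(g)
  # brute-force rank formula: H = 12/(N(N+1)) sum R_i^2/n_i - 3(N+1)
  H_hand <- 12 / (9 * 10) * (6^2 / 3 + 15^2 / 3 + 24^2 / 3) - 3 * 10
  expect_equal(res$H, H_hand)

  # two-group exact permutation p equals the exact rank-sum (Wilcoxon) p
  set.seed(2)
  a <- rnorm(5)
  b <- rnorm(6) + 1
  kw <- kruskal_wallis(list(a, b), method = "exact")
  wx <- stats::wilcox.test(a, b, exact = TRUE)
  expect_equal(kw$p, wx$p.value, tolerance = 1e-6)
})

test_that("exact enumeration matches the chi-square H and caches by group sizes", {
  set.seed(5)
  g <- list(rnorm(4), rnorm(4), rnorm(4))
  e1 <- kruskal_wallis(g, method = "exact")
  c1 <- kruskal_wallis(g, method = "chisq")
  expect_equal(e1$H, c1$H)
  expect_true(e1$p >= 0 && e1$p <= 1)
  # repeat call is fast thanks to the cached null distribution
  t0 <- Sys.time()
  for (i in 1:25) kruskal_wallis(list(rnorm(4), rnorm(4), rnorm(4)),
                                 method = "exact")
  expect_lt(as.numeric(Sys.time() - t0), 2)
})

test_that("Scheffe contrasts match the textbook formula and edge cases", {
  # small worked dataset, independent hand computation
  g <- list(a = c(3, 5, 4), b = c(8, 9, 10), c = c(4, 6, 5))
  res <- scheffe_posthoc(g)
  means <- sapply(g, mean)
  sse <- sum(sapply(g, function(x) sum((x - mean(x))^2)))
  mse <- sse / (9 - 3)
  Fab <- (means["a"] - means["b"])^2 / (mse * (1 / 3 + 1 / 3))
  i <- which(res$group1 == "a" & res$group2 == "b")
  expect_equal(res$statistic[i], unname(Fab))
  expect_equal(res$p[i], stats::pf(unname(Fab) / 2, 2, 6, lower.tail = FALSE))
  expect_true(res$significant[i])

  # identical groups: nothing significant (degenerate zero variance)
  same <- list(x = c(1, 1, 1), y = c(1, 1, 1), z = c(1, 1, 1))
  rs <- scheffe_posthoc(same)
  expect_true(attr(rs, "degenerate"))
  expect_false(any(rs$significant))

  # one group shifted by ~100 sigma: its pairs are significant
  set.seed(7)
  far <- list(a = rnorm(4), b = rnorm(4), c = rnorm(4) + 100)
  rf <- scheffe_posthoc(far)
  cc <- rf$group1 == "c" | rf$group2 == "c"
  expect_true(all(rf$significant[cc]))
  expect_false(any(rf$significant[!cc]))

  expect_error(scheffe_posthoc(list(1:3, 4:6)), "at least 3")

  # Dunn alternative is available and flags the shifted group first
  rd <- dunn_posthoc(far)
  expect_lt(min(rd$p[rd$group1 == "c" | rd$group2 == "c"]),
            min(rd$p[!(rd$group1 == "c" | rd$group2 == "c")]))
})

test_that("cohort report tabulates mean +/- s.e.m. deterministically", {
  expect_equal(sem(c(1, 2, 3)), 0.5774, tolerance = 1e-4)
  expect_true(is.na(sem(5)))

  df <- data.frame(group = c("a", "a", "a", "b"),
                   ssr = c(1, 2, 3, 10), vmax = c(2, 2, 2, 4))
  rep1 <- cohort_report(df, c("ssr", "vmax"))
  gt <- rep1$group_table
  expect_equal(gt$mean[gt$group == "a" & gt$marker == "ssr"], 2)
  expect_equal(gt$sem[gt$group == "a" & gt$marker == "ssr"], sem(c(1, 2, 3)))
  expect_true(is.na(gt$sem[gt$group == "b" & gt$marker == "ssr"]))
  rep2 <- cohort_report(df, c("ssr", "vmax"))
  expect_identical(rep1$group_table, rep2$group_table)
})
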