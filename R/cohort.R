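# Synthetic cohorts mimicking a control / stable-aneurysm / dilating-aneurysm
# study structure.

#' Cohort specification
#'
#' Parameter distributions for a synthetic three-group cohort. The groups
#' emulate healthy controls and aneurysm patients with stable versus
#' dilating ascending aortas (dilation label: growth >= 0.6 mm/year):
#' dilating cases draw larger radii, more eccentric and angled jets, and a
#' stronger helical component concentrated in the distal ascending segment
#' (multipliers 1x / 2x / 6x of `helical_base` by default). Target pulse
#' wave velocities are drawn per group within the 6.2-20.7 m/s clinical
#' range. Effect sizes are package configuration for qualitative group
#' separation, not published effect estimates.
#'
#' @param n_control,n_stable,n_dilating group sizes (>= 0, not all zero).
#' @param pwv_ranges per-group `c(lo, hi)` target PWV (m s^-1).
#' @param radius_mean,radius_sd per-group lumen radius distribution (mm).
#' @param jet_offset_range,jet_angle_range per-group uniform ranges (mm, deg).
#' @param helical_base control-level swirl strength k (s^-1 m^-1).
#' @param helical_multipliers per-group multipliers on `helical_base`.
#' @param mean_flow_mean,mean_flow_sd inflow distribution (mL s^-1).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 4L, n_stable = 4L, n_dilating = 4L,
                        pwv_ranges = list(control = c(6.4, 11.1),
                                          stable = c(6.2, 12.5),
                                          dilating = c(6.8, 20.7)),
                        radius_mean = c(control = 12.75, stable = 14,
                                        dilating = 18.4),
                        radius_sd = c(control = 0.75, stable = 0.9,
                                      dilating = 1.5),
                        jet_offset_range = list(control = c(0, 1.5),
                                                stable = c(1, 3),
                                                dilating = c(2, 3.5)),
                        jet_angle_range = list(control = c(0, 5),
                                               stable = c(4, 12),
                                               dilating = c(8, 20)),
                        helical_base = 800,
                        helical_multipliers = c(control = 1, stable = 2,
                                                dilating = 6),
                        mean_flow_mean = 83, mean_flow_sd = 8) {
  n <- c(control = as.integer(n_control), stable = as.integer(n_stable),
         dilating = as.integer(n_dilating))
  if (any(n < 0L)) stop("group sizes must be >= 0")
  if (sum(n) == 0L) stop("cohort is empty")
  structure(list(n = n, pwv_ranges = pwv_ranges, radius_mean = radius_mean,
                 radius_sd = radius_sd, jet_offset_range = jet_offset_range,
                 jet_angle_range = jet_angle_range,
                 helical_base = helical_base,
                 helical_multipliers = helical_multipliers,
                 mean_flow_mean = mean_flow_mean,
                 mean_flow_sd = mean_flow_sd),
            class = "cohort_spec")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic cohort manifest
#'
#' Draws per-case parameters (geometry, jet, swirl, target PWV, inflow) for
#' every case in the specification, fully reproducibly from the seed. Case
#' fields are built on demand by [synth_case()] so that large cohorts can be
#' processed one case at a time.
#'
#' @param spec a `cohort_spec`.
#' @param seed integer seed, recorded in the manifest.
#' @return object of class `cohort`: the `manifest` data frame (one row per
#'   case), the `spec` and the `seed`.
#' @export
generate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  manifest <- with_seed(seed, {
    rows <- list()
    for (grp in names(spec$n)) {
      ng <- spec$n[[grp]]
      if (ng == 0L) next
      for (i in seq_len(ng)) {
        r <- max(stats::rnorm(1L, spec$radius_mean[[grp]],
                              spec$radius_sd[[grp]]), 8)
        rows[[length(rows) + 1L]] <- data.frame(
          case = sprintf("%s%d", toupper(substr(grp, 1L, 1L)), i),
          group = grp,
          target_pwv = stats::runif(1L, spec$pwv_ranges[[grp]][1L],
                                    spec$pwv_ranges[[grp]][2L]),
          radius = r,
          thickness = r / 10,
          jet_offset = stats::runif(1L, spec$jet_offset_range[[grp]][1L],
                                    spec$jet_offset_range[[grp]][2L]),
          jet_angle = stats::runif(1L, spec$jet_angle_range[[grp]][1L],
                                   spec$jet_angle_range[[grp]][2L]),
          helical_strength = spec$helical_base *
            spec$helical_multipliers[[grp]] * stats::runif(1L, 0.85, 1.15),
          mean_flow = max(stats::rnorm(1L, spec$mean_flow_mean,
                                       spec$mean_flow_sd), 40),
          noise_seed = sample.int(.Machine$integer.max, 1L))
      }
    }
    do.call(rbind, rows)
  })
  rownames(manifest) <- NULL
  structure(list(manifest = manifest, spec = spec, seed = seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d cases (seed %d): %s\n", nrow(x$manifest), x$seed,
              paste(sprintf("%s n=%d", names(table(x$manifest$group)),
                            table(x$manifest$group)), collapse = ", ")))
  invisible(x)
}

#' Build one synthetic case from a cohort
#'
#' Constructs the case's vessel geometry (a gently curved ascending-aorta
#' arc, labelled as one "ascending" segment so that its distal half is the
#' regional analysis target), flow parameters (with the helical component
#' windowed to the distal half), the fine-grid analytic velocity field, and
#' optionally an MRI-like degraded copy.
#'
#' @param cohort a `cohort`.
#' @param i case index (row of the manifest).
#' @param spacing fine-grid voxel size (mm), default 0.8.
#' @param frame_times field frame times (ms); default a systolic window
#'   around peak systole at 10 ms spacing; `"peak"` stores only the
#'   peak-systole frame.
#' @param period cycle length (ms).
#' @param mri if TRUE also build the 2.5 mm / 25 ms degraded field.
#' @param snr signal-to-noise ratio for the degraded copy.
#' @param n_stations,arc_angle,curvature_radius geometry discretization.
#' @return list with `geometry`, `flow`, `fine`, `mri` (or NULL),
#'   `t_peak`, `period` and the manifest `row`.
#' @export
synth_case <- function(cohort, i, spacing = 0.8, frame_times = NULL,
                       period = 1000, mri = TRUE, snr = 20,
                       n_stations = 40L, arc_angle = 80,
                       curvature_radius = 55) {
  row <- cohort$manifest[i, ]
  cl <- make_arc_centerline(curvature_radius, arc_angle, n_stations)
  geom <- build_tube_geometry(cl, radius_profile = row$radius,
                              thickness_profile = row$thickness,
                              segment_bounds = c(0, 1),
                              segment_names = "ascending")
  flow <- flow_params(mean_flow = row$mean_flow,
                      jet_offset = row$jet_offset,
                      jet_angle = row$jet_angle,
                      helical_strength = row$helical_strength,
                      helical_window = c(0.5, 1))
  t_peak <- flow$systolic_fraction * period / 2
  if (is.null(frame_times)) {
    frame_times <- t_peak + seq(-20, 20, by = 10)
  } else if (identical(frame_times, "peak")) {
    frame_times <- t_peak
  }
  fine <- sample_field(geom, flow, spacing = spacing,
                       frame_times = frame_times, period = period)
  mri_field <- if (mri)
    degrade_to_mri(fine, voxel = 2.5, dt = 25, snr = snr,
                   seed = row$noise_seed)
  else NULL
  list(geometry = geom, flow = flow, fine = fine, mri = mri_field,
       t_peak = t_peak, period = period, row = row)
}

#' Distal-ascending 90th-percentile SSR for every cohort case
#'
#' The cohort-level stratification summary: for each case, computes wall
#' shear stress on the fine field at peak systole, forms the SSR, and takes
#' the 90th percentile of its cumulative frequency over the
#' ascending-distal surface nodes.
#'
#' @param cohort a `cohort`.
#' @param spacing fine-grid voxel size (mm).
#' @param q percentile (default 90).
#' @param segment segment over which the distribution is pooled.
#' @param ... passed to [synth_case()].
#' @return data frame with `case`, `group`, `ssr_p90` (and the target PWV).
#' @export
cohort_ssr_summary <- function(cohort, spacing = 0.8, q = 90,
                               segment = "ascending-distal", ...) {
  man <- cohort$manifest
  out <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    cs <- synth_case(cohort, i, spacing = spacing, mri = FALSE,
                     frame_times = "peak", ...)
    k <- which.min(abs(cs$fine$times - cs$t_peak))
    w <- ssr(wall_shear(cs$fine, cs$geometry, mu = cs$flow$viscosity,
                        frames = k))
    seg <- segment_split(cs$geometry)
    keep <- w$valid[, 1L] & !w$flagged[, 1L] & seg == segment
    keep[is.na(keep)] <- FALSE
    cf <- cumulative_frequency(w$ssr[keep, 1L])
    out[[i]] <- data.frame(case = man$case[i], group = man$group[i],
                           target_pwv = man$target_pwv[i],
                           ssr_p90 = cf$percentile(q))
  }
  do.call(rbind, out)
}
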