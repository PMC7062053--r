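#' @useDynLib aortassr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- internal vector helpers -------------------------------------------------

vnorm <- function(x) sqrt(sum(x^2))

normalize <- function(x) {
  n <- vnorm(x)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  x / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Cumulative arc length of a 3D polyline
#'
#' @param points numeric matrix (n x 3) of ordered coordinates in mm.
#' @return numeric vector of length n, starting at 0 (mm).
#' @keywords internal
polyline_arclength <- function(points) {
  d <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  c(0, cumsum(d))
}

#' Rotation-minimizing frames along a polyline
#'
#' Computes an orthonormal moving frame (tangent, normal, binormal) along an
#' ordered polyline using the double-reflection method, which transports the
#' in-plane axes with (numerically) zero twist. Rotation-minimizing frames are
#' preferred over Frenet frames because they remain stable on straight or
#' near-straight sections where curvature-based normals are undefined or flip.
#'
#' @param points numeric matrix (n x 3), n >= 2.
#' @param normal0 optional initial normal direction; projected to be orthogonal
#'   to the first tangent. Default picks the coordinate axis least aligned with
#'   the first tangent.
#' @return list with matrices `tangent`, `normal`, `binormal`, each n x 3.
#' @export
rmf_frames <- function(points, normal0 = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 centerline points")
  tang <- matrix(0, n, 3L)
  seg <- points[-1L, , drop = FALSE] - points[-n, , drop = FALSE]
  seg_len <- sqrt(rowSums(seg^2))
  if (any(seg_len < .Machine$double.eps))
    stop("centerline has coincident consecutive points (non-monotone arc length)")
  segu <- seg / seg_len
  tang[1L, ] <- segu[1L, ]
  tang[n, ] <- segu[n - 1L, ]
  if (n > 2L) {
    mid <- segu[-1L, , drop = FALSE] + segu[-(n - 1L), , drop = FALSE]
    tang[2:(n - 1L), ] <- mid / sqrt(rowSums(mid^2))
  }

  if (is.null(normal0)) {
    ax <- diag(3L)[which.min(abs(tang[1L, ])), ]
    normal0 <- ax
  }
  r0 <- normal0 - sum(normal0 * tang[1L, ]) * tang[1L, ]
  if (vnorm(r0) < 1e-12)
    stop("initial normal is parallel to the first tangent")
  nor <- matrix(0, n, 3L)
  nor[1L, ] <- normalize(r0)

  # double-reflection transport (Wang et al. style)
  for (i in seq_len(n - 1L)) {
    v1 <- points[i + 1L, ] - points[i, ]
    c1 <- sum(v1 * v1)
    rl <- nor[i, ] - (2 / c1) * sum(v1 * nor[i, ]) * v1
    tl <- tang[i, ] - (2 / c1) * sum(v1 * tang[i, ]) * v1
    v2 <- tang[i + 1L, ] - tl
    c2 <- sum(v2 * v2)
    ri <- if (c2 < 1e-300) rl else rl - (2 / c2) * sum(v2 * rl) * v2
    # re-orthonormalize against accumulated rounding
    ri <- ri - sum(ri * tang[i + 1L, ]) * tang[i + 1L, ]
    nor[i + 1L, ] <- normalize(ri)
  }
  bin <- t(vapply(seq_len(n), function(i) cross3(tang[i, ], nor[i, ]),
                  numeric(3L)))
  list(tangent = tang, normal = nor, binormal = bin)
}

# ---- vessel geometry ---------------------------------------------------------

#' Build a parametric tube geometry around a centerline
#'
#' Constructs a `vessel_geometry`: a triangulated lateral tube surface around a
#' 3D centerline, with per-station lumen radius and wall thickness, a
#' rotation-minimizing frame at every station, and per-vertex station index and
#' angular coordinate. This is the geometric substrate on which wall shear
#' stress is sampled and regional (segment x quadrant) statistics are formed.
#'
#' @param centerline n x 3 matrix of ordered points (mm).
#' @param radius_profile lumen radius r per station (mm); scalar recycled.
#' @param thickness_profile wall thickness h per station (mm); scalar recycled.
#' @param circumferential_resolution number of vertices per ring (default 32).
#' @param segment_bounds arc-length fractions (including 0 and 1) delimiting
#'   named segments; default five segments of an aorta-like vessel.
#' @param segment_names one name per segment; a segment named `"ascending"` is
#'   later split into proximal/distal halves by [segment_split()].
#' @return object of class `vessel_geometry`.
#' @examples
#' cl <- cbind(0, 0, seq(0, 100, length.out = 11))
#' g <- build_tube_geometry(cl, radius_profile = 12.5, thickness_profile = 1.25)
#' @export
build_tube_geometry <- function(centerline, radius_profile, thickness_profile,
                                circumferential_resolution = 32L,
                                segment_bounds = c(0, 0.3, 0.5, 0.68, 0.85, 1),
                                segment_names = c("ascending", "arch",
                                                  "descending-proximal",
                                                  "descending-mid",
                                                  "descending-distal")) {
  centerline <- as.matrix(centerline)
  n <- nrow(centerline)
  if (n < 2L) stop("need at least 2 centerline points")
  radius <- rep_len(radius_profile, n)
  thickness <- rep_len(thickness_profile, n)
  if (any(radius <= 0)) stop("all radii must be positive")
  if (any(thickness <= 0)) stop("all wall thicknesses must be positive")
  arclength <- polyline_arclength(centerline)
  if (any(diff(arclength) <= 0))
    stop("centerline arc length is not strictly increasing")

  # reject locally self-intersecting tubes: r * curvature must stay < 1
  if (n >= 3L) {
    kappa <- numeric(n)
    for (i in 2:(n - 1L)) {
      a <- centerline[i, ] - centerline[i - 1L, ]
      b <- centerline[i + 1L, ] - centerline[i, ]
      sa <- vnorm(a); sb <- vnorm(b)
      cosang <- max(-1, min(1, sum(a * b) / (sa * sb)))
      kappa[i] <- 2 * sin(acos(cosang) / 2) / sqrt(sa * sb)
    }
    if (any(radius * kappa >= 1))
      stop("tube self-intersects: radius exceeds local radius of curvature at station(s) ",
           paste(which(radius * kappa >= 1), collapse = ", "))
  }

  if (length(segment_bounds) != length(segment_names) + 1L)
    stop("segment_bounds must have one more entry than segment_names")
  check_segment_bounds(segment_bounds)

  frames <- rmf_frames(centerline)
  m <- as.integer(circumferential_resolution)
  if (m < 3L) stop("circumferential_resolution must be >= 3")
  theta <- (seq_len(m) - 1L) * 360 / m         # degrees in [0, 360)
  th_rad <- theta * pi / 180

  V <- n * m
  vertices <- matrix(0, V, 3L)
  normals <- matrix(0, V, 3L)
  station <- rep(seq_len(n), each = m)
  theta_all <- rep(theta, times = n)
  ct <- cos(th_rad); st <- sin(th_rad)
  for (i in seq_len(n)) {
    idx <- ((i - 1L) * m + 1L):(i * m)
    dirs <- outer(ct, frames$normal[i, ]) + outer(st, frames$binormal[i, ])
    vertices[idx, ] <- matrix(centerline[i, ], m, 3L, byrow = TRUE) +
      radius[i] * dirs
    normals[idx, ] <- dirs                     # radial outward normals
  }

  # quad strips split into triangles, indices 1-based
  tri <- matrix(0L, 2L * (n - 1L) * m, 3L)
  k <- 1L
  for (i in seq_len(n - 1L)) {
    for (j in seq_len(m)) {
      jn <- if (j == m) 1L else j + 1L
      a <- (i - 1L) * m + j
      b <- (i - 1L) * m + jn
      cc <- i * m + j
      d <- i * m + jn
      tri[k, ] <- c(a, b, cc); k <- k + 1L
      tri[k, ] <- c(b, d, cc); k <- k + 1L
    }
  }

  structure(list(
    centerline = centerline, arclength = arclength,
    radius = radius, thickness = thickness, frames = frames,
    surface = list(vertices = vertices, triangles = tri, station = station,
                   theta = theta_all, normals = normals),
    segment_bounds = segment_bounds, segment_names = segment_names,
    circumferential_resolution = m
  ), class = "vessel_geometry")
}

check_segment_bounds <- function(b) {
  if (any(b < 0) || any(b > 1)) stop("segment_bounds must lie in [0, 1]")
  if (any(diff(b) <= 0)) stop("segment_bounds must be strictly increasing")
  if (abs(b[1L]) > 1e-12 || abs(b[length(b)] - 1) > 1e-12)
    stop("segment_bounds must start at 0 and end at 1")
  invisible(b)
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat("vessel_geometry:", nrow(x$centerline), "stations,",
      nrow(x$surface$vertices), "surface vertices\n")
  cat("  length", sprintf("%.1f", max(x$arclength)), "mm; radius",
      sprintf("%.2f-%.2f", min(x$radius), max(x$radius)), "mm; thickness",
      sprintf("%.2f-%.2f", min(x$thickness), max(x$thickness)), "mm\n")
  cat("  segments:", paste(x$segment_names, collapse = ", "), "\n")
  invisible(x)
}

#' Total area of the triangulated tube surface
#' @param geometry a `vessel_geometry`.
#' @return area in mm^2.
#' @export
surface_area <- function(geometry) {
  v <- geometry$surface$vertices
  tr <- geometry$surface$triangles
  a <- v[tr[, 2L], ] - v[tr[, 1L], ]
  b <- v[tr[, 3L], ] - v[tr[, 1L], ]
  cx <- a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L]
  cy <- a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L]
  cz <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Cross-section plane at a given arc length
#'
#' Interpolates position, rotation-minimizing frame and lumen radius at arc
#' length `s` and returns a `section_plane` (origin on the centerline, unit
#' tangent, two orthonormal in-plane axes). Section planes are the reference
#' for flow-rate integration and for flow displacement / jet angle, both of
#' which are defined relative to the centerline.
#'
#' @param geometry a `vessel_geometry`.
#' @param s arc length from the inlet (mm), within range.
#' @return object of class `section_plane` with fields `origin`, `tangent`,
#'   `axes` (2 x 3 matrix), `lumen_radius`, `s`.
#' @export
local_frame <- function(geometry, s) {
  al <- geometry$arclength
  if (s < al[1L] || s > al[length(al)])
    stop(sprintf("arc length s = %.3f outside [%.3f, %.3f]",
                 s, al[1L], al[length(al)]))
  i <- findInterval(s, al, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(al) - 1L)
  w <- (s - al[i]) / (al[i + 1L] - al[i])
  origin <- (1 - w) * geometry$centerline[i, ] + w * geometry$centerline[i + 1L, ]
  tangent <- normalize((1 - w) * geometry$frames$tangent[i, ] +
                         w * geometry$frames$tangent[i + 1L, ])
  e1 <- (1 - w) * geometry$frames$normal[i, ] + w * geometry$frames$normal[i + 1L, ]
  e1 <- normalize(e1 - sum(e1 * tangent) * tangent)
  e2 <- cross3(tangent, e1)
  r <- (1 - w) * geometry$radius[i] + w * geometry$radius[i + 1L]
  structure(list(origin = origin, tangent = tangent,
                 axes = rbind(e1, e2), lumen_radius = r, s = s),
            class = "section_plane")
}

#' @export
print.section_plane <- function(x, ...) {
  cat(sprintf("section_plane at s = %.1f mm, lumen radius %.2f mm\n",
              x$s, x$lumen_radius))
  invisible(x)
}

# ---- labelling ---------------------------------------------------------------

quadrant_conventions <- list(
  # Fig-1c-style patient axes: reference direction -> "anterior"
  anatomical = c("anterior", "left", "posterior", "right"),
  # curvature-style labels: reference -> "anterior", +90 deg -> "interior"
  `interior-exterior` = c("anterior", "interior", "posterior", "exterior")
)

#' Quadrant label per surface vertex
#'
#' Assigns each surface vertex to one of four 90-degree sectors of its
#' circumference. The reference axis (theta = 0 of the sectors) is a
#' user-supplied "anterior" direction projected into each cross-section plane;
#' sectors are centred at 0, 90, 180 and 270 degrees from that axis, each
#' covering `[c - 45, c + 45)` degrees.
#'
#' Two label sets are supported: `"anatomical"` (anterior / left / posterior /
#' right) and `"interior-exterior"` (anterior / interior / posterior /
#' exterior). The mapping between the two conventions is a configuration
#' choice, not an anatomical claim.
#'
#' @param geometry a `vessel_geometry`.
#' @param convention `"anatomical"` or `"interior-exterior"`.
#' @param anterior 3-vector giving the anterior reference direction.
#' @return factor of length `nrow(geometry$surface$vertices)`.
#' @export
quadrant_labels <- function(geometry, convention = "anatomical",
                            anterior = c(0, 1, 0)) {
  if (!convention %in% names(quadrant_conventions))
    stop("unknown quadrant convention '", convention, "'; available: ",
         paste(names(quadrant_conventions), collapse = ", "))
  labels <- quadrant_conventions[[convention]]
  n <- nrow(geometry$centerline)
  # reference angle of the projected anterior direction, per station
  phi_ref <- numeric(n)
  for (i in seq_len(n)) {
    tg <- geometry$frames$tangent[i, ]
    ap <- anterior - sum(anterior * tg) * tg
    if (vnorm(ap) < 1e-9)
      stop("anterior direction is parallel to the centerline tangent at station ", i)
    phi_ref[i] <- atan2(sum(ap * geometry$frames$binormal[i, ]),
                        sum(ap * geometry$frames$normal[i, ])) * 180 / pi
  }
  th_rel <- (geometry$surface$theta - phi_ref[geometry$surface$station]) %% 360
  sector <- floor(((th_rel + 45) %% 360) / 90) + 1L
  factor(labels[sector], levels = labels)
}

#' Segment label per surface vertex
#'
#' Partitions the surface along the centerline into the named segments given
#' by `segment_bounds` (arc-length fractions). A segment named `"ascending"`
#' is further split at the arithmetic midpoint of its arc-length range into
#' `"ascending-proximal"` and `"ascending-distal"`.
#'
#' @param geometry a `vessel_geometry`.
#' @return factor of per-vertex segment labels.
#' @export
segment_split <- function(geometry) {
  b <- geometry$segment_bounds
  check_segment_bounds(b)
  nm <- geometry$segment_names
  L <- max(geometry$arclength)
  frac <- geometry$arclength[geometry$surface$station] / L
  seg <- findInterval(frac, b, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), length(nm))
  lab <- nm[seg]
  if ("ascending" %in% nm) {
    i <- match("ascending", nm)
    mid <- (b[i] + b[i + 1L]) / 2
    asc <- lab == "ascending"
    lab[asc] <- ifelse(frac[asc] < mid, "ascending-proximal", "ascending-distal")
    nm <- append(nm[-i], c("ascending-proximal", "ascending-distal"), after = i - 1L)
  }
  factor(lab, levels = nm)
}

# ---- canned centerlines ------------------------------------------------------

#' Aorta-like candy-cane centerline
#'
#' Straight ascending segment, a semicircular arch, and a straight descending
#' segment, in the x-z plane. Dimensions default to adult thoracic-aorta
#' scale.
#'
#' @param ascending_length mm of straight ascending vessel.
#' @param arch_radius radius of the arch (mm).
#' @param descending_length mm of straight descending vessel.
#' @param n_points number of stations.
#' @return n x 3 matrix of points (mm).
#' @export
make_aorta_centerline <- function(ascending_length = 70, arch_radius = 32,
                                  descending_length = 120, n_points = 60L) {
  arc_len <- pi * arch_radius
  total <- ascending_length + arc_len + descending_length
  s <- seq(0, total, length.out = n_points)
  pts <- matrix(0, n_points, 3L)
  for (k in seq_len(n_points)) {
    if (s[k] <= ascending_length) {
      pts[k, ] <- c(0, 0, s[k])
    } else if (s[k] <= ascending_length + arc_len) {
      a <- (s[k] - ascending_length) / arch_radius   # 0..pi
      pts[k, ] <- c(arch_radius * (1 - cos(a)), 0,
                    ascending_length + arch_radius * sin(a))
    } else {
      pts[k, ] <- c(2 * arch_radius, 0,
                    ascending_length - (s[k] - ascending_length - arc_len))
    }
  }
  pts
}

#' Gently curved ascending-aorta-like arc centerline
#'
#' Planar circular arc used as the default analysis geometry for the synthetic
#' cohort (the regional SSR analysis concerns the ascending aorta).
#'
#' @param curvature_radius radius of the arc (mm).
#' @param arc_angle swept angle (degrees).
#' @param n_points number of stations.
#' @return n x 3 matrix (mm).
#' @export
make_arc_centerline <- function(curvature_radius = 55, arc_angle = 80,
                                n_points = 40L) {
  a <- seq(0, arc_angle * pi / 180, length.out = n_points)
  cbind(curvature_radius * (1 - cos(a)), 0, curvature_radius * sin(a))
}
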