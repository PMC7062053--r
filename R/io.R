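# Plain-text I/O: centerline CSV, waveform CSV, legacy-VTK surfaces and
# image series, STL, and JSON manifests.

#' Read and write centerlines as CSV
#'
#' Columns `x, y, z, radius, thickness` (all mm).
#'
#' @param geometry a `vessel_geometry` (for writing).
#' @param path file path.
#' @return `read_centerline_csv` returns a list with `centerline`, `radius`,
#'   `thickness` suitable for [build_tube_geometry()].
#' @export
write_centerline_csv <- function(geometry, path) {
  df <- data.frame(x = geometry$centerline[, 1L],
                   y = geometry$centerline[, 2L],
                   z = geometry$centerline[, 3L],
                   radius = geometry$radius,
                   thickness = geometry$thickness)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centerline_csv
#' @export
read_centerline_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x", "y", "z", "radius", "thickness")
  if (!all(need %in% names(df)))
    stop("centerline CSV must have columns ", paste(need, collapse = ", "))
  list(centerline = as.matrix(df[, c("x", "y", "z")]),
       radius = df$radius, thickness = df$thickness)
}

#' Read and write flow waveforms as CSV
#'
#' Columns `time_ms, flow_ml_s`.
#'
#' @param w a `flow_waveform` (for writing).
#' @param path file path.
#' @export
write_waveform_csv <- function(w, path) {
  utils::write.csv(data.frame(time_ms = w$time, flow_ml_s = w$flow), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_ms", "flow_ml_s") %in% names(df)))
    stop("waveform CSV must have columns time_ms, flow_ml_s")
  flow_waveform(df$time_ms, df$flow_ml_s)
}

#' Write a tube surface as legacy-VTK polydata
#'
#' ASCII legacy VTK with triangles and optional per-vertex scalar arrays
#' (e.g. quadrant or segment labels, SSR maps).
#'
#' @param geometry a `vessel_geometry`.
#' @param path output `.vtk` path.
#' @param scalars named list of per-vertex numeric vectors or factors.
#' @export
write_surface_vtk <- function(geometry, path, scalars = list()) {
  v <- geometry$surface$vertices
  tr <- geometry$surface$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "tube surface", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", nrow(v))), con)
  utils::write.table(format(v, digits = 10, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("POLYGONS %d %d", nrow(tr), nrow(tr) * 4L), con)
  utils::write.table(cbind(3L, tr - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  if (length(scalars)) {
    writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
    for (nm in names(scalars)) {
      s <- scalars[[nm]]
      s <- if (is.factor(s)) as.integer(s) else as.numeric(s)
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(s, digits = 10, trim = TRUE, scientific = FALSE), con)
    }
  }
  invisible(path)
}

#' Read a legacy-VTK polydata surface
#'
#' Minimal reader for the files written by [write_surface_vtk()].
#'
#' @param path `.vtk` path.
#' @return list with `vertices`, `triangles` (1-based) and `scalars`.
#' @export
read_surface_vtk <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1L]
  np <- as.integer(strsplit(lines[ip], "\\s+")[[1L]][2L])
  vert <- matrix(scan(text = lines[(ip + 1L):(ip + np)], quiet = TRUE),
                 ncol = 3L, byrow = TRUE)
  it <- grep("^POLYGONS", lines)[1L]
  nt <- as.integer(strsplit(lines[it], "\\s+")[[1L]][2L])
  tri <- matrix(scan(text = lines[(it + 1L):(it + nt)], quiet = TRUE),
                ncol = 4L, byrow = TRUE)[, 2:4, drop = FALSE] + 1L
  scalars <- list()
  is <- grep("^SCALARS", lines)
  for (j in is) {
    nm <- strsplit(lines[j], "\\s+")[[1L]][2L]
    scalars[[nm]] <- scan(text = lines[(j + 2L):(j + 1L + np)], quiet = TRUE)
  }
  list(vertices = vert, triangles = tri, scalars = scalars)
}

#' Write a tube surface as ASCII STL
#'
#' @param geometry a `vessel_geometry`.
#' @param path output `.stl` path.
#' @export
write_surface_stl <- function(geometry, path) {
  v <- geometry$surface$vertices
  tr <- geometry$surface$triangles
  a <- v[tr[, 2L], ] - v[tr[, 1L], ]
  b <- v[tr[, 3L], ] - v[tr[, 1L], ]
  n <- cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
             a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
             a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  n <- n / pmax(sqrt(rowSums(n^2)), 1e-30)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid tube", con)
  fmt <- function(x) format(x, digits = 9, trim = TRUE)
  for (i in seq_len(nrow(tr))) {
    writeLines(c(sprintf("  facet normal %s %s %s", fmt(n[i, 1L]),
                         fmt(n[i, 2L]), fmt(n[i, 3L])),
                 "    outer loop",
                 sprintf("      vertex %s %s %s",
                         fmt(v[tr[i, ], 1L]), fmt(v[tr[i, ], 2L]),
                         fmt(v[tr[i, ], 3L])),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid tube", con)
  invisible(path)
}

#' Write a velocity field as a legacy-VTK image series
#'
#' One ASCII `STRUCTURED_POINTS` file per frame (vector array `velocity`,
#' scalar array `lumen`) plus a JSON manifest listing frames, times, grid
#' origin and spacing.
#'
#' @param field a `velocity_field`.
#' @param dir output directory (created if needed).
#' @param basename file-name stem.
#' @return manifest path, invisibly.
#' @export
write_field_vtk <- function(field, dir, basename = "frame") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- field$dims
  files <- character(length(field$times))
  for (k in seq_along(field$times)) {
    fn <- sprintf("%s_%03d.vtk", basename, k)
    files[k] <- fn
    con <- file(file.path(dir, fn), "w")
    writeLines(c("# vtk DataFile Version 3.0",
                 sprintf("velocity frame t=%g ms", field$times[k]), "ASCII",
                 "DATASET STRUCTURED_POINTS",
                 sprintf("DIMENSIONS %d %d %d", d[1L], d[2L], d[3L]),
                 sprintf("ORIGIN %g %g %g", field$origin[1L] + field$spacing[1L] / 2,
                         field$origin[2L] + field$spacing[2L] / 2,
                         field$origin[3L] + field$spacing[3L] / 2),
                 sprintf("SPACING %g %g %g", field$spacing[1L],
                         field$spacing[2L], field$spacing[3L]),
                 sprintf("POINT_DATA %d", prod(d)),
                 "VECTORS velocity double"), con)
    vmat <- matrix(field$v[, , , , k], ncol = 3L)
    utils::write.table(format(vmat, digits = 9, trim = TRUE), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    writeLines(c("SCALARS lumen int 1", "LOOKUP_TABLE default"), con)
    writeLines(as.character(as.integer(field$mask)), con)
    close(con)
  }
  manifest <- list(format = "vtk-structured-points-series",
                   files = files, times_ms = field$times,
                   origin_mm = field$origin, spacing_mm = field$spacing,
                   dims = field$dims)
  mpath <- file.path(dir, paste0(basename, "_manifest.json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Read a velocity-field VTK series written by [write_field_vtk()]
#'
#' @param manifest_path path to the JSON manifest.
#' @return a `velocity_field`.
#' @export
read_field_vtk <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  d <- as.integer(man$dims)
  nt <- length(man$files)
  v <- array(0, dim = c(d, 3L, nt))
  mask <- NULL
  for (k in seq_len(nt)) {
    lines <- readLines(file.path(dir, man$files[k]))
    iv <- grep("^VECTORS", lines)[1L]
    vals <- scan(text = lines[(iv + 1L):(iv + prod(d))], quiet = TRUE)
    v[, , , , k] <- array(matrix(vals, ncol = 3L, byrow = TRUE), dim = c(d, 3L))
    if (is.null(mask)) {
      im <- grep("^SCALARS lumen", lines)[1L]
      mask <- array(scan(text = lines[(im + 2L):(im + 1L + prod(d))],
                         quiet = TRUE) > 0, dim = d)
    }
  }
  velocity_field(man$origin_mm, man$spacing_mm, man$times_ms, v, mask)
}

#' Write and read a cohort manifest as JSON
#'
#' @param cohort a `cohort`.
#' @param path JSON path.
#' @export
write_cohort_json <- function(cohort, path) {
  jsonlite::write_json(list(seed = cohort$seed,
                            n = as.list(cohort$spec$n),
                            cases = cohort$manifest),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_json
#' @export
read_cohort_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
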