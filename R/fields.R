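#' Velocity snapshot on a masked grid
#'
#' @param grid A [field_grid()].
#' @param u Velocity array of dimension `c(grid$dims, 3)`, m/s. Values
#'   outside the mask are zeroed.
#' @param time Snapshot time, s.
#' @return Object of class `field_snapshot`.
#' @export
field_snapshot <- function(grid, u, time = 0) {
  stopifnot(inherits(grid, "field_grid"),
            all(dim(u) == c(grid$dims, 3L)))
  if (any(!is.finite(u))) stop("velocity field contains non-finite values")
  u <- u * as.vector(grid$mask)   # mask recycles over the 3 components
  structure(list(grid = grid, u = u, time = time), class = "field_snapshot")
}

#' Time series of velocity snapshots
#'
#' Uniformly sampled, time-ordered velocity fields with an integer number
#' of snapshots per cardiac cycle.
#'
#' @param grid A [field_grid()].
#' @param u_list List of velocity arrays (each `c(dims, 3)`), m/s.
#' @param dt Uniform snapshot interval, s.
#' @param T_cycle Cycle length, s; must be an integer multiple of `dt`.
#' @param t0 Time of the first snapshot, s.
#' @return Object of class `field_series` with elements `grid`, `u`
#'   (list), `times`, `dt`, `T_cycle`, `n_per_cycle`.
#' @export
field_series <- function(grid, u_list, dt, T_cycle, t0 = 0) {
  stopifnot(inherits(grid, "field_grid"), length(u_list) >= 1, dt > 0,
            T_cycle > 0)
  n_per_cycle <- T_cycle / dt
  if (abs(n_per_cycle - round(n_per_cycle)) > 1e-9) {
    stop("T_cycle must be an integer multiple of dt")
  }
  for (u in u_list) stopifnot(all(dim(u) == c(grid$dims, 3L)))
  structure(list(grid = grid, u = u_list,
                 times = t0 + (seq_along(u_list) - 1) * dt,
                 dt = dt, T_cycle = T_cycle,
                 n_per_cycle = as.integer(round(n_per_cycle))),
            class = "field_series")
}

#' Number of complete cycles in a series
#' @param series A `field_series`.
#' @return Integer cycle count.
#' @export
series_cycles <- function(series) length(series$u) %/% series$n_per_cycle

#' Write a snapshot as a legacy VTK structured-points file
#'
#' ASCII legacy VTK with the cell-center lattice as structured points, the
#' velocity as a 3-component `POINT_DATA` array named `velocity` (SI units)
#' and the in-domain mask as an integer scalar array named `mask`.
#'
#' @param snap A [field_snapshot()].
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_field_vtk <- function(snap, path) {
  g <- snap$grid
  n <- prod(g$dims)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("rvadflow velocity field t=%.9g s", snap$time),
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", g$dims[1], g$dims[2], g$dims[3]),
               sprintf("ORIGIN %.9g %.9g %.9g",
                       g$origin[1], g$origin[2], g$origin[3]),
               sprintf("SPACING %.9g %.9g %.9g",
                       g$spacing[1], g$spacing[2], g$spacing[3]),
               sprintf("POINT_DATA %d", n),
               "VECTORS velocity double"), con)
  m <- matrix(snap$u, nrow = n)   # column-major == VTK x-fastest ordering
  writeLines(paste(format(m[, 1], digits = 9, trim = TRUE),
                   format(m[, 2], digits = 9, trim = TRUE),
                   format(m[, 3], digits = 9, trim = TRUE)), con)
  writeLines(c("SCALARS mask int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(as.integer(g$mask)), con)
  invisible(path)
}

#' Read a legacy VTK structured-points snapshot
#'
#' Counterpart of [write_field_vtk()]; expects a `velocity` vector array
#' and an optional `mask` scalar array.
#'
#' @param path `.vtk` file path.
#' @param time Snapshot time to attach, s (the writer also stores it in the
#'   VTK title line, which is parsed when `time` is `NULL`).
#' @return A [field_snapshot()].
#' @export
read_field_vtk <- function(path, time = NULL) {
  lines <- readLines(path)
  grab <- function(prefix) {
    ln <- grep(paste0("^", prefix), lines, value = TRUE)[1]
    as.numeric(strsplit(trimws(sub(prefix, "", ln)), "\\s+")[[1]])
  }
  if (!any(grepl("^DATASET STRUCTURED_POINTS", lines))) {
    stop("not a legacy VTK structured-points file: ", path)
  }
  dims <- as.integer(grab("DIMENSIONS"))
  origin <- grab("ORIGIN")
  spacing <- grab("SPACING")
  n <- prod(dims)
  iv <- grep("^VECTORS velocity", lines)[1]
  if (is.na(iv)) stop("no 'velocity' VECTORS array in ", path)
  vec <- scan(text = lines[(iv + 1):(iv + n)], quiet = TRUE)
  u <- array(matrix(vec, ncol = 3, byrow = TRUE), c(dims, 3L))
  im <- grep("^SCALARS mask", lines)[1]
  msk <- if (!is.na(im)) {
    array(scan(text = lines[(im + 2):(im + 1 + n)], quiet = TRUE) > 0, dims)
  } else array(TRUE, dims)
  if (is.null(time)) {
    tm <- regmatches(lines[2], regexpr("t=[-0-9.eE+]+", lines[2]))
    time <- if (length(tm)) as.numeric(sub("t=", "", tm)) else 0
  }
  g <- field_grid(dims, spacing, msk, origin)
  field_snapshot(g, u, time)
}

#' Write a field series as VTK files plus a JSON sidecar
#'
#' One `snapshot_%04d.vtk` per time point and a `series.json` sidecar with
#' the cycle metadata and optional provenance record.
#'
#' @param series A [field_series()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_field_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("snapshot_%04d.vtk", seq_along(series$u))
  for (i in seq_along(series$u)) {
    write_field_vtk(field_snapshot(series$grid, series$u[[i]],
                                   series$times[i]),
                    file.path(dir, files[i]))
  }
  meta <- list(dt = series$dt, T_cycle = series$T_cycle,
               n_per_cycle = series$n_per_cycle,
               times = series$times, files = files,
               provenance = series$provenance)
  jsonlite::write_json(meta, file.path(dir, "series.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a field series written by [write_field_series()]
#'
#' @param dir Directory with `series.json` and the snapshot `.vtk` files.
#' @return A [field_series()] (with `provenance` if recorded).
#' @export
read_field_series <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "series.json"),
                              simplifyVector = TRUE)
  snaps <- lapply(file.path(dir, meta$files), read_field_vtk)
  s <- field_series(snaps[[1]]$grid, lapply(snaps, `[[`, "u"),
                    dt = meta$dt, T_cycle = meta$T_cycle,
                    t0 = meta$times[1])
  s$provenance <- meta$provenance
  s
}
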