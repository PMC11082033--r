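#' Blood-stagnation criteria
#'
#' Cells are stagnant when the time-averaged velocity magnitude is below
#' `velocity` AND the strain rate is below `strain_rate`. Defaults are the
#' standard thresholds 0.001 m/s and 100 1/s.
#'
#' @param velocity Velocity threshold, m/s.
#' @param strain_rate Strain-rate threshold, 1/s.
#' @return List of class `stagnation_criteria`.
#' @export
stagnation_criteria <- function(velocity = 0.001, strain_rate = 100) {
  stopifnot(velocity > 0, strain_rate > 0)
  structure(list(velocity = velocity, strain_rate = strain_rate),
            class = "stagnation_criteria")
}

#' TAWSS classification bands
#'
#' Three-band wall-shear classification: low non-physiological below `low`
#' (default 0.3 Pa), physiological between the bounds, high
#' non-physiological above `high` (default 9 Pa). Faces exactly at a bound
#' are assigned to the physiological band (the named middle class), so the
#' three bands partition all faces.
#'
#' @param low Lower bound, Pa.
#' @param high Upper bound, Pa.
#' @return List of class `tawss_bands`.
#' @export
tawss_bands <- function(low = 0.3, high = 9) {
  stopifnot(low > 0, high > low)
  structure(list(low = low, high = high), class = "tawss_bands")
}

#' Time-averaged field of a series
#'
#' Arithmetic mean of the velocity snapshots over the trailing `window`
#' cycles (default: up to 5, mirroring a five-cycle averaging window), and
#' the derived time-averaged speed and strain-rate fields used by the
#' stagnation criterion. Two conventions are available for both the speed
#' and the strain rate:
#'
#' * speed `"mean_vector"` (default): magnitude of the time-averaged
#'   velocity vector, so oscillatory-but-netless motion counts as
#'   stagnant; `"mean_magnitude"`: time average of the instantaneous
#'   speed.
#' * strain `"of_mean"` (default): strain rate of the time-averaged
#'   field; `"time_mean"`: time average of the instantaneous strain rate.
#'
#' @param series A [field_series()].
#' @param window Averaging window, cycles; `NULL` means `min(5, available)`.
#' @param speed,strain Convention switches, see above.
#' @return List of class `field_average` with `u_mean` (array), `speed`
#'   (array, m/s), `gamma_dot` (array, 1/s), `grid`, `window`.
#' @export
time_average <- function(series, window = NULL,
                         speed = c("mean_vector", "mean_magnitude"),
                         strain = c("of_mean", "time_mean")) {
  speed <- match.arg(speed)
  strain <- match.arg(strain)
  avail <- series_cycles(series)
  if (is.null(window)) window <- min(5L, max(avail, 1L))
  n_take <- min(length(series$u), window * series$n_per_cycle)
  if (window > avail && avail >= 1) {
    stop("averaging window of ", window, " cycles exceeds the ", avail,
         " available")
  }
  idx <- seq(length(series$u) - n_take + 1L, length(series$u))
  g <- series$grid
  u_mean <- Reduce(`+`, series$u[idx]) / length(idx)

  speed_field <- if (speed == "mean_vector") {
    sqrt(u_mean[, , , 1]^2 + u_mean[, , , 2]^2 + u_mean[, , , 3]^2)
  } else {
    Reduce(`+`, lapply(series$u[idx], function(u) {
      sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
    })) / length(idx)
  }
  gamma <- if (strain == "of_mean") {
    strain_rate(velocity_gradient(field_snapshot(g, u_mean)))
  } else {
    Reduce(`+`, lapply(series$u[idx], function(u) {
      strain_rate(velocity_gradient(field_snapshot(g, u)))
    })) / length(idx)
  }
  structure(list(u_mean = u_mean, speed = array(speed_field, g$dims),
                 gamma_dot = gamma, grid = g, window = window),
            class = "field_average")
}

#' Blood stagnation volume
#'
#' Volume of in-domain cells whose time-averaged velocity AND strain rate
#' both fall below the thresholds.
#'
#' @param x A [field_series()] or a precomputed [time_average()] result.
#' @param crit A [stagnation_criteria()].
#' @param ... Passed to [time_average()] when `x` is a series.
#' @return List with `volume_ml` and the logical cell `mask` of stagnant
#'   cells.
#' @export
stagnation_volume <- function(x, crit = stagnation_criteria(), ...) {
  avg <- if (inherits(x, "field_average")) x else time_average(x, ...)
  g <- avg$grid
  stag <- g$mask & (avg$speed < crit$velocity) &
    (avg$gamma_dot < crit$strain_rate)
  list(volume_ml = sum(stag) * g$cell_volume * 1e6, mask = stag)
}

#' Instantaneous wall shear stress
#'
#' Magnitude of the tangential traction on each wall face, estimated as
#' the local Carreau viscosity times the wall-normal gradient of the
#' tangential velocity at the first in-domain cell, with no-slip assumed
#' at the wall (the cell center sits half a spacing from the face, so the
#' gradient is `|u_t| / (h/2)`). Exact for a linear (Couette) profile.
#'
#' @param snap A [field_snapshot()].
#' @param visc A [viscosity_params()].
#' @return Numeric vector, Pa, one entry per row of
#'   `snap$grid$wall_faces`.
#' @export
wss <- function(snap, visc = viscosity_params()) {
  g <- snap$grid
  wf <- g$wall_faces
  if (!nrow(wf)) return(numeric())
  n <- prod(g$dims)
  u1 <- snap$u[wf$cell]
  u2 <- snap$u[wf$cell + n]
  u3 <- snap$u[wf$cell + 2L * n]
  # drop the normal component (normals are axis-aligned)
  ut_sq <- u1^2 + u2^2 + u3^2 -
    ifelse(wf$axis == 1, u1, ifelse(wf$axis == 2, u2, u3))^2
  half_h <- g$spacing[wf$axis] / 2
  gamma <- sqrt(pmax(ut_sq, 0)) / half_h
  carreau_viscosity(gamma, visc) * gamma
}

#' Time-averaged wall shear stress with band classification
#'
#' TAWSS per wall face (time mean of the instantaneous wall-shear
#' magnitude over the trailing `window` cycles), its area-weighted mean,
#' and the area fractions of the three bands of [tawss_bands()]. The
#' fractions partition the wall: they sum to one.
#'
#' @param series A [field_series()].
#' @param bands A [tawss_bands()].
#' @param visc A [viscosity_params()].
#' @param window Averaging window, cycles; `NULL` means all full cycles
#'   available (capped at 5).
#' @return List with `tawss` (Pa per face), `area_weighted_mean_Pa`,
#'   `band_fractions` (named: low, physiological, high) and `band` (factor
#'   per face).
#' @export
tawss <- function(series, bands = tawss_bands(), visc = viscosity_params(),
                  window = NULL) {
  g <- series$grid
  avail <- series_cycles(series)
  if (is.null(window)) window <- min(5L, max(avail, 1L))
  n_take <- min(length(series$u), window * series$n_per_cycle)
  idx <- seq(length(series$u) - n_take + 1L, length(series$u))
  acc <- numeric(nrow(g$wall_faces))
  for (i in idx) {
    acc <- acc + wss(field_snapshot(g, series$u[[i]],
                                    series$times[i]), visc)
  }
  ta <- acc / length(idx)
  a <- g$wall_faces$area
  band <- cut(ta, c(-Inf, bands$low - .Machine$double.eps, bands$high, Inf),
              labels = c("low", "physiological", "high"))
  # bounds belong to the physiological (middle) band
  band[ta >= bands$low & ta <= bands$high] <- "physiological"
  fr <- tapply(a, band, sum, default = 0) / sum(a)
  fr <- stats::setNames(as.numeric(fr[c("low", "physiological", "high")]),
                        c("low", "physiological", "high"))
  list(tawss = ta,
       area_weighted_mean_Pa = sum(ta * a) / sum(a),
       band_fractions = fr,
       band = band)
}

#' Cycle-averaged kinetic energy
#'
#' Volume integral of the flow kinetic energy,
#' \eqn{KE = \tfrac12 \rho \sum_c |u_c|^2 V_c}, per snapshot and averaged
#' over the trailing cycle(s).
#'
#' @param series A [field_series()].
#' @param visc A [viscosity_params()] (supplies the density).
#' @param window Averaging window, cycles; `NULL` means one trailing cycle.
#' @return List with `mean_mJ` and `per_snapshot_mJ`.
#' @export
kinetic_energy <- function(series, visc = viscosity_params(),
                           window = NULL) {
  g <- series$grid
  if (is.null(window)) window <- 1L
  n_take <- min(length(series$u), window * series$n_per_cycle)
  idx <- seq(length(series$u) - n_take + 1L, length(series$u))
  ke <- vapply(series$u[idx], function(u) {
    0.5 * visc$rho * sum(u^2) * g$cell_volume * 1e3   # J -> mJ
  }, numeric(1))
  list(mean_mJ = mean(ke), per_snapshot_mJ = ke)
}

#' Velocity-magnitude profile along a monitoring line
#'
#' Samples the velocity by component-wise trilinear interpolation on the
#' cell-center lattice at uniformly spaced points along a segment and
#' returns the interpolated speed. Points whose interpolation stencil
#' leaves the mask are flagged missing (`NA`).
#'
#' @param x A [field_snapshot()], or a plain velocity array with `grid`
#'   given.
#' @param from,to Segment end points, m (length-3).
#' @param n Number of sample points.
#' @param grid Required when `x` is a plain array.
#' @return Data frame with columns `s` (arc length, m), `x`, `y`, `z` and
#'   `speed` (m/s, `NA` outside the domain).
#' @export
line_profile <- function(x, from, to, n = 50, grid = NULL) {
  if (inherits(x, "field_snapshot")) {
    grid <- x$grid
    u <- x$u
  } else {
    stopifnot(inherits(grid, "field_grid"))
    u <- x
  }
  ts <- seq(0, 1, length.out = n)
  pts <- cbind(from[1] + ts * (to[1] - from[1]),
               from[2] + ts * (to[2] - from[2]),
               from[3] + ts * (to[3] - from[3]))
  comps <- vapply(1:3, function(k) {
    .trilinear(array(u[, , , k], grid$dims), grid, pts)
  }, numeric(n))
  if (all(is.na(comps))) warning("monitoring line does not intersect domain")
  data.frame(s = ts * sqrt(sum((to - from)^2)),
             x = pts[, 1], y = pts[, 2], z = pts[, 3],
             speed = sqrt(rowSums(comps^2)))
}

# trilinear interpolation at points (rows of pts) of cell-centred values;
# NA where a stencil corner is outside the grid or the mask
.trilinear <- function(F, grid, pts) {
  d <- grid$dims; h <- grid$spacing; o <- grid$origin
  out <- rep(NA_real_, nrow(pts))
  fc <- sapply(1:3, function(a) (pts[, a] - o[a]) / h[a])  # 0-based coords
  i0 <- floor(fc)
  w <- fc - i0
  ok <- rep(TRUE, nrow(pts))
  for (a in 1:3) ok <- ok & i0[, a] >= 0 & i0[, a] <= d[a] - 2
  if (!any(ok)) return(out)
  val <- numeric(sum(ok))
  valid <- rep(TRUE, sum(ok))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ii <- cbind(i0[ok, 1] + dx + 1, i0[ok, 2] + dy + 1, i0[ok, 3] + dz + 1)
    wt <- (if (dx == 1) w[ok, 1] else 1 - w[ok, 1]) *
          (if (dy == 1) w[ok, 2] else 1 - w[ok, 2]) *
          (if (dz == 1) w[ok, 3] else 1 - w[ok, 3])
    val <- val + wt * F[ii]
    valid <- valid & grid$mask[ii]
  }
  val[!valid] <- NA_real_
  out[ok] <- val
  out
}
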