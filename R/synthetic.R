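#' Synthetic ventricle-flow case parameters
#'
#' Parameter set of the synthetic pulsatile velocity-field generator: an
#' ellipsoidal ventricle-like cavity with a tricuspid-surrogate inflow jet
#' entering near the base, an interior regularized point sink standing in
#' for the assist-device inflow-cannula tip, and a solenoidal
#' recirculation component. The sink sits on the long axis at
#' `tip_offset + depth` below the jet entry plane, so `depth` is the
#' cannulation-length surrogate: deeper insertion moves the tip farther
#' from the inflow, lengthening the jet path toward the apex (the study
#' family: 5, 10, 15 and 25 mm).
#'
#' @param semi_axes Ellipsoid semi-axes, m (x, y, z; z is the long axis).
#' @param resolution Cells per axis (>= 16).
#' @param depth Cannulation-depth surrogate, m.
#' @param tip_offset Base distance from the jet entry plane to the tip at
#'   zero depth, m.
#' @param inlet_center_xy Lateral position of the inlet disc center, m.
#' @param inlet_radius Inlet disc radius, m.
#' @param jet_radius Gaussian jet core radius, m.
#' @param jet_speed Peak jet speed, m/s.
#' @param suction_length Screening length of the sink's suction field, m
#'   (confined-chamber suction is local, not free-space potential flow).
#'   `NULL` (default) ties the reach to the insertion depth,
#'   `tip_offset / 2 + depth + 0.015`, so a deeper tip draws from a
#'   broader region of the chamber.
#' @param recirc_frac Peak recirculation speed as a fraction of
#'   `jet_speed`.
#' @param swirl_frac Peak speed of the basal azimuthal swirl (the
#'   annulus-adjacent rotational flow the inflow maintains across the
#'   base, independent of cannula depth) as a fraction of `jet_speed`.
#' @param cycle_length Cardiac cycle, s.
#' @param cycles Number of cycles generated.
#' @param n_per_cycle Snapshots per cycle.
#' @param waveform `NULL` for the built-in two-peak (E/A) inflow shape, or
#'   an [lpm_read_waveforms()] / [lpm_export_waveforms()] object whose
#'   tricuspid inflow (normalized to unit peak) modulates the field.
#' @param projection_passes Divergence-cleaning projection passes.
#' @param seed Integer seed (jitters the recirculation center;
#'   deterministic output for a fixed seed).
#' @return List of class `synthetic_case_params`.
#' @export
synthetic_case_params <- function(semi_axes = c(0.030, 0.025, 0.045),
                                  resolution = c(32, 32, 32),
                                  depth = 0.010,
                                  tip_offset = 0.030,
                                  inlet_center_xy = c(0.0105, 0),
                                  inlet_radius = 0.010,
                                  jet_radius = 0.0067,
                                  jet_speed = 1.2,
                                  suction_length = NULL,
                                  recirc_frac = 0.25,
                                  swirl_frac = 0.06,
                                  cycle_length = 0.8,
                                  cycles = 3,
                                  n_per_cycle = 20,
                                  waveform = NULL,
                                  projection_passes = 1,
                                  seed = 1) {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0),
            all(resolution >= 16), cycle_length > 0, cycles >= 1,
            depth > 0, jet_speed > 0, n_per_cycle >= 4)
  p <- structure(as.list(environment()), class = "synthetic_case_params")
  # tip must lie inside the cavity
  geom <- .case_geometry(p)
  rel <- (geom$sink[1] / semi_axes[1])^2 + (geom$sink[2] / semi_axes[2])^2 +
    (geom$sink[3] / semi_axes[3])^2
  if (rel >= 0.95) stop("sink (cannula tip) falls outside the cavity")
  p
}

# inlet entry plane and sink (tip) location in domain coordinates
# (cavity centered at the origin)
.case_geometry <- function(p) {
  a <- p$semi_axes
  xy <- p$inlet_center_xy
  ztop <- a[3] * sqrt(max(0, 1 - (xy[1] / a[1])^2 - (xy[2] / a[2])^2))
  z_entry <- ztop - 2 * (2 * a[3] / p$resolution[3])   # two cells inboard
  list(entry = c(xy[1], xy[2], z_entry),
       sink = c(0, 0, z_entry - p$tip_offset - p$depth))
}

#' Ellipsoidal ventricle-like domain
#'
#' Builds the masked grid: cells whose centers satisfy the ellipsoid
#' inequality are in-domain. The grid spans the bounding box of the
#' ellipsoid; at the default resolution the voxelized volume is within 1%
#' of the analytic \eqn{4\pi abc/3}.
#'
#' @param p A [synthetic_case_params()].
#' @return A [field_grid()].
#' @export
make_domain <- function(p) {
  stopifnot(inherits(p, "synthetic_case_params"))
  a <- p$semi_axes
  if (any(a <= 0)) stop("degenerate semi-axes")
  d <- as.integer(p$resolution)
  h <- 2 * a / d
  origin <- -a + h / 2
  g0 <- field_grid(d, h, origin = origin)
  co <- grid_coords(g0)
  mask <- (co$x / a[1])^2 + (co$y / a[2])^2 + (co$z / a[3])^2 <= 1
  field_grid(d, h, mask, origin = origin)
}

#' Built-in two-peak (E/A) inflow pulsatility
#'
#' Diastolic filling shape over one cycle: an early-filling (E) peak and a
#' later atrial-kick (A) peak, as two Gaussians at 46% and 87% of the
#' cycle with relative weight 0.55 for the A wave, normalized to unit
#' peak. Non-negative everywhere.
#'
#' @param t Time, s (vectorized; interpreted modulo the cycle).
#' @param T_cycle Cycle length, s.
#' @return Dimensionless amplitude in `[0, 1]`.
#' @export
pulsatility_ea <- function(t, T_cycle = 0.8) {
  tau <- (t / T_cycle) %% 1
  raw <- function(x) {
    exp(-((x - 0.46) / 0.07)^2) + 0.55 * exp(-((x - 0.87) / 0.05)^2)
  }
  pk <- max(raw(seq(0, 1, length.out = 2001)))
  raw(tau) / pk
}

# pulsatility samples at the snapshot times, unit peak
.pulsatility <- function(p, times) {
  if (is.null(p$waveform)) {
    pulsatility_ea(times, p$cycle_length)
  } else {
    w <- p$waveform
    q <- w$tricuspid_inflow_ml_s
    if (max(q) <= 0) return(rep(0, length(times)))
    f <- stats::approxfun(w$time_s, q / max(q), rule = 2)
    f(times %% attr(w, "T_cycle"))
  }
}

# discrete divergence of a face-flux set (1/s per cell)
.flux_divergence <- function(flux, grid) {
  div <- array(0, grid$dims)
  for (a in 1:3) {
    div <- div + flux[[a]] - .shift_array(flux[[a]], a, -1, fill = 0)
  }
  div / grid$cell_volume * grid$mask
}

# face-average discrete divergence of a cell-centred field, 1/s
.divergence <- function(u, grid) {
  .flux_divergence(.face_fluxes(u, grid), grid)
}

# compact 7-point Neumann Laplacian on the masked cells (negated: PSD)
.masked_laplacian <- function(grid) {
  d <- grid$dims
  idx <- array(0L, d)
  cells <- which(grid$mask)
  idx[cells] <- seq_along(cells)
  ii <- jj <- integer(0)
  xx <- numeric(0)
  diag_acc <- numeric(length(cells))
  for (a in 1:3) {
    w <- 1 / grid$spacing[a]^2
    open <- grid$mask & .shift_array(grid$mask, a, +1, fill = FALSE)
    lo <- which(open)
    if (!length(lo)) next
    hi_idx <- idx[.shift_array(idx, a, +1, fill = 0L) > 0 & open]
    # linear index of the +a neighbor
    stride <- c(1L, d[1], d[1] * d[2])[a]
    i1 <- idx[lo]
    i2 <- idx[lo + stride]
    ii <- c(ii, i1, i2)
    jj <- c(jj, i2, i1)
    xx <- c(xx, rep(-w, 2 * length(lo)))
    diag_acc[i1] <- diag_acc[i1] + w
    diag_acc[i2] <- diag_acc[i2] + w
  }
  M <- Matrix::sparseMatrix(i = c(ii, seq_along(cells)),
                            j = c(jj, seq_along(cells)),
                            x = c(xx, diag_acc),
                            dims = c(length(cells), length(cells)))
  # Ground the Neumann nullspace by fixing phi = 0 at cell 1 and solving
  # the reduced (SPD) system on the remaining cells; with a compatible
  # right-hand side the dropped equation is satisfied automatically
  # because the Laplacian's rows sum to zero. The sparse Cholesky factor
  # is cached for reuse across patterns and passes.
  M2 <- M[-1, -1, drop = FALSE]
  list(M = M, chol = Matrix::Cholesky(M2, LDL = FALSE, super = TRUE),
       cells = cells, idx = idx)
}

# Staggered projection: solves the compact Neumann Poisson problem for a
# potential whose FACE gradient removes the divergence of the face fluxes
# exactly (to solver precision) on every cell outside `source_cells`.
# Returns the corrected face fluxes (exactly mass-conserving — these drive
# the scalar transport) and the cell-centred velocity corrected with the
# averaged face gradients (second-order consistent; used by the gradient /
# WSS / energy kernels, where exact discrete solenoidality is immaterial).
.project_pattern <- function(u, grid, lap, source_cells = integer()) {
  flux <- .face_fluxes(u, grid)
  div <- .flux_divergence(flux, grid)
  rhs <- -as.vector(div)[lap$cells]   # M is the negated Laplacian
  src <- lap$idx[source_cells]
  src <- src[src > 0]
  rhs[src] <- 0
  free <- setdiff(seq_along(rhs), src)
  rhs[free] <- rhs[free] - mean(rhs[free])   # Neumann compatibility
  phi_v <- c(0, as.numeric(Matrix::solve(lap$chol, rhs[-1],
                                         system = "A")))
  phi <- array(0, grid$dims)
  phi[lap$cells] <- phi_v

  h <- grid$spacing
  areas <- c(h[2] * h[3], h[1] * h[3], h[1] * h[2])
  for (a in 1:3) {
    open <- grid$mask & .shift_array(grid$mask, a, +1, fill = FALSE)
    gface <- (.shift_array(phi, a, +1, fill = 0) - phi) / h[a] * open
    flux[[a]] <- flux[[a]] - gface * areas[a]
    glo <- .shift_array(gface, a, -1, fill = 0)
    u[, , , a] <- u[, , , a] - 0.5 * (gface + glo)
  }
  list(u = u * as.vector(grid$mask), flux = flux,
       div = .flux_divergence(flux, grid))
}

#' Generate a synthetic pulsatile ventricle-flow series
#'
#' Builds the spatial flow pattern — Gaussian inflow jet decaying toward
#' the sink, screened regularized point sink at the cannula-tip surrogate,
#' and an analytically solenoidal recirculation cell — rebalances the
#' discrete jet/sink fluxes so they cancel exactly, cleans the residual
#' divergence with sparse-Poisson projection passes (divergence is allowed
#' only at the inlet and sink cells), and modulates the pattern with the
#' pulsatility waveform. Deterministic for a fixed seed.
#'
#' @param p A [synthetic_case_params()].
#' @return A [field_series()] with extra elements `provenance` (the
#'   parameters, seed and divergence diagnostic), `inlet_cells`,
#'   `sink_cells`.
#' @export
make_series <- function(p) {
  stopifnot(inherits(p, "synthetic_case_params"))
  g <- make_domain(p)
  co <- grid_coords(g)
  geom <- .case_geometry(p)
  sink <- geom$sink
  entry <- geom$entry

  # seed only the generator's own RNG stream
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(p$seed)
  jitter <- stats::runif(3, -0.002, 0.002)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  U <- p$jet_speed
  rj <- p$jet_radius
  L_jet <- p$tip_offset + p$depth + 0.005
  r2 <- (co$x - entry[1])^2 + (co$y - entry[2])^2
  ax_decay <- exp(-pmax(entry[3] - co$z, 0) / L_jet)
  jet <- array(0, c(g$dims, 3L))
  jet[, , , 3] <- -U * exp(-r2 / rj^2) * ax_decay

  # basal azimuthal swirl u = Omega(z) (-y, x, 0): solenoidal by
  # construction (and exactly so on the discrete face-average divergence,
  # since u_x is independent of x and u_y of y)
  Om <- p$swirl_frac * U / p$semi_axes[1] *
    exp(-((co$z - (entry[3] - 0.004)) / 0.010)^2)
  jet[, , , 1] <- jet[, , , 1] - Om * co$y
  jet[, , , 2] <- jet[, , , 2] + Om * co$x

  # screened, regularized point sink of unit volumetric strength; the
  # suction reach grows with insertion depth unless overridden
  L_suction <- if (is.null(p$suction_length)) {
    p$tip_offset / 2 + p$depth + 0.015
  } else p$suction_length
  eps <- 1.5 * max(g$spacing)
  dx <- co$x - sink[1]; dy <- co$y - sink[2]; dz <- co$z - sink[3]
  rr2 <- dx^2 + dy^2 + dz^2
  coef <- -exp(-rr2 / L_suction^2) / (4 * pi * (rr2 + eps^2)^1.5)
  s_unit <- array(0, c(g$dims, 3L))
  s_unit[, , , 1] <- coef * dx
  s_unit[, , , 2] <- coef * dy
  s_unit[, , , 3] <- coef * dz

  # source cells where divergence is physical (inlet disc, sink core)
  inlet_cells <- which(g$mask & r2 <= p$inlet_radius^2 &
                         co$z >= entry[3] - 1.5 * g$spacing[3])
  sink_cells <- which(g$mask & rr2 <= (2.2 * max(g$spacing))^2)
  if (!length(inlet_cells)) stop("inlet disc does not intersect the domain")
  source_cells <- c(inlet_cells, sink_cells)

  # scale the sink so the free-region divergence integrates to zero:
  # the projection then removes it entirely and the discrete sink outflux
  # balances the discrete jet influx
  msk <- as.vector(g$mask)
  free_sum <- function(u_arr) {
    d <- .divergence(u_arr * msk, g)
    sum(d) - sum(d[source_cells])
  }
  Q_s <- -free_sum(jet) / free_sum(s_unit)
  base <- (jet + Q_s * s_unit) * msk

  # solenoidal recirculation: curl of a Gaussian vector potential (y-axis)
  rc <- c(0.004, 0, (entry[3] + sink[3]) / 2) + jitter
  w_rc <- 0.35 * p$semi_axes[1]
  A_rc <- p$recirc_frac * U * w_rc / (sqrt(2) * exp(-0.5))
  q2 <- ((co$x - rc[1])^2 + (co$y - rc[2])^2 + (co$z - rc[3])^2) / w_rc^2
  psi <- A_rc * exp(-q2)
  recirc <- array(0, c(g$dims, 3L))
  recirc[, , , 1] <- psi * (-2 * (co$z - rc[3]) / w_rc^2)
  recirc[, , , 3] <- -psi * (-2 * (co$x - rc[1]) / w_rc^2)
  recirc <- recirc * msk

  lap <- .masked_laplacian(g)
  pa <- .project_pattern(base, g, lap, source_cells)
  pb <- .project_pattern(recirc, g, lap)
  for (k in seq_len(max(0L, p$projection_passes - 1L))) {
    pa <- .project_pattern(pa$u, g, lap, source_cells)
    pb <- .project_pattern(pb$u, g, lap)
  }
  div_a <- pa$div
  div_a[source_cells] <- 0
  div_resid <- max(abs(div_a), abs(pb$div))

  # pulsatility drives the through-flow; the recirculation cell carries
  # the zero-mean (oscillatory) part, so the time-averaged field is the
  # jet/sink pattern alone at the mean inflow amplitude
  times <- (seq_len(p$cycles * p$n_per_cycle) - 1) *
    p$cycle_length / p$n_per_cycle
  amp <- .pulsatility(p, times)
  amp_rc <- amp - mean(amp[seq_len(p$n_per_cycle)])
  u_list <- lapply(seq_along(times), function(k) {
    pa$u * amp[k] + pb$u * amp_rc[k]
  })
  series <- field_series(g, u_list,
                         dt = p$cycle_length / p$n_per_cycle,
                         T_cycle = p$cycle_length)
  series$inlet_cells <- inlet_cells
  series$sink_cells <- sink_cells
  series$flux_patterns <- list(pa$flux, pb$flux)
  series$amps <- cbind(amp, amp_rc)
  series$patterns <- list(through_flow = pa$u, recirculation = pb$u)
  series$provenance <- list(
    params = p[setdiff(names(p), "waveform")],
    waveform_supplied = !is.null(p$waveform),
    sink_strength_m3s = Q_s,
    divergence_residual = div_resid,
    divergence_bound = 1e-3 * U / min(g$spacing))
  if (div_resid > series$provenance$divergence_bound) {
    warning(sprintf(
      "post-projection divergence %.3g exceeds bound %.3g 1/s",
      div_resid, series$provenance$divergence_bound))
  }
  series
}
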