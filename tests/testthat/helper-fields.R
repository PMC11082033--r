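# Small analytic field fixtures built in code.

# full rectangular box grid (all cells in-domain)
box_grid <- function(dims, spacing = rep(1e-3, 3)) {
  field_grid(dims, spacing)
}

# slab for Couette/Poiseuille profiles: z in (0, H), walls top and bottom
slab_snapshot <- function(nz, profile, nx = 6, ny = 5, H = 0.01) {
  h <- H / nz
  g <- field_grid(c(nx, ny, nz), c(h, h, h))
  co <- grid_coords(g)
  u <- array(0, c(g$dims, 3L))
  u[, , , 1] <- profile(co$z)
  field_snapshot(g, u)
}

# straight channel along x (3 x 3 cross-section), uniform speed u0
channel_series <- function(nx = 64, u0 = 0.1, dx = 1e-3, dt = 0.01,
                           n_per_cycle = 20) {
  g <- field_grid(c(nx, 3, 3), c(dx, dx, dx))
  u <- array(0, c(g$dims, 3L))
  u[, , , 1] <- u0
  field_series(g, rep(list(u), n_per_cycle), dt = dt,
               T_cycle = dt * n_per_cycle)
}

# linear indices of the first-column (x = 1) cells of a grid
first_slab_cells <- function(g) {
  which(slice.index(array(0, g$dims), 1) == 1 & g$mask)
}

# smooth trigonometric velocity field with analytic gradient
trig_field <- function(g) {
  co <- grid_coords(g)
  L <- g$dims * g$spacing
  kx <- 2 * pi / L[1]; ky <- 2 * pi / L[2]; kz <- 2 * pi / L[3]
  u <- array(0, c(g$dims, 3L))
  u[, , , 1] <- sin(kx * co$x) * cos(ky * co$y)
  u[, , , 2] <- cos(kz * co$z)
  u[, , , 3] <- sin(ky * co$y) * sin(kz * co$z)
  grad <- array(0, c(g$dims, 3L, 3L))
  grad[, , , 1, 1] <- kx * cos(kx * co$x) * cos(ky * co$y)
  grad[, , , 1, 2] <- -ky * sin(kx * co$x) * sin(ky * co$y)
  grad[, , , 2, 3] <- -kz * sin(kz * co$z)
  grad[, , , 3, 2] <- ky * cos(ky * co$y) * sin(kz * co$z)
  grad[, , , 3, 3] <- kz * sin(ky * co$y) * cos(kz * co$z)
  list(snap = field_snapshot(g, u), grad = grad)
}

# small, fast synthetic case for structural tests
small_case <- function(resolution = c(16, 16, 16), ...) {
  synthetic_case_params(resolution = resolution, cycles = 2,
                        n_per_cycle = 10, ...)
}

.field_cache <- new.env(parent = emptyenv())
small_series_cached <- function() {
  if (is.null(.field_cache$series)) {
    .field_cache$series <- make_series(small_case())
  }
  .field_cache$series
}
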