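test_that("time averaging: constant, alternating and sinusoidal series", {
  g <- box_grid(c(6, 6, 6))
  u <- array(0.2, c(g$dims, 3L))
  const <- field_series(g, rep(list(u), 8), dt = 0.1, T_cycle = 0.4)
  avg <- time_average(const)
  expect_equal(avg$u_mean, u)
  expect_equal(array(avg$speed, g$dims), array(sqrt(3 * 0.2^2), g$dims))

  alt <- field_series(g, rep(list(u, -u), 4), dt = 0.1, T_cycle = 0.4)
  a2 <- time_average(alt)
  expect_equal(max(abs(a2$u_mean)), 0)
  expect_equal(max(a2$speed), 0)
  # mean-of-magnitudes convention sees the motion
  a3 <- time_average(alt, speed = "mean_magnitude")
  expect_equal(array(a3$speed, g$dims), array(sqrt(3 * 0.2^2), g$dims))

  # sinusoidal modulation: sample mean vs continuous quadrature
  n <- 16
  amp <- 1 + 0.5 * sin(2 * pi * (0:(n - 1)) / n)
  sinser <- field_series(g, lapply(amp, function(a) u * a),
                         dt = 1 / n, T_cycle = 1)
  a4 <- time_average(sinser)
  oracle <- stats::integrate(function(t) 1 + 0.5 * sin(2 * pi * t),
                             0, 1)$value
  expect_equal(a4$u_mean[1, 1, 1, 1], 0.2 * oracle, tolerance = 1e-9)
  expect_error(time_average(const, window = 5), "window")
})

test_that("stagnation volume: all-stagnant, none, and a counted pocket", {
  g <- box_grid(c(8, 8, 8))
  zero <- field_series(g, rep(list(array(0, c(g$dims, 3L))), 4),
                       dt = 0.1, T_cycle = 0.4)
  res <- stagnation_volume(zero)
  expect_equal(res$volume_ml, g$n_cells * g$cell_volume * 1e6)

  fast <- array(0, c(g$dims, 3L))
  fast[, , , 1] <- 1
  fser <- field_series(g, rep(list(fast), 4), dt = 0.1, T_cycle = 0.4)
  expect_equal(stagnation_volume(fser)$volume_ml, 0)

  # constructed two-region field: an 8-cell quiescent pocket
  u <- fast
  u[1:2, 1:2, 1:2, 1] <- 0
  pser <- field_series(g, rep(list(u), 4), dt = 0.1, T_cycle = 0.4)
  res <- stagnation_volume(pser)
  # the pocket's interior cell(s) see zero velocity and low shear; cells
  # bordering the moving region exceed the strain-rate threshold
  pocket <- which(res$mask)
  expect_true(all(pocket %in% which(u[, , , 1] == 0)))
  expect_equal(res$volume_ml, length(pocket) * g$cell_volume * 1e6)
  expect_gt(length(pocket), 0)
})

test_that("stagnation volume is monotone in both thresholds", {
  s <- small_series_cached()
  avg <- time_average(s)
  vol <- function(v, sr) {
    stagnation_volume(avg, stagnation_criteria(v, sr))$volume_ml
  }
  v0 <- vol(0.001, 100)
  expect_lte(vol(0.0005, 100), v0)
  expect_gte(vol(0.002, 100), v0)
  expect_lte(vol(0.001, 50), v0)
  expect_gte(vol(0.001, 200), v0)
})

test_that("WSS: quiescent wall, Couette closed form, Poiseuille converges", {
  quiet <- slab_snapshot(8, function(z) 0 * z)
  expect_equal(max(abs(wss(quiet))), 0)

  # planar Couette: u_x = U z / H; wall traction = eta(U/H) * U / H
  U <- 0.3; H <- 0.01
  sn <- slab_snapshot(10, function(z) U * z / H, H = H)
  tau <- wss(sn)
  wf <- sn$grid$wall_faces
  bottom <- wf$axis == 3 & wf$side == -1
  gam <- U / H
  expect_equal(tau[bottom], rep(carreau_viscosity(gam) * gam, sum(bottom)),
               tolerance = 1e-9)

  # Poiseuille: u_x = 4 Um z (H - z) / H^2, wall shear rate 4 Um / H;
  # the first-cell estimator is first-order accurate
  Um <- 0.4
  err <- vapply(c(8, 16), function(nz) {
    s <- slab_snapshot(nz, function(z) 4 * Um * z * (H - z) / H^2, H = H)
    t2 <- wss(s)
    b <- s$grid$wall_faces$axis == 3 & s$grid$wall_faces$side == -1
    gw <- 4 * Um / H
    mean(abs(t2[b] - carreau_viscosity(gw) * gw)) /
      (carreau_viscosity(gw) * gw)
  }, numeric(1))
  expect_lt(err[2], 0.75 * err[1])
  expect_lt(err[2], 0.1)
})

test_that("TAWSS matches a per-face brute-force oracle with exact bands", {
  g <- box_grid(c(6, 6, 8), spacing = rep(5e-4, 3))
  co <- grid_coords(g)
  H <- g$dims[3] * g$spacing[3]
  u <- array(0, c(g$dims, 3L))
  u[, , , 1] <- 30 * co$z * (H - co$z) / H   # strongly sheared in z
  ser <- field_series(g, list(u, u * 0.5), dt = 0.1, T_cycle = 0.2)
  res <- tawss(ser)

  # independent face-by-face computation
  wf <- g$wall_faces
  n <- prod(g$dims)
  oracle <- vapply(seq_len(nrow(wf)), function(f) {
    tau_t <- vapply(c(1, 0.5), function(a) {
      uv <- c(u[wf$cell[f]], u[wf$cell[f] + n], u[wf$cell[f] + 2 * n]) * a
      uv[wf$axis[f]] <- 0
      gam <- sqrt(sum(uv^2)) / (g$spacing[wf$axis[f]] / 2)
      carreau_viscosity(gam) * gam
    }, numeric(1))
    mean(tau_t)
  }, numeric(1))
  expect_equal(res$tawss, oracle, tolerance = 1e-12)
  expect_equal(sum(res$band_fractions), 1, tolerance = 1e-9)
  fr_oracle <- c(
    low = sum(wf$area[oracle < 0.3]),
    physiological = sum(wf$area[oracle >= 0.3 & oracle <= 9]),
    high = sum(wf$area[oracle > 9])) / sum(wf$area)
  expect_equal(unname(unlist(res$band_fractions)), unname(fr_oracle),
               tolerance = 1e-12)
  expect_equal(res$area_weighted_mean_Pa,
               sum(oracle * wf$area) / sum(wf$area), tolerance = 1e-12)
})

test_that("TAWSS of a steady series equals the instantaneous WSS", {
  sn <- slab_snapshot(8, function(z) 0.2 * z / 0.01)
  ser <- field_series(sn$grid, rep(list(sn$u), 4), dt = 0.1, T_cycle = 0.2)
  expect_equal(tawss(ser)$tawss, wss(sn), tolerance = 1e-12)
})

test_that("kinetic energy: zero, uniform closed form, pulsatile quadrature", {
  g <- box_grid(c(8, 8, 8))
  zero <- field_series(g, rep(list(array(0, c(g$dims, 3L))), 4),
                       dt = 0.1, T_cycle = 0.4)
  expect_equal(kinetic_energy(zero)$mean_mJ, 0)

  u0 <- 0.25
  u <- array(0, c(g$dims, 3L))
  u[, , , 2] <- u0
  uni <- field_series(g, rep(list(u), 4), dt = 0.1, T_cycle = 0.4)
  V <- g$n_cells * g$cell_volume
  expect_equal(kinetic_energy(uni)$mean_mJ, 0.5 * 1060 * u0^2 * V * 1e3,
               tolerance = 1e-12)

  amp <- c(0.2, 0.9, 1.4, 0.6)
  pul <- field_series(g, lapply(amp, function(a) u * a),
                      dt = 0.1, T_cycle = 0.4)
  oracle <- mean(0.5 * 1060 * (u0 * amp)^2 * V * 1e3)   # trapezoid on a
  expect_equal(kinetic_energy(pul)$mean_mJ, oracle, tolerance = 1e-12)
})

test_that("line profiles: constant, linear exactness, dense oracle", {
  g <- box_grid(c(12, 12, 12))
  u <- array(0, c(g$dims, 3L))
  u[, , , 1] <- 0.4
  snap <- field_snapshot(g, u)
  ext <- g$dims * g$spacing
  from <- ext * 0.25; to <- ext * 0.75
  pr <- line_profile(snap, from, to, n = 21)
  expect_equal(pr$speed, rep(0.4, 21))

  co <- grid_coords(g)
  ul <- array(0, c(g$dims, 3L))
  ul[, , , 1] <- 2 + 100 * co$x + 50 * co$y - 30 * co$z
  prl <- line_profile(field_snapshot(g, ul), from, to, n = 21)
  expect_equal(prl$speed,
               abs(2 + 100 * prl$x + 50 * prl$y - 30 * prl$z),
               tolerance = 1e-9)

  # smooth field: trilinear vs direct evaluation error shrinks with h
  err <- vapply(c(12, 24), function(n) {
    gg <- field_grid(rep(n, 3), rep(0.012 / n, 3))
    tf <- trig_field(gg)
    p <- line_profile(tf$snap, c(0.003, 0.004, 0.003),
                      c(0.009, 0.008, 0.009), n = 15)
    L <- gg$dims * gg$spacing
    truth <- sqrt((sin(2 * pi * p$x / L[1]) * cos(2 * pi * p$y / L[2]))^2 +
                  cos(2 * pi * p$z / L[3])^2 +
                  (sin(2 * pi * p$y / L[2]) * sin(2 * pi * p$z / L[3]))^2)
    max(abs(p$speed - truth))
  }, numeric(1))
  expect_lt(err[2], err[1] / 2.5)

  # samples outside the mask are flagged missing
  m <- array(TRUE, g$dims); m[, , 7:12] <- FALSE
  gm <- field_grid(g$dims, g$spacing, m)
  um <- array(0.1, c(gm$dims, 3L))
  prm <- line_profile(field_snapshot(gm, um), from, to, n = 21)
  expect_true(any(is.na(prm$speed)))
  expect_true(any(!is.na(prm$speed)))
})
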