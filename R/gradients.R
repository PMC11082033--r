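# Finite-difference kernels on the masked grid: velocity gradient tensor,
# strain rate and Q-criterion. Second-order central differences in the
# interior, one-sided first-order at mask boundaries, zero where a cell has
# no in-mask neighbor along an axis.

# derivative of one scalar array along one axis, mask-aware
.masked_deriv <- function(F, mask, axis, h) {
  Fp <- .shift_array(F, axis, +1, fill = 0)
  Fm <- .shift_array(F, axis, -1, fill = 0)
  mp <- .shift_array(mask, axis, +1, fill = FALSE)
  mm <- .shift_array(mask, axis, -1, fill = FALSE)
  both <- mp & mm
  d <- array(0, dim(F))
  d[both] <- (Fp[both] - Fm[both]) / (2 * h)
  fo <- mp & !mm
  d[fo] <- (Fp[fo] - F[fo]) / h
  ba <- mm & !mp
  d[ba] <- (F[ba] - Fm[ba]) / h
  d * mask
}

#' Velocity gradient tensor
#'
#' Cell-wise gradient `G[i,j] = du_i/dx_j` of a snapshot: second-order
#' central differences where both axis neighbors are in-domain, one-sided
#' differences at mask boundaries, zero where a cell has no in-mask
#' neighbor along an axis (a warning flags fully isolated cells).
#'
#' @param snap A [field_snapshot()].
#' @return Array of dimension `c(dims, 3, 3)`, 1/s; zero outside the mask.
#' @export
velocity_gradient <- function(snap) {
  g <- snap$grid
  G <- array(0, c(g$dims, 3L, 3L))
  for (i in 1:3) {
    Fi <- array(snap$u[, , , i], g$dims)
    for (j in 1:3) {
      G[, , , i, j] <- .masked_deriv(Fi, g$mask, j, g$spacing[j])
    }
  }
  nb <- Reduce(`|`, lapply(1:3, function(a) {
    .shift_array(g$mask, a, +1, FALSE) | .shift_array(g$mask, a, -1, FALSE)
  }))
  if (any(g$mask & !nb)) {
    warning("isolated single-cell region(s): gradient set to zero there")
  }
  G
}

#' Shear (strain) rate magnitude
#'
#' \eqn{\dot\gamma = \sqrt{2\,S\!:\!S}} with `S` the symmetric part of the
#' velocity gradient — the invariant the Carreau law consumes. Zero for
#' rigid-body rotation; equal to the shear rate `k` for simple shear.
#'
#' @param grad Gradient array from [velocity_gradient()].
#' @return Array of dimension `dims`, 1/s.
#' @export
strain_rate <- function(grad) {
  d <- dim(grad)[1:3]
  acc <- array(0, d)
  for (i in 1:3) for (j in 1:3) {
    S <- 0.5 * (grad[, , , i, j] + grad[, , , j, i])
    acc <- acc + S * S
  }
  sqrt(2 * acc)
}

#' Q-criterion vortex indicator
#'
#' \eqn{Q = \tfrac12(\|\Omega\|^2 - \|S\|^2)} (Frobenius norms of the
#' antisymmetric and symmetric parts of the velocity gradient): positive
#' where rotation dominates strain. For rigid rotation at rate
#' \eqn{\omega}, `Q` equals \eqn{\omega^2}; identically zero for any pure
#' shear.
#'
#' @param grad Gradient array from [velocity_gradient()].
#' @return Array of dimension `dims`, 1/s^2.
#' @export
q_criterion <- function(grad) {
  d <- dim(grad)[1:3]
  acc <- array(0, d)
  for (i in 1:3) for (j in 1:3) {
    S <- 0.5 * (grad[, , , i, j] + grad[, , , j, i])
    W <- 0.5 * (grad[, , , i, j] - grad[, , , j, i])
    acc <- acc + W * W - S * S
  }
  0.5 * acc
}

#' Volume where the Q-criterion exceeds a threshold
#'
#' The published visualisation threshold (a plain number, 325, carried
#' without resolving its printed units) is the default; the thresholded
#' volume quantifies how much of the domain is vortical, it is not itself
#' a thrombosis-risk metric.
#'
#' @param Q Array from [q_criterion()].
#' @param grid The [field_grid()] the field lives on.
#' @param threshold Threshold value (default 325).
#' @return Volume, ml.
#' @export
q_exceed_volume <- function(Q, grid, threshold = 325) {
  sum(Q > threshold & grid$mask) * grid$cell_volume * 1e6
}
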