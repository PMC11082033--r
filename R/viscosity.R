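#' Carreau blood-viscosity parameters
#'
#' Shear-thinning constitutive constants for blood,
#' \deqn{\eta(\dot\gamma) = \eta_\infty + (\eta_0-\eta_\infty)
#'   \left[1 + (\dot\gamma\lambda)^2\right]^{(N-1)/2},}
#' with the standard literature values as defaults: zero-shear viscosity
#' 0.056 kg/(m s), infinite-shear viscosity 0.00345 kg/(m s), relaxation
#' time 3.313 s, power index 0.3568, density 1060 kg/m^3.
#'
#' @param eta_inf Infinite-shear viscosity, kg/(m s).
#' @param eta_0 Zero-shear viscosity, kg/(m s).
#' @param lambda Relaxation time, s.
#' @param N Power-law index, dimensionless, in (0, 1).
#' @param rho Density, kg/m^3.
#' @return A list of class `viscosity_params`.
#' @export
viscosity_params <- function(eta_inf = 0.00345, eta_0 = 0.056,
                             lambda = 3.313, N = 0.3568, rho = 1060) {
  stopifnot(eta_0 > eta_inf, eta_inf > 0, lambda > 0, N > 0, N < 1, rho > 0)
  structure(list(eta_inf = eta_inf, eta_0 = eta_0, lambda = lambda,
                 N = N, rho = rho),
            class = "viscosity_params")
}

#' Carreau effective viscosity
#'
#' Evaluates the Carreau law at the given shear rates. Strictly decreasing
#' on positive shear rate, bounded in (`eta_inf`, `eta_0`].
#'
#' @param gamma_dot Shear rate, 1/s (vectorized, non-negative).
#' @param p A [viscosity_params()] object.
#' @return Viscosity, kg/(m s).
#' @export
carreau_viscosity <- function(gamma_dot, p = viscosity_params()) {
  if (any(gamma_dot < 0, na.rm = TRUE)) {
    stop("shear rate must be non-negative")
  }
  p$eta_inf + (p$eta_0 - p$eta_inf) *
    (1 + (gamma_dot * p$lambda)^2)^((p$N - 1) / 2)
}
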