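#' Principal stretches and strain invariants for incompressible uniaxial
#' extension
#'
#' Builds the kinematic state of an incompressible bar stretched uniaxially
#' to stretch ratio \eqn{\lambda}: \eqn{\lambda_1 = \lambda},
#' \eqn{\lambda_2 = \lambda_3 = \lambda^{-1/2}}, so that the third invariant
#' \eqn{I_3 = \lambda_1^2\lambda_2^2\lambda_3^2 = 1} (volume conservation).
#'
#' @param stretch stretch ratio \eqn{\lambda > 0}.
#' @return Object of class `stretch_state` with fields `lambda1..lambda3`
#'   and invariants `i1`, `i2`, `i3`.
#' @examples
#' uniaxial_state(2)  # i1 = 5, i2 = 4.25, i3 = 1
#' @export
uniaxial_state <- function(stretch) {
  check_scalar_number(stretch, "stretch", positive = TRUE)
  l1 <- stretch
  l2 <- stretch^(-0.5)
  l3 <- l2
  structure(
    list(
      lambda1 = l1, lambda2 = l2, lambda3 = l3,
      i1 = l1^2 + l2^2 + l3^2,
      i2 = 1 / l1^2 + 1 / l2^2 + 1 / l3^2,
      i3 = l1^2 * l2^2 * l3^2
    ),
    class = "stretch_state"
  )
}

#' Mooney-Rivlin strain-energy density
#'
#' \eqn{W = C_{10}(I_1-3) + C_{01}(I_2-3) + C_{11}(I_1-3)(I_2-3)}, in MPa.
#' Exactly zero in the undeformed state (\eqn{I_1 = I_2 = 3}).
#'
#' @param state a `stretch_state` (see [uniaxial_state()]) or a stretch
#'   ratio, in which case the uniaxial incompressible state is implied.
#' @param params a [mooney_rivlin()] object.
#' @return Energy density in MPa.
#' @examples
#' strain_energy(2, mooney_rivlin(1, 0, 0))  # I1 - 3 = 2
#' @export
strain_energy <- function(state, params) {
  if (!inherits(state, "stretch_state")) state <- uniaxial_state(state)
  a <- state$i1 - 3
  b <- state$i2 - 3
  params$c10 * a + params$c01 * b + params$c11 * a * b
}

# The three basis functions of the uniaxial Cauchy stress; stress is linear
# in (C10, C01, C11) with these as design columns.
mr_basis <- function(lambda) {
  cbind(
    b10 = 2 * (lambda^2 - 1 / lambda),
    b01 = 2 * (lambda - 1 / lambda^2),
    b11 = 6 * (lambda^3 - lambda^2 - lambda + 1 / lambda + 1 / lambda^2 -
                 1 / lambda^3)
  )
}

# d(basis)/d(lambda), for the analytic stress-stretch slope
mr_basis_deriv <- function(lambda) {
  cbind(
    2 * (2 * lambda + 1 / lambda^2),
    2 * (1 + 2 / lambda^3),
    6 * (3 * lambda^2 - 2 * lambda - 1 - 1 / lambda^2 - 2 / lambda^3 +
           3 / lambda^4)
  )
}

#' Uniaxial Cauchy stress of the three-parameter Mooney-Rivlin model
#'
#' \deqn{\sigma_1(\lambda) = 2C_{10}(\lambda^2 - 1/\lambda)
#'   + 2C_{01}(\lambda - 1/\lambda^2)
#'   + 6C_{11}(\lambda^3 - \lambda^2 - \lambda + 1/\lambda + 1/\lambda^2
#'             - 1/\lambda^3)}
#'
#' This is \eqn{\lambda \, dW/d\lambda} along the incompressible uniaxial
#' path; every bracket vanishes at \eqn{\lambda = 1}, so the undeformed
#' stress is exactly zero for any coefficients.
#'
#' @param stretch stretch ratio(s), > 0; vectorised.
#' @param params a [mooney_rivlin()] object.
#' @return Cauchy stress in MPa, same length as `stretch`.
#' @examples
#' uniaxial_stress(2, mooney_rivlin(1, 0, 0))  # 7 MPa
#' @export
uniaxial_stress <- function(stretch, params) {
  if (!is.numeric(stretch) || any(!is.finite(stretch)) || any(stretch <= 0)) {
    stop_pugraft("`stretch` must be finite and > 0", "pugraft_value_error")
  }
  drop(mr_basis(stretch) %*% c(params$c10, params$c01, params$c11))
}

#' Slope of the uniaxial stress-stretch curve
#'
#' Analytic \eqn{d\sigma_1/d\lambda}. At \eqn{\lambda = 1} this reduces to
#' \eqn{6(C_{10} + C_{01})}, the small-strain tangent modulus of the model.
#'
#' @inheritParams uniaxial_stress
#' @return Slope in MPa per unit stretch, same length as `stretch`.
#' @export
uniaxial_stress_deriv <- function(stretch, params) {
  if (!is.numeric(stretch) || any(!is.finite(stretch)) || any(stretch <= 0)) {
    stop_pugraft("`stretch` must be finite and > 0", "pugraft_value_error")
  }
  drop(mr_basis_deriv(stretch) %*% c(params$c10, params$c01, params$c11))
}
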