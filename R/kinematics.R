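# Uniaxial incompressible kinematics: principal stretches, deformation
# gradient and strain invariants for a specimen pulled along one axis.

#' Strain invariants for incompressible uniaxial stretch
#'
#' For an incompressible material stretched uniaxially to \eqn{\lambda}, the
#' transverse principal stretches are \eqn{\lambda^{-1/2}} and the invariants
#' of the Cauchy–Green tensor reduce to
#' \eqn{I_1 = \lambda^2 + 2/\lambda}, \eqn{I_2 = 2\lambda + 1/\lambda^2},
#' \eqn{I_3 = 1}.
#'
#' @param lambda principal stretch along the loading axis (> 0); vectorised.
#' @return A list of class `stretch_state` with components `lambda`,
#'   `lambda2`, `lambda3` (transverse stretches) and `I1`, `I2`, `I3`.
#' @examples
#' uniaxial_invariants(1.2)$I1  # 3.10667
#' @export
uniaxial_invariants <- function(lambda) {
  if (!is.numeric(lambda) || any(!is.finite(lambda)) || any(lambda <= 0)) {
    stopf("stretch must be positive and finite")
  }
  out <- list(
    lambda  = lambda,
    lambda2 = lambda^(-0.5),
    lambda3 = lambda^(-0.5),
    I1 = lambda^2 + 2 / lambda,
    I2 = 2 * lambda + 1 / lambda^2,
    I3 = rep(1, length(lambda))
  )
  class(out) <- "stretch_state"
  out
}

#' @export
print.stretch_state <- function(x, ...) {
  cat("Uniaxial incompressible stretch state\n")
  print(data.frame(lambda = x$lambda, I1 = x$I1, I2 = x$I2, I3 = x$I3,
                   row.names = NULL), ...)
  invisible(x)
}

#' Deformation gradient of incompressible uniaxial stretch
#'
#' Returns `diag(lambda, 1/sqrt(lambda), 1/sqrt(lambda))`, the volume
#' preserving (det = 1) deformation gradient of uniaxial extension.
#'
#' @param lambda principal stretch (> 0), scalar.
#' @return 3x3 numeric matrix.
#' @export
deformation_gradient_uniaxial <- function(lambda) {
  if (!is_number(lambda) || lambda <= 0) stopf("stretch must be a positive number")
  diag(c(lambda, lambda^(-0.5), lambda^(-0.5)))
}

# Invariants of C = F'F for arbitrary principal stretches (used by the
# finite-difference stress oracle, where incompressibility is relaxed
# during the perturbation).
invariants_from_stretches <- function(l1, l2, l3) {
  list(
    I1 = l1^2 + l2^2 + l3^2,
    I2 = l1^2 * l2^2 + l2^2 * l3^2 + l1^2 * l3^2,
    I3 = l1^2 * l2^2 * l3^2
  )
}
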