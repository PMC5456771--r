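# Registry of isotropic incompressible hyperelastic models and their
# uniaxial-tension Cauchy stress expressions.
#
# Each entry defines the strain-energy density W as a function of the three
# principal stretches (used by the finite-difference oracle), the closed-form
# uniaxial Cauchy stress sigma(lambda) derived from
#   sigma_1 = lambda_1 dW/dlambda_1 - lambda_3 dW/dlambda_3
# (equivalently 2 (lambda^2 - 1/lambda)(dW/dI1 + dW/dI2 / lambda)), the
# initial tangent modulus dsigma/dlambda at lambda = 1, and a fitting start
# heuristic keyed on the curve's small-strain modulus E0.
#
# Coefficients are ordered a1, a2, ... ; stress-like coefficients are in MPa,
# exponents dimensionless.

# exp() with a clipped argument: Fung-type exponents explored by the
# multistart optimiser can otherwise overflow.
.safe_exp <- function(x, cap = 60) exp(pmin(pmax(x, -cap), cap))

.model_registry <- local({
  # helper: I1 - 3 for uniaxial stretch
  x1 <- function(l) l^2 + 2 / l - 3
  pref <- function(l) l^2 - 1 / l  # kinematic prefactor of invariant models

  list(
    neo_hookean = list(
      label = "Neo-Hookean", n_coeffs = 1L, exponent_idx = integer(0),
      W3 = function(a, l1, l2, l3) {
        iv <- invariants_from_stretches(l1, l2, l3)
        a[1] * (iv$I1 - 3)
      },
      sigma = function(a, l) 2 * a[1] * pref(l),
      tangent = function(a) 6 * a[1],
      start = function(E0) E0 / 6,
      lower = -Inf, upper = Inf
    ),
    mooney_rivlin = list(
      label = "Mooney-Rivlin", n_coeffs = 2L, exponent_idx = integer(0),
      W3 = function(a, l1, l2, l3) {
        iv <- invariants_from_stretches(l1, l2, l3)
        a[1] * (iv$I1 - 3) + a[2] * (iv$I2 - 3)
      },
      sigma = function(a, l) 2 * pref(l) * (a[1] + a[2] / l),
      tangent = function(a) 6 * (a[1] + a[2]),
      start = function(E0) c(E0 / 6, 0),
      lower = c(-Inf, -Inf), upper = c(Inf, Inf)
    ),
    yeoh = list(
      label = "Yeoh", n_coeffs = 3L, exponent_idx = integer(0),
      W3 = function(a, l1, l2, l3) {
        iv <- invariants_from_stretches(l1, l2, l3)
        x <- iv$I1 - 3
        a[1] * x + a[2] * x^2 + a[3] * x^3
      },
      sigma = function(a, l) {
        x <- x1(l)
        2 * pref(l) * (a[1] + 2 * a[2] * x + 3 * a[3] * x^2)
      },
      tangent = function(a) 6 * a[1],
      start = function(E0) c(E0 / 6, 0, 0),
      lower = rep(-Inf, 3), upper = rep(Inf, 3)
    ),
    fung = list(
      label = "Fung", n_coeffs = 2L, exponent_idx = 2L,
      W3 = function(a, l1, l2, l3) {
        iv <- invariants_from_stretches(l1, l2, l3)
        a[1] / (2 * a[2]) * (.safe_exp(a[2] * (iv$I1 - 3)) - 1)
      },
      sigma = function(a, l) a[1] * pref(l) * .safe_exp(a[2] * x1(l)),
      tangent = function(a) 3 * a[1],
      start = function(E0) c(E0 / 3, 1),
      lower = c(-Inf, 1e-4), upper = c(Inf, 50)
    ),
    humphrey = list(
      label = "Humphrey", n_coeffs = 2L, exponent_idx = 2L,
      W3 = function(a, l1, l2, l3) {
        iv <- invariants_from_stretches(l1, l2, l3)
        a[1] * (.safe_exp(a[2] * (iv$I1 - 3)) - 1)
      },
      sigma = function(a, l) 2 * a[1] * a[2] * pref(l) * .safe_exp(a[2] * x1(l)),
      tangent = function(a) 6 * a[1] * a[2],
      start = function(E0) c(E0 / 6, 1),
      lower = c(-Inf, 1e-4), upper = c(Inf, 50)
    ),
    ogden = list(
      label = "Ogden", n_coeffs = 6L, exponent_idx = c(2L, 4L, 6L),
      W3 = function(a, l1, l2, l3) {
        w <- 0
        for (n in 1:3) {
          mu <- a[2 * n - 1]; al <- a[2 * n]
          w <- w + mu / al * (l1^al + l2^al + l3^al - 3)
        }
        w
      },
      sigma = function(a, l) {
        s <- 0
        for (n in 1:3) {
          mu <- a[2 * n - 1]; al <- a[2 * n]
          s <- s + mu * (l^al - l^(-al / 2))
        }
        s
      },
      tangent = function(a) 1.5 * sum(a[c(1, 3, 5)] * a[c(2, 4, 6)]),
      start = function(E0) c(E0 / 3, 2, E0 / 30, 1, E0 / 30, 4),
      lower = c(-Inf, 0.05, -Inf, 0.05, -Inf, 0.05),
      upper = c(Inf, 20, Inf, 20, Inf, 20)
    ),
    veronda_westmann = list(
      label = "Veronda-Westmann", n_coeffs = 2L, exponent_idx = 2L,
      W3 = function(a, l1, l2, l3) {
        iv <- invariants_from_stretches(l1, l2, l3)
        a[1] * (.safe_exp(a[2] * (iv$I1 - 3)) - 1) -
          a[1] * a[2] / 2 * (iv$I2 - 3)
      },
      sigma = function(a, l) {
        2 * a[1] * a[2] * pref(l) * (.safe_exp(a[2] * x1(l)) - 1 / (2 * l))
      },
      tangent = function(a) 3 * a[1] * a[2],
      start = function(E0) c(E0 / 3, 1),
      lower = c(-Inf, 1e-4), upper = c(Inf, 50)
    )
  )
})

#' Names of the available hyperelastic models
#'
#' @return Character vector of model identifiers.
#' @export
hyperelastic_models <- function() names(.model_registry)

model_def <- function(model_id) {
  def <- .model_registry[[model_id]]
  if (is.null(def)) {
    stopf("unknown model '%s'; available: %s", model_id,
          paste(hyperelastic_models(), collapse = ", "))
  }
  def
}

#' Hyperelastic parameter set
#'
#' Bundles a model identifier with its ordered coefficient vector
#' `a1, a2, ...`.  Stress-like coefficients are in MPa; the exponents of the
#' Fung, Humphrey, Veronda-Westmann and Ogden models are dimensionless and
#' must be nonzero where they appear in the strain energy.
#'
#' @param model one of [hyperelastic_models()].
#' @param coeffs numeric coefficient vector whose length matches the model
#'   (Neo-Hookean 1, Mooney-Rivlin/Fung/Humphrey/Veronda-Westmann 2, Yeoh 3,
#'   three-term Ogden 6).
#' @return An object of class `hyper_params`.
#' @examples
#' hyper_params("yeoh", c(3.583, -2.534, 12.020))
#' @export
hyper_params <- function(model, coeffs) {
  def <- model_def(model)
  coeffs <- as.numeric(coeffs)
  if (length(coeffs) != def$n_coeffs || any(!is.finite(coeffs))) {
    stopf("model '%s' needs %d finite coefficients, got %d",
          model, def$n_coeffs, length(coeffs))
  }
  if (length(def$exponent_idx) && any(coeffs[def$exponent_idx] == 0)) {
    stopf("model '%s' requires nonzero exponent coefficients (positions %s)",
          model, paste(def$exponent_idx, collapse = ", "))
  }
  structure(list(model = model, coeffs = coeffs), class = "hyper_params")
}

#' @export
print.hyper_params <- function(x, ...) {
  def <- model_def(x$model)
  cat(sprintf("<hyper_params> %s\n", def$label))
  v <- x$coeffs
  names(v) <- paste0("a", seq_along(v))
  print(round(v, 6))
  invisible(x)
}

as_params <- function(x) {
  if (inherits(x, "hyper_params")) return(x)
  stopf("expected a 'hyper_params' object")
}

#' Strain-energy density of a hyperelastic model
#'
#' Evaluates W (MPa) at the incompressible uniaxial state with axial stretch
#' `lambda`.  W(1) = 0 for every model.
#'
#' @param params a [hyper_params()] object.
#' @param lambda axial stretch (> 0); vectorised.
#' @return Numeric vector of strain-energy densities, MPa.
#' @export
strain_energy <- function(params, lambda) {
  params <- as_params(params)
  st <- uniaxial_invariants(lambda)
  def <- model_def(params$model)
  def$W3(params$coeffs, st$lambda, st$lambda2, st$lambda3)
}

#' Uniaxial Cauchy stress of a hyperelastic model (closed form)
#'
#' Evaluates the closed-form Cauchy stress of an incompressible isotropic
#' material under uniaxial tension, e.g. `2*a1*(lambda^2 - 1/lambda)` for the
#' Neo-Hookean solid.  All models give zero stress at `lambda = 1`.
#'
#' @inheritParams strain_energy
#' @return Numeric vector of Cauchy stresses, MPa.
#' @examples
#' cauchy_stress(hyper_params("neo_hookean", 1), 1.2)  # 1.21333
#' @export
cauchy_stress <- function(params, lambda) {
  params <- as_params(params)
  if (!is.numeric(lambda) || any(!is.finite(lambda)) || any(lambda <= 0)) {
    stopf("stretch must be positive and finite")
  }
  model_def(params$model)$sigma(params$coeffs, lambda)
}

#' Finite-difference oracle for the uniaxial Cauchy stress
#'
#' Computes \eqn{\sigma_1 = \lambda_1 \partial W/\partial\lambda_1 -
#' \lambda_3 \partial W/\partial\lambda_3} with the partial derivatives taken
#' by central finite differences of the strain energy written as a function
#' of the three principal stretches.  Serves as an independent brute-force
#' check of [cauchy_stress()]; it shares only the strain-energy definition,
#' not the differentiated closed forms.
#'
#' @inheritParams strain_energy
#' @param step relative perturbation of the stretches (default `1e-6`).
#' @return Numeric vector of Cauchy stresses, MPa.
#' @export
cauchy_stress_fd <- function(params, lambda, step = 1e-6) {
  params <- as_params(params)
  st <- uniaxial_invariants(lambda)
  def <- model_def(params$model)
  a <- params$coeffs
  l1 <- st$lambda; l3 <- st$lambda3; l2 <- st$lambda2
  h1 <- step * l1; h3 <- step * l3
  dW1 <- (def$W3(a, l1 + h1, l2, l3) - def$W3(a, l1 - h1, l2, l3)) / (2 * h1)
  dW3 <- (def$W3(a, l1, l2, l3 + h3) - def$W3(a, l1, l2, l3 - h3)) / (2 * h3)
  l1 * dW1 - l3 * dW3
}

#' Initial tangent modulus of a hyperelastic model
#'
#' The slope of the uniaxial Cauchy stress-stretch curve at the reference
#' configuration, `dsigma/dlambda` at `lambda = 1`, by closed form (e.g.
#' `6*a1` for Neo-Hookean and Yeoh, `6*(a1 + a2)` for Mooney-Rivlin).  A
#' negative value flags non-physical small-strain behaviour of a fitted
#' coefficient set.
#'
#' @inheritParams strain_energy
#' @return Scalar modulus, MPa.
#' @export
initial_tangent_modulus <- function(params) {
  params <- as_params(params)
  model_def(params$model)$tangent(params$coeffs)
}

#' Serialize / parse hyperelastic parameters as JSON
#'
#' The schema is `{"model": "<id>", "coeffs": [..]}`.
#'
#' @param params a [hyper_params()] object.
#' @return `hyper_params_to_json()` a JSON string; `hyper_params_from_json()`
#'   a `hyper_params` object.
#' @export
hyper_params_to_json <- function(params) {
  params <- as_params(params)
  jsonlite::toJSON(list(model = params$model, coeffs = params$coeffs),
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname hyper_params_to_json
#' @param json JSON string as produced by `hyper_params_to_json()`.
#' @export
hyper_params_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  hyper_params(obj$model, obj$coeffs)
}
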