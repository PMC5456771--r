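# Hyperelastic model fitting by multistart Levenberg-Marquardt least
# squares, model ranking by the coefficient of determination, and linear
# (Young's) modulus extraction.

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} with the total sum of squares taken
#' about the mean of the observations (the standard curve-fitting
#' convention).
#'
#' @param observed,predicted numeric vectors of equal length (>= 3).
#' @return Scalar R^2 (<= 1; can be negative for fits worse than the mean).
#' @examples
#' r_squared(c(0, 1, 2), c(0, 1, 3))  # 0.5
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 3L) {
    stopf("observed and predicted must have equal length >= 3")
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stopf("R^2 undefined: observations are constant")
  1 - sum((observed - predicted)^2) / ss_tot
}

# Draw multistart initial coefficient vectors.  The deterministic heuristic
# start is derived from the curve's small-strain modulus E0; the remaining
# starts spread stress-like coefficients over +/- (0.1-10) x E0/6 and
# exponents log-uniformly over [0.1, 20].
.multistart_inits <- function(def, E0, n_starts) {
  starts <- list(def$start(max(E0, 1e-6)))
  scale <- max(abs(E0) / 6, 1e-3)
  n_extra <- max(n_starts - 1L, 0L)
  for (k in seq_len(n_extra)) {
    a <- numeric(def$n_coeffs)
    for (j in seq_len(def$n_coeffs)) {
      if (j %in% def$exponent_idx) {
        a[j] <- exp(stats::runif(1, log(0.1), log(20)))
      } else {
        a[j] <- sign(stats::runif(1) - 0.3) * scale * 10^stats::runif(1, -1, 1)
      }
    }
    starts[[k + 1L]] <- a
  }
  starts
}

.clamp_start <- function(a, lower, upper) pmin(pmax(a, lower), upper)

#' Fit a hyperelastic model to a stress-stretch curve
#'
#' Minimises the sum of squared Cauchy-stress residuals over the curve's
#' stretch grid with the Levenberg-Marquardt algorithm
#' ([minpack.lm::nls.lm()]), restarted from `n_starts` initial coefficient
#' vectors: one deterministic heuristic derived from the curve's small-strain
#' modulus, the rest drawn from a seeded spread covering the coefficient
#' magnitudes typical of soft-tissue fits.  The best local optimum is
#' returned.
#'
#' @param curve a [stress_stretch_curve()].
#' @param model one of [hyperelastic_models()].
#' @param init optional initial coefficient vector; replaces the heuristic
#'   start.
#' @param n_starts number of optimiser starts (default 16).
#' @param seed integer seed for the multistart spread (default 1); fitting is
#'   bit-reproducible for a fixed seed.
#' @return An object of class `hyperfit` with components `model`, `coeffs`
#'   (named `a1..`), `params` ([hyper_params()]), `r_squared`,
#'   `residual_norm` (MPa), `converged`, `n_points`, `tissue`, plus the data
#'   used.  Methods: `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`, `plot`.
#' @examples
#' p <- hyper_params("yeoh", c(0.063, 0.394, -0.171))
#' cv <- stress_stretch_curve(seq(1, 1.5, 0.01),
#'                            cauchy_stress(p, seq(1, 1.5, 0.01)),
#'                            tissue = "smooth_muscle")
#' fit <- hyperfit(cv, "yeoh")
#' coef(fit)
#' @export
hyperfit <- function(curve, model, init = NULL, n_starts = 16L, seed = 1L) {
  if (!inherits(curve, "stress_stretch_curve")) stopf("curve expected")
  def <- model_def(model)
  min_pts <- max(def$n_coeffs + 2L, 10L)
  if (length(curve$stretch) < min_pts) {
    stopf("curve has %d points; model '%s' needs >= %d",
          length(curve$stretch), model, min_pts)
  }
  lam <- curve$stretch; obs <- curve$stress

  # small-strain modulus anchor for start heuristics
  E0 <- tryCatch(linear_modulus(curve, lambda_max = max(lam))$modulus,
                 error = function(e) 1)

  starts <- with_local_seed(seed, .multistart_inits(def, E0, n_starts))
  if (!is.null(init)) {
    if (length(init) != def$n_coeffs) stopf("init has wrong length for '%s'", model)
    starts[[1]] <- as.numeric(init)
  }

  resid_fn <- function(a) def$sigma(a, lam) - obs

  best <- NULL
  for (a0 in starts) {
    a0 <- .clamp_start(a0, def$lower, def$upper)
    res <- tryCatch(
      minpack.lm::nls.lm(par = a0, fn = resid_fn,
                         lower = def$lower, upper = def$upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res)) next
    ss <- sum(res$fvec^2)
    if (is.null(best) || ss < best$ss - 1e-15) {
      best <- list(par = res$par, ss = ss, info = res$info)
    }
  }
  if (is.null(best)) {
    stopf("all %d optimiser starts failed for model '%s'", length(starts), model)
  }
  coeffs <- as.numeric(best$par)
  names(coeffs) <- paste0("a", seq_along(coeffs))
  pred <- def$sigma(coeffs, lam)
  structure(list(
    model = model, coeffs = coeffs,
    params = hyper_params(model, coeffs),
    r_squared = r_squared(obs, pred),
    residual_norm = sqrt(best$ss),
    converged = best$info %in% 1:3,
    n_points = length(lam),
    tissue = curve$tissue,
    lambda = lam, observed = obs, fitted_values = pred,
    n_starts = length(starts), seed = seed
  ), class = "hyperfit")
}

#' @export
print.hyperfit <- function(x, ...) {
  cat(sprintf("%s fit%s: R^2 = %.4f, %s\n",
              model_def(x$model)$label,
              if (is.na(x$tissue)) "" else paste0(" (", x$tissue, ")"),
              x$r_squared,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$coeffs, 6))
  invisible(x)
}

#' @export
coef.hyperfit <- function(object, ...) object$coeffs

#' @export
fitted.hyperfit <- function(object, ...) object$fitted_values

#' @export
residuals.hyperfit <- function(object, ...) object$observed - object$fitted_values

#' @export
predict.hyperfit <- function(object, newdata = NULL, ...) {
  lam <- if (is.null(newdata)) object$lambda else {
    if (is.list(newdata)) newdata$stretch else as.numeric(newdata)
  }
  cauchy_stress(object$params, lam)
}

#' @export
summary.hyperfit <- function(object, ...) {
  structure(list(fit = object,
                 tangent = initial_tangent_modulus(object$params)),
            class = "summary.hyperfit")
}

#' @export
print.summary.hyperfit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  points: %d, residual norm: %.4g MPa\n", f$n_points, f$residual_norm))
  cat(sprintf("  initial tangent modulus: %.4g MPa%s\n", x$tangent,
              if (x$tangent < 0) "  [non-physical at small strain]" else ""))
  invisible(x)
}

#' @export
plot.hyperfit <- function(x, ...) {
  graphics::plot(x$lambda, x$observed, pch = 20, cex = 0.5,
                 xlab = expression(lambda), ylab = "Cauchy stress (MPa)",
                 main = sprintf("%s fit (R^2 = %.3f)",
                                model_def(x$model)$label, x$r_squared), ...)
  graphics::lines(x$lambda, x$fitted_values, col = 2, lwd = 2)
  invisible(x)
}

#' Fit all hyperelastic models to one curve and rank by R^2
#'
#' Fits the seven registered models and orders them by descending
#' coefficient of determination; ties at the printed 0.001 resolution go to
#' the model with fewer coefficients.
#'
#' @inheritParams hyperfit
#' @param models model identifiers to fit (default: all registered).
#' @return An object of class `model_ranking`: a list with `table` (a
#'   data.frame with columns model, n_coeffs, r_squared, converged),
#'   `best_model`, and `fits` (named list of `hyperfit` objects).
#' @export
fit_all_models <- function(curve, models = hyperelastic_models(),
                           n_starts = 16L, seed = 1L) {
  fits <- list(); errs <- character(0)
  for (m in models) {
    f <- tryCatch(hyperfit(curve, m, n_starts = n_starts, seed = seed),
                  error = function(e) e)
    if (inherits(f, "error")) {
      errs <- c(errs, sprintf("%s: %s", m, conditionMessage(f)))
    } else {
      fits[[m]] <- f
    }
  }
  if (length(errs)) warnf("model fit failures: %s", paste(errs, collapse = "; "))
  if (!length(fits)) stopf("no model could be fitted")
  tab <- data.frame(
    model = names(fits),
    n_coeffs = vapply(fits, function(f) length(f$coeffs), 0L),
    r_squared = vapply(fits, function(f) f$r_squared, 0),
    converged = vapply(fits, function(f) f$converged, TRUE),
    row.names = NULL, stringsAsFactors = FALSE
  )
  # rank on R^2 rounded to the printed 0.001, fewer parameters breaking ties
  ord <- order(-round(tab$r_squared, 3), tab$n_coeffs, -tab$r_squared)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, best_model = tab$model[1], fits = fits,
                 tissue = curve$tissue),
            class = "model_ranking")
}

#' @export
print.model_ranking <- function(x, ...) {
  cat(sprintf("Hyperelastic model ranking%s (best: %s)\n",
              if (is.na(x$tissue)) "" else paste0(" for ", x$tissue),
              x$best_model))
  tab <- x$table
  tab$r_squared <- sprintf("%.3f", tab$r_squared)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Linear (Young's) modulus of a stress-stretch curve
#'
#' Ordinary least squares of Cauchy stress on engineering strain
#' (\eqn{\lambda - 1}) with a free intercept, over `[1, lambda_max]`.  The
#' slope is the Young's modulus in MPa; the intercept absorbs any residual
#' preload offset.
#'
#' @param curve a [stress_stretch_curve()].
#' @param lambda_max upper stretch of the regression window (default 1.2,
#'   the quasi-linear range of cartilage).
#' @return List of class `linear_modulus` with `modulus` (MPa), `r_squared`,
#'   `intercept` (MPa) and `n_points`.
#' @export
linear_modulus <- function(curve, lambda_max = 1.2) {
  if (!inherits(curve, "stress_stretch_curve")) stopf("curve expected")
  if (max(curve$stretch) < lambda_max - 1e-9) {
    stopf("curve reaches only lambda = %.4g < %.4g", max(curve$stretch), lambda_max)
  }
  keep <- curve$stretch <= lambda_max + 1e-9
  lam <- curve$stretch[keep]; sig <- curve$stress[keep]
  if (length(lam) < 3L) stopf("fewer than 3 points below lambda_max = %.3g", lambda_max)
  fit <- stats::lm.fit(cbind(1, lam - 1), sig)
  pred <- cbind(1, lam - 1) %*% fit$coefficients
  structure(list(modulus = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 r_squared = r_squared(sig, as.numeric(pred)),
                 n_points = length(lam), lambda_max = lambda_max),
            class = "linear_modulus")
}

#' @export
print.linear_modulus <- function(x, ...) {
  cat(sprintf("Linear modulus over [1, %.3g]: E = %.4g MPa (R^2 = %.4f, n = %d)\n",
              x$lambda_max, x$modulus, x$r_squared, x$n_points))
  invisible(x)
}
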