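# Tensile-test processing: raw force-displacement records to Cauchy
# stress-stretch curves, resampling and per-tissue averaging.

#' Specimen geometry
#'
#' @param L0 initial (preload-referenced) gauge length, mm.
#' @param A0 initial cross-sectional area, mm^2.
#' @return List of class `specimen_geometry`.
#' @export
specimen_geometry <- function(L0, A0) {
  if (!is_number(L0) || L0 <= 0) stopf("L0 must be a positive length (mm)")
  if (!is_number(A0) || A0 <= 0) stopf("A0 must be a positive area (mm^2)")
  structure(list(L0 = L0, A0 = A0), class = "specimen_geometry")
}

#' Force-displacement record of one uniaxial test
#'
#' Holds the machine output of one tensile test together with specimen
#' geometry and provenance.  Non-increasing displacement samples (machine
#' jitter) are dropped with a message.
#'
#' @param specimen_id,subject_id identifiers.
#' @param tissue one of `"cartilage"`, `"smooth_muscle"`, `"connective"`.
#' @param displacement displacement series, mm (non-decreasing after jitter
#'   removal, starting at the record's current origin).
#' @param force force series, N; same length as `displacement`.
#' @param geometry a [specimen_geometry()].
#' @return List of class `fd_record`.
#' @export
fd_record <- function(specimen_id, subject_id, tissue, displacement, force,
                      geometry) {
  check_tissue(tissue)
  if (!inherits(geometry, "specimen_geometry")) {
    stopf("geometry must be a specimen_geometry object")
  }
  displacement <- as.numeric(displacement)
  force <- as.numeric(force)
  if (length(displacement) != length(force) || length(force) < 2L) {
    stopf("displacement and force must have equal length >= 2")
  }
  keep <- c(TRUE, diff(displacement) > 0)
  # retain strictly increasing displacement; count drops for diagnostics
  if (!all(keep)) {
    message(sprintf("fd_record: dropped %d non-increasing displacement sample(s) [%s]",
                    sum(!keep), specimen_id))
    displacement <- displacement[keep]
    force <- force[keep]
    if (length(force) < 2L) stopf("record '%s' degenerate after jitter removal", specimen_id)
  }
  structure(list(specimen_id = as.character(specimen_id),
                 subject_id = as.character(subject_id),
                 tissue = tissue,
                 displacement = displacement, force = force,
                 geometry = geometry),
            class = "fd_record")
}

#' @export
print.fd_record <- function(x, ...) {
  cat(sprintf("<fd_record> %s (%s, subject %s): %d samples, L0 = %.3g mm, A0 = %.3g mm^2\n",
              x$specimen_id, x$tissue, x$subject_id, length(x$force),
              x$geometry$L0, x$geometry$A0))
  invisible(x)
}

#' Stretch from crosshead displacement
#'
#' \eqn{\lambda = (L_0 + \Delta L)/L_0}.
#'
#' @param delta_L displacement, mm (>= 0); vectorised.
#' @param L0 reference gauge length, mm (> 0).
#' @return Stretch (dimensionless).
#' @export
stretch_from_displacement <- function(delta_L, L0) {
  if (!is_number(L0) || L0 <= 0) stopf("L0 must be positive")
  if (any(delta_L < 0)) stopf("negative displacement: compression is not modelled")
  (L0 + delta_L) / L0
}

#' Cauchy stress from force under incompressibility
#'
#' \eqn{\sigma = (T/A_0)\,\lambda}: the true stress referred to the current
#' cross-section \eqn{A_0/\lambda} of an incompressible specimen.  With force
#' in N and area in mm^2 the result is in MPa.
#'
#' @param T_force tensile force, N; vectorised.
#' @param A0 reference cross-sectional area, mm^2 (> 0).
#' @param lambda stretch (>= 1).
#' @return Cauchy stress, MPa.
#' @export
cauchy_stress_from_force <- function(T_force, A0, lambda) {
  if (!is_number(A0) || A0 <= 0) stopf("A0 must be positive")
  if (any(lambda < 1)) stopf("stretch below 1: compression is not modelled")
  (T_force / A0) * lambda
}

#' Re-reference a record to its preload crossing
#'
#' The tensile protocol defines the reference length at a small preload
#' (0.1 N).  The first sample whose force reaches the preload becomes the
#' new origin: its displacement is subtracted from the remaining samples and
#' earlier samples are discarded.
#'
#' @param record an [fd_record()].
#' @param preload preload force level, N (default 0.1).
#' @return The re-referenced `fd_record`.
#' @export
preload_reference <- function(record, preload = 0.1) {
  if (!inherits(record, "fd_record")) stopf("record must be an fd_record")
  idx <- which(record$force >= preload)
  if (!length(idx)) {
    stopf("record '%s': force never reaches the %.3g N preload (max %.3g N)",
          record$specimen_id, preload, max(record$force))
  }
  i0 <- idx[1]
  if (length(record$force) - i0 < 1L) {
    stopf("record '%s': no samples beyond the preload crossing", record$specimen_id)
  }
  record$displacement <- record$displacement[i0:length(record$displacement)] -
    record$displacement[i0]
  record$force <- record$force[i0:length(record$force)]
  record
}

#' Cauchy stress-stretch curve
#'
#' @param stretch strictly increasing stretch series (>= 1, dimensionless).
#' @param stress Cauchy stress series, MPa; same length.
#' @param tissue optional tissue tag.
#' @param n_samples number of specimens averaged into the curve (1 for a
#'   single specimen).
#' @param stress_sd optional pointwise standard deviation, MPa.
#' @return List of class `stress_stretch_curve`.
#' @export
stress_stretch_curve <- function(stretch, stress, tissue = NA_character_,
                                 n_samples = 1L, stress_sd = NULL) {
  stretch <- as.numeric(stretch); stress <- as.numeric(stress)
  if (length(stretch) != length(stress) || length(stretch) < 2L) {
    stopf("stretch and stress must have equal length >= 2")
  }
  if (any(stretch < 1 - 1e-9)) stopf("stretch values must be >= 1")
  if (any(diff(stretch) <= 0)) stopf("stretch must be strictly increasing")
  if (!is.null(stress_sd) && length(stress_sd) != length(stress)) {
    stopf("stress_sd length mismatch")
  }
  structure(list(stretch = stretch, stress = stress,
                 tissue = if (is.na(tissue)) NA_character_ else check_tissue(tissue),
                 n_samples = as.integer(n_samples), stress_sd = stress_sd),
            class = "stress_stretch_curve")
}

#' @export
print.stress_stretch_curve <- function(x, ...) {
  cat(sprintf("<stress_stretch_curve> %s: %d points, lambda in [%.3f, %.3f], sigma_max = %.4g MPa, n = %d\n",
              if (is.na(x$tissue)) "untagged" else x$tissue,
              length(x$stretch), min(x$stretch), max(x$stretch),
              max(x$stress), x$n_samples))
  invisible(x)
}

#' @export
as.data.frame.stress_stretch_curve <- function(x, ...) {
  d <- data.frame(stretch = x$stretch, stress_MPa = x$stress)
  if (!is.null(x$stress_sd)) d$stress_sd_MPa <- x$stress_sd
  d
}

#' @export
plot.stress_stretch_curve <- function(x, ...) {
  graphics::plot(x$stretch, x$stress, type = "l",
                 xlab = expression(lambda), ylab = "Cauchy stress (MPa)",
                 main = if (is.na(x$tissue)) "" else x$tissue, ...)
  if (!is.null(x$stress_sd)) {
    graphics::lines(x$stretch, x$stress + x$stress_sd, lty = 3)
    graphics::lines(x$stretch, pmax(x$stress - x$stress_sd, 0), lty = 3)
  }
  invisible(x)
}

#' Convert a preload-referenced record to a stress-stretch curve
#'
#' Applies the stretch and Cauchy stress formulas pointwise.  The force
#' carried at the reference sample (the preload) is subtracted before
#' computing stress, so the curve starts at \eqn{(\lambda, \sigma) = (1, 0)}
#' and a noiseless simulated record round-trips exactly to its generating
#' stress function.
#'
#' @param record an [fd_record()] already passed through
#'   [preload_reference()] (displacement starting at 0).
#' @return A [stress_stretch_curve()] with `n_samples = 1`.
#' @export
record_to_curve <- function(record) {
  if (!inherits(record, "fd_record")) stopf("record must be an fd_record")
  if (abs(record$displacement[1]) > 1e-12) {
    stopf("record '%s' is not preload-referenced (displacement does not start at 0)",
          record$specimen_id)
  }
  lam <- stretch_from_displacement(record$displacement, record$geometry$L0)
  sig <- cauchy_stress_from_force(record$force - record$force[1],
                                  record$geometry$A0, lam)
  stress_stretch_curve(lam, sig, tissue = record$tissue, n_samples = 1L)
}

#' Resample a curve onto a stretch grid by linear interpolation
#'
#' @param curve a [stress_stretch_curve()].
#' @param grid strictly increasing stretch values within the curve's range
#'   (no extrapolation).
#' @return The resampled `stress_stretch_curve`.
#' @export
resample_to_grid <- function(curve, grid) {
  if (!inherits(curve, "stress_stretch_curve")) stopf("curve expected")
  grid <- as.numeric(grid)
  eps <- 1e-9
  if (min(grid) < min(curve$stretch) - eps || max(grid) > max(curve$stretch) + eps) {
    stopf("grid [%.4f, %.4f] outside curve range [%.4f, %.4f]: extrapolation refused",
          min(grid), max(grid), min(curve$stretch), max(curve$stretch))
  }
  # the range was checked to eps above; clamp so that endpoints hit by a
  # rounding ulp (e.g. after a CSV round-trip) interpolate, not NA out
  grid_c <- pmin(pmax(grid, min(curve$stretch)), max(curve$stretch))
  s <- stats::approx(curve$stretch, curve$stress, xout = grid_c, rule = 1)$y
  sd <- if (!is.null(curve$stress_sd)) {
    stats::approx(curve$stretch, curve$stress_sd, xout = grid_c, rule = 1)$y
  } else NULL
  stress_stretch_curve(grid, s, tissue = curve$tissue,
                       n_samples = curve$n_samples, stress_sd = sd)
}

#' Default per-tissue maximum stretch of the averaged curves
#'
#' Cartilage curves are analysed to a stretch of 1.2, smooth muscle and
#' connective tissue to 1.5 — levels every specimen reaches before failure.
#'
#' @param tissue tissue tag.
#' @return Scalar stretch.
#' @export
default_lambda_max <- function(tissue) {
  check_tissue(tissue)
  c(cartilage = 1.2, smooth_muscle = 1.5, connective = 1.5)[[tissue]]
}

#' Average stress-stretch curves on a common grid
#'
#' Curves are resampled onto the uniform grid `[1, lambda_max]` with the
#' given step, then averaged pointwise; the pointwise sample standard
#' deviation (n - 1 denominator) is stored in `stress_sd`.  Curves that do
#' not reach `lambda_max` are excluded with a warning, mirroring a protocol
#' that truncates the analysis at a stretch all retained specimens attain.
#'
#' @param curves list of [stress_stretch_curve()] objects of one tissue.
#' @param lambda_max upper stretch of the averaging grid; defaults to the
#'   tissue's [default_lambda_max()].
#' @param step grid step (default 0.01).
#' @return A `stress_stretch_curve` with `n_samples` = number of curves used.
#' @export
average_curves <- function(curves, lambda_max = NULL, step = 0.01) {
  if (!length(curves)) stopf("no curves to average")
  if (!all(vapply(curves, inherits, TRUE, "stress_stretch_curve"))) {
    stopf("curves must be stress_stretch_curve objects")
  }
  tissues <- unique(vapply(curves, function(c) c$tissue, ""))
  if (length(tissues) != 1L) stopf("curves mix tissues: %s", paste(tissues, collapse = ", "))
  if (is.null(lambda_max)) {
    lambda_max <- if (is.na(tissues)) max(vapply(curves, function(c) max(c$stretch), 0)) else
      default_lambda_max(tissues)
  }
  reach <- vapply(curves, function(c) max(c$stretch) >= lambda_max - 1e-9, TRUE)
  if (!all(reach)) {
    warnf("excluding %d curve(s) not reaching lambda = %.3g from the average",
          sum(!reach), lambda_max)
    curves <- curves[reach]
    if (!length(curves)) stopf("no curve reaches lambda_max = %.3g", lambda_max)
  }
  grid <- seq(1, lambda_max, by = step)
  mat <- vapply(curves, function(c) resample_to_grid(c, grid)$stress,
                numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  m <- rowMeans(mat)
  sd <- if (ncol(mat) > 1L) apply(mat, 1, stats::sd) else rep(0, length(grid))
  stress_stretch_curve(grid, m, tissue = tissues, n_samples = ncol(mat),
                       stress_sd = sd)
}

# ---- CSV interfaces ----

#' Read / write per-specimen force-displacement CSVs
#'
#' Record files carry columns `displacement_mm`, `force_N`; the manifest
#' carries `specimen_id`, `subject_id`, `tissue`, `L0_mm`, `A0_mm2`.
#'
#' @param path file path.
#' @param record an [fd_record()].
#' @return `read_record_csv()` an `fd_record`; `write_record_csv()` the path,
#'   invisibly.
#' @export
write_record_csv <- function(record, path) {
  utils::write.csv(data.frame(displacement_mm = record$displacement,
                              force_N = record$force),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_record_csv
#' @param specimen_id,subject_id,tissue,L0,A0 specimen metadata (normally
#'   taken from a manifest row).
#' @export
read_record_csv <- function(path, specimen_id, subject_id, tissue, L0, A0) {
  d <- utils::read.csv(path)
  if (!all(c("displacement_mm", "force_N") %in% names(d))) {
    stopf("%s: expected columns displacement_mm, force_N", path)
  }
  fd_record(specimen_id, subject_id, tissue, d$displacement_mm, d$force_N,
            specimen_geometry(L0, A0))
}

#' Write a stress-stretch curve as CSV
#'
#' Columns `stretch`, `stress_MPa` and, when available, `stress_sd_MPa`.
#'
#' @param curve a [stress_stretch_curve()].
#' @param path file path.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
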