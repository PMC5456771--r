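# Synthetic-cohort generator: force-displacement records with the
# statistical structure the analysis assumes, so that every pipeline stage
# is testable without access to donor tissue.

#' Configuration of the synthetic donor cohort
#'
#' Defaults emulate the study conditions of the tracheal-tissue cohort: 30
#' donors (13 young = 5 female + 8 male, aged 18-36; 17 old = 7 female + 10
#' male, aged 49-65), three specimens per tissue per donor, per-tissue mean
#' stress-stretch behaviour given by the reported Yeoh coefficient sets, and
#' cartilage stiffness heterogeneity moment-matched to the reported group
#' statistics (young 13.30 +/- 5.72 MPa, old 20.71 +/- 10.17 MPa).
#'
#' Gauge lengths follow the reported per-tissue distributions (means
#' 4.13/6.37/1.60 mm).  Cross-sections are documented fixture choices (the
#' source tables print none): they scale forces but cancel out of stresses.
#' Soft-tissue ageing is a configurable multiplicative shift, largest for
#' connective tissue and smallest for smooth muscle, mirroring the reported
#' ordering of age sensitivity.
#'
#' @param seed integer seed; mandatory (no wall-clock default).
#' @param n_young_f,n_young_m,n_old_f,n_old_m subject counts (5, 8, 7, 10).
#' @param specimens_per_tissue specimens per tissue per subject (3).
#' @param tissue_params named list of [hyper_params()] giving each tissue's
#'   ground-truth mean curve.
#' @param cartilage_targets list with `young = c(mean, sd)` and
#'   `old = c(mean, sd)` cartilage linear moduli, MPa.
#' @param soft_scale list per soft tissue with `old_ratio` (old/young mean
#'   stiffness multiplier) and `cv` (between-subject coefficient of
#'   variation of the stiffness scale).
#' @param geometry list per tissue with `L0 = c(mean, sd)` mm and
#'   `A0 = c(mean, sd)` mm^2.
#' @param noise_sd force noise SD relative to the record's peak force (0.01).
#' @param step stretch grid step of simulated records (0.01).
#' @param preload preload force, N (0.1).
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(seed,
                          n_young_f = 5L, n_young_m = 8L,
                          n_old_f = 7L, n_old_m = 10L,
                          specimens_per_tissue = 3L,
                          tissue_params = list(
                            cartilage = hyper_params("yeoh", c(3.583, -2.534, 12.020)),
                            smooth_muscle = hyper_params("yeoh", c(0.063, 0.394, -0.171)),
                            connective = hyper_params("yeoh", c(0.257, 0.483, -0.148))),
                          cartilage_targets = list(young = c(13.30, 5.72),
                                                   old = c(20.71, 10.17)),
                          soft_scale = list(
                            smooth_muscle = list(old_ratio = 1.10, cv = 0.40),
                            connective = list(old_ratio = 1.35, cv = 0.40)),
                          geometry = list(
                            cartilage = list(L0 = c(4.13, 1.81), A0 = c(5, 1.5)),
                            smooth_muscle = list(L0 = c(6.37, 1.91), A0 = c(3, 1)),
                            connective = list(L0 = c(1.60, 0.33), A0 = c(3, 1))),
                          noise_sd = 0.01, step = 0.01, preload = 0.1) {
  if (missing(seed) || !is_number(seed)) {
    stopf("an explicit integer seed is required for cohort generation")
  }
  counts <- c(n_young_f, n_young_m, n_old_f, n_old_m)
  if (any(counts < 0)) stopf("subject counts must be >= 0")
  if (!all(TISSUES %in% names(tissue_params))) {
    stopf("tissue_params must cover: %s", paste(TISSUES, collapse = ", "))
  }
  cfg <- list(seed = as.integer(seed),
              n_young_f = n_young_f, n_young_m = n_young_m,
              n_old_f = n_old_f, n_old_m = n_old_m,
              specimens_per_tissue = as.integer(specimens_per_tissue),
              tissue_params = tissue_params,
              cartilage_targets = cartilage_targets,
              soft_scale = soft_scale,
              geometry = geometry,
              noise_sd = noise_sd, step = step, preload = preload)
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> %d subjects (%d young: %dF/%dM; %d old: %dF/%dM), %d specimens/tissue, seed %d\n",
              x$n_young_f + x$n_young_m + x$n_old_f + x$n_old_m,
              x$n_young_f + x$n_young_m, x$n_young_f, x$n_young_m,
              x$n_old_f + x$n_old_m, x$n_old_f, x$n_old_m,
              x$specimens_per_tissue, x$seed))
  invisible(x)
}

# Linear modulus of a tissue's ground-truth mean curve over [1, 1.2] — the
# anchor converting the dimensionless subject scale into MPa for cartilage.
base_modulus <- function(params, lambda_max = 1.2, step = 0.01) {
  grid <- seq(1, lambda_max, by = step)
  cv <- stress_stretch_curve(grid, cauchy_stress(params, grid))
  linear_modulus(cv, lambda_max = lambda_max)$modulus
}

# moment-matched lognormal parameters for given mean m > 0 and sd s >= 0
.lognormal_pars <- function(m, s) {
  if (m <= 0) stopf("lognormal moment matching needs a positive mean")
  s2 <- log(1 + (s / m)^2)
  if (!is.finite(s2)) stopf("infeasible lognormal moment matching (sd/mean too large)")
  c(mu = log(m) - s2 / 2, sigma = sqrt(s2))
}

#' Draw per-subject stiffness multipliers
#'
#' Subject heterogeneity is a single positive multiplicative scale on the
#' tissue's ground-truth stress curve.  For cartilage the scale is lognormal
#' with moments set so that `scale x E_base` has the configured group mean
#' and SD, where `E_base` is the linear modulus of the ground-truth curve
#' over stretches 1-1.2.  For soft tissues the scale is lognormal around 1
#' (young) or `old_ratio` (old) with the configured coefficient of
#' variation.  A zero SD target gives a deterministic scale.
#'
#' Draws use the current RNG state; seed via the cohort seed or
#' [set.seed()].
#'
#' @param config a [cohort_config()].
#' @param tissue tissue tag.
#' @param age_group `"young"` or `"old"`.
#' @param n number of draws.
#' @return Numeric vector of positive multipliers.
#' @export
sample_subject_scale <- function(config, tissue, age_group, n = 1L) {
  check_tissue(tissue)
  if (!age_group %in% c("young", "old")) stopf("age_group must be young or old")
  if (tissue == "cartilage") {
    tgt <- config$cartilage_targets[[age_group]]
    e_base <- base_modulus(config$tissue_params$cartilage)
    m <- tgt[1] / e_base; s <- tgt[2] / e_base
  } else {
    sc <- config$soft_scale[[tissue]]
    m <- if (age_group == "old") sc$old_ratio else 1
    s <- sc$cv * m
  }
  if (s == 0) return(rep(m, n))
  p <- .lognormal_pars(m, s)
  stats::rlnorm(n, p["mu"], p["sigma"])
}

# positive truncated-normal draw (simple rejection; deterministic under seed)
.rtrunc_pos <- function(n, mean, sd, lo = 0.2 * mean) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v > lo) { out[i] <- v; break }
    }
  }
  out
}

#' Simulate one force-displacement record
#'
#' Inverts the stress and stretch formulas: on the stretch grid
#' `[1, lambda_max]` the tissue stress is `scale * cauchy_stress(params, .)`,
#' the force is `sigma * A0 / lambda` plus the preload offset and additive
#' Gaussian noise (SD = `noise_sd` x peak model force; the preload-holding
#' reference sample itself is noise-free, as the machine servo holds the
#' preload set-point).  A short sub-preload lead-in is prepended so that
#' [preload_reference()] is exercised.
#'
#' Uses the current RNG state.
#'
#' @param params ground-truth [hyper_params()].
#' @param scale subject stiffness multiplier (> 0).
#' @param geometry a [specimen_geometry()].
#' @param tissue tissue tag.
#' @param lambda_max maximum simulated stretch (default: tissue's
#'   [default_lambda_max()]).
#' @param noise_sd relative force noise SD (0 for noiseless records).
#' @param step stretch grid step.
#' @param preload preload force, N.
#' @param specimen_id,subject_id identifiers.
#' @return An [fd_record()].
#' @export
simulate_record <- function(params, scale, geometry, tissue,
                            lambda_max = NULL, noise_sd = 0.01, step = 0.01,
                            preload = 0.1,
                            specimen_id = "sim", subject_id = "sim") {
  params <- as_params(params)
  if (!is_number(scale) || scale <= 0) stopf("scale must be positive")
  if (is.null(lambda_max)) lambda_max <- default_lambda_max(tissue)
  if (lambda_max <= 1) stopf("lambda_max must exceed 1")
  lam <- seq(1, lambda_max, by = step)
  sig <- scale * cauchy_stress(params, lam)
  t_model <- sig * geometry$A0 / lam
  noise <- if (noise_sd > 0) {
    e <- stats::rnorm(length(lam), 0, noise_sd * max(t_model))
    e[1] <- 0
    e
  } else 0
  force_main <- preload + t_model + noise
  d_pre <- 0.02 * geometry$L0
  disp_main <- d_pre + (lam - 1) * geometry$L0
  # lead-in below the preload so the crossing must be located
  disp <- c(0, d_pre / 2, disp_main)
  force <- c(0, preload / 2, force_main)
  fd_record(specimen_id, subject_id, tissue, disp, force, geometry)
}

#' Generate a synthetic donor cohort
#'
#' Draws the subject table (ages uniform within the group bands, sexes per
#' the configured counts), one stiffness scale per subject x tissue, and
#' per-specimen geometry, then simulates every force-displacement record.
#' Fully deterministic for a fixed `config$seed` (byte-identical CSVs on
#' disk).
#'
#' @param config a [cohort_config()].
#' @param dir optional output directory; when given, per-specimen record
#'   CSVs (under `records/`), `manifest.csv`, `subjects.csv` and
#'   `ground_truth.json` are written.
#' @param tissues tissues to simulate (default all three; restricting to
#'   `"cartilage"` speeds up modulus-only studies).
#' @return List of class `synthetic_cohort` with `records` (named list of
#'   [fd_record()]), `manifest`, `subjects` (data.frames) and
#'   `ground_truth` (subject scales and true coefficients).
#' @export
generate_cohort <- function(config, dir = NULL, tissues = TISSUES) {
  if (!inherits(config, "cohort_config")) stopf("config must be a cohort_config")
  tissues <- vapply(tissues, check_tissue, "")
  with_local_seed(config$seed, {
    counts <- c(young_female = config$n_young_f, young_male = config$n_young_m,
                old_female = config$n_old_f, old_male = config$n_old_m)
    n_sub <- sum(counts)
    groups <- rep(c("young", "young", "old", "old"), counts)
    sexes <- rep(c("female", "male", "female", "male"), counts)
    subjects <- data.frame(
      subject_id = sprintf("S%02d", seq_len(n_sub)),
      age = numeric(n_sub), age_group = groups, sex = sexes,
      stringsAsFactors = FALSE)
    if (n_sub > 0) {
      subjects$age <- round(ifelse(groups == "young",
                                   stats::runif(n_sub, 18, 36),
                                   stats::runif(n_sub, 49, 65)), 1)
    }
    records <- list(); manifest <- list(); gt_scales <- list()
    abbr <- c(cartilage = "car", smooth_muscle = "smu", connective = "con")
    for (i in seq_len(n_sub)) {
      sid <- subjects$subject_id[i]
      for (tis in tissues) {
        scale <- sample_subject_scale(config, tis, subjects$age_group[i], 1L)
        gt_scales[[length(gt_scales) + 1L]] <-
          data.frame(subject_id = sid, tissue = tis, scale = scale)
        geo_cfg <- config$geometry[[tis]]
        for (k in seq_len(config$specimens_per_tissue)) {
          L0 <- .rtrunc_pos(1, geo_cfg$L0[1], geo_cfg$L0[2])
          A0 <- .rtrunc_pos(1, geo_cfg$A0[1], geo_cfg$A0[2])
          spec_id <- sprintf("%s_%s_%d", sid, abbr[[tis]], k)
          rec <- simulate_record(config$tissue_params[[tis]], scale,
                                 specimen_geometry(L0, A0), tis,
                                 noise_sd = config$noise_sd,
                                 step = config$step, preload = config$preload,
                                 specimen_id = spec_id, subject_id = sid)
          records[[spec_id]] <- rec
          manifest[[length(manifest) + 1L]] <-
            data.frame(specimen_id = spec_id, subject_id = sid, tissue = tis,
                       L0_mm = L0, A0_mm2 = A0)
        }
      }
    }
    manifest <- if (length(manifest)) do.call(rbind, manifest) else
      data.frame(specimen_id = character(0), subject_id = character(0),
                 tissue = character(0), L0_mm = numeric(0), A0_mm2 = numeric(0))
    gt <- list(
      seed = config$seed,
      base_modulus_cartilage = base_modulus(config$tissue_params$cartilage),
      tissue_params = lapply(config$tissue_params,
                             function(p) list(model = p$model, coeffs = p$coeffs)),
      subject_scales = if (length(gt_scales)) do.call(rbind, gt_scales) else
        data.frame(subject_id = character(0), tissue = character(0),
                   scale = numeric(0)))
    out <- structure(list(records = records, manifest = manifest,
                          subjects = subjects, ground_truth = gt,
                          config = config),
                     class = "synthetic_cohort")
    if (!is.null(dir)) write_cohort(out, dir)
    out
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d records (seed %d)\n",
              nrow(x$subjects), length(x$records), x$config$seed))
  invisible(x)
}

#' Write / read a cohort to and from disk
#'
#' The on-disk layout is `records/<specimen_id>.csv` (displacement_mm,
#' force_N), `manifest.csv`, `subjects.csv` and `ground_truth.json`.
#'
#' @param cohort a `synthetic_cohort` (for writing).
#' @param dir directory.
#' @return `write_cohort()` the directory, invisibly; `read_cohort()` a list
#'   with `records`, `manifest` and `subjects`.
#' @export
write_cohort <- function(cohort, dir) {
  rec_dir <- file.path(dir, "records")
  dir.create(rec_dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$records) {
    write_record_csv(rec, file.path(rec_dir, paste0(rec$specimen_id, ".csv")))
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE, quote = FALSE)
  gt <- cohort$ground_truth
  gt$subject_scales <- as.list(gt$subject_scales)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) stopf("no manifest.csv under %s", dir)
  manifest <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  subj_path <- file.path(dir, "subjects.csv")
  subjects <- if (file.exists(subj_path)) {
    utils::read.csv(subj_path, stringsAsFactors = FALSE)
  } else NULL
  records <- list()
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    records[[m$specimen_id]] <- read_record_csv(
      file.path(dir, "records", paste0(m$specimen_id, ".csv")),
      m$specimen_id, m$subject_id, m$tissue, m$L0_mm, m$A0_mm2)
  }
  list(records = records, manifest = manifest, subjects = subjects)
}
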