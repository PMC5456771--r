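# Workflow orchestration: records -> curves -> per-tissue average curves and
# model rankings -> per-subject moduli -> cohort statistics, with disk-based
# command wrappers and a YAML run configuration.

# normalise the pipeline input: a synthetic_cohort, a read_cohort() list, or
# a directory path
.as_cohort_input <- function(input) {
  if (inherits(input, "synthetic_cohort")) {
    return(list(records = input$records, subjects = input$subjects))
  }
  if (is.character(input) && length(input) == 1L) {
    co <- read_cohort(input)
    return(list(records = co$records, subjects = co$subjects))
  }
  if (is.list(input) && !is.null(input$records)) {
    return(list(records = input$records, subjects = input$subjects))
  }
  stopf("input must be a synthetic_cohort, a cohort directory, or a list with $records")
}

#' Process records of one tissue into per-subject averaged curves
#'
#' Each record is preload-referenced and converted to a stress-stretch
#' curve; specimen curves are first averaged within subject, then the
#' subject curves are averaged across the cohort (two-stage averaging, so
#' each donor contributes equally regardless of specimen count).
#'
#' @param input a `synthetic_cohort`, a cohort directory, or a list with
#'   `$records`.
#' @param tissue tissue tag.
#' @param lambda_max averaging grid upper stretch (default: the tissue's
#'   [default_lambda_max()]).
#' @param preload preload level, N.
#' @param step averaging grid step.
#' @param subset_subjects optional subject ids to keep.
#' @return List with `average` (the cohort mean [stress_stretch_curve()])
#'   and `subject_curves` (named list of per-subject mean curves).
#' @export
tissue_average_curve <- function(input, tissue, lambda_max = NULL,
                                 preload = 0.1, step = 0.01,
                                 subset_subjects = NULL) {
  check_tissue(tissue)
  if (is.null(lambda_max)) lambda_max <- default_lambda_max(tissue)
  co <- .as_cohort_input(input)
  recs <- Filter(function(r) r$tissue == tissue, co$records)
  if (!is.null(subset_subjects)) {
    recs <- Filter(function(r) r$subject_id %in% subset_subjects, recs)
  }
  if (!length(recs)) stopf("no records for tissue '%s'", tissue)
  by_subject <- split(recs, vapply(recs, function(r) r$subject_id, ""))
  subject_curves <- lapply(by_subject, function(rs) {
    curves <- lapply(rs, function(r) record_to_curve(preload_reference(r, preload)))
    average_curves(curves, lambda_max = lambda_max, step = step)
  })
  avg <- average_curves(unname(subject_curves), lambda_max = lambda_max,
                        step = step)
  list(average = avg, subject_curves = subject_curves)
}

#' Per-subject linear moduli of a tissue
#'
#' Converts every record of the tissue to a curve, extracts the linear
#' modulus of each specimen over `[1, lambda_max]`, and averages specimens
#' within subject; subject metadata (age, age group, sex) is joined when
#' available.
#'
#' @inheritParams tissue_average_curve
#' @param lambda_max regression window upper stretch; default 1.2 for
#'   cartilage, the tissue's full analysed range otherwise.
#' @return data.frame with columns `subject_id`, `modulus` (MPa),
#'   `r_squared` (mean specimen fit R^2), `n_specimens`, and, if subject
#'   metadata is present, `age`, `age_group`, `sex`.
#' @export
subject_moduli <- function(input, tissue = "cartilage", lambda_max = NULL,
                           preload = 0.1) {
  check_tissue(tissue)
  if (is.null(lambda_max)) {
    lambda_max <- if (tissue == "cartilage") 1.2 else default_lambda_max(tissue)
  }
  co <- .as_cohort_input(input)
  recs <- Filter(function(r) r$tissue == tissue, co$records)
  if (!length(recs)) stopf("no records for tissue '%s'", tissue)
  per_spec <- lapply(recs, function(r) {
    lmod <- linear_modulus(record_to_curve(preload_reference(r, preload)),
                           lambda_max = lambda_max)
    data.frame(subject_id = r$subject_id, modulus = lmod$modulus,
               r_squared = lmod$r_squared, stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, per_spec)
  agg <- do.call(rbind, lapply(split(d, d$subject_id), function(g) {
    data.frame(subject_id = g$subject_id[1], modulus = mean(g$modulus),
               r_squared = mean(g$r_squared), n_specimens = nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  if (!is.null(co$subjects)) {
    agg <- merge(agg, co$subjects, by = "subject_id", sort = TRUE)
  }
  agg
}

#' Run configuration from YAML
#'
#' Reads a run configuration with optional blocks `cohort` (arguments to
#' [cohort_config()]), `fit` (`n_starts`, `seed`) and `anova` (`alpha`).
#' An explicit seed must be present under `cohort`.
#'
#' @param path YAML file path.
#' @return List with elements `cohort` (a [cohort_config()]), `fit`,
#'   `anova`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  ccfg <- do.call(cohort_config, c(y$cohort))
  fit <- utils::modifyList(list(n_starts = 16L, seed = 1L), as.list(y$fit))
  anova <- utils::modifyList(list(alpha = 0.05), as.list(y$anova))
  if (anova$alpha <= 0 || anova$alpha >= 1) stopf("alpha must lie in (0, 1)")
  list(cohort = ccfg, fit = fit, anova = anova)
}

#' Command-style pipeline stages
#'
#' Thin disk-based wrappers tying the stages into a reproducible workflow:
#' `cmd_simulate()` writes a synthetic cohort, `cmd_fit()` processes records
#' and writes per-tissue model rankings (an R^2 matrix of model x tissue)
#' and the Yeoh/Mooney-Rivlin coefficient table, `cmd_cohort()` writes group
#' statistics, per-tissue two-way ANOVA tables and normality diagnostics.
#' All stages are deterministic for fixed seeds.
#'
#' @param config a list as returned by [load_run_config()], or a
#'   [cohort_config()] (for `cmd_simulate`).
#' @param out_dir output directory.
#' @param in_dir cohort directory produced by `cmd_simulate()` (or any
#'   directory with the same layout).
#' @return Invisibly, the computed objects.
#' @export
cmd_simulate <- function(config, out_dir) {
  ccfg <- if (inherits(config, "cohort_config")) config else config$cohort
  if (!inherits(ccfg, "cohort_config")) stopf("no cohort configuration found")
  message(sprintf("simulate: seed %d -> %s", ccfg$seed, out_dir))
  cohort <- generate_cohort(ccfg, dir = out_dir)
  message(sprintf("simulate: wrote %d records for %d subjects",
                  length(cohort$records), nrow(cohort$subjects)))
  invisible(cohort)
}

#' @rdname cmd_simulate
#' @export
cmd_fit <- function(in_dir, out_dir, config = NULL) {
  fitcfg <- if (!is.null(config)) config$fit else list(n_starts = 16L, seed = 1L)
  preload <- if (!is.null(config)) config$cohort$preload else 0.1
  co <- .as_cohort_input(in_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  present <- intersect(TISSUES, unique(vapply(co$records, function(r) r$tissue, "")))
  if (!length(present)) stopf("no usable records found")
  if (length(present) < length(TISSUES)) {
    warnf("missing tissue(s): %s — partial output",
          paste(setdiff(TISSUES, present), collapse = ", "))
  }
  rankings <- list()
  for (tis in present) {
    avg <- tissue_average_curve(co, tis, preload = preload)$average
    rk <- fit_all_models(avg, n_starts = fitcfg$n_starts, seed = fitcfg$seed)
    rankings[[tis]] <- rk
    for (f in rk$fits) {
      if (!f$converged) warnf("%s/%s did not converge", tis, f$model)
    }
    report <- lapply(rk$fits, function(f) list(
      tissue = tis, model = f$model, coeffs = unname(f$coeffs),
      r_squared = f$r_squared, converged = f$converged,
      n_points = f$n_points, lambda_max = max(f$lambda)))
    jsonlite::write_json(report, file.path(out_dir, paste0("fits_", tis, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  # model x tissue R^2 matrix
  r2 <- data.frame(model = hyperelastic_models())
  for (tis in present) {
    r2[[tis]] <- vapply(r2$model, function(m) {
      f <- rankings[[tis]]$fits[[m]]
      if (is.null(f)) NA_real_ else round(f$r_squared, 3)
    }, 0)
  }
  names(r2) <- c("model", paste0("R2_", present))
  utils::write.csv(r2, file.path(out_dir, "model_r2_matrix.csv"),
                   row.names = FALSE, quote = FALSE)
  # Yeoh / Mooney-Rivlin coefficient table
  coefs <- do.call(rbind, lapply(c("yeoh", "mooney_rivlin"), function(m) {
    do.call(rbind, lapply(present, function(tis) {
      f <- rankings[[tis]]$fits[[m]]
      if (is.null(f)) return(NULL)
      a <- rep(NA_real_, 3); a[seq_along(f$coeffs)] <- f$coeffs
      data.frame(model = m, tissue = tis, r_squared = round(f$r_squared, 3),
                 a1_MPa = a[1], a2 = a[2], a3 = a[3])
    }))
  }))
  utils::write.csv(coefs, file.path(out_dir, "best_model_coefficients.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(rankings)
}

#' @rdname cmd_simulate
#' @param alpha significance level for flagging ANOVA effects.
#' @export
cmd_cohort <- function(in_dir, out_dir, config = NULL, alpha = NULL) {
  if (is.null(alpha)) alpha <- if (!is.null(config)) config$anova$alpha else 0.05
  preload <- if (!is.null(config)) config$cohort$preload else 0.1
  co <- .as_cohort_input(in_dir)
  if (is.null(co$subjects)) stopf("subject metadata required for cohort statistics")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  present <- intersect(TISSUES, unique(vapply(co$records, function(r) r$tissue, "")))
  out <- list()
  for (tis in present) {
    subj <- subject_moduli(co, tissue = tis, preload = preload)
    gs <- group_stats(subj)
    norm <- normality_check(subj$modulus)
    anova_tab <- tryCatch(two_way_anova(subj), error = function(e) {
      warnf("ANOVA skipped for %s: %s", tis, conditionMessage(e)); NULL
    })
    utils::write.csv(cbind(tissue = tis, gs$by_age_sex),
                     file.path(out_dir, paste0("group_stats_", tis, ".csv")),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(anova_tab)) {
      tab <- as.data.frame(anova_tab)
      tab$significant <- tab$p_value < alpha
      utils::write.csv(cbind(tissue = tis, tab),
                       file.path(out_dir, paste0("anova_", tis, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(
      list(tissue = tis, shapiro_W = norm$statistic, shapiro_p = norm$p_value,
           note = "no multiple-testing correction is applied across tissues"),
      file.path(out_dir, paste0("normality_", tis, ".json")),
      auto_unbox = TRUE, digits = NA)
    out[[tis]] <- list(subjects = subj, group_stats = gs, anova = anova_tab,
                       normality = norm)
  }
  invisible(out)
}
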