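# Cohort-level statistics: young/old x female/male comparison of tissue
# stiffness by two-way ANOVA with normality screening.

#' Assign donors to age groups
#'
#' The cohort design has two disjoint age bands: young donors aged 18-36 and
#' old donors aged 49-65.  Ages outside both bands are rejected.
#'
#' @param age age in years; vectorised.
#' @return Factor with levels `young`, `old`.
#' @export
assign_age_group <- function(age) {
  if (!is.numeric(age)) stopf("age must be numeric")
  out <- ifelse(age >= 18 & age <= 36, "young",
                ifelse(age >= 49 & age <= 65, "old", NA_character_))
  if (anyNA(out)) {
    stopf("age(s) outside the cohort bands [18, 36] and [49, 65]: %s",
          paste(age[is.na(out)], collapse = ", "))
  }
  factor(out, levels = c("young", "old"))
}

#' Group mean and standard deviation of a subject-level response
#'
#' Sample mean and sample SD (n - 1 denominator) per age group and per
#' age-group x sex cell.
#'
#' @param subjects data.frame with columns `age_group`, `sex` and the
#'   response column.
#' @param response name of the response column (default `"modulus"`).
#' @return List with data.frames `by_age` and `by_age_sex`, each with
#'   columns `n`, `mean`, `sd`.
#' @export
group_stats <- function(subjects, response = "modulus") {
  if (!all(c("age_group", "sex", response) %in% names(subjects))) {
    stopf("subjects must have columns age_group, sex, %s", response)
  }
  v <- subjects[[response]]
  smry <- function(idx) {
    data.frame(n = length(idx), mean = mean(v[idx]),
               sd = if (length(idx) > 1L) stats::sd(v[idx]) else NA_real_)
  }
  ag <- factor(subjects$age_group, levels = c("young", "old"))
  sx <- factor(subjects$sex, levels = c("female", "male"))
  by_age <- do.call(rbind, lapply(levels(ag), function(g) {
    idx <- which(ag == g)
    if (!length(idx)) { warnf("empty age group '%s' omitted", g); return(NULL) }
    cbind(data.frame(age_group = g), smry(idx))
  }))
  cells <- expand.grid(age_group = levels(ag), sex = levels(sx),
                       stringsAsFactors = FALSE)
  by_age_sex <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    idx <- which(ag == cells$age_group[i] & sx == cells$sex[i])
    if (!length(idx)) return(NULL)
    cbind(cells[i, , drop = FALSE], smry(idx))
  }))
  rownames(by_age) <- rownames(by_age_sex) <- NULL
  list(by_age = by_age, by_age_sex = by_age_sex, response = response)
}

#' Two-way ANOVA of stiffness on age group and sex
#'
#' Factorial analysis of variance of a subject-level stiffness measure on
#' age group, sex and their interaction.  The donor cohort is unbalanced
#' (13 young / 17 old), so Type II sums of squares are used
#' ([car::Anova()]); for balanced designs these coincide with the classical
#' decomposition.  If an age x sex cell is empty the interaction is dropped
#' with a warning.
#'
#' @param subjects data.frame with columns `age_group`, `sex` and the
#'   response.
#' @param response name of the response column (default `"modulus"`).
#' @return Object of class `anova_table`: a data.frame with rows
#'   `age_group`, `sex`, `age_group:sex`, `Residuals` and columns `sum_sq`,
#'   `df`, `F`, `p_value`.
#' @export
two_way_anova <- function(subjects, response = "modulus") {
  if (!all(c("age_group", "sex", response) %in% names(subjects))) {
    stopf("subjects must have columns age_group, sex, %s", response)
  }
  d <- data.frame(y = subjects[[response]],
                  age_group = factor(subjects$age_group, levels = c("young", "old")),
                  sex = factor(subjects$sex, levels = c("female", "male")))
  d <- droplevels(d[stats::complete.cases(d), ])
  if (nlevels(d$age_group) < 2L || nlevels(d$sex) < 2L) {
    stopf("both levels of age_group and sex must be present")
  }
  cell_n <- table(d$age_group, d$sex)
  form <- if (any(cell_n == 0)) {
    warnf("empty age x sex cell: interaction term dropped")
    y ~ age_group + sex
  } else {
    y ~ age_group * sex
  }
  fit <- stats::lm(form, data = d)
  if (fit$df.residual < 1L) stopf("no residual degrees of freedom")
  if (stats::var(d$y) == 0) {
    # constant response: every decomposition is exactly zero, F undefined
    effects <- attr(stats::terms(form), "term.labels")
    out <- data.frame(effect = c(effects, "Residuals"),
                      sum_sq = 0,
                      df = c(rep(1L, length(effects)), fit$df.residual),
                      F = NA_real_, p_value = NA_real_,
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("anova_table", "data.frame"),
                     response = response, lm_fit = fit))
  }
  a <- car::Anova(fit, type = 2)
  out <- data.frame(effect = rownames(a),
                    sum_sq = a[["Sum Sq"]],
                    df = a[["Df"]],
                    F = a[["F value"]],
                    p_value = a[["Pr(>F)"]],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("anova_table", "data.frame"),
            response = response, lm_fit = fit)
}

#' @export
print.anova_table <- function(x, ...) {
  cat(sprintf("Two-way ANOVA (Type II) of %s on age group and sex\n",
              attr(x, "response")))
  y <- as.data.frame(x)
  y$sum_sq <- signif(y$sum_sq, 5); y$F <- signif(y$F, 4)
  y$p_value <- signif(y$p_value, 3)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Normality screening of a stiffness sample
#'
#' Shapiro-Wilk test plus the theoretical-vs-sample quantile pairs used for
#' a normal Q-Q plot.
#'
#' @param values numeric vector, length >= 3.
#' @return List of class `normality_check` with `statistic` (Shapiro-Wilk
#'   W), `p_value`, and `qq` (data.frame with columns `theoretical`,
#'   `sample`).
#' @export
normality_check <- function(values) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(values) < 3L) stopf("need at least 3 values")
  sw <- stats::shapiro.test(values)
  qq <- stats::qqnorm(values, plot.it = FALSE)
  structure(list(statistic = unname(sw$statistic),
                 p_value = sw$p.value,
                 qq = data.frame(theoretical = qq$x, sample = qq$y)),
            class = "normality_check")
}

#' @export
print.normality_check <- function(x, ...) {
  cat(sprintf("Shapiro-Wilk W = %.4f, p = %.4g (n = %d)\n",
              x$statistic, x$p_value, nrow(x$qq)))
  invisible(x)
}

#' @export
plot.normality_check <- function(x, ...) {
  graphics::plot(x$qq$theoretical, x$qq$sample,
                 xlab = "Theoretical quantiles", ylab = "Sample quantiles",
                 main = "Normal Q-Q", ...)
  graphics::qqline(x$qq$sample)
  invisible(x)
}
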