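# Cohort-level statistics linking the arcade angle (and its one-year
# change) to choroidal thickness: spherical-equivalent computation and
# high-myopia filtering, paired baseline/follow-up change tests with
# normality-driven test choice, correlation and age/gender-adjusted
# regression, trend across angle groups, the multivariable change-of-pChT
# model with a collinearity (VIF) screen, and the automated-vs-manual
# validation metrics.

#' Spherical equivalent
#'
#' `SE = sphere + 0.5 * cylinder`, in diopters.
#'
#' @param sphere_d,cylinder_d Spherical and cylindrical power (D),
#'   vectorized.
#' @return Numeric vector of spherical equivalents (D).
#' @examples
#' compute_se(-8, -1) # -8.5
#' @export
compute_se <- function(sphere_d, cylinder_d) {
  stopifnot(is.numeric(sphere_d), is.numeric(cylinder_d))
  sphere_d + 0.5 * cylinder_d
}

#' Keep only highly myopic records
#'
#' High myopia is `SE <= -5.0 D`; the boundary is included.
#'
#' @param records A data frame with an `se_d` column.
#' @param cutoff_d Cutoff (default -5).
#' @return The filtered tibble.
#' @export
filter_high_myopia <- function(records, cutoff_d = -5.0) {
  stopifnot("se_d" %in% names(records))
  dplyr::filter(tibble::as_tibble(records), .data$se_d <= cutoff_d)
}

#' Paired baseline / follow-up change test
#'
#' Per-subject deltas of one variable; normality of the deltas is
#' assessed with the Shapiro-Wilk test, then a paired t-test is used for
#' normal deltas and otherwise a nonparametric alternative: by default
#' the Wilcoxon signed-rank test (the paired analogue), or the
#' Mann-Whitney U test of the two visits when
#' `paired_test = "auto-mannwhitney"` is requested for strict fidelity
#' to protocols that name it.
#'
#' @param baseline,followup Cohort tibbles linked by `subject_id`.
#' @param variable Column name to test.
#' @param paired_test `"auto-wilcoxon"` (default), `"auto-mannwhitney"`,
#'   `"t"` or `"wilcoxon"`.
#' @param normality_alpha Shapiro-Wilk significance level (default 0.05).
#' @return A one-row tibble: `variable`, `mean_change`, `sd_change`,
#'   `p_value`, `test_used`, `n`.
#' @export
paired_change_test <- function(baseline, followup, variable,
                               paired_test = c("auto-wilcoxon",
                                               "auto-mannwhitney",
                                               "t", "wilcoxon"),
                               normality_alpha = 0.05) {
  paired_test <- match.arg(paired_test)
  stopifnot(variable %in% names(baseline), variable %in% names(followup))
  m <- dplyr::inner_join(
    baseline[, c("subject_id", variable)],
    followup[, c("subject_id", variable)],
    by = "subject_id", suffix = c("_b", "_f")
  )
  if (nrow(m) < nrow(baseline) || nrow(m) < nrow(followup)) {
    stop_vaangle("baseline and follow-up subject ids do not match", "schema")
  }
  if (nrow(m) < 2) {
    stop_vaangle("need at least 2 linked subjects for a paired test",
                 "invalid_params")
  }
  d <- m[[paste0(variable, "_f")]] - m[[paste0(variable, "_b")]]
  n <- length(d)
  mean_change <- mean(d)
  sd_change <- stats::sd(d)

  if (sd_change == 0) {
    # all deltas identical: the t statistic degenerates
    p <- if (mean_change == 0) 1 else 0
    return(tibble::tibble(variable = variable, mean_change = mean_change,
                          sd_change = sd_change, p_value = p,
                          test_used = "paired t-test (degenerate)", n = n))
  }
  normal <- .shapiro_ok(d, normality_alpha)
  use_t <- switch(paired_test,
                  "t" = TRUE,
                  "wilcoxon" = FALSE,
                  normal)
  if (use_t) {
    p <- stats::t.test(d)$p.value
    test_used <- "paired t-test"
  } else if (paired_test == "auto-mannwhitney") {
    p <- suppressWarnings(
      stats::wilcox.test(m[[paste0(variable, "_f")]],
                         m[[paste0(variable, "_b")]])$p.value
    )
    test_used <- "Mann-Whitney U"
  } else {
    p <- suppressWarnings(stats::wilcox.test(d)$p.value)
    test_used <- "Wilcoxon signed-rank"
  }
  tibble::tibble(variable = variable, mean_change = mean_change,
                 sd_change = sd_change, p_value = p, test_used = test_used,
                 n = n)
}

.shapiro_ok <- function(x, alpha) {
  x <- x[is.finite(x)]
  if (length(x) > 5000) x <- x[seq_len(5000)]
  if (length(x) < 3 || stats::sd(x) == 0) return(FALSE)
  stats::shapiro.test(x)$p.value > alpha
}

#' Correlation with normality-driven method choice
#'
#' Pearson product-moment correlation with a two-sided p-value; falls
#' back to Spearman when either variable fails the Shapiro-Wilk
#' normality check (the method used is reported).
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param method `"auto"` (default), `"pearson"` or `"spearman"`.
#' @param normality_alpha Shapiro-Wilk significance level.
#' @return A one-row tibble: `r`, `p_value`, `method`, `n`.
#' @export
correlate <- function(x, y, method = c("auto", "pearson", "spearman"),
                      normality_alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) {
    stop_vaangle("need at least 3 complete pairs", "invalid_params")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_vaangle("zero variance: correlation undefined", "invalid_params")
  }
  if (method == "auto") {
    method <- if (.shapiro_ok(x, normality_alpha) &&
                  .shapiro_ok(y, normality_alpha)) "pearson" else "spearman"
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 method = method, n = length(x))
}

#' Age- and gender-adjusted regression
#'
#' Ordinary least squares of the response on the predictor of interest
#' plus adjustment covariates (age and gender by default), reporting the
#' coefficient, its 95% confidence interval, the standardized
#' coefficient and the two-sided p-value for every term.
#'
#' @param data A cohort tibble.
#' @param response,predictor Column names.
#' @param covariates Adjustment columns (default `c("age_yr", "gender")`;
#'   use `character(0)` for an unadjusted fit).
#' @return An object of class `vaa_model`; `tidy()` returns the term
#'   table, `glance()` the fit summary.
#' @export
adjusted_regression <- function(data, response, predictor,
                                covariates = c("age_yr", "gender")) {
  stopifnot(all(c(response, predictor, covariates) %in% names(data)))
  rhs <- paste(c(predictor, covariates), collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  n_terms <- length(covariates) + 2L
  if (nrow(data) <= n_terms) {
    stop_vaangle("need more observations than model terms", "invalid_params")
  }
  fit <- stats::lm(fml, data = data)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop_vaangle(paste0("rank-deficient fit; collinear terms: ",
                        paste(bad, collapse = ", ")),
                 "collinearity")
  }
  if (any(!is.finite(stats::model.matrix(fit))) ||
      qr(stats::model.matrix(fit))$rank < ncol(stats::model.matrix(fit))) {
    stop_vaangle("rank-deficient design matrix", "collinearity")
  }
  structure(list(fit = fit, table = .lm_term_table(fit),
                 response = response, predictor = predictor,
                 n = stats::nobs(fit)),
            class = "vaa_model")
}

# term table with unstandardized and standardized betas, 95% CI, p
.lm_term_table <- function(fit, vif = NULL) {
  sm <- summary(fit)
  co <- sm$coefficients
  mm <- stats::model.matrix(fit)
  y <- stats::model.response(stats::model.frame(fit))
  sy <- stats::sd(y)
  terms_all <- rownames(co)
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  beta <- co[, 1]
  se <- co[, 2]
  p <- co[, 4]
  # a perfect fit has zero residual variance: the CI collapses onto beta
  zero_se <- se < 1e-12 | !is.finite(se)
  ci[zero_se, 1] <- beta[zero_se]
  ci[zero_se, 2] <- beta[zero_se]
  p[zero_se] <- ifelse(abs(beta[zero_se]) > 1e-12, 0, 1)
  std <- vapply(terms_all, function(tm) {
    if (tm == "(Intercept)") return(NA_real_)
    if (sy == 0) return(0)
    beta[tm] * stats::sd(mm[, tm]) / sy
  }, numeric(1))
  tb <- tibble::tibble(
    term = terms_all,
    beta = unname(beta),
    ci95_low = unname(ci[, 1]),
    ci95_high = unname(ci[, 2]),
    standardized_beta = unname(std),
    p_value = unname(p),
    n = stats::nobs(fit)
  )
  if (!is.null(vif)) {
    tb$vif <- unname(vif[match(tb$term, names(vif))])
  }
  tb
}

#' Trend of choroidal thickness across angle groups
#'
#' Records are binned into `n_groups` quantile groups of the angle
#' variable; the p-for-trend is the significance of the ordinal group
#' score in a linear regression of the thickness variable on that score.
#'
#' @param records A cohort tibble.
#' @param vaa_variable Angle column used for grouping.
#' @param cht_variable Thickness column tested for trend.
#' @param n_groups Number of quantile groups (default 4; >= 2).
#' @return An object of class `vaa_trend` with `group_means` (tibble:
#'   `group`, `n`, `vaa_mean`, `cht_mean`, `cht_sd`) and `p_for_trend`.
#' @export
trend_by_group <- function(records, vaa_variable, cht_variable,
                           n_groups = 4L) {
  stopifnot(all(c(vaa_variable, cht_variable) %in% names(records)))
  if (n_groups < 2) {
    stop_vaangle("need at least 2 groups for a trend", "invalid_params")
  }
  v <- records[[vaa_variable]]
  ct <- records[[cht_variable]]
  ok <- is.finite(v) & is.finite(ct)
  v <- v[ok]
  ct <- ct[ok]
  br <- stats::quantile(v, probs = seq(0, 1, length.out = n_groups + 1L))
  if (anyDuplicated(br)) {
    stop_vaangle("quantile cut points are not distinct: empty group",
                 "invalid_params")
  }
  grp <- cut(v, breaks = br, include.lowest = TRUE, labels = FALSE)
  if (length(unique(grp)) < n_groups) {
    stop_vaangle("empty angle group", "invalid_params")
  }
  gm <- tibble::tibble(group = grp, vaa = v, cht = ct) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     vaa_mean = mean(.data$vaa),
                     cht_mean = mean(.data$cht),
                     cht_sd = stats::sd(.data$cht),
                     .groups = "drop")
  fit <- stats::lm(ct ~ grp)
  sm <- summary(fit)$coefficients
  p <- if (nrow(sm) >= 2 && is.finite(sm[2, 4])) sm[2, 4] else 0
  structure(list(group_means = gm, p_for_trend = p,
                 vaa_variable = vaa_variable, cht_variable = cht_variable,
                 n_groups = n_groups),
            class = "vaa_trend")
}

#' @export
print.vaa_trend <- function(x, ...) {
  cat(sprintf("<vaa_trend> %s across %d groups of %s: p for trend = %.4g\n",
              x$cht_variable, x$n_groups, x$vaa_variable, x$p_for_trend))
  print(x$group_means)
  invisible(x)
}

#' Per-subject changes between two visits
#'
#' @param baseline,followup Linked cohort tibbles.
#' @return A tibble with `subject_id`, `gender`, `age_yr` (baseline) and
#'   a `<var>_change` column for each numeric cohort variable.
#' @export
compute_changes <- function(baseline, followup) {
  .check_cohort_schema(baseline)
  .check_cohort_schema(followup)
  num_vars <- setdiff(.cohort_columns(),
                      c("subject_id", "visit", "gender", "age_yr"))
  m <- dplyr::inner_join(baseline, followup, by = "subject_id",
                         suffix = c("_b", "_f"))
  if (nrow(m) < nrow(baseline)) {
    stop_vaangle("unmatched subject ids between visits", "schema")
  }
  out <- tibble::tibble(subject_id = m$subject_id,
                        gender = m$gender_b,
                        age_yr = m$age_yr_b)
  for (v in num_vars) {
    out[[paste0(v, "_change")]] <- m[[paste0(v, "_f")]] - m[[paste0(v, "_b")]]
  }
  out
}

#' Multivariable change-of-pChT model with a collinearity screen
#'
#' Ordinary least squares of the peripapillary choroidal-thickness change
#' on gender, baseline age and the one-year changes of axial length,
#' spherical equivalent, peripapillary atrophy, disc-area tessellation
#' density, and one (only one) of the two angle changes. Perfectly
#' aliased predictors and predictors whose variance inflation factor
#' exceeds the ceiling are dropped before the final fit; each kept term
#' is reported with its coefficient, 95% CI, standardized coefficient,
#' p-value and VIF.
#'
#' @param changes A [compute_changes()] tibble.
#' @param response Response column (default `"pcht_um_change"`).
#' @param predictors Predictor columns; must contain exactly one of
#'   `vaa_1pd_deg_change` / `vaa_2pd_deg_change`.
#' @param vif_ceiling Predictors with VIF above this are dropped
#'   (default 10).
#' @return An object of class `vaa_change_model`; `tidy()` gives the
#'   term table (with `vif`), `glance()` the fit summary; `dropped`
#'   lists screened-out predictors.
#' @export
change_model_vif <- function(changes,
                             response = "pcht_um_change",
                             predictors = c("gender", "age_yr",
                                            "al_mm_change", "se_d_change",
                                            "ppa_mm2_change",
                                            "ftd_disc_pct_change",
                                            "vaa_1pd_deg_change"),
                             vif_ceiling = 10) {
  stopifnot(all(c(response, predictors) %in% names(changes)))
  vaa_terms <- intersect(c("vaa_1pd_deg_change", "vaa_2pd_deg_change"),
                         predictors)
  if (length(vaa_terms) > 1) {
    stop_vaangle(
      "supply only one angle-change variant per model (1PD or 2PD)",
      "invalid_params"
    )
  }
  dat <- changes[stats::complete.cases(changes[, c(response, predictors)]), ]
  dropped <- character(0)
  preds <- predictors

  fit_with <- function(preds) {
    fml <- stats::as.formula(paste(response, "~",
                                   paste(preds, collapse = " + ")))
    stats::lm(fml, data = dat)
  }

  repeat {
    fit <- fit_with(preds)
    co <- stats::coef(fit)
    if (anyNA(co)) {
      # perfectly aliased term: infinite VIF, screened out first
      aliased <- names(co)[is.na(co)]
      bad <- preds[vapply(preds, function(p) {
        any(startsWith(aliased, p))
      }, logical(1))]
      if (length(bad) == 0) bad <- preds[length(preds)]
      dropped <- c(dropped, bad[1])
      preds <- setdiff(preds, bad[1])
      if (length(preds) == 0) {
        stop_vaangle("all predictors aliased", "collinearity")
      }
      next
    }
    if (length(preds) < 2) break
    v <- car::vif(fit)
    if (is.matrix(v)) v <- v[, 1] # GVIF for factor terms
    if (max(v) <= vif_ceiling) break
    worst <- names(v)[which.max(v)]
    dropped <- c(dropped, worst)
    preds <- setdiff(preds, worst)
  }

  fit <- fit_with(preds)
  v <- if (length(preds) >= 2) {
    vv <- car::vif(fit)
    if (is.matrix(vv)) vv <- vv[, 1]
    # map term-level VIF onto coefficient rows (factor dummies share it)
    cn <- colnames(stats::model.matrix(fit))[-1]
    out <- stats::setNames(numeric(length(cn)), cn)
    for (nm in names(vv)) out[startsWith(cn, nm)] <- vv[[nm]]
    out
  } else {
    stats::setNames(rep(1, length(preds)), preds)
  }
  structure(list(fit = fit, table = .lm_term_table(fit, vif = v),
                 dropped = dropped, response = response,
                 predictors = preds, vif_ceiling = vif_ceiling,
                 n = stats::nobs(fit)),
            class = "vaa_change_model")
}

#' Automated-versus-manual validation metrics
#'
#' Root mean squared error (degrees) and mean relative error (%) of
#' automated angle measurements against paired manual readings.
#'
#' @param auto_angles,manual_angles Paired numeric vectors (degrees);
#'   manual angles must be positive.
#' @return A one-row tibble: `rmse_deg`, `relative_error_pct`, `n`.
#' @examples
#' validation_metrics(c(105, 95), c(100, 100))
#' @export
validation_metrics <- function(auto_angles, manual_angles) {
  stopifnot(length(auto_angles) == length(manual_angles),
            length(auto_angles) >= 1)
  if (any(manual_angles <= 0)) {
    stop_vaangle("manual angles must be positive", "invalid_params")
  }
  d <- auto_angles - manual_angles
  tibble::tibble(
    rmse_deg = sqrt(mean(d^2)),
    relative_error_pct = mean(abs(d) / manual_angles) * 100,
    n = length(d)
  )
}

# ---- broom-style methods ----------------------------------------------------

#' @export
#' @method tidy vaa_model
tidy.vaa_model <- function(x, ...) x$table

#' @export
#' @method tidy vaa_change_model
tidy.vaa_change_model <- function(x, ...) x$table

#' @export
#' @method tidy vaa_trend
tidy.vaa_trend <- function(x, ...) x$group_means

#' @export
#' @method glance vaa_model
glance.vaa_model <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(r.squared = sm$r.squared, adj.r.squared = sm$adj.r.squared,
                 sigma = sm$sigma, nobs = stats::nobs(x$fit))
}

#' @export
#' @method glance vaa_change_model
glance.vaa_change_model <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(r.squared = sm$r.squared, adj.r.squared = sm$adj.r.squared,
                 sigma = sm$sigma, nobs = stats::nobs(x$fit),
                 n_dropped = length(x$dropped))
}

#' @export
print.vaa_model <- function(x, ...) {
  cat(sprintf("<vaa_model> %s ~ %s (adjusted), n = %d\n",
              x$response, x$predictor, x$n))
  print(x$table)
  invisible(x)
}

#' @export
print.vaa_change_model <- function(x, ...) {
  cat(sprintf("<vaa_change_model> %s, n = %d%s\n", x$response, x$n,
              if (length(x$dropped)) paste0("; dropped: ",
                                            paste(x$dropped, collapse = ", ")) else ""))
  print(x$table)
  invisible(x)
}
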