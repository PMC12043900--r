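# Batch execution tying the pipeline together: measure a set of images,
# run the cohort analysis tables, and run the automated-vs-manual
# validation. All three are thin, deterministic drivers over the module
# functions; the CLI in inst/cli/vaa calls them.

#' Measure the arcade angle over a batch of images
#'
#' @param inputs A character vector of image paths, a list of
#'   [generate_fundus_scene()] scenes, or a single scene/image.
#' @param config A [vaa_config()].
#' @param out_dir Optional output directory: per-image JSON results and
#'   an aggregate `measurements.csv` (angles serialized with 2
#'   decimals) are written there.
#' @param strict If `TRUE` (or `config$strict_mode`), any QC failure
#'   raises an error instead of producing a flagged row.
#' @return A tibble with one row per image: `image_id`, `vaa_1pd_deg`,
#'   `vaa_2pd_deg`, `pd_px`, `qc_flags`.
#' @export
run_measure <- function(inputs, config = vaa_config(), out_dir = NULL,
                        strict = config$strict_mode) {
  if (inherits(inputs, "fundus_scene") || inherits(inputs, "Image")) {
    inputs <- list(inputs)
  }
  if (length(inputs) == 0) {
    stop_vaangle("no input images", "usage")
  }
  ids <- if (is.character(inputs)) {
    sub("\\.[A-Za-z]+$", "", basename(inputs))
  } else if (!is.null(names(inputs))) {
    names(inputs)
  } else {
    sprintf("image_%03d", seq_along(inputs))
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  rows <- vector("list", length(inputs))
  for (i in seq_along(inputs)) {
    input <- if (is.character(inputs)) inputs[[i]] else inputs[[i]]
    m <- tryCatch(
      measure_vaa(input, config = config, keep_artifacts = FALSE),
      error = function(e) {
        if (strict) stop(e)
        structure(list(vaa_1pd_deg = NA_real_, vaa_2pd_deg = NA_real_,
                       pd_px = NA_real_, qc_flags = "read_error"),
                  class = "vaa_measurement")
      }
    )
    if (strict && length(m$qc_flags) > 0) {
      stop_vaangle(
        sprintf("QC failure on %s: %s", ids[i],
                paste(m$qc_flags, collapse = ",")),
        "qc_failure"
      )
    }
    if (!is.null(out_dir)) {
      write_measurement_json(m, file.path(out_dir, paste0(ids[i], ".json")))
    }
    rows[[i]] <- tibble::tibble(
      image_id = ids[i],
      vaa_1pd_deg = m$vaa_1pd_deg,
      vaa_2pd_deg = m$vaa_2pd_deg,
      pd_px = m$pd_px,
      qc_flags = paste(m$qc_flags, collapse = ";")
    )
  }
  res <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    out <- res
    out$vaa_1pd_deg <- round(out$vaa_1pd_deg, 2)
    out$vaa_2pd_deg <- round(out$vaa_2pd_deg, 2)
    out$pd_px <- round(out$pd_px, 2)
    utils::write.csv(out, file.path(out_dir, "measurements.csv"),
                     row.names = FALSE)
  }
  res
}

#' Run the full cohort analysis
#'
#' Produces the three standard tables: paired baseline/follow-up change
#' per variable; cross-sectional correlation plus age/gender-adjusted
#' regression of each ocular parameter on the two angles; and the
#' multivariable change-of-pChT model (one block per angle variant) with
#' VIFs.
#'
#' @param baseline,followup Cohort tibbles (or CSV paths) in the
#'   standard schema.
#' @param config A [vaa_config()] (uses `stats.*` keys).
#' @param out_dir Optional directory for `table1_change.csv`,
#'   `table2_correlates.csv`, `table3_change_model.csv`.
#' @return A list of class `vaa_cohort_tables` with tibbles `change`
#'   (paired tests), `correlates`, `change_model`.
#' @export
run_cohort <- function(baseline, followup, config = vaa_config(),
                       out_dir = NULL) {
  if (is.character(baseline)) baseline <- read_cohort_csv(baseline)
  if (is.character(followup)) followup <- read_cohort_csv(followup)
  .check_cohort_schema(baseline)
  .check_cohort_schema(followup)

  change_vars <- c("age_yr", "bmi", "al_mm", "se_d", "mcht_um", "pcht_um",
                   "ftd_macula_pct", "ftd_disc_pct", "ppa_mm2",
                   "vaa_1pd_deg", "vaa_2pd_deg")
  tab1 <- dplyr::bind_rows(lapply(change_vars, function(v) {
    tb <- paired_change_test(baseline, followup, v,
                             paired_test = config$stats.paired_test)
    tb$baseline_mean <- mean(baseline[[v]])
    tb$baseline_sd <- stats::sd(baseline[[v]])
    tb$followup_mean <- mean(followup[[v]])
    tb$followup_sd <- stats::sd(followup[[v]])
    tb[, c("variable", "baseline_mean", "baseline_sd", "followup_mean",
           "followup_sd", "mean_change", "sd_change", "p_value",
           "test_used", "n")]
  }))

  params <- c("al_mm", "se_d", "mcht_um", "pcht_um", "ppa_mm2",
              "ftd_macula_pct", "ftd_disc_pct")
  tab2 <- dplyr::bind_rows(lapply(c("vaa_1pd_deg", "vaa_2pd_deg"), function(vv) {
    dplyr::bind_rows(lapply(params, function(p) {
      co <- correlate(baseline[[p]], baseline[[vv]])
      fit <- adjusted_regression(baseline, response = vv, predictor = p)
      row <- tidy(fit)[tidy(fit)$term == p, ]
      tibble::tibble(vaa_variable = vv, parameter = p,
                     r = co$r, r_p_value = co$p_value,
                     beta = row$beta, ci95_low = row$ci95_low,
                     ci95_high = row$ci95_high,
                     beta_p_value = row$p_value, n = co$n)
    }))
  }))

  ch <- compute_changes(baseline, followup)
  tab3 <- dplyr::bind_rows(lapply(c("1pd", "2pd"), function(variant) {
    preds <- c("gender", "age_yr", "al_mm_change", "se_d_change",
               "ppa_mm2_change", "ftd_disc_pct_change",
               paste0("vaa_", variant, "_deg_change"))
    fit <- change_model_vif(ch, predictors = preds,
                            vif_ceiling = config$stats.vif_ceiling)
    tb <- tidy(fit)
    tb$vaa_variant <- variant
    tb
  }))

  out <- structure(list(change = tab1, correlates = tab2,
                        change_model = tab3),
                   class = "vaa_cohort_tables")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(tab1, file.path(out_dir, "table1_change.csv"),
                     row.names = FALSE)
    utils::write.csv(tab2, file.path(out_dir, "table2_correlates.csv"),
                     row.names = FALSE)
    utils::write.csv(tab3, file.path(out_dir, "table3_change_model.csv"),
                     row.names = FALSE)
  }
  out
}

#' @export
print.vaa_cohort_tables <- function(x, ...) {
  cat("<vaa_cohort_tables>\n$change (paired baseline/follow-up tests):\n")
  print(x$change)
  cat("\n$correlates (correlation + adjusted regression):\n")
  print(x$correlates)
  cat("\n$change_model (multivariable pChT-change model):\n")
  print(x$change_model)
  invisible(x)
}

#' Automated-versus-manual validation over a paired table
#'
#' @param paired A tibble (or CSV path) with columns
#'   `auto_vaa_1pd_deg`, `manual_vaa_1pd_deg`, `auto_vaa_2pd_deg`,
#'   `manual_vaa_2pd_deg`.
#' @return A tibble with one row per angle variant: `variant`,
#'   `rmse_deg`, `relative_error_pct`, `n`.
#' @export
run_validate <- function(paired) {
  if (is.character(paired)) {
    paired <- tibble::as_tibble(utils::read.csv(paired))
  }
  need <- c("auto_vaa_1pd_deg", "manual_vaa_1pd_deg",
            "auto_vaa_2pd_deg", "manual_vaa_2pd_deg")
  missing_cols <- setdiff(need, names(paired))
  if (length(missing_cols) > 0) {
    stop_vaangle(paste0("validation table is missing columns: ",
                        paste(missing_cols, collapse = ", ")),
                 "schema")
  }
  if (anyNA(paired[, need])) {
    stop_vaangle("validation table has unpaired (missing) entries", "schema")
  }
  dplyr::bind_rows(
    dplyr::mutate(validation_metrics(paired$auto_vaa_1pd_deg,
                                     paired$manual_vaa_1pd_deg),
                  variant = "1pd", .before = 1),
    dplyr::mutate(validation_metrics(paired$auto_vaa_2pd_deg,
                                     paired$manual_vaa_2pd_deg),
                  variant = "2pd", .before = 1)
  )
}
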