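# Synthetic two-visit cohort of highly myopic eyes. Baseline covariates
# follow a single-factor Gaussian model whose loadings reproduce the
# targeted correlations between the arcade angles and the ocular
# parameters; the follow-up visit adds correlated one-year changes, with
# the change of peripapillary choroidal thickness generated from an
# explicit linear model so that regression recovery can be tested
# against a known truth.

#' Parameters of the synthetic cohort generator
#'
#' Defaults reproduce the baseline means/SDs, change means/SDs, the sign
#' and magnitude structure of the cross-sectional correlations, and the
#' change-model coefficients observed in a one-year cohort of 277 highly
#' myopic children (e.g. VAA(1PD) 128.38 +/- 9.56 degrees at baseline,
#' change -0.67 +/- 2.75 degrees; true change-model slope 0.855 um per
#' degree of VAA(1PD) change).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param means,sds Named numeric vectors of baseline means / SDs for
#'   `age_yr`, `bmi`, `al_mm`, `se_d`, `mcht_um`, `pcht_um`,
#'   `ftd_macula_pct`, `ftd_disc_pct`, `ppa_mm2`, `vaa_1pd_deg`,
#'   `vaa_2pd_deg`. Entries override the defaults.
#' @param r_targets Named target correlations of VAA(1PD) with the ocular
#'   parameters (signs shared by VAA(2PD)).
#' @param vaa_loading Loading of the arcade angles on the latent severity
#'   factor; correlation targets are met as `loading_j = r_j /
#'   vaa_loading`.
#' @param vaa_shared Loading of both angles on a second, angle-specific
#'   shared factor (controls their mutual correlation).
#' @param change_means,change_sds Named one-year change means / SDs for
#'   `age_yr`, `bmi`, `al_mm`, `se_d`, `mcht_um`, `ftd_macula_pct`,
#'   `ftd_disc_pct`, `ppa_mm2`, `vaa_1pd_deg`, `vaa_2pd_deg` (entries
#'   override defaults).
#' @param change_coefs True coefficients of the change-of-pChT model
#'   (named: `gender_boy`, `age`, `al_change`, `se_change`,
#'   `ppa_change`, `ftd_disc_change`, `vaa_change`).
#' @param change_model_variant Which angle drives the generated pChT
#'   change: `"1pd"` (slope default 0.855 um/degree) or `"2pd"` (0.719).
#' @param pcht_change_mean Target marginal mean of the pChT change (um).
#' @param pcht_change_noise_sd Residual SD of the pChT change model (um);
#'   the default yields a marginal SD near 10.9 um.
#' @param proportion_boys Proportion of boys.
#' @param seed Integer seed; generation is reproducible.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 277L,
                          means = NULL, sds = NULL,
                          r_targets = NULL,
                          vaa_loading = 0.6, vaa_shared = 0.55,
                          change_means = NULL, change_sds = NULL,
                          change_coefs = NULL,
                          change_model_variant = c("1pd", "2pd"),
                          pcht_change_mean = 1.69,
                          pcht_change_noise_sd = 10.2,
                          proportion_boys = 0.444,
                          seed = 1L) {
  change_model_variant <- match.arg(change_model_variant)
  def_means <- c(age_yr = 13.27, bmi = 19.71, al_mm = 26.66, se_d = -8.54,
                 mcht_um = 186.09, pcht_um = 111.72, ftd_macula_pct = 4.86,
                 ftd_disc_pct = 6.58, ppa_mm2 = 0.51,
                 vaa_1pd_deg = 128.38, vaa_2pd_deg = 110.25)
  def_sds <- c(age_yr = 2.90, bmi = 4.16, al_mm = 1.08, se_d = 2.09,
               mcht_um = 50.47, pcht_um = 36.63, ftd_macula_pct = 6.85,
               ftd_disc_pct = 8.82, ppa_mm2 = 0.38,
               vaa_1pd_deg = 9.56, vaa_2pd_deg = 11.97)
  def_r <- c(al_mm = -0.194, se_d = 0.142, mcht_um = 0.297, pcht_um = 0.213,
             ppa_mm2 = -0.347, ftd_macula_pct = -0.179, ftd_disc_pct = -0.148)
  def_cmeans <- c(age_yr = 0.96, bmi = 0.77, al_mm = 0.20, se_d = -0.43,
                  mcht_um = 0.50, ftd_macula_pct = 0.60, ftd_disc_pct = 0.49,
                  ppa_mm2 = 0.05, vaa_1pd_deg = -0.67, vaa_2pd_deg = -0.88)
  def_csds <- c(age_yr = 0.93, bmi = 1.42, al_mm = 0.18, se_d = 0.46,
                mcht_um = 15.23, ftd_macula_pct = 0.01, ftd_disc_pct = 2.90,
                ppa_mm2 = 0.15, vaa_1pd_deg = 2.75, vaa_2pd_deg = 4.23)
  def_coefs <- c(gender_boy = 0.243, age = -0.569, al_change = -7.521,
                 se_change = 1.143, ppa_change = 0.026,
                 ftd_disc_change = -0.730,
                 vaa_change = if (change_model_variant == "1pd") 0.855 else 0.719)
  merge_named <- function(def, usr) {
    if (!is.null(usr)) def[names(usr)] <- usr
    def
  }
  p <- structure(list(
    n_subjects = as.integer(n_subjects),
    means = merge_named(def_means, means),
    sds = merge_named(def_sds, sds),
    r_targets = merge_named(def_r, r_targets),
    vaa_loading = vaa_loading,
    vaa_shared = vaa_shared,
    change_means = merge_named(def_cmeans, change_means),
    change_sds = merge_named(def_csds, change_sds),
    change_coefs = merge_named(def_coefs, change_coefs),
    change_model_variant = change_model_variant,
    pcht_change_mean = pcht_change_mean,
    pcht_change_noise_sd = pcht_change_noise_sd,
    proportion_boys = proportion_boys,
    seed = as.integer(seed)
  ), class = "cohort_params")
  if (p$n_subjects < 2) {
    stop_vaangle("n_subjects must be at least 2", "invalid_params")
  }
  if (any(p$sds <= 0) || any(p$change_sds < 0)) {
    stop_vaangle("SDs must be positive", "invalid_params")
  }
  if (any(abs(p$r_targets / p$vaa_loading) >= 1)) {
    stop_vaangle("r_targets/vaa_loading must stay below 1 in magnitude",
                 "invalid_params")
  }
  p
}

#' Generate a linked baseline / follow-up cohort
#'
#' Baseline: each ocular parameter loads on a latent myopia-severity
#' factor so that its correlation with VAA(1PD) matches the target; both
#' angles additionally share an angle-specific factor. Follow-up equals
#' baseline plus one-year changes drawn from a correlated change model;
#' the change of peripapillary choroidal thickness is generated as
#' `intercept + coefficients x predictors + noise` with a known true
#' slope on the chosen angle's change.
#'
#' @param params A [cohort_params()] object.
#' @return A list of class `cohort_pair` with tibbles `baseline` and
#'   `followup` in the standard cohort schema (`subject_id`, `visit`,
#'   `age_yr`, `gender`, `bmi`, `al_mm`, `se_d`, `mcht_um`, `pcht_um`,
#'   `ftd_macula_pct`, `ftd_disc_pct`, `ppa_mm2`, `vaa_1pd_deg`,
#'   `vaa_2pd_deg`).
#' @examples
#' coh <- generate_cohort(cohort_params(n_subjects = 100, seed = 2))
#' mean(coh$baseline$vaa_1pd_deg)
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_subjects
  rs <- .preserve_rng()
  on.exit(.restore_rng(rs), add = TRUE)
  set.seed(params$seed)

  mu <- params$means
  sd_ <- params$sds
  r <- params$r_targets
  a <- params$vaa_loading
  b <- params$vaa_shared

  z <- stats::rnorm(n) # latent severity (more severe = larger z)
  w <- stats::rnorm(n) # angle-specific shared factor
  load_std <- function(lambda) {
    lambda * z + sqrt(1 - lambda^2) * stats::rnorm(n)
  }
  vaa_std <- function() {
    cres <- sqrt(max(1 - a^2 - b^2, 0))
    a * z + b * w + cres * stats::rnorm(n)
  }
  mk <- function(var, lambda) mu[[var]] + sd_[[var]] * load_std(lambda)

  gender <- ifelse(stats::runif(n) < params$proportion_boys, "boy", "girl")
  baseline <- tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    visit = "baseline",
    age_yr = mu[["age_yr"]] + sd_[["age_yr"]] * stats::rnorm(n),
    gender = gender,
    bmi = mu[["bmi"]] + sd_[["bmi"]] * stats::rnorm(n),
    al_mm = mk("al_mm", r[["al_mm"]] / a),
    se_d = mk("se_d", r[["se_d"]] / a),
    mcht_um = mk("mcht_um", r[["mcht_um"]] / a),
    pcht_um = mk("pcht_um", r[["pcht_um"]] / a),
    ftd_macula_pct = mk("ftd_macula_pct", r[["ftd_macula_pct"]] / a),
    ftd_disc_pct = mk("ftd_disc_pct", r[["ftd_disc_pct"]] / a),
    ppa_mm2 = mk("ppa_mm2", r[["ppa_mm2"]] / a),
    vaa_1pd_deg = mu[["vaa_1pd_deg"]] + sd_[["vaa_1pd_deg"]] * vaa_std(),
    vaa_2pd_deg = mu[["vaa_2pd_deg"]] + sd_[["vaa_2pd_deg"]] * vaa_std()
  )

  # correlated one-year changes on a progression factor dz
  cm <- params$change_means
  cs <- params$change_sds
  dz <- stats::rnorm(n)
  dw <- stats::rnorm(n) # shared angle-change factor
  dload <- c(age_yr = 0, bmi = 0, al_mm = 0.4, se_d = -0.4, mcht_um = -0.3,
             ftd_macula_pct = 0, ftd_disc_pct = 0.3, ppa_mm2 = 0.3,
             vaa_1pd_deg = -0.5, vaa_2pd_deg = -0.5)
  dch <- function(var, extra = 0) {
    lam <- dload[[var]]
    resid <- sqrt(max(1 - lam^2 - extra^2, 0))
    cm[[var]] + cs[[var]] *
      (lam * dz + extra * dw + resid * stats::rnorm(n))
  }
  ch <- tibble::tibble(
    age_yr = dch("age_yr"),
    bmi = dch("bmi"),
    al_mm = dch("al_mm"),
    se_d = dch("se_d"),
    mcht_um = dch("mcht_um"),
    ftd_macula_pct = dch("ftd_macula_pct"),
    ftd_disc_pct = dch("ftd_disc_pct"),
    ppa_mm2 = dch("ppa_mm2"),
    vaa_1pd_deg = dch("vaa_1pd_deg", extra = 0.6),
    vaa_2pd_deg = dch("vaa_2pd_deg", extra = 0.6)
  )

  # structural change of peripapillary ChT with a known true slope
  cf <- params$change_coefs
  vaa_change <- if (params$change_model_variant == "1pd") {
    ch$vaa_1pd_deg
  } else {
    ch$vaa_2pd_deg
  }
  lin <- cf[["gender_boy"]] * (gender == "boy") +
    cf[["age"]] * baseline$age_yr +
    cf[["al_change"]] * ch$al_mm +
    cf[["se_change"]] * ch$se_d +
    cf[["ppa_change"]] * ch$ppa_mm2 +
    cf[["ftd_disc_change"]] * ch$ftd_disc_pct +
    cf[["vaa_change"]] * vaa_change
  expected_lin <- cf[["gender_boy"]] * params$proportion_boys +
    cf[["age"]] * mu[["age_yr"]] +
    cf[["al_change"]] * cm[["al_mm"]] +
    cf[["se_change"]] * cm[["se_d"]] +
    cf[["ppa_change"]] * cm[["ppa_mm2"]] +
    cf[["ftd_disc_change"]] * cm[["ftd_disc_pct"]] +
    cf[["vaa_change"]] *
      cm[[if (params$change_model_variant == "1pd") "vaa_1pd_deg" else "vaa_2pd_deg"]]
  intercept <- params$pcht_change_mean - expected_lin
  pcht_change <- intercept + lin +
    params$pcht_change_noise_sd * stats::rnorm(n)

  followup <- baseline
  followup$visit <- "followup"
  for (v in names(ch)) followup[[v]] <- baseline[[v]] + ch[[v]]
  followup$pcht_um <- baseline$pcht_um + pcht_change

  structure(list(baseline = baseline, followup = followup, params = params),
            class = "cohort_pair")
}

#' @export
print.cohort_pair <- function(x, ...) {
  cat(sprintf("<cohort_pair> %d subjects, two visits (true d-pChT slope %.3f um/deg on VAA(%s) change)\n",
              nrow(x$baseline), x$params$change_coefs[["vaa_change"]],
              toupper(x$params$change_model_variant)))
  invisible(x)
}

#' Write / read a cohort table in the standard CSV schema
#'
#' The schema has exactly the columns `subject_id, visit, age_yr, gender,
#' bmi, al_mm, se_d, mcht_um, pcht_um, ftd_macula_pct, ftd_disc_pct,
#' ppa_mm2, vaa_1pd_deg, vaa_2pd_deg`.
#'
#' @param x A cohort tibble.
#' @param path CSV path.
#' @return `read_cohort_csv()` returns a validated tibble.
#' @export
write_cohort_csv <- function(x, path) {
  .check_cohort_schema(x)
  utils::write.csv(x[, .cohort_columns()], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  x <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  .check_cohort_schema(x)
  x
}

.cohort_columns <- function() {
  c("subject_id", "visit", "age_yr", "gender", "bmi", "al_mm", "se_d",
    "mcht_um", "pcht_um", "ftd_macula_pct", "ftd_disc_pct", "ppa_mm2",
    "vaa_1pd_deg", "vaa_2pd_deg")
}

.check_cohort_schema <- function(x) {
  missing_cols <- setdiff(.cohort_columns(), names(x))
  if (length(missing_cols) > 0) {
    stop_vaangle(paste0("cohort table is missing columns: ",
                        paste(missing_cols, collapse = ", ")),
                 "schema")
  }
  invisible(x)
}
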