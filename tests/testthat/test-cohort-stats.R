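test_that("spherical equivalent and the high-myopia filter are exact", {
  expect_identical(compute_se(-8.0, -1.0), -8.5)
  expect_identical(compute_se(-5.0, 0), -5.0)
  expect_identical(compute_se(0, 2.0), 1.0)
  # linearity
  expect_equal(compute_se(c(1, 2), c(3, 4)) + compute_se(c(5, 6), c(7, 8)),
               compute_se(c(6, 8), c(10, 12)))

  rec <- tibble::tibble(se_d = c(-5.0, -4.75, -5.25, -7), id = 1:4)
  kept <- filter_high_myopia(rec)
  expect_equal(kept$se_d, c(-5.0, -5.25, -7)) # boundary included
  expect_equal(nrow(filter_high_myopia(rec[0, ])), 0)
})

test_that("paired change test handles identity, degeneracy and power", {
  coh <- generate_cohort(cohort_params(n_subjects = 60, seed = 8))
  same <- paired_change_test(coh$baseline, coh$baseline, "vaa_1pd_deg")
  expect_equal(same$mean_change, 0)
  expect_equal(same$p_value, 1)

  one <- coh$baseline[1, ]
  expect_error(paired_change_test(one, one, "vaa_1pd_deg"),
               class = "vaangle_invalid_params")

  unmatched <- coh$baseline
  unmatched$subject_id <- paste0("X", unmatched$subject_id)
  expect_error(paired_change_test(coh$baseline, unmatched, "vaa_1pd_deg"),
               class = "vaangle_schema")

  # power to detect the observed angle change (-0.67 +/- 2.75 at
  # n = 277) at the p < 0.001 level matches the noncentral-t prediction
  hits <- vapply(1:60, function(r) {
    coh <- generate_cohort(cohort_params(n_subjects = 277, seed = 300 + r))
    paired_change_test(coh$baseline, coh$followup,
                       "vaa_1pd_deg")$p_value < 0.001
  }, logical(1))
  ncp <- 0.67 / (2.75 / sqrt(277))
  tcrit <- stats::qt(1 - 0.001 / 2, df = 276)
  power <- stats::pt(-tcrit, df = 276, ncp = ncp) +
    1 - stats::pt(tcrit, df = 276, ncp = ncp)
  mc_se <- sqrt(power * (1 - power) / 60)
  expect_lt(abs(mean(hits) - power), 3.5 * mc_se)
})

test_that("the Mann-Whitney variant runs when configured", {
  coh <- generate_cohort(cohort_params(n_subjects = 80, seed = 12))
  out <- paired_change_test(coh$baseline, coh$followup, "ppa_mm2",
                            paired_test = "auto-mannwhitney")
  expect_true(out$test_used %in% c("paired t-test", "Mann-Whitney U"))
  forced <- paired_change_test(coh$baseline, coh$followup, "ppa_mm2",
                               paired_test = "wilcoxon")
  expect_equal(forced$test_used, "Wilcoxon signed-rank")
})

test_that("correlate reports r, p and the method actually used", {
  x <- seq(1, 10)
  perfect <- correlate(x, x, method = "pearson")
  expect_equal(perfect$r, 1)

  set.seed(9)
  null_r <- correlate(rnorm(10000), rnorm(10000), method = "pearson")
  expect_lt(abs(null_r$r), 0.05)
  expect_gt(null_r$p_value, 1e-4)

  expect_error(correlate(rep(1, 5), 1:5), class = "vaangle_invalid_params")

  coh <- generate_cohort(cohort_params(n_subjects = 10000, seed = 7))
  got <- correlate(coh$baseline$vaa_1pd_deg, coh$baseline$mcht_um,
                   method = "pearson")
  expect_equal(got$r, 0.297, tolerance = 0.03 / 0.297)
})

test_that("adjusted regression recovers exact and simulated slopes", {
  d <- tibble::tibble(x = seq(0, 10, length.out = 30), y = 2 * seq(0, 10, length.out = 30))
  fit <- suppressWarnings( # a perfect fit makes summary() grumble
    adjusted_regression(d, "y", "x", covariates = character(0))
  )
  row <- tidy(fit)[tidy(fit)$term == "x", ]
  expect_equal(row$beta, 2, tolerance = 1e-9)
  expect_equal(row$ci95_high - row$ci95_low, 0, tolerance = 1e-9)

  d$const <- 1
  expect_error(adjusted_regression(d, "y", "const", covariates = character(0)),
               class = "vaangle_collinearity")

  # conditional slope of SE on the angle given age and gender
  est <- vapply(1:40, function(r) {
    coh <- generate_cohort(cohort_params(n_subjects = 277, seed = 700 + r))
    fit <- adjusted_regression(coh$baseline, "se_d", "vaa_1pd_deg")
    tidy(fit)$beta[tidy(fit)$term == "vaa_1pd_deg"]
  }, numeric(1))
  truth <- 0.142 * 2.09 / 9.56 # implied slope of the generator model
  expect_lt(abs(mean(est) - truth) / truth, 0.10)
})

test_that("trend across angle groups behaves under signal and under the null", {
  d <- tibble::tibble(vaa = seq_len(200), cht = seq_len(200) * 0.5)
  tr <- trend_by_group(d, "vaa", "cht")
  expect_true(all(diff(tr$group_means$cht_mean) > 0))
  expect_lt(tr$p_for_trend, 1e-10)
  expect_equal(nrow(tidy(tr)), 4)

  expect_error(trend_by_group(d, "vaa", "cht", n_groups = 1),
               class = "vaangle_invalid_params")
  const <- tibble::tibble(vaa = rep(1, 50), cht = rnorm(50))
  expect_error(trend_by_group(const, "vaa", "cht"),
               class = "vaangle_invalid_params")
})

test_that("the change model screens collinearity and reports VIFs", {
  set.seed(15)
  n <- 120
  # orthonormal (and centred, hence uncorrelated) predictors: VIF = 1
  q <- qr.Q(qr(scale(matrix(rnorm(n * 3), n, 3), scale = FALSE)))
  d <- tibble::tibble(y = rnorm(n), a = q[, 1], b = q[, 2], cc = q[, 3])
  fit <- change_model_vif(d, response = "y", predictors = c("a", "b", "cc"))
  expect_true(all(abs(tidy(fit)$vif[-1] - 1) < 1e-6))

  # duplicated predictor: aliased, screened out
  d$a2 <- d$a
  fit2 <- change_model_vif(d, response = "y",
                           predictors = c("a", "a2", "b"))
  expect_true("a2" %in% fit2$dropped || "a" %in% fit2$dropped)
  expect_equal(length(fit2$predictors), 2)

  # both angle variants in one model are refused
  coh <- generate_cohort(cohort_params(n_subjects = 50, seed = 2))
  ch <- compute_changes(coh$baseline, coh$followup)
  expect_error(
    change_model_vif(ch, predictors = c("gender", "vaa_1pd_deg_change",
                                        "vaa_2pd_deg_change")),
    class = "vaangle_invalid_params"
  )
})

test_that("the change model recovers the generated slope with honest CIs", {
  res <- lapply(1:50, function(r) {
    coh <- generate_cohort(cohort_params(n_subjects = 277, seed = 900 + r))
    ch <- compute_changes(coh$baseline, coh$followup)
    fit <- change_model_vif(ch)
    tidy(fit)[tidy(fit)$term == "vaa_1pd_deg_change", ]
  })
  est <- vapply(res, `[[`, numeric(1), "beta")
  cover <- vapply(res, function(r) {
    r$ci95_low <= 0.855 && 0.855 <= r$ci95_high
  }, logical(1))
  expect_lt(abs(mean(est) - 0.855) / 0.855, 0.10)
  expect_gt(mean(cover), 0.85)
  g <- glance(change_model_vif(compute_changes(
    generate_cohort(cohort_params(n_subjects = 100, seed = 1))$baseline,
    generate_cohort(cohort_params(n_subjects = 100, seed = 1))$followup
  )))
  expect_true(all(c("r.squared", "nobs") %in% names(g)))
})

test_that("validation metrics match closed-form and independent recomputation", {
  same <- validation_metrics(c(100, 120), c(100, 120))
  expect_equal(same$rmse_deg, 0)
  expect_equal(same$relative_error_pct, 0)

  shifted <- validation_metrics(rep(105, 8), rep(100, 8))
  expect_equal(shifted$rmse_deg, 5)
  expect_equal(shifted$relative_error_pct, 5)

  set.seed(20)
  auto <- runif(50, 90, 150)
  manual <- runif(50, 90, 150)
  got <- validation_metrics(auto, manual)
  expect_equal(got$rmse_deg, sqrt(mean((auto - manual)^2)), tolerance = 1e-12)
  expect_equal(got$relative_error_pct, 100 * mean(abs(auto - manual) / manual),
               tolerance = 1e-12)
  expect_error(validation_metrics(auto, -manual),
               class = "vaangle_invalid_params")
})
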