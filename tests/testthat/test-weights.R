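test_that("identical covariate distributions give every record the trial fraction as PS", {
  d <- dplyr::bind_rows(
    lot_table(patient_id = sprintf("T%02d", 1:6), cohort = "TRIAL"),
    lot_table(patient_id = sprintf("C%02d", 1:4), cohort = "RWPC")
  )
  fit <- fit_propensity(d)
  expect_equal(fit$data$ps, rep(0.6, 10), tolerance = 1e-8)
  w <- att_weights(fit)
  # raw control weight is the odds 0.6/0.4; renormalization restores sum 4
  expect_equal(w$data$raw_weight[w$data$cohort == "RWPC"], rep(1.5, 4),
               tolerance = 1e-8)
  expect_equal(w$renorm_factor, 4 / 6, tolerance = 1e-8)
  expect_equal(sum(w$data$weight[w$data$cohort == "RWPC"]), 4, tolerance = 1e-9)

  # equal-sized balanced cohorts: PS one half, unit odds, renorm factor 1
  d2 <- dplyr::bind_rows(
    lot_table(patient_id = sprintf("T%02d", 1:5), cohort = "TRIAL"),
    lot_table(patient_id = sprintf("C%02d", 1:5), cohort = "RWPC")
  )
  w2 <- att_weights(fit_propensity(d2))
  expect_equal(w2$renorm_factor, 1, tolerance = 1e-9)
  expect_equal(w2$data$weight, rep(1, 10), tolerance = 1e-9)
})

test_that("coefficients match a brute-force likelihood-maximization oracle", {
  d <- lot_table(
    patient_id = sprintf("P%02d", 1:8),
    cohort = c("TRIAL", "TRIAL", "TRIAL", "TRIAL", "RWPC", "RWPC", "RWPC", "RWPC"),
    ecog = c("1", "1", "0", "1", "0", "1", "0", "0"),
    brain_met = c("yes", "no", "yes", "no", "no", "yes", "no", "yes")
  )
  fit <- fit_propensity(d, covariates = c("ecog", "brain_met"))
  X <- cbind(1, d$ecog == "1", d$brain_met == "yes")
  colnames(X) <- c("(Intercept)", "ecog1", "brain_metyes")
  oracle <- oracle_logistic(X, as.integer(d$cohort == "TRIAL"))
  expect_equal(unname(fit$coefficients), unname(oracle), tolerance = 1e-4)
})

test_that("a covariate level present in only one cohort raises a separation error", {
  d <- dplyr::bind_rows(
    lot_table(patient_id = sprintf("T%02d", 1:5), cohort = "TRIAL",
              liver_met = "yes"),
    lot_table(patient_id = sprintf("C%02d", 1:5), cohort = "RWPC",
              liver_met = "no")
  )
  expect_error(fit_propensity(d, covariates = "liver_met"),
               "liver_met", class = "extarm_separation_error")
})

test_that("records with missing covariates are rejected, not silently dropped", {
  d <- fixture_missingness_cohort()
  expect_error(fit_propensity(d), "missing covariates",
               class = "extarm_validation_error")
})

test_that("ATT weights: trial 1, control odds, renormalized to the control size", {
  d <- impute_metastases(fixture_missingness_cohort())$data
  fit <- att_weights(fit_propensity(d))
  w <- weight_table(fit)
  expect_identical(w$weight[w$cohort == "TRIAL"], rep(1, 114))
  expect_identical(w$raw_weight[w$cohort == "TRIAL"], rep(1, 114))
  ctrl <- w[w$cohort == "RWPC", ]
  expect_equal(sum(ctrl$weight), 55, tolerance = 1e-9)
  expect_equal(ctrl$raw_weight, ctrl$ps / (1 - ctrl$ps), tolerance = 1e-12)
  # renormalization preserves relative weights
  expect_equal(ctrl$weight / ctrl$weight[1],
               ctrl$raw_weight / ctrl$raw_weight[1], tolerance = 1e-12)
  expect_true(all(w$weight > 0))
})

test_that("propensity fitting is invariant to record order", {
  d <- impute_metastases(fixture_missingness_cohort())$data
  fit1 <- fit_propensity(d)
  set.seed(3)
  d2 <- d[sample(nrow(d)), ]
  fit2 <- fit_propensity(d2)
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-9)
})

test_that("the binary SMD formula reproduces a hand-computed value", {
  # ECOG 1: trial 81/114 vs control 32/55 -> 0.2717 by the pooled-variance formula
  d <- dplyr::bind_rows(
    lot_table(patient_id = sprintf("T%03d", 1:114), cohort = "TRIAL",
              ecog = c(rep("1", 81), rep("0", 33))),
    lot_table(patient_id = sprintf("C%03d", 1:55), cohort = "RWPC",
              ecog = c(rep("1", 32), rep("0", 23)))
  )
  fit <- att_weights(fit_propensity(d, covariates = "ecog"))
  bal <- balance_table(fit)
  smd <- bal$smd_unweighted[bal$covariate == "ecog" & bal$level == "1"]
  expect_equal(smd, 0.2717, tolerance = 5e-4)
  # direction: trial minus control, ECOG 1 more frequent in trial -> positive
  expect_gt(smd, 0)
})

test_that("equal weighted proportions give SMD zero; degenerate levels are flagged", {
  d <- dplyr::bind_rows(
    lot_table(patient_id = sprintf("T%02d", 1:10), cohort = "TRIAL",
              bone_met = rep(c("yes", "no"), 5)),
    lot_table(patient_id = sprintf("C%02d", 1:10), cohort = "RWPC",
              bone_met = rep(c("yes", "no"), 5))
  )
  bal <- balance_table(att_weights(fit_propensity(d, covariates = "bone_met")))
  expect_equal(bal$smd_unweighted, c(0, 0), tolerance = 1e-9)

  d2 <- dplyr::bind_rows(
    lot_table(patient_id = sprintf("T%02d", 1:10), cohort = "TRIAL",
              ecog = rep(c("0", "1"), 5)),
    lot_table(patient_id = sprintf("C%02d", 1:10), cohort = "RWPC",
              ecog = rep(c("0", "1"), 5), pleural_met = "no")
  )
  # pleural_met is 'no' everywhere: proportions agree -> SMD 0, not NaN
  bal2 <- balance_table(att_weights(fit_propensity(d2, covariates = c("ecog", "pleural_met"))))
  expect_equal(bal2$smd_unweighted[bal2$covariate == "pleural_met"], c(0, 0))
})

test_that("multi-level covariates report per-level SMDs plus a non-negative summary", {
  d <- impute_metastases(fixture_missingness_cohort())$data
  bal <- balance_table(att_weights(fit_propensity(d)))
  pl <- bal[bal$covariate == "prior_lines", ]
  expect_equal(nrow(pl), 3L)
  s <- attr(bal, "summary")
  expect_true(all(s$smd_unweighted >= 0))
  expect_true(all(s$smd_weighted >= 0))
  expect_true(all(is.finite(bal$smd_weighted)))
  # weighted frequencies sum to 1 per covariate
  sums <- bal |>
    dplyr::summarise(s = sum(p_control_weighted), .by = covariate)
  expect_equal(sums$s, rep(1, nrow(sums)), tolerance = 1e-9)
})

test_that("weighting balances covariates: weighted control means approach trial means", {
  cfg <- sim_config(seed = 77, n_trial = 3000, n_control_patients = 3000,
                    lot_rate = 0, missing_block_prob = 0)
  d <- simulate_cohort(cfg)
  fit <- att_weights(fit_propensity(d))
  bal <- balance_table(fit)
  expect_lt(max(abs(bal$smd_weighted)), 0.05)
  expect_gt(max(abs(bal$smd_unweighted)), 0.2)  # margins differ by design
})

test_that("PS overlap summary is reported", {
  d <- impute_metastases(fixture_missingness_cohort())$data
  g <- glance(att_weights(fit_propensity(d)))
  expect_true(g$ps_min_trial > 0 && g$ps_max_control < 1)
  expect_equal(g$n_control, 55L)
})
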