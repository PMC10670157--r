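test_that("the unadjusted response contrast reproduces the published 2x2 analysis", {
  d <- orr_table(114, 42, 55, 9, miss_ctrl = 1)
  eff <- binary_effect(d, "unadjusted")
  or <- eff[eff$measure == "odds_ratio", ]
  rr <- eff[eff$measure == "rate_ratio", ]
  expect_equal(round(or$estimate, 2), 2.92)
  expect_equal(round(c(or$ci_low, or$ci_high), 2), c(1.30, 6.56))
  expect_equal(round(or$p_value, 4), 0.0096)
  expect_equal(round(rr$estimate, 2), 2.21)
  expect_equal(round(c(rr$ci_low, rr$ci_high), 2), c(1.16, 4.20))
  expect_equal(round(rr$p_value, 4), 0.0156)
  expect_equal(or$n_control, 54L)  # missing response excluded
})

test_that("identical response rates give OR = RR = 1", {
  d <- orr_table(20, 5, 20, 5)
  eff <- binary_effect(d, "unadjusted")
  expect_equal(eff$estimate, c(1, 1), tolerance = 1e-9)
})

test_that("OR is at least as extreme as RR for harmful-direction 2x2 tables", {
  grid <- expand.grid(a = c(3, 9, 15), c_ = c(1, 4, 8))
  for (i in seq_len(nrow(grid))) {
    a <- grid$a[i]; c_ <- grid$c_[i]
    if (a / 20 <= c_ / 20) next
    eff <- binary_effect(orr_table(20, a, 20, c_), "unadjusted")
    expect_gte(eff$estimate[eff$measure == "odds_ratio"],
               eff$estimate[eff$measure == "rate_ratio"])
  }
})

test_that("a zero cell errors with continuity-correction instructions, and the flag works", {
  d <- orr_table(10, 0, 10, 3)
  expect_error(binary_effect(d, "unadjusted"), "continuity",
               class = "extarm_zero_cell_error")
  eff <- binary_effect(d, "unadjusted", continuity = TRUE)
  expect_match(eff$note[1], "continuity")
  expect_true(all(is.finite(eff$estimate)))
})

test_that("weighted and multivariable response models run with clustered variance", {
  d <- impute_metastases(fixture_missingness_cohort())$data
  fit <- att_weights(fit_propensity(d))
  att <- binary_effect(fit, "att")
  expect_equal(att$method, c("att", "att"))
  expect_true(all(att$ci_low < att$estimate & att$estimate < att$ci_high))
  mv <- binary_effect(d, "multivariable")
  forest <- attr(mv, "forest")
  expect_s3_class(forest, "tbl_df")
  expect_true(all(is.na(forest$estimate[forest$reference])))
  expect_equal(forest$covariate[1], "treatment")
})

test_that("unit-weight product-limit matches the hand-computed step function", {
  cv <- km_curve(c(1, 2), c(TRUE, TRUE))
  expect_equal(cv$time, c(1, 2))
  expect_equal(cv$surv, c(0.5, 0))
  med <- attr(cv, "median")
  expect_true(med$median_defined)
  expect_equal(med$median, 1)
})

test_that("km_curve with unit weights equals the classical estimator with censoring", {
  set.seed(42)
  t <- round(rexp(60, 1 / 50)) + 1
  e <- runif(60) < 0.7
  cv <- km_curve(t, e)
  ref <- survival::survfit(survival::Surv(t, as.integer(e)) ~ 1)
  expect_equal(cv$surv, ref$surv, tolerance = 1e-12)
  expect_equal(cv$n_risk, ref$n.risk, tolerance = 1e-12)
})

test_that("the weighted KM median recovers the closed-form exponential median", {
  set.seed(7)
  n <- 5000
  t <- rexp(n, log(2) / 10)
  cv <- km_curve(t, rep(TRUE, n))
  med <- attr(cv, "median")$median
  expect_lt(abs(med - 10) / 10, 0.03)
})

test_that("rescaling all weights leaves the survival curve unchanged", {
  set.seed(8)
  t <- rexp(100, 1 / 30); e <- runif(100) < 0.8
  w <- runif(100, 0.5, 2)
  a <- km_curve(t, e, w)
  b <- km_curve(t, e, 2 * w)
  expect_equal(a$surv, b$surv, tolerance = 1e-12)
  expect_equal(attr(a, "median")$median, attr(b, "median")$median)
})

test_that("an all-censored sample yields a flagged undefined median, not an error", {
  cv <- km_curve(c(10, 20, 30), c(FALSE, FALSE, FALSE))
  expect_true(all(cv$surv == 1))
  expect_false(attr(cv, "median")$median_defined)
})

test_that("the Cox coefficient matches a brute-force partial-likelihood oracle", {
  d <- lot_table(
    patient_id = sprintf("P%d", 1:6),
    cohort = c("TRIAL", "TRIAL", "TRIAL", "RWPC", "RWPC", "RWPC"),
    os_days = c(30L, 80L, 200L, 25L, 60L, 150L),
    os_event = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  )
  cx <- cox_model(d, "os", "unadjusted")
  beta_hat <- log(cx$effect$estimate)
  oracle <- oracle_cox(d$os_days, d$os_event, as.numeric(d$cohort == "TRIAL"))
  expect_equal(beta_hat, oracle, tolerance = 1e-5)
})

test_that("unit weights and singleton clusters reduce to the plain Cox fit", {
  set.seed(10)
  d <- lot_table(
    patient_id = sprintf("P%02d", 1:40),
    cohort = rep(c("TRIAL", "RWPC"), 20),
    os_days = as.integer(sample(20:400, 40)),
    os_event = runif(40) < 0.8
  )
  cx <- cox_model(d, "os", "unadjusted")
  ref <- survival::coxph(survival::Surv(os_days, os_event) ~ I(cohort == "TRIAL"),
                         data = d, ties = "efron")
  expect_equal(unname(coef(cx$model)), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(unname(summary(cx$model)$coefficients[, "se(coef)"]),
               unname(summary(ref)$coefficients[, "se(coef)"]), tolerance = 1e-8)
})

test_that("a two-arm exponential simulation recovers a hazard ratio of 0.42", {
  cfg <- null_sim_config(seed = 20, n_trial = 4000, n_control_patients = 4000,
                         lot_rate = 0, frailty_variance = 0)
  # scale progression and death hazards together so the composite
  # progression-free time has an exact hazard ratio of 0.42
  cfg$hazard_models$pfs$treatment <- log(0.42)
  cfg$hazard_models$os$treatment <- log(0.42)
  d <- simulate_cohort(cfg)
  cx <- cox_model(d, "pfs", "unadjusted")
  se <- summary(cx$model)$coefficients[1, "robust se"]
  expect_lt(abs(log(cx$effect$estimate) - log(0.42)), 3 * se)
})

test_that("no events in one arm raises a monotone-likelihood error naming the arm", {
  d <- dplyr::bind_rows(
    lot_table(patient_id = sprintf("T%d", 1:5), cohort = "TRIAL",
              os_event = FALSE),
    lot_table(patient_id = sprintf("C%d", 1:5), cohort = "RWPC",
              os_event = TRUE)
  )
  expect_error(cox_model(d, "os", "unadjusted"), "TRIAL",
               class = "extarm_monotone_error")
})

test_that("run_all_endpoints assembles every contrast with forests and medians", {
  d <- impute_metastases(fixture_missingness_cohort())$data
  fit <- att_weights(fit_propensity(d))
  res <- run_all_endpoints(fit)
  eff <- res$effects
  expect_equal(nrow(eff), 15L)  # 6 ORR rows + 9 hazard-ratio rows
  expect_setequal(unique(eff$endpoint), c("ORR", "PFS", "TTNT", "OS"))
  expect_true(all(eff$ci_low <= eff$estimate & eff$estimate <= eff$ci_high))
  expect_setequal(names(res$forests), c("orr", "pfs", "ttnt", "os"))
  expect_equal(nrow(res$medians), 12L)  # 3 endpoints x 2 methods x 2 cohorts
  expect_named(res$km, c("pfs", "ttnt", "os"))
  # unadjusted ORR row equals the direct 2x2 computation
  direct <- binary_effect(d, "unadjusted")
  expect_equal(eff$estimate[1:2], direct$estimate, tolerance = 1e-12)
})

test_that("an empty control cohort gives a structured error, no partial output", {
  d <- lot_table(patient_id = sprintf("T%d", 1:5), cohort = "TRIAL")
  expect_error(fit_propensity(d), class = "extarm_separation_error")
})
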