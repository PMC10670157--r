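test_that("equal seeds give byte-identical cohorts, different seeds differ", {
  cfg <- sim_config(seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_lot_table(a, p1); write_lot_table(b, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  expect_false(identical(a, simulate_cohort(sim_config(seed = 12))))
})

test_that("simulation leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_cohort(sim_config(seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("invalid configurations error before any sampling", {
  expect_error(sim_config(lot_rate = -1), class = "extarm_config_error")
  expect_error(sim_config(frailty_variance = -0.1), class = "extarm_config_error")
  expect_error(sim_config(missing_block_prob = 1.2), class = "extarm_config_error")
  m <- default_covariate_margins()
  m$rwpc$ecog <- c("0" = 0.7, "1" = 0.7)
  expect_error(sim_config(covariate_margins = m), class = "extarm_config_error")
})

test_that("expected control LOT count is close to 55 under the defaults", {
  counts <- vapply(1:100, function(s) {
    lot_counts(simulate_cohort(sim_config(seed = s)))$n_control_lots
  }, numeric(1))
  expect_gt(mean(counts), 55 * 0.8)
  expect_lt(mean(counts), 55 * 1.2)
})

test_that("simulated category frequencies match the configured margins", {
  d <- simulate_cohort(sim_config(seed = 21, n_trial = 10000,
                                  n_control_patients = 10000, lot_rate = 0,
                                  missing_block_prob = 0))
  margins <- default_covariate_margins()
  for (coh in c("TRIAL", "RWPC")) {
    sub <- d[d$cohort == coh, ]
    m <- margins[[if (coh == "TRIAL") "trial" else "rwpc"]]
    for (cov in lot_covariates()) {
      for (lev in names(m[[cov]])) {
        expect_lt(abs(mean(sub[[cov]] == lev) - m[[cov]][[lev]]), 0.02)
      }
    }
  }
})

test_that("structural invariants hold: one trial LOT, monotone sites, ordered endpoints", {
  d <- simulate_cohort(sim_config(seed = 31, n_control_patients = 300))
  expect_true(all(d$lot_seq[d$cohort == "TRIAL"] == 1L))
  expect_true(all(d$pfs_days <= d$os_days))
  expect_true(all(d$ttnt_days <= d$os_days))
  ctrl <- d[d$cohort == "RWPC" & !is.na(d$brain_met), ]
  for (site in lot_schema()$met_sites) {
    drops <- ctrl |>
      dplyr::group_by(patient_id) |>
      dplyr::arrange(lot_seq, .by_group = TRUE) |>
      dplyr::summarise(
        drop = any(diff(.data[[site]] == "yes") < 0), .groups = "drop")
    expect_false(any(drops$drop))
  }
  pl <- ctrl |>
    dplyr::group_by(patient_id) |>
    dplyr::arrange(lot_seq, .by_group = TRUE) |>
    dplyr::summarise(ok = all(diff(match(prior_lines, c("1", "2", "3plus"))) >= 0),
                     .groups = "drop")
  expect_true(all(pl$ok))
})

test_that("masking is absent when disabled and always leaves an observed neighbour", {
  d0 <- simulate_cohort(sim_config(seed = 41, missing_block_prob = 0))
  expect_false(anyNA(d0[lot_schema()$met_sites]))

  d <- simulate_cohort(sim_config(seed = 42, n_control_patients = 500,
                                  lot_rate = 1.0, missing_block_prob = 0.3))
  miss <- is.na(d$brain_met)
  expect_gt(sum(miss), 0)
  for (i in which(miss)) {
    sibs <- d$patient_id == d$patient_id[i] & !miss
    expect_gt(sum(sibs), 0)
  }
})

test_that("gamma frailty induces positive within-patient outcome correlation", {
  cfg <- null_sim_config(seed = 51, n_control_patients = 2000, lot_rate = 2,
                         frailty_variance = 2)
  d <- simulate_cohort(cfg)
  pairs <- d[d$cohort == "RWPC", ] |>
    dplyr::group_by(patient_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::arrange(lot_seq, .by_group = TRUE) |>
    dplyr::summarise(a = os_days[1], b = os_days[2], .groups = "drop")
  expect_gt(cor(pairs$a, pairs$b, method = "spearman"), 0.1)

  cfg0 <- null_sim_config(seed = 52, n_control_patients = 2000, lot_rate = 2,
                          frailty_variance = 0)
  d0 <- simulate_cohort(cfg0)
  pairs0 <- d0[d0$cohort == "RWPC", ] |>
    dplyr::group_by(patient_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::arrange(lot_seq, .by_group = TRUE) |>
    dplyr::summarise(a = os_days[1], b = os_days[2], .groups = "drop")
  expect_lt(abs(cor(pairs0$a, pairs0$b, method = "spearman")), 0.1)
})

test_that("a single-covariate proportional-hazards effect is recovered by Cox regression", {
  m <- default_covariate_margins()
  m$trial <- lapply(m$trial, function(p) p)
  beta <- 0.5
  cfg <- sim_config(
    seed = 61, n_trial = 3000, n_control_patients = 3000, lot_rate = 0,
    frailty_variance = 0, missing_block_prob = 0,
    # the effect enters both the progression and death hazards, so the
    # composite progression-free time is exactly proportional-hazards in it
    hazard_models = list(
      pfs = list(rate = log(2) / 148, treatment = 0,
                 covariates = list(bone_met = c(yes = beta))),
      ttnt = list(rate = 1 / 45, treatment = 0, covariates = list()),
      os = list(rate = log(2) / 349, treatment = 0,
                covariates = list(bone_met = c(yes = beta)))
    )
  )
  d <- simulate_cohort(cfg)
  fit <- survival::coxph(survival::Surv(pfs_days, pfs_event) ~ I(bone_met == "yes"),
                         data = d)
  se <- sqrt(diag(vcov(fit)))[1]
  expect_lt(abs(coef(fit)[1] - beta), 3 * se)
})

test_that("the missingness fixture reproduces the study pattern", {
  d <- fixture_missingness_cohort()
  counts <- lot_counts(d)
  expect_equal(counts$n_trial, 114L)
  expect_equal(counts$n_control_lots, 55L)
  expect_equal(counts$n_control_patients, 38L)

  miss <- d[is.na(d$brain_met), ]
  expect_equal(nrow(miss), 9L)
  expect_equal(dplyr::n_distinct(miss$patient_id), 8L)
  expect_true(all(miss$cohort == "RWPC"))

  # neighbour classification of each masked LOT
  obs <- d[d$cohort == "RWPC" & !is.na(d$brain_met), ]
  kind <- vapply(seq_len(nrow(miss)), function(i) {
    sibs <- obs[obs$patient_id == miss$patient_id[i], ]
    has_prior <- any(sibs$lot_seq < miss$lot_seq[i])
    has_post <- any(sibs$lot_seq > miss$lot_seq[i])
    if (has_prior && has_post) "both" else if (has_prior) "prior" else "post"
  }, character(1))
  expect_equal(sum(kind == "both"), 3L)
  expect_equal(sum(kind == "prior"), 4L)
  expect_equal(sum(kind == "post"), 2L)

  # at least one both-neighbour case with discordant neighbours
  disc <- d[d$patient_id == "C0002", ]
  expect_identical(disc$liver_met, c("no", NA, "yes"))

  # exactly one response-unevaluable control LOT; 42/114 and 9/54 responders
  expect_equal(sum(is.na(d$response[d$cohort == "RWPC"])), 1L)
  expect_equal(sum(d$response[d$cohort == "TRIAL"] == "responder"), 42L)
  expect_equal(sum(d$response[d$cohort == "RWPC"] == "responder", na.rm = TRUE), 9L)
})
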