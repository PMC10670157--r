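#' Default per-cohort covariate marginals
#'
#' Category probabilities for each baseline covariate, one set per cohort.
#' Defaults reproduce the observed baseline distributions of the motivating
#' study: 114 trial patients and 55 post-imputation control LOTs.
#'
#' @return Named list with elements `trial` and `rwpc`; each is a named list
#'   of probability vectors (named by category level, summing to 1).
#' @export
default_covariate_margins <- function() {
  list(
    trial = list(
      ecog        = c("0" = 33 / 114, "1" = 81 / 114),
      prior_lines = c("1" = 48 / 114, "2" = 34 / 114, "3plus" = 32 / 114),
      brain_met   = c(no = 85 / 114, yes = 29 / 114),
      liver_met   = c(no = 101 / 114, yes = 13 / 114),
      bone_met    = c(no = 63 / 114, yes = 51 / 114),
      lymph_met   = c(no = 52 / 114, yes = 62 / 114),
      adrenal_met = c(no = 108 / 114, yes = 6 / 114),
      pleural_met = c(no = 83 / 114, yes = 31 / 114),
      other_met   = c(no = 72 / 114, yes = 42 / 114),
      age_cat     = c(lt65 = 67 / 114, "65to75" = 38 / 114, ge75 = 9 / 114)
    ),
    rwpc = list(
      ecog        = c("0" = 23 / 55, "1" = 32 / 55),
      prior_lines = c("1" = 24 / 55, "2" = 17 / 55, "3plus" = 14 / 55),
      brain_met   = c(no = 47 / 55, yes = 8 / 55),
      liver_met   = c(no = 44 / 55, yes = 11 / 55),
      bone_met    = c(no = 28 / 55, yes = 27 / 55),
      lymph_met   = c(no = 32 / 55, yes = 23 / 55),
      adrenal_met = c(no = 52 / 55, yes = 3 / 55),
      pleural_met = c(no = 37 / 55, yes = 18 / 55),
      other_met   = c(no = 16 / 55, yes = 39 / 55),
      age_cat     = c(lt65 = 30 / 55, "65to75" = 17 / 55, ge75 = 8 / 55)
    )
  )
}

#' Simulation configuration
#'
#' Defines the generative model for a synthetic two-cohort LOT dataset:
#' cohort sizes, covariate marginals, a logistic best-response model,
#' exponential proportional-hazards models for progression, next-treatment
#' delay and death, a shared gamma frailty inducing within-patient outcome
#' correlation, independent exponential censoring with an administrative cap,
#' and MCAR block masking of the metastatic-site fields on control LOTs.
#'
#' Covariate effects are given per model as a named list: covariate name ->
#' named vector of log-odds / log-hazard-ratio offsets per non-reference
#' level, e.g. `list(ecog = c("1" = 0.4), other_met = c(yes = 0.3))`.
#'
#' @param seed Integer RNG seed; identical seeds give identical cohorts.
#' @param n_trial Number of trial patients (one LOT each).
#' @param n_control_patients Number of control patients.
#' @param lot_rate Mean of the Poisson number of extra LOTs per control
#'   patient, truncated at 3 (max 4 LOTs). The default 0.448 makes the
#'   expected control LOT count approximately 55 for 38 patients.
#' @param covariate_margins Per-cohort category probabilities
#'   (see [default_covariate_margins()]).
#' @param response_model List with `intercept` (log-odds of response on a
#'   reference-covariate control LOT), `treatment` (log odds ratio), and
#'   `covariates` (effect list as above).
#' @param hazard_models Named list with elements `pfs` (progression hazard),
#'   `ttnt` (hazard of starting the next therapy after progression), and `os`
#'   (death hazard); each has `rate` (baseline events/day), `treatment`
#'   (log hazard ratio) and `covariates`.
#' @param frailty_variance Variance theta of the mean-1 gamma frailty shared
#'   by all of a patient's LOT outcomes; 0 disables the frailty.
#' @param censor_rate Rate of the independent exponential censoring time.
#' @param admin_cap_days Administrative follow-up cutoff in days.
#' @param missing_block_prob Probability that a control LOT's metastatic-site
#'   block is masked; masking is only applied where an observed neighbouring
#'   LOT of the same patient remains, unless `allow_unimputable` is TRUE.
#' @param allow_unimputable Permit masking LOTs with no observed neighbour.
#' @param response_missing_prob Probability a control LOT's best response is
#'   unevaluable (recorded missing).
#' @param progression_prob Per-line probability that a metastatic site absent
#'   at one LOT is present at the patient's next LOT (sites never regress).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_trial = 114L,
                       n_control_patients = 38L,
                       lot_rate = 0.448,
                       covariate_margins = default_covariate_margins(),
                       response_model = list(
                         intercept  = qlogis(9 / 54),
                         treatment  = log(2.8),
                         covariates = list(ecog = c("1" = -0.6))
                       ),
                       hazard_models = list(
                         pfs  = list(rate = log(2) / 148, treatment = log(0.42),
                                     covariates = list(ecog = c("1" = 0.35))),
                         ttnt = list(rate = 1 / 45, treatment = 0,
                                     covariates = list()),
                         os   = list(rate = log(2) / 349, treatment = log(0.48),
                                     covariates = list(ecog = c("1" = 0.45)))
                       ),
                       frailty_variance = 0.5,
                       censor_rate = 1 / 700,
                       admin_cap_days = 1095L,
                       missing_block_prob = 9 / 55,
                       allow_unimputable = FALSE,
                       response_missing_prob = 1 / 55,
                       progression_prob = 0.1) {
  cfg <- list(
    seed = as.integer(seed), n_trial = as.integer(n_trial),
    n_control_patients = as.integer(n_control_patients), lot_rate = lot_rate,
    covariate_margins = covariate_margins, response_model = response_model,
    hazard_models = hazard_models, frailty_variance = frailty_variance,
    censor_rate = censor_rate, admin_cap_days = as.numeric(admin_cap_days),
    missing_block_prob = missing_block_prob,
    allow_unimputable = isTRUE(allow_unimputable),
    response_missing_prob = response_missing_prob,
    progression_prob = progression_prob
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) abort(msg, class = "extarm_config_error")
  chk(cfg$n_trial >= 1 && cfg$n_control_patients >= 1, "cohort sizes must be >= 1")
  chk(cfg$lot_rate >= 0, "lot_rate must be >= 0")
  chk(cfg$frailty_variance >= 0, "frailty_variance must be >= 0")
  chk(cfg$censor_rate > 0, "censor_rate must be > 0")
  chk(cfg$admin_cap_days > 0, "admin_cap_days must be > 0")
  probs <- c(cfg$missing_block_prob, cfg$response_missing_prob, cfg$progression_prob)
  chk(all(probs >= 0 & probs <= 1), "probabilities must lie in [0, 1]")
  for (coh in c("trial", "rwpc")) {
    margins <- cfg$covariate_margins[[coh]]
    chk(!is.null(margins), paste0("covariate_margins$", coh, " missing"))
    for (cov in lot_covariates()) {
      p <- margins[[cov]]
      chk(!is.null(p) && all(p >= 0) && abs(sum(p) - 1) < 1e-8,
          paste0("margins for '", cov, "' (", coh, ") must be probabilities summing to 1"))
      chk(setequal(names(p), covariate_levels(cov)),
          paste0("margins for '", cov, "' (", coh, ") must name levels ",
                 paste(covariate_levels(cov), collapse = "/")))
    }
  }
  for (m in cfg$hazard_models) chk(m$rate > 0, "baseline hazard rates must be > 0")
  invisible(cfg)
}

# linear predictor contribution from a covariate-effect list
covariate_lp <- function(effects, covs) {
  if (length(effects) == 0) return(rep(0, nrow(covs)))
  lp <- rep(0, nrow(covs))
  for (cov in names(effects)) {
    eff <- effects[[cov]]
    for (lev in names(eff)) lp <- lp + eff[[lev]] * (covs[[cov]] == lev)
  }
  lp
}

draw_cat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# run expr under the config seed, restoring the caller's RNG state
with_sim_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Simulate a two-cohort LOT dataset
#'
#' Draws a trial cohort (one LOT per patient) and a control cohort (one or
#' more LOTs per patient) under the generative model in a [sim_config()]:
#' covariates from per-cohort marginals with monotone metastatic-site
#' progression and incrementing prior-line count across a patient's LOTs; a
#' per-patient mean-1 gamma frailty multiplying all of the patient's hazards;
#' progression-free survival as the minimum of progression and death,
#' time-to-next-treatment as the minimum of (progression + delay) and death
#' (so PFS <= OS and TTNT <= OS by construction); a common per-LOT censoring
#' time; best response from the logistic model; and MCAR block masking of the
#' metastatic-site fields on control LOTs with an observed neighbour.
#'
#' @param config A [sim_config()].
#' @return A validated LOT tibble.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    config <- do.call(sim_config, config)
  }
  validate_sim_config(unclass(config))
  with_sim_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  sch <- lot_schema()
  covs <- lot_covariates()

  draw_baseline <- function(n, margins) {
    out <- tibble(.rows = n)
    for (cov in covs) out[[cov]] <- draw_cat(n, margins[[cov]])
    out
  }

  # ---- trial cohort: one LOT per patient -------------------------------
  trial <- draw_baseline(cfg$n_trial, cfg$covariate_margins$trial) |>
    mutate(
      patient_id = sprintf("T%04d", seq_len(cfg$n_trial)),
      cohort = "TRIAL", lot_seq = 1L,
      egfr_tested_before = TRUE, prior_platinum = TRUE,
      contains_amivantamab = TRUE
    )

  # ---- control cohort: 1 + truncated-Poisson extra LOTs per patient ----
  n_pat <- cfg$n_control_patients
  n_lots <- 1L + pmin(rpois(n_pat, cfg$lot_rate), 3L)
  first <- draw_baseline(n_pat, cfg$covariate_margins$rwpc)
  idx <- rep(seq_len(n_pat), n_lots)
  seq_in_pat <- sequence(n_lots)
  ctrl <- first[idx, , drop = FALSE]
  ctrl$patient_id <- sprintf("C%04d", idx)
  ctrl$lot_seq <- seq_in_pat
  # prior-line count increments with each further line (capped at 3plus)
  pl_levels <- c("1", "2", "3plus")
  ctrl$prior_lines <- pl_levels[
    pmin(match(ctrl$prior_lines, pl_levels) + seq_in_pat - 1L, 3L)]
  # monotone site progression: a site absent at baseline converts to present
  # at a geometric later line and stays present thereafter
  for (site in sch$met_sites) {
    conv_line <- if (cfg$progression_prob > 0) {
      2L + rgeom(n_pat, cfg$progression_prob)
    } else {
      rep(Inf, n_pat)
    }
    ctrl[[site]] <- ifelse(first[[site]][idx] == "yes" |
                             seq_in_pat >= conv_line[idx], "yes", "no")
  }
  ctrl <- ctrl |>
    mutate(cohort = "RWPC", egfr_tested_before = TRUE, prior_platinum = TRUE,
           contains_amivantamab = FALSE)

  data <- bind_rows(trial, ctrl)
  n <- nrow(data)
  treated <- data$cohort == "TRIAL"

  # ---- frailty shared across a patient's LOTs --------------------------
  pats <- unique(data$patient_id)
  frail <- if (cfg$frailty_variance > 0) {
    th <- cfg$frailty_variance
    setNames(rgamma(length(pats), shape = 1 / th, scale = th), pats)
  } else {
    setNames(rep(1, length(pats)), pats)
  }
  z <- frail[data$patient_id]

  haz <- function(m) m$rate * z * exp(m$treatment * treated + covariate_lp(m$covariates, data))
  t_prog  <- rexp(n, haz(cfg$hazard_models$pfs))
  t_delay <- rexp(n, haz(cfg$hazard_models$ttnt))
  t_death <- rexp(n, haz(cfg$hazard_models$os))
  t_pfs  <- pmin(t_prog, t_death)
  t_ttnt <- pmin(t_prog + t_delay, t_death)
  cens   <- pmin(rexp(n, cfg$censor_rate), cfg$admin_cap_days)

  data <- data |>
    mutate(
      pfs_days  = as.integer(floor(pmin(t_pfs, cens))),
      pfs_event = t_pfs <= cens,
      ttnt_days  = as.integer(floor(pmin(t_ttnt, cens))),
      ttnt_event = t_ttnt <= cens,
      os_days  = as.integer(floor(pmin(t_death, cens))),
      os_event = t_death <= cens
    )

  rm <- cfg$response_model
  p_resp <- plogis(rm$intercept + rm$treatment * treated + covariate_lp(rm$covariates, data))
  response <- ifelse(rbinom(n, 1, p_resp) == 1, "responder", "non_responder")
  miss_resp <- !treated & runif(n) < cfg$response_missing_prob
  response[miss_resp] <- NA_character_
  data$response <- response

  # ---- MCAR block masking of control metastatic sites ------------------
  mask <- rep(FALSE, n)
  candidate <- !treated & runif(n) < cfg$missing_block_prob
  for (i in which(candidate)) {
    sibs <- which(data$patient_id == data$patient_id[i])
    sibs <- setdiff(sibs, i)
    if (cfg$allow_unimputable || any(!mask[sibs] & length(sibs) > 0)) {
      mask[i] <- TRUE
    }
  }
  for (site in sch$met_sites) data[[site]][mask] <- NA_character_

  out <- data |>
    select(all_of(sch$columns)) |>
    arrange(desc(.data$cohort == "TRIAL"), .data$patient_id, .data$lot_seq)
  validate_lot_table(out)
  out
}

#' Deterministic missingness fixture
#'
#' A fixed synthetic two-cohort dataset reproducing the missingness pattern of
#' the motivating chart-review cohort: 114 trial LOTs plus 55 control LOTs
#' from 38 patients, of which exactly 9 LOTs from 8 unique patients have a
#' block-missing metastatic-site profile, partitioned as 3 LOTs with both
#' neighbours observed (at least one with discordant neighbours: site absent
#' before, present after), 4 with only a prior LOT observed, and 2 with only
#' a subsequent LOT observed. Exactly one control LOT has a missing best
#' response, so the response-evaluable control denominator is 54.
#'
#' The fixture is built deterministically (no RNG) and is synthetic: covariate
#' values cycle through categories to approximate the study's marginals but
#' are not patient-level study data.
#'
#' @return A validated LOT tibble.
#' @export
fixture_missingness_cohort <- function() {
  sch <- lot_schema()

  # deterministic category assignment hitting a target count of "hi" values
  alloc <- function(n, n_hi, hi, lo) {
    v <- rep(lo, n)
    if (n_hi > 0) v[round(seq(1, n, length.out = n_hi))] <- hi
    v
  }
  trial <- tibble(
    patient_id = sprintf("T%04d", 1:114),
    cohort = "TRIAL", lot_seq = 1L,
    ecog = alloc(114, 81, "1", "0"),
    prior_lines = rep(c("1", "2", "3plus"), times = c(48, 34, 32)),
    brain_met   = alloc(114, 29, "yes", "no"),
    liver_met   = alloc(114, 13, "yes", "no"),
    bone_met    = alloc(114, 51, "yes", "no"),
    lymph_met   = alloc(114, 62, "yes", "no"),
    adrenal_met = alloc(114, 6, "yes", "no"),
    pleural_met = alloc(114, 31, "yes", "no"),
    other_met   = alloc(114, 42, "yes", "no"),
    age_cat     = rep(c("lt65", "65to75", "ge75"), times = c(67, 38, 9)),
    egfr_tested_before = TRUE, prior_platinum = TRUE, contains_amivantamab = TRUE,
    response = alloc(114, 42, "responder", "non_responder")
  )
  i <- 1:114
  trial <- trial |>
    mutate(
      os_days  = as.integer(90 + 11 * i),
      pfs_days = as.integer(floor(os_days * 0.55)),
      ttnt_days = as.integer(floor(os_days * 0.8)),
      os_event  = i %% 3 != 0,
      pfs_event = i %% 4 != 0,
      ttnt_event = i %% 5 != 0
    )

  # control LOT structure: patient id, number of LOTs, masked lot_seq values
  plan <- list(
    list(id = 1L, n = 4L, masked = c(2L, 4L)),   # both-neighbour + prior-only
    list(id = 2L, n = 3L, masked = 2L),          # both-neighbour, discordant
    list(id = 3L, n = 3L, masked = 2L),          # both-neighbour, concordant
    list(id = 4L, n = 2L, masked = 2L),          # prior-only
    list(id = 5L, n = 2L, masked = 2L),
    list(id = 6L, n = 2L, masked = 2L),
    list(id = 7L, n = 2L, masked = 1L),          # subsequent-only
    list(id = 8L, n = 2L, masked = 1L)
  )
  plan <- c(plan,
            map(9:13, ~ list(id = .x, n = 2L, masked = integer())),
            map(14:38, ~ list(id = .x, n = 1L, masked = integer())))

  ctrl <- map(plan, function(p) {
    tibble(patient_id = sprintf("C%04d", p$id), lot_seq = seq_len(p$n),
           masked = seq_len(p$n) %in% p$masked)
  }) |> list_rbind()
  n_c <- nrow(ctrl)            # 55
  first_lot <- ctrl$lot_seq == 1L
  n_pat <- sum(first_lot)      # 38

  # baseline covariates per patient, cycled to approximate study marginals
  base <- tibble(
    ecog = alloc(n_pat, 22, "1", "0"),
    prior_lines_first = rep(c("1", "2", "3plus"), length.out = n_pat),
    brain_met   = alloc(n_pat, 5, "yes", "no"),
    liver_met   = alloc(n_pat, 8, "yes", "no"),
    bone_met    = alloc(n_pat, 19, "yes", "no"),
    lymph_met   = alloc(n_pat, 16, "yes", "no"),
    adrenal_met = alloc(n_pat, 2, "yes", "no"),
    pleural_met = alloc(n_pat, 13, "yes", "no"),
    other_met   = alloc(n_pat, 27, "yes", "no"),
    age_cat     = rep(c("lt65", "65to75", "ge75"), times = c(21, 12, 5))
  )
  base$patient_id <- sprintf("C%04d", seq_len(n_pat))
  ctrl <- ctrl |> left_join(base, by = "patient_id")

  # prior_lines increments with lot_seq (capped at 3plus)
  bump <- function(x, k) {
    idx <- pmin(match(x, c("1", "2", "3plus")) + k, 3L)
    c("1", "2", "3plus")[idx]
  }
  ctrl <- ctrl |>
    mutate(prior_lines = bump(.data$prior_lines_first, .data$lot_seq - 1L)) |>
    select(-"prior_lines_first")

  # discordant neighbours for patient C0002: liver absent at LOT 1, present at LOT 3
  ctrl$liver_met[ctrl$patient_id == "C0002"] <- c("no", "no", "yes")
  # monotone site progression for one prior-only patient (carried value = yes)
  ctrl$bone_met[ctrl$patient_id == "C0004"] <- c("yes", "yes")

  for (site in sch$met_sites) ctrl[[site]][ctrl$masked] <- NA_character_

  j <- seq_len(n_c)
  ctrl <- ctrl |>
    mutate(
      cohort = "RWPC",
      egfr_tested_before = TRUE, prior_platinum = TRUE,
      contains_amivantamab = FALSE,
      response = alloc(n_c, 9, "responder", "non_responder"),
      os_days  = as.integer(60 + 9 * j),
      pfs_days = as.integer(floor(.data$os_days * 0.5)),
      ttnt_days = as.integer(floor(.data$os_days * 0.75)),
      os_event  = j %% 4 != 0,
      pfs_event = j %% 3 != 0,
      ttnt_event = j %% 2 != 0
    )
  ctrl$response[27] <- NA_character_   # one response-unevaluable control LOT

  out <- bind_rows(trial, ctrl |> select(-"masked")) |>
    select(all_of(sch$columns))
  validate_lot_table(out)
  out
}
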