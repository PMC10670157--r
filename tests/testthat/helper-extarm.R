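# One valid LOT record with overridable fields, in schema column order.
new_lot <- function(patient_id = "P001", cohort = "RWPC", lot_seq = 1L,
                    ecog = "0", prior_lines = "1",
                    brain_met = "no", liver_met = "no", bone_met = "no",
                    lymph_met = "no", adrenal_met = "no", pleural_met = "no",
                    other_met = "no", age_cat = "lt65",
                    egfr_tested_before = TRUE, prior_platinum = TRUE,
                    contains_amivantamab = (cohort == "TRIAL"),
                    response = "non_responder",
                    pfs_days = 100L, pfs_event = TRUE,
                    ttnt_days = 150L, ttnt_event = TRUE,
                    os_days = 200L, os_event = TRUE) {
  tibble::tibble(
    patient_id = patient_id, cohort = cohort, lot_seq = as.integer(lot_seq),
    ecog = ecog, prior_lines = prior_lines,
    brain_met = brain_met, liver_met = liver_met, bone_met = bone_met,
    lymph_met = lymph_met, adrenal_met = adrenal_met,
    pleural_met = pleural_met, other_met = other_met,
    age_cat = age_cat,
    egfr_tested_before = egfr_tested_before, prior_platinum = prior_platinum,
    contains_amivantamab = contains_amivantamab, response = response,
    pfs_days = as.integer(pfs_days), pfs_event = pfs_event,
    ttnt_days = as.integer(ttnt_days), ttnt_event = ttnt_event,
    os_days = as.integer(os_days), os_event = os_event
  )
}

# Stack new_lot() rows from parallel vectors.
lot_table <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  rows <- lapply(seq_len(n), function(i) {
    do.call(new_lot, lapply(args, function(a) a[[((i - 1L) %% length(a)) + 1L]]))
  })
  dplyr::bind_rows(rows)
}

# Two-cohort response table: sizes and responder counts per arm, distinct
# patients per record, with optional missing control responses.
orr_table <- function(n_trial, resp_trial, n_ctrl, resp_ctrl, miss_ctrl = 0) {
  trial <- lot_table(
    patient_id = sprintf("T%03d", seq_len(n_trial)), cohort = "TRIAL",
    response = c(rep("responder", resp_trial),
                 rep("non_responder", n_trial - resp_trial))
  )
  ctrl <- lot_table(
    patient_id = sprintf("C%03d", seq_len(n_ctrl)), cohort = "RWPC",
    response = c(rep("responder", resp_ctrl),
                 rep(NA_character_, miss_ctrl),
                 rep("non_responder", n_ctrl - resp_ctrl - miss_ctrl))
  )
  dplyr::bind_rows(trial, ctrl)
}

# Brute-force logistic log-likelihood maximizer (independent oracle).
oracle_logistic <- function(X, y) {
  negll <- function(beta) {
    eta <- drop(X %*% beta)
    -sum(y * eta - log1p(exp(eta)))
  }
  fit <- optim(rep(0, ncol(X)), negll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  stats::setNames(fit$par, colnames(X))
}

# Brute-force Cox partial-likelihood maximizer for untied data (independent
# oracle; with no ties Efron and Breslow coincide).
oracle_cox <- function(time, event, x) {
  stopifnot(!anyDuplicated(time[event]))
  negpl <- function(beta) {
    eta <- x * beta
    val <- 0
    for (i in which(event)) {
      risk <- time >= time[i]
      val <- val + eta[i] - log(sum(exp(eta[risk])))
    }
    -val
  }
  optimize(negpl, interval = c(-10, 10), tol = 1e-10)$minimum
}

# Shared null-effect simulation configuration (no treatment or covariate
# effects) used by the variance-calibration properties.
null_sim_config <- function(seed, n_trial = 150L, n_control_patients = 60L,
                            lot_rate = 1.5, frailty_variance = 1) {
  sim_config(
    seed = seed, n_trial = n_trial, n_control_patients = n_control_patients,
    lot_rate = lot_rate, frailty_variance = frailty_variance,
    missing_block_prob = 0, response_missing_prob = 0,
    response_model = list(intercept = qlogis(0.2), treatment = 0,
                          covariates = list()),
    hazard_models = list(
      pfs = list(rate = log(2) / 148, treatment = 0, covariates = list()),
      ttnt = list(rate = 1 / 45, treatment = 0, covariates = list()),
      os = list(rate = log(2) / 349, treatment = 0, covariates = list())
    )
  )
}
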