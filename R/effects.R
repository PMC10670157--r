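ci_z <- function(conf_level = 0.95) qnorm(1 - (1 - conf_level) / 2)

wald_row <- function(endpoint, measure, method, log_est, se,
                     n_trial, n_control, conf_level = 0.95) {
  z <- ci_z(conf_level)
  log_est <- unname(log_est)
  se <- unname(se)
  tibble(
    endpoint = endpoint, measure = measure, method = method,
    estimate = exp(log_est),
    ci_low = exp(log_est - z * se), ci_high = exp(log_est + z * se),
    p_value = 2 * pnorm(-abs(log_est / se)),
    n_trial = n_trial, n_control = n_control
  )
}

# cluster-robust covariance for a glm; CR0 by default, CR1 adds the usual
# m/(m-1) * (n-1)/(n-k) small-sample factor
glm_cluster_vcov <- function(model, cluster, cr = c("CR0", "CR1")) {
  cr <- match.arg(cr)
  sandwich::vcovCL(model, cluster = cluster, type = "HC0",
                   cadjust = identical(cr, "CR1"))
}

covariate_factors <- function(data, covariates) {
  refs <- covariate_reference_levels()
  for (cov in covariates) {
    levs <- covariate_levels(cov)
    data[[cov]] <- factor(data[[cov]],
                          levels = c(refs[[cov]], setdiff(levs, refs[[cov]])))
  }
  data
}

# term-level forest rows (reference rows included) from a fitted glm/coxph
forest_from_fit <- function(coefs, ses, data, covariates, conf_level = 0.95) {
  z <- ci_z(conf_level)
  level_counts <- function(cov, lev) {
    c(trial = sum(data$cohort == "TRIAL" & data[[cov]] == lev),
      control = sum(data$cohort == "RWPC" & data[[cov]] == lev))
  }
  rows <- list(tibble(
    covariate = "treatment", level = "TRIAL vs RWPC", reference = FALSE,
    estimate = exp(coefs[[".treated"]]),
    ci_low = exp(coefs[[".treated"]] - z * ses[[".treated"]]),
    ci_high = exp(coefs[[".treated"]] + z * ses[[".treated"]]),
    p_value = 2 * pnorm(-abs(coefs[[".treated"]] / ses[[".treated"]])),
    n_trial = sum(data$cohort == "TRIAL"), n_control = sum(data$cohort == "RWPC")
  ))
  refs <- covariate_reference_levels()
  for (cov in covariates) {
    levs <- covariate_levels(cov)
    ref <- refs[[cov]]
    for (lev in c(ref, setdiff(levs, ref))) {
      nm <- paste0(cov, lev)
      n <- level_counts(cov, lev)
      if (lev == ref || !nm %in% names(coefs)) {
        rows[[length(rows) + 1L]] <- tibble(
          covariate = cov, level = lev, reference = TRUE,
          estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          p_value = NA_real_, n_trial = n[["trial"]], n_control = n[["control"]]
        )
      } else {
        rows[[length(rows) + 1L]] <- tibble(
          covariate = cov, level = lev, reference = FALSE,
          estimate = exp(coefs[[nm]]),
          ci_low = exp(coefs[[nm]] - z * ses[[nm]]),
          ci_high = exp(coefs[[nm]] + z * ses[[nm]]),
          p_value = 2 * pnorm(-abs(coefs[[nm]] / ses[[nm]])),
          n_trial = n[["trial"]], n_control = n[["control"]]
        )
      }
    }
  }
  list_rbind(rows)
}

#' Response odds ratio and rate ratio
#'
#' Contrasts the trial and control response rates three ways. `unadjusted`
#' uses the classical Wald variance from the 2x2 table. `att` fits an
#' ATT-weighted logistic model (odds ratio) and an ATT-weighted log-link
#' binomial model (rate ratio, with a robust-Poisson fallback when the
#' log-binomial fit does not converge), both with patient-clustered robust
#' (CR0 sandwich) variance. `multivariable` fits unit-weight models with the
#' treatment term plus the baseline covariates, again with clustered robust
#' variance. Records with missing response are excluded (response-rate
#' analyses only). Confidence intervals are exp(log-estimate +/- z * SE) and
#' p-values two-sided Wald.
#'
#' @param data Analysis-set tibble (a `ps_fit` may be given instead, in which
#'   case its data and weights are used).
#' @param method One of `unadjusted`, `att`, `multivariable`.
#' @param weights Optional per-record weights (required for `att` when `data`
#'   is a plain table).
#' @param covariates Covariates for the multivariable model.
#' @param cr Cluster-robust flavour, `CR0` (default) or `CR1`.
#' @param continuity Add 0.5 to all cells of the unadjusted 2x2 table when a
#'   zero cell occurs (the result is flagged in the `note` column).
#' @param conf_level Confidence level.
#' @return Tibble with two effect rows (odds ratio, rate ratio). A
#'   `multivariable` call carries the odds-ratio forest in `attr(, "forest")`.
#' @export
binary_effect <- function(data, method = c("unadjusted", "att", "multivariable"),
                          weights = NULL, covariates = lot_covariates(),
                          cr = c("CR0", "CR1"), continuity = FALSE,
                          conf_level = 0.95) {
  method <- match.arg(method)
  cr <- match.arg(cr)
  if (inherits(data, "ps_fit")) {
    weights <- weights %||% data$data$weight
    data <- data$data
  }
  d <- data |> mutate(.orr = derive_orr_flag(.data$response))
  keep <- d$.orr != "excluded"
  d <- d[keep, , drop = FALSE]
  w <- if (is.null(weights)) rep(1, nrow(d)) else weights[keep]
  if (method == "att" && is.null(weights)) {
    abort("ATT analysis needs weights", class = "extarm_usage_error")
  }
  if (method != "att") w <- rep(1, nrow(d))
  d$.y <- as.integer(d$.orr == "responder")
  d$.treated <- as.integer(d$cohort == "TRIAL")
  n_t <- sum(d$.treated == 1L)
  n_c <- sum(d$.treated == 0L)
  if (n_t == 0 || n_c == 0) {
    abort("Both cohorts must contain response-evaluable records",
          class = "extarm_data_error")
  }
  note <- NA_character_

  if (method == "unadjusted") {
    a <- sum(d$.y[d$.treated == 1L]); b <- n_t - a
    c_ <- sum(d$.y[d$.treated == 0L]); dd <- n_c - c_
    if (min(a, b, c_, dd) == 0) {
      if (!continuity) {
        abort(paste0("Zero cell in the 2x2 response table; rerun with ",
                     "continuity = TRUE to add 0.5 to all cells"),
              class = "extarm_zero_cell_error")
      }
      a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; dd <- dd + 0.5
      note <- "continuity-corrected (0.5 added to all cells)"
    }
    n1 <- a + b; n0 <- c_ + dd
    or_row <- wald_row("ORR", "odds_ratio", method, log(a * dd / (b * c_)),
                       sqrt(1 / a + 1 / b + 1 / c_ + 1 / dd), n_t, n_c, conf_level)
    rr_row <- wald_row("ORR", "rate_ratio", method, log((a / n1) / (c_ / n0)),
                       sqrt(1 / a - 1 / n1 + 1 / c_ - 1 / n0), n_t, n_c, conf_level)
    return(bind_rows(or_row, rr_row) |> mutate(note = note))
  }

  d <- covariate_factors(d, covariates)
  rhs <- if (method == "multivariable") {
    paste(c(".treated", covariates), collapse = " + ")
  } else ".treated"
  d$.w <- w
  fit_logit <- suppressWarnings(
    glm(as.formula(paste(".y ~", rhs)), data = d, family = quasibinomial(),
        weights = .w, control = list(epsilon = 1e-10, maxit = 100))
  )
  vc_or <- glm_cluster_vcov(fit_logit, d$patient_id, cr)
  se_or <- sqrt(diag(vc_or))[".treated"]

  fit_log <- tryCatch(
    suppressWarnings(glm(as.formula(paste(".y ~", rhs)), data = d,
                         family = quasibinomial(link = "log"), weights = .w,
                         start = c(log(max(mean(d$.y), 1e-3)),
                                   rep(0, length(coef(fit_logit)) - 1L)),
                         control = list(epsilon = 1e-10, maxit = 200))),
    error = function(e) NULL
  )
  if (is.null(fit_log) || !fit_log$converged) {
    # robust-Poisson fallback for the rate ratio
    fit_log <- suppressWarnings(
      glm(as.formula(paste(".y ~", rhs)), data = d, family = quasipoisson(),
          weights = .w, control = list(epsilon = 1e-10, maxit = 100))
    )
    note <- "rate ratio from robust-Poisson fallback"
  }
  vc_rr <- glm_cluster_vcov(fit_log, d$patient_id, cr)
  se_rr <- sqrt(diag(vc_rr))[".treated"]

  out <- bind_rows(
    wald_row("ORR", "odds_ratio", method, coef(fit_logit)[".treated"], se_or,
             n_t, n_c, conf_level),
    wald_row("ORR", "rate_ratio", method, coef(fit_log)[".treated"], se_rr,
             n_t, n_c, conf_level)
  ) |> mutate(note = note)
  if (method == "multivariable") {
    attr(out, "forest") <- forest_from_fit(
      coef(fit_logit), sqrt(diag(vc_or)), d, covariates, conf_level)
  }
  out
}

#' Weighted Kaplan-Meier curve for one sample
#'
#' Product-limit estimator with weighted event and at-risk sums, weighted
#' Greenwood variance, pointwise log(-log) confidence limits, and a median
#' whose confidence bounds are the times at which the survival confidence
#' limits cross one half. With unit weights this is the classical
#' Kaplan-Meier estimator; rescaling all weights by a constant leaves the
#' curve unchanged.
#'
#' @param time Non-negative event/censoring times.
#' @param event Logical event indicators.
#' @param weight Optional positive weights (default 1).
#' @param conf_level Confidence level for the pointwise limits and median CI.
#' @return A `km_curve`: tibble (`time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`, `ci_low`, `ci_high`) with the median summary (time units of the
#'   input) in `attr(, "median")`; `median_defined` is FALSE when the curve
#'   never reaches one half (no exception is raised).
#' @export
km_curve <- function(time, event, weight = NULL, conf_level = 0.95) {
  stopifnot(all(time >= 0), is.logical(event) || all(event %in% c(0, 1)))
  w <- weight %||% rep(1, length(time))
  stopifnot(all(w > 0))
  df <- data.frame(.t = time, .e = as.integer(event), .w = w)
  fit <- survival::survfit(survival::Surv(.t, .e) ~ 1, data = df, weights = .w,
                           conf.type = "log-log", conf.int = conf_level)
  curve <- tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, surv = fit$surv,
    ci_low = fit$lower, ci_high = fit$upper
  )
  # median: first time the survival estimate falls to <= 1/2; its confidence
  # limits are the first times each pointwise survival limit falls to <= 1/2
  # (the times whose survival CI still covers 1/2)
  first_at_half <- function(s) {
    i <- which(!is.na(s) & s <= 0.5 + 1e-12)
    if (length(i) == 0) NA_real_ else curve$time[min(i)]
  }
  med <- first_at_half(curve$surv)
  attr(curve, "median") <- tibble(
    median = med,
    ci_low = first_at_half(curve$ci_low),
    ci_high = first_at_half(curve$ci_high),
    median_defined = !is.na(med)
  )
  class(curve) <- c("km_curve", class(curve))
  curve
}

#' Weighted Kaplan-Meier curves by cohort
#'
#' Runs [km_curve()] per cohort for one endpoint of an analysis set, with
#' unit weights (`method = "unadjusted"`) or renormalized ATT weights
#' (`method = "att"`).
#'
#' @param data Analysis set or `ps_fit`.
#' @param endpoint One of `pfs`, `ttnt`, `os`.
#' @param method `unadjusted` or `att`.
#' @param weights Optional weight vector when `data` is a plain table.
#' @param conf_level Confidence level.
#' @return A `km_curves` tibble (`cohort` plus the [km_curve()] columns);
#'   medians in days and months per cohort in `attr(, "median")`.
#' @export
weighted_km <- function(data, endpoint = c("pfs", "ttnt", "os"),
                        method = c("unadjusted", "att"), weights = NULL,
                        conf_level = 0.95) {
  endpoint <- match.arg(endpoint)
  method <- match.arg(method)
  if (inherits(data, "ps_fit")) {
    weights <- weights %||% data$data$weight
    data <- data$data
  }
  if (method == "att" && is.null(weights)) {
    abort("ATT analysis needs weights", class = "extarm_usage_error")
  }
  w <- if (method == "att") weights else rep(1, nrow(data))
  tcol <- paste0(endpoint, "_days"); ecol <- paste0(endpoint, "_event")
  pieces <- map(c("TRIAL", "RWPC"), function(coh) {
    idx <- data$cohort == coh
    cv <- km_curve(data[[tcol]][idx], data[[ecol]][idx], w[idx], conf_level)
    med <- attr(cv, "median") |>
      mutate(cohort = coh,
             median_months = .data$median / DAYS_PER_MONTH,
             ci_low_months = .data$ci_low / DAYS_PER_MONTH,
             ci_high_months = .data$ci_high / DAYS_PER_MONTH)
    list(curve = cv |> mutate(cohort = coh) |> select("cohort", everything()),
         median = med)
  })
  out <- list_rbind(map(pieces, "curve"))
  attr(out, "median") <- list_rbind(map(pieces, "median")) |>
    mutate(endpoint = endpoint, method = method) |>
    select("endpoint", "method", "cohort", everything())
  attr(out, "endpoint") <- endpoint
  attr(out, "method") <- method
  class(out) <- c("km_curves", "km_curve", class(out))
  out
}

#' @export
glance.km_curve <- function(x, ...) attr(x, "median")

#' Cox proportional-hazards contrast
#'
#' Weighted partial likelihood with Efron tie handling and a Newton
#' convergence tolerance of 1e-9. Variance is the patient-clustered robust
#' sandwich (score residuals aggregated within `patient_id`) for every
#' method, reflecting repeated control lines per patient. `unadjusted` is the
#' treatment-only model with unit weights, `att` the treatment-only model
#' with renormalized ATT weights, `multivariable` the unit-weight model with
#' treatment plus baseline covariates.
#'
#' @param data Analysis set or `ps_fit`.
#' @param endpoint One of `pfs`, `ttnt`, `os`.
#' @param method `unadjusted`, `att`, or `multivariable`.
#' @param weights Optional weight vector when `data` is a plain table.
#' @param covariates Covariates for the multivariable model.
#' @param conf_level Confidence level.
#' @return A `cox_effect`: list with `effect` (one EffectEstimate row, robust
#'   SE), `forest` (per-term hazard ratios with reference-level rows),
#'   `model` (the `coxph` fit), `endpoint`, `method`.
#' @export
cox_model <- function(data, endpoint = c("pfs", "ttnt", "os"),
                      method = c("unadjusted", "att", "multivariable"),
                      weights = NULL, covariates = lot_covariates(),
                      conf_level = 0.95) {
  endpoint <- match.arg(endpoint)
  method <- match.arg(method)
  if (inherits(data, "ps_fit")) {
    weights <- weights %||% data$data$weight
    data <- data$data
  }
  if (method == "att" && is.null(weights)) {
    abort("ATT analysis needs weights", class = "extarm_usage_error")
  }
  tcol <- paste0(endpoint, "_days"); ecol <- paste0(endpoint, "_event")
  d <- data |> mutate(.treated = as.integer(.data$cohort == "TRIAL"))
  for (coh in c("TRIAL", "RWPC")) {
    if (sum(d[[ecol]][d$cohort == coh]) == 0) {
      abort(paste0("No observed ", toupper(endpoint), " events in the ", coh,
                   " arm: the partial likelihood for the treatment effect is monotone"),
            class = "extarm_monotone_error")
    }
  }
  d$.w <- if (method == "att") weights else rep(1, nrow(d))
  d <- covariate_factors(d, covariates)
  rhs <- if (method == "multivariable") {
    paste(c(".treated", covariates), collapse = " + ")
  } else ".treated"
  form <- as.formula(paste0("survival::Surv(", tcol, ", ", ecol, ") ~ ", rhs))
  fit <- survival::coxph(
    form, data = d, weights = .w, cluster = patient_id, ties = "efron",
    control = survival::coxph.control(eps = 1e-9, iter.max = 100)
  )
  sm <- summary(fit)$coefficients
  se_rob <- sm[, "robust se"]
  names(se_rob) <- rownames(sm)
  coefs <- coef(fit)
  effect <- wald_row(toupper(endpoint), "hazard_ratio", method,
                     coefs[[".treated"]], se_rob[[".treated"]],
                     sum(d$.treated == 1L), sum(d$.treated == 0L), conf_level)
  forest <- forest_from_fit(
    coefs, se_rob, d,
    if (method == "multivariable") covariates else character(), conf_level)
  structure(
    list(effect = effect, forest = forest, model = fit,
         endpoint = endpoint, method = method),
    class = "cox_effect"
  )
}

#' @export
tidy.cox_effect <- function(x, ...) x$forest

#' @export
glance.cox_effect <- function(x, ...) x$effect

#' @export
print.cox_effect <- function(x, ...) {
  e <- x$effect
  cat(sprintf("%s hazard ratio (%s): %.2f (%.2f, %.2f), p = %.4g\n",
              e$endpoint, e$method, e$estimate, e$ci_low, e$ci_high, e$p_value))
  invisible(x)
}

#' Run every endpoint through every adjustment method
#'
#' Orchestrates the full comparison: response odds and rate ratios
#' (unadjusted, ATT-weighted, multivariable), and for each time-to-event
#' endpoint unadjusted and ATT-weighted Kaplan-Meier curves with medians plus
#' unadjusted/ATT/multivariable Cox hazard ratios, all with
#' patient-clustered robust variance where adjustment is involved.
#'
#' @param fit A `ps_fit` after [att_weights()].
#' @param covariates Covariates for the multivariable models (defaults to the
#'   propensity covariates).
#' @param cr Cluster-robust flavour for GLMs.
#' @param conf_level Confidence level.
#' @return An `endpoint_results` bundle: `effects` (all contrast rows),
#'   `medians` (per endpoint/method/cohort), `km` (nested list of
#'   `km_curves`), `forests` (multivariable forest per endpoint),
#'   `orr` (observed response rates), `counts`.
#' @export
run_all_endpoints <- function(fit, covariates = NULL, cr = c("CR0", "CR1"),
                              conf_level = 0.95) {
  stopifnot(inherits(fit, "ps_fit"))
  cr <- match.arg(cr)
  if (is.null(fit$data$weight)) {
    abort("Call att_weights() before run_all_endpoints()",
          class = "extarm_usage_error")
  }
  covariates <- covariates %||% fit$covariates
  data <- fit$data
  counts <- lot_counts(data)
  if (counts$n_control_lots == 0 || counts$n_trial == 0) {
    abort("Both cohorts must be non-empty", class = "extarm_data_error")
  }
  w <- data$weight

  with_label <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("[", label, "] ", conditionMessage(e)), parent = e,
            class = "extarm_endpoint_error")
    })
  }

  orr_rows <- list(
    with_label("ORR unadjusted", binary_effect(data, "unadjusted",
                                               conf_level = conf_level)),
    with_label("ORR att", binary_effect(data, "att", weights = w, cr = cr,
                                        conf_level = conf_level)),
    with_label("ORR multivariable",
               binary_effect(data, "multivariable", covariates = covariates,
                             cr = cr, conf_level = conf_level))
  )
  forests <- list(orr = attr(orr_rows[[3]], "forest"))

  evaluable <- derive_orr_flag(data$response) != "excluded"
  resp <- as.integer(derive_orr_flag(data$response) == "responder")
  trial_ev <- evaluable & data$cohort == "TRIAL"
  ctrl_ev <- evaluable & data$cohort == "RWPC"
  orr <- tibble(
    method = c("unadjusted", "att"),
    orr_trial = rep(sum(resp[trial_ev]) / sum(trial_ev), 2),
    orr_control = c(sum(resp[ctrl_ev]) / sum(ctrl_ev),
                    sum((w * resp)[ctrl_ev]) / sum(w[ctrl_ev]))
  )

  km <- list(); medians <- list(); tte_rows <- list()
  for (ep in c("pfs", "ttnt", "os")) {
    km[[ep]] <- list(
      unadjusted = with_label(paste(ep, "KM unadjusted"),
                              weighted_km(data, ep, "unadjusted",
                                          conf_level = conf_level)),
      att = with_label(paste(ep, "KM att"),
                       weighted_km(data, ep, "att", weights = w,
                                   conf_level = conf_level))
    )
    medians[[ep]] <- bind_rows(attr(km[[ep]]$unadjusted, "median"),
                               attr(km[[ep]]$att, "median"))
    for (m in c("unadjusted", "att", "multivariable")) {
      cx <- with_label(paste(ep, "Cox", m),
                       cox_model(data, ep, m,
                                 weights = if (m == "att") w else NULL,
                                 covariates = covariates,
                                 conf_level = conf_level))
      tte_rows[[paste(ep, m)]] <- cx$effect
      if (m == "multivariable") forests[[ep]] <- cx$forest
    }
  }

  structure(
    list(
      effects = bind_rows(list_rbind(orr_rows), list_rbind(unname(tte_rows))),
      medians = list_rbind(unname(medians)),
      km = km, forests = forests, orr = orr, counts = counts
    ),
    class = "endpoint_results"
  )
}

#' @export
tidy.endpoint_results <- function(x, ...) x$effects

#' @export
glance.endpoint_results <- function(x, ...) {
  bind_cols(x$counts, tibble(n_effects = nrow(x$effects)))
}

#' @export
print.endpoint_results <- function(x, ...) {
  cat("Endpoint results: ", x$counts$n_trial, " trial patients vs ",
      x$counts$n_control_lots, " control LOTs from ",
      x$counts$n_control_patients, " patients\n", sep = "")
  print(x$effects |>
          mutate(across(c("estimate", "ci_low", "ci_high"), ~ round(.x, 2)),
                 p_value = signif(.data$p_value, 3)))
  invisible(x)
}
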