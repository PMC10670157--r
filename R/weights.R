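#' Fit the propensity-score model
#'
#' Main-effects multivariable logistic regression of trial membership on the
#' dummy-coded baseline covariates (reference levels: ECOG 0, one prior line,
#' each site absent, age < 65). The propensity score is the modelled
#' probability of belonging to the trial cohort given covariates, so the
#' control ATT weight is the usual odds of treatment, ps / (1 - ps). Fitting
#' is iteratively reweighted least squares run to a relative deviance change
#' below 1e-10 within 100 iterations.
#'
#' @param data A post-imputation LOT table; records still missing any model
#'   covariate are rejected.
#' @param covariates Covariate columns to include (default all of
#'   [lot_covariates()]).
#' @return An object of class `ps_fit`: the fitted model, coefficient table,
#'   the analysis data with propensity scores, and (after [att_weights()])
#'   ATT weights.
#' @export
fit_propensity <- function(data, covariates = lot_covariates()) {
  data <- validate_analysis_set(data)
  bad_cov <- setdiff(covariates, lot_covariates())
  if (length(bad_cov) > 0) {
    abort(paste0("Unknown covariate(s): ", paste(bad_cov, collapse = ", ")),
          class = "extarm_config_error")
  }
  incomplete <- rowSums(is.na(data[covariates])) > 0
  if (any(incomplete)) {
    abort(paste0(sum(incomplete), " record(s) have missing covariates; ",
                 "impute or drop them before propensity fitting"),
          class = "extarm_validation_error")
  }

  refs <- covariate_reference_levels()
  model_data <- data
  for (cov in covariates) {
    levs <- covariate_levels(cov)
    model_data[[cov]] <- factor(model_data[[cov]],
                                levels = c(refs[[cov]], setdiff(levs, refs[[cov]])))
  }
  model_data$.treated <- as.integer(model_data$cohort == "TRIAL")
  # constant covariates carry no membership information and would break the
  # design matrix; drop them from the model (the fit is unchanged)
  varying <- covariates[vapply(covariates,
                               function(cov) n_distinct(model_data[[cov]]) > 1L,
                               logical(1))]
  form <- as.formula(paste(".treated ~",
                           if (length(varying) > 0) {
                             paste(varying, collapse = " + ")
                           } else "1"))

  sep_warning <- FALSE
  fit <- withCallingHandlers(
    glm(form, data = model_data, family = binomial(),
        control = list(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warning <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  ps <- as.numeric(fitted(fit))
  if (sep_warning || any(ps <= 1e-12) || any(ps >= 1 - 1e-12)) {
    culprit <- find_separating_covariate(model_data, covariates)
    abort(paste0("Perfect separation in the propensity model",
                 if (!is.na(culprit)) paste0(" (covariate: ", culprit, ")") else ""),
          class = "extarm_separation_error")
  }
  if (!fit$converged) {
    abort(paste0("Propensity model did not converge in ", fit$iter, " iterations"),
          class = "extarm_convergence_error")
  }

  structure(
    list(
      model = fit,
      covariates = covariates,
      coefficients = setNames(coef(fit), names(coef(fit))),
      data = data |> mutate(ps = ps),
      renorm_factor = NULL
    ),
    class = "ps_fit"
  )
}

# level of some covariate observed in only one cohort (a zero cross-cell)
find_separating_covariate <- function(model_data, covariates) {
  for (cov in covariates) {
    tab <- table(model_data[[cov]], model_data$.treated)
    if (any(rowSums(tab > 0) == 1L & rowSums(tab) > 0)) return(cov)
  }
  NA_character_
}

#' Compute renormalized ATT weights
#'
#' Trial records receive weight 1. Control records receive the raw ATT odds
#' weight ps / (1 - ps), then all control weights are multiplied by the ratio
#' of the control sample size to the sum of the raw control weights, so the
#' renormalized control weights sum exactly to the number of control LOTs.
#' Renormalization is a common rescaling and never changes relative weights.
#'
#' @param fit A `ps_fit` from [fit_propensity()].
#' @return The `ps_fit` with `raw_weight`, `weight` columns added to `$data`
#'   and `renorm_factor` set.
#' @export
att_weights <- function(fit) {
  stopifnot(inherits(fit, "ps_fit"))
  d <- fit$data
  ctrl <- d$cohort == "RWPC"
  if (any(ctrl & d$ps >= 1 - 1e-12)) {
    abort("Propensity score numerically 1 on a control record: infinite ATT weight",
          class = "extarm_weight_error")
  }
  raw <- ifelse(ctrl, d$ps / (1 - d$ps), 1)
  n_ctrl <- sum(ctrl)
  factor <- n_ctrl / sum(raw[ctrl])
  fit$data <- d |>
    mutate(raw_weight = raw,
           weight = ifelse(ctrl, raw * factor, 1))
  fit$renorm_factor <- factor
  fit
}

#' Per-record weight table
#'
#' @param fit A `ps_fit` after [att_weights()].
#' @return Tibble with `patient_id`, `lot_seq`, `cohort`, `ps`, `raw_weight`,
#'   `weight`.
#' @export
weight_table <- function(fit) {
  stopifnot(inherits(fit, "ps_fit"))
  if (is.null(fit$data$weight)) {
    abort("Call att_weights() before weight_table()", class = "extarm_usage_error")
  }
  fit$data |> select("patient_id", "lot_seq", "cohort", "ps", "raw_weight", "weight")
}

#' @export
tidy.ps_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
         statistic = s[, 3], p_value = s[, 4])
}

#' @export
glance.ps_fit <- function(x, ...) {
  d <- x$data
  ctrl <- d$cohort == "RWPC"
  tibble(
    n_trial = sum(!ctrl), n_control = sum(ctrl),
    ps_min_trial = min(d$ps[!ctrl]), ps_max_trial = max(d$ps[!ctrl]),
    ps_min_control = min(d$ps[ctrl]), ps_max_control = max(d$ps[ctrl]),
    renorm_factor = x$renorm_factor %||% NA_real_,
    deviance = x$model$deviance, iterations = x$model$iter
  )
}

#' @export
print.ps_fit <- function(x, ...) {
  g <- glance(x)
  cat("Propensity-score fit: ", g$n_trial, " trial vs ", g$n_control,
      " control LOTs\n", sep = "")
  cat(sprintf("  PS range: trial [%.3f, %.3f], control [%.3f, %.3f]\n",
              g$ps_min_trial, g$ps_max_trial, g$ps_min_control, g$ps_max_control))
  if (!is.null(x$renorm_factor)) {
    cat(sprintf("  ATT weights renormalized (factor %.4f)\n", x$renorm_factor))
  }
  invisible(x)
}

# standardized difference of two proportions with pooled binomial variance
smd_binary <- function(p1, p2) {
  v <- (p1 * (1 - p1) + p2 * (1 - p2)) / 2
  if (v <= 0) {
    if (isTRUE(all.equal(p1, p2))) return(0)
    return(Inf)
  }
  (p1 - p2) / sqrt(v)
}

# Mahalanobis-type multi-level SMD over the non-reference level proportions
smd_multilevel <- function(p1, p2) {
  k <- length(p1)
  if (k < 2) return(abs(smd_binary(p1, p2)))
  d <- (p1 - p2)[-1]
  cov_of <- function(p) {
    s <- -outer(p[-1], p[-1])
    diag(s) <- p[-1] * (1 - p[-1])
    s
  }
  S <- (cov_of(p1) + cov_of(p2)) / 2
  inv <- tryCatch(solve(S), error = function(e) MASS::ginv(S))
  val <- drop(t(d) %*% inv %*% d)
  sqrt(max(val, 0))
}

weighted_props <- function(values, levels, w) {
  p <- vapply(levels, function(l) sum(w * (values == l)) / sum(w), numeric(1))
  setNames(p, levels)
}

#' Covariate balance table
#'
#' Per-level covariate frequencies and standardized mean differences (SMDs)
#' before and after ATT weighting. For a binary covariate the SMD is the
#' difference of trial and (weighted) control proportions divided by the
#' pooled binomial standard deviation; multi-level covariates additionally
#' report per-level SMDs plus a non-negative Mahalanobis-type summary over
#' the level proportions. Direction is trial minus (weighted) control. SMDs
#' for degenerate levels (proportion 0 or 1 in both cohorts) are 0 when the
#' proportions agree and infinite-flagged otherwise.
#'
#' @param fit A `ps_fit` after [att_weights()].
#' @param unimputed Optional pre-imputation LOT table; adds observed-only
#'   control frequencies (`p_control_observed`) for reporting.
#' @return A `balance_table`: tibble with one row per covariate level
#'   (`covariate`, `level`, `n_trial`, `p_trial`, `n_control`, `p_control`,
#'   `p_control_weighted`, `smd_unweighted`, `smd_weighted`) carrying a
#'   per-covariate summary (multi-level Mahalanobis SMDs) in
#'   `attr(, "summary")`.
#' @export
balance_table <- function(fit, unimputed = NULL) {
  stopifnot(inherits(fit, "ps_fit"))
  d <- fit$data
  if (is.null(d$weight)) {
    abort("Call att_weights() before balance_table()", class = "extarm_usage_error")
  }
  trial <- d |> filter(.data$cohort == "TRIAL")
  ctrl <- d |> filter(.data$cohort == "RWPC")
  w_ctrl <- ctrl$weight

  rows <- list()
  summaries <- list()
  for (cov in fit$covariates) {
    levs <- covariate_levels(cov)
    p_t  <- weighted_props(trial[[cov]], levs, rep(1, nrow(trial)))
    p_c  <- weighted_props(ctrl[[cov]], levs, rep(1, nrow(ctrl)))
    p_cw <- weighted_props(ctrl[[cov]], levs, w_ctrl)
    p_obs <- if (!is.null(unimputed)) {
      obs <- unimputed |> filter(.data$cohort == "RWPC", !is.na(.data[[cov]]))
      weighted_props(obs[[cov]], levs, rep(1, nrow(obs)))
    } else {
      setNames(rep(NA_real_, length(levs)), levs)
    }
    rows[[cov]] <- tibble(
      covariate = cov, level = levs,
      n_trial = as.integer(round(p_t * nrow(trial))),
      p_trial = unname(p_t),
      n_control = as.integer(round(p_c * nrow(ctrl))),
      p_control = unname(p_c),
      p_control_observed = unname(p_obs),
      p_control_weighted = unname(p_cw),
      smd_unweighted = vapply(levs, function(l) smd_binary(p_t[[l]], p_c[[l]]),
                              numeric(1), USE.NAMES = FALSE),
      smd_weighted = vapply(levs, function(l) smd_binary(p_t[[l]], p_cw[[l]]),
                            numeric(1), USE.NAMES = FALSE)
    )
    summaries[[cov]] <- tibble(
      covariate = cov, n_levels = length(levs),
      smd_unweighted = smd_multilevel(p_t, p_c),
      smd_weighted = smd_multilevel(p_t, p_cw)
    )
  }
  out <- list_rbind(rows)
  attr(out, "summary") <- list_rbind(summaries)
  class(out) <- c("balance_table", class(out))
  out
}

#' @export
glance.balance_table <- function(x, ...) {
  s <- attr(x, "summary")
  tibble(
    max_abs_smd_unweighted = max(abs(s$smd_unweighted)),
    max_abs_smd_weighted = max(abs(s$smd_weighted)),
    n_covariates = nrow(s)
  )
}
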