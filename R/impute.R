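#' Impute block-missing metastatic-site profiles from neighbouring LOTs
#'
#' Fills a LOT's missing metastatic-site block from the same patient's
#' nearest observed lines. For each missing-block LOT, per site:
#'
#' * both neighbours observed and concordant - the shared value is imputed;
#'   both observed but discordant (in either direction) - presence is imputed,
#'   conservative toward disease progression;
#' * only a prior LOT observed - its value is carried forward;
#' * only a subsequent LOT observed - its value is carried backward;
#' * no observed neighbour - the block is left missing and counted
#'   unimputable.
#'
#' "Prior"/"subsequent" mean the nearest *observed* LOT by line number within
#' the patient, so a chain of missing lines still imputes from the closest
#' observed line on each side. Observed values are never altered, and
#' applying the imputation twice equals applying it once.
#'
#' @param data A LOT table with block-wise metastatic-site missingness.
#' @return A list with `data` (imputed tibble) and `audit` (class
#'   `imputation_audit`): `n_missing_before`, `n_rule_both`,
#'   `n_rule_prior_only`, `n_rule_subsequent_only`, `n_unimputable`,
#'   `n_missing_after`.
#' @export
impute_metastases <- function(data) {
  data <- validate_lot_table(data)
  sites <- lot_schema()$met_sites
  miss <- is.na(data[[sites[1]]])   # block-wise, so one site indexes the block

  counts <- c(both = 0L, prior_only = 0L, subsequent_only = 0L, unimputable = 0L)
  out <- data
  for (i in which(miss)) {
    sibs <- which(data$patient_id == data$patient_id[i] & !miss)
    prior <- sibs[data$lot_seq[sibs] < data$lot_seq[i]]
    subsq <- sibs[data$lot_seq[sibs] > data$lot_seq[i]]
    prior <- if (length(prior)) prior[which.max(data$lot_seq[prior])] else NA_integer_
    subsq <- if (length(subsq)) subsq[which.min(data$lot_seq[subsq])] else NA_integer_

    if (!is.na(prior) && !is.na(subsq)) {
      counts["both"] <- counts["both"] + 1L
      for (s in sites) {
        a <- data[[s]][prior]; b <- data[[s]][subsq]
        out[[s]][i] <- if (a == b) a else "yes"
      }
    } else if (!is.na(prior)) {
      counts["prior_only"] <- counts["prior_only"] + 1L
      for (s in sites) out[[s]][i] <- data[[s]][prior]
    } else if (!is.na(subsq)) {
      counts["subsequent_only"] <- counts["subsequent_only"] + 1L
      for (s in sites) out[[s]][i] <- data[[s]][subsq]
    } else {
      counts["unimputable"] <- counts["unimputable"] + 1L
    }
  }

  audit <- structure(
    list(
      n_missing_before = sum(miss),
      n_rule_both = unname(counts["both"]),
      n_rule_prior_only = unname(counts["prior_only"]),
      n_rule_subsequent_only = unname(counts["subsequent_only"]),
      n_unimputable = unname(counts["unimputable"]),
      n_missing_after = unname(counts["unimputable"])
    ),
    class = "imputation_audit"
  )
  validate_lot_table(out)
  list(data = out, audit = audit)
}

#' @export
print.imputation_audit <- function(x, ...) {
  cat("Metastatic-site imputation audit\n",
      "  missing blocks before: ", x$n_missing_before, "\n",
      "  both neighbours:       ", x$n_rule_both, "\n",
      "  prior only (LOCF):     ", x$n_rule_prior_only, "\n",
      "  subsequent only:       ", x$n_rule_subsequent_only, "\n",
      "  unimputable:           ", x$n_unimputable, "\n",
      "  missing blocks after:  ", x$n_missing_after, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.imputation_audit <- function(x, ...) {
  tibble(
    rule = c("both_neighbours", "prior_only", "subsequent_only", "unimputable"),
    n = c(x$n_rule_both, x$n_rule_prior_only, x$n_rule_subsequent_only,
          x$n_unimputable)
  )
}

#' @export
glance.imputation_audit <- function(x, ...) {
  tibble(n_missing_before = x$n_missing_before,
         n_missing_after = x$n_missing_after,
         n_imputed = x$n_missing_before - x$n_missing_after)
}
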