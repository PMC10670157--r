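#' Eligibility rules for the control cohort
#'
#' The testable line-level eligibility rules: ECOG performance status 0-1,
#' prior platinum-based therapy, EGFR Exon20ins testing performed before line
#' initiation, and exclusion of amivantamab-containing lines together with
#' every later line of the same patient. Rules apply to control (RWPC)
#' records; trial records are retained as-is. Each LOT is judged
#' independently except for the amivantamab rule, which looks back across the
#' patient's earlier lines.
#'
#' @param ecog_allowed Allowed ECOG levels at line initiation.
#' @param require_platinum Require prior platinum-based therapy.
#' @param require_egfr_testing Require Exon20ins testing before initiation.
#' @param drop_amivantamab Exclude amivantamab-containing and subsequent LOTs.
#' @return An object of class `eligibility_rules`.
#' @export
eligibility_rules <- function(ecog_allowed = c("0", "1"),
                              require_platinum = TRUE,
                              require_egfr_testing = TRUE,
                              drop_amivantamab = TRUE) {
  structure(
    list(ecog_allowed = ecog_allowed,
         require_platinum = isTRUE(require_platinum),
         require_egfr_testing = isTRUE(require_egfr_testing),
         drop_amivantamab = isTRUE(drop_amivantamab)),
    class = "eligibility_rules"
  )
}

#' Assemble the analysis set
#'
#' Applies the eligibility rules to validated LOT records and derives the
#' two-cohort analysis set. Excluded control LOTs are counted per rule in a
#' fixed application order (ECOG, prior platinum, EGFR testing,
#' amivantamab/subsequent); each record is attributed to the first rule it
#' fails, so the per-rule counts plus the retained count equal the input
#' count. Filters report, they never raise.
#'
#' @param records A LOT table (validated on entry).
#' @param rules An [eligibility_rules()] object.
#' @return A list with `data` (the retained analysis set, a tibble) and
#'   `report` (class `eligibility_report`: `input_lots`, `retained`, and a
#'   tibble `excluded_by_rule` with one row per rule).
#' @export
assemble_cohort <- function(records, rules = eligibility_rules()) {
  records <- validate_lot_table(records)
  is_ctrl <- records$cohort == "RWPC"

  # earliest amivantamab-containing line per control patient
  ami_lots <- records |>
    filter(.data$cohort == "RWPC", .data$contains_amivantamab)
  ami_first <- if (nrow(ami_lots) > 0) {
    ami_lots |>
      group_by(.data$patient_id) |>
      summarise(first_ami = min(.data$lot_seq), .groups = "drop")
  } else {
    tibble(patient_id = character(), first_ami = integer())
  }
  rec <- records |>
    left_join(ami_first, by = "patient_id")

  rule_names <- c("ecog", "prior_platinum", "egfr_testing", "amivantamab")
  fails <- cbind(
    ecog = is_ctrl & !(rec$ecog %in% rules$ecog_allowed),
    prior_platinum = is_ctrl & rules$require_platinum & !rec$prior_platinum,
    egfr_testing = is_ctrl & rules$require_egfr_testing & !rec$egfr_tested_before,
    amivantamab = is_ctrl & rules$drop_amivantamab &
      !is.na(rec$first_ami) & rec$lot_seq >= rec$first_ami
  )
  first_fail <- apply(fails, 1L, function(f) {
    i <- which(f)
    if (length(i) == 0) NA_character_ else rule_names[i[1L]]
  })

  keep <- is.na(first_fail)
  data <- records[keep, , drop = FALSE]
  excl <- tibble(rule = rule_names) |>
    left_join(tibble(rule = first_fail[!keep]) |> count(.data$rule),
              by = "rule") |>
    mutate(n_excluded = coalesce(.data$n, 0L)) |>
    select("rule", "n_excluded")
  report <- structure(
    list(input_lots = nrow(records), retained = nrow(data),
         excluded_by_rule = excl),
    class = "eligibility_report"
  )
  validate_analysis_set(data)
  list(data = data, report = report)
}

#' @export
print.eligibility_report <- function(x, ...) {
  cat("Eligibility report: ", x$input_lots, " LOTs in, ",
      x$retained, " retained\n", sep = "")
  print(x$excluded_by_rule)
  invisible(x)
}

#' Classify best response for the response-rate analysis
#'
#' LOTs without response information are excluded from response-rate
#' analyses only; they remain in the time-to-event analyses.
#'
#' @param response Character vector with values `responder`,
#'   `non_responder`, or `NA`.
#' @return Character vector with values `responder`, `non_responder`,
#'   `excluded`.
#' @export
derive_orr_flag <- function(response) {
  dplyr::case_when(
    is.na(response) ~ "excluded",
    response == "responder" ~ "responder",
    TRUE ~ "non_responder"
  )
}

#' Check endpoint-time consistency
#'
#' Verifies the ordering constraints between endpoint durations: when death
#' is observed, progression-free survival and time-to-next-treatment cannot
#' exceed overall survival (violations); when OS is censored, an observed
#' PFS/TTNT event beyond the last-known-alive date is flagged as suspicious
#' (follow-up for progression extended past the survival follow-up) but not
#' fatal.
#'
#' @param data A LOT table.
#' @return A tibble of flagged records (`patient_id`, `lot_seq`, `check`,
#'   `severity`); zero rows when the set is consistent.
#' @export
check_endpoint_consistency <- function(data) {
  data <- validate_lot_table(data)
  flag_one <- function(days, event, label) {
    viol <- data$os_event & days > data$os_days
    susp <- !data$os_event & event & days > data$os_days
    bind_rows(
      tibble(idx = which(viol), check = paste0(label, "_exceeds_observed_os"),
             severity = "violation"),
      tibble(idx = which(susp), check = paste0(label, "_event_beyond_censored_os"),
             severity = "suspicious")
    )
  }
  flags <- bind_rows(
    flag_one(data$pfs_days, data$pfs_event, "pfs"),
    flag_one(data$ttnt_days, data$ttnt_event, "ttnt")
  )
  if (nrow(flags) == 0) {
    return(tibble(patient_id = character(), lot_seq = integer(),
                  check = character(), severity = character()))
  }
  flags |>
    mutate(patient_id = data$patient_id[.data$idx],
           lot_seq = data$lot_seq[.data$idx]) |>
    select("patient_id", "lot_seq", "check", "severity") |>
    arrange(.data$patient_id, .data$lot_seq)
}
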