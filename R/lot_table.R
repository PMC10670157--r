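#' LOT-table schema
#'
#' Column names, order and enumerated levels for LOT-level records. One row is
#' one line of therapy (LOT) for one patient: the trial cohort contributes one
#' LOT per patient, the real-world physician's-choice (RWPC) cohort may
#' contribute several per patient.
#'
#' @return A named list with `columns` (character vector in canonical order),
#'   `levels` (named list of enumerated levels per categorical column),
#'   `met_sites` (the seven metastatic-site columns, which are missing jointly
#'   or not at all), and column class groups (`logical_cols`, `integer_cols`).
#' @export
lot_schema <- function() {
  list(
    columns = c(
      "patient_id", "cohort", "lot_seq",
      "ecog", "prior_lines",
      "brain_met", "liver_met", "bone_met", "lymph_met",
      "adrenal_met", "pleural_met", "other_met",
      "age_cat",
      "egfr_tested_before", "prior_platinum", "contains_amivantamab",
      "response",
      "pfs_days", "pfs_event", "ttnt_days", "ttnt_event",
      "os_days", "os_event"
    ),
    levels = list(
      cohort      = c("TRIAL", "RWPC"),
      ecog        = c("0", "1"),
      prior_lines = c("1", "2", "3plus"),
      age_cat     = c("lt65", "65to75", "ge75"),
      response    = c("responder", "non_responder")
    ),
    met_sites = c(
      "brain_met", "liver_met", "bone_met", "lymph_met",
      "adrenal_met", "pleural_met", "other_met"
    ),
    met_levels   = c("yes", "no"),
    logical_cols = c(
      "egfr_tested_before", "prior_platinum", "contains_amivantamab",
      "pfs_event", "ttnt_event", "os_event"
    ),
    integer_cols = c("lot_seq", "pfs_days", "ttnt_days", "os_days")
  )
}

#' Baseline covariate columns used for adjustment
#'
#' The prognostic covariate set: ECOG performance status, number of prior
#' lines, the seven metastatic-site indicators, and age category.
#'
#' @return Character vector of column names.
#' @export
lot_covariates <- function() {
  sch <- lot_schema()
  c("ecog", "prior_lines", sch$met_sites, "age_cat")
}

#' Reference level of each covariate
#'
#' Dummy coding in the propensity and outcome models uses these as the
#' omitted category: ECOG 0, one prior line, site absent, age < 65.
#'
#' @return Named character vector, one reference level per covariate.
#' @export
covariate_reference_levels <- function() {
  sch <- lot_schema()
  refs <- c(ecog = "0", prior_lines = "1", age_cat = "lt65")
  c(refs, setNames(rep("no", length(sch$met_sites)), sch$met_sites))
}

covariate_levels <- function(covariate) {
  sch <- lot_schema()
  if (covariate %in% sch$met_sites) return(c("no", "yes"))
  sch$levels[[covariate]]
}

#' Validate a LOT table
#'
#' Checks field-level invariants: canonical columns, enumerated categorical
#' values, non-negative integer durations, logical event flags, block
#' missingness of the seven metastatic-site fields (all seven missing or none),
#' and that trial records are single first-line amivantamab-containing LOTs.
#' Validation rejects, it never coerces.
#'
#' @param data A data frame of LOT records.
#' @return `data` as a tibble, invisibly, if valid; otherwise an error.
#' @export
validate_lot_table <- function(data) {
  sch <- lot_schema()
  unknown <- setdiff(names(data), sch$columns)
  if (length(unknown) > 0) {
    abort(paste0("Unknown column(s): ", paste(unknown, collapse = ", ")),
          class = "extarm_schema_error")
  }
  missing_cols <- setdiff(sch$columns, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "extarm_schema_error")
  }
  data <- as_tibble(data)[, sch$columns]

  fail_rows <- function(ok, what) {
    bad <- which(!ok)
    if (length(bad) > 0) {
      abort(paste0("Invalid ", what, " in row(s): ",
                   paste(head(bad, 5L), collapse = ", "),
                   if (length(bad) > 5L) " ..." else ""),
            class = "extarm_validation_error")
    }
  }

  fail_rows(!is.na(data$patient_id) & nzchar(data$patient_id), "patient_id")
  for (col in names(sch$levels)) {
    vals <- data[[col]]
    ok <- vals %in% sch$levels[[col]]
    if (col == "response") ok <- ok | is.na(vals)
    fail_rows(ok, paste0("value for '", col, "'"))
  }
  for (col in sch$met_sites) {
    fail_rows(data[[col]] %in% sch$met_levels | is.na(data[[col]]),
              paste0("value for '", col, "'"))
  }
  # block missingness: the seven site fields are missing jointly or not at all
  n_missing_sites <- rowSums(is.na(as.matrix(data[sch$met_sites])))
  fail_rows(n_missing_sites %in% c(0L, length(sch$met_sites)),
            "metastatic-site block (sites must be missing jointly or not at all)")

  for (col in sch$logical_cols) {
    fail_rows(is.logical(data[[col]]) & !is.na(data[[col]]),
              paste0("logical flag '", col, "'"))
  }
  for (col in sch$integer_cols) {
    v <- data[[col]]
    fail_rows(is.numeric(v) & !is.na(v) & v >= 0 & v == floor(v),
              paste0("non-negative integer '", col, "'"))
  }
  trial <- data$cohort == "TRIAL"
  fail_rows(!trial | (data$lot_seq == 1L & data$contains_amivantamab),
            "TRIAL record (must have lot_seq 1 and contain amivantamab)")
  invisible(data)
}

#' Read a LOT table from CSV
#'
#' Reads the canonical comma-separated, UTF-8, headered dialect: missing
#' values are empty cells, booleans are 0/1, durations are integer days from
#' the LOT index date. The table is validated on read; malformed files error
#' rather than being silently coerced.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of LOT records.
#' @export
read_lot_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "extarm_io_error")
  }
  sch <- lot_schema()
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  unknown <- setdiff(names(raw), sch$columns)
  if (length(unknown) > 0) {
    abort(paste0("Unknown column(s): ", paste(unknown, collapse = ", ")),
          class = "extarm_schema_error")
  }
  missing_cols <- setdiff(sch$columns, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "extarm_schema_error")
  }
  raw <- raw[, sch$columns]
  empty_to_na <- function(x) ifelse(nzchar(x), x, NA_character_)
  out <- raw |> mutate(across(everything(), empty_to_na))
  parse_bool <- function(x, col) {
    ok <- x %in% c("0", "1")
    if (any(!ok)) {
      abort(paste0("Column '", col, "' must be 0/1; bad row(s): ",
                   paste(head(which(!ok), 5L), collapse = ", ")),
            class = "extarm_validation_error")
    }
    x == "1"
  }
  parse_int <- function(x, col) {
    v <- suppressWarnings(as.numeric(x))
    ok <- !is.na(v) & v >= 0 & v == floor(v)
    if (any(!ok)) {
      abort(paste0("Column '", col, "' must be a non-negative integer; bad row(s): ",
                   paste(head(which(!ok), 5L), collapse = ", ")),
            class = "extarm_validation_error")
    }
    as.integer(v)
  }
  for (col in sch$logical_cols) out[[col]] <- parse_bool(out[[col]], col)
  for (col in sch$integer_cols) out[[col]] <- parse_int(out[[col]], col)
  validate_lot_table(out)
  out
}

#' Write a LOT table to CSV
#'
#' Inverse of [read_lot_table()]: missing values become empty cells and
#' booleans are written as 0/1, so a write/read round trip is the identity.
#'
#' @param data A valid LOT table.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_lot_table <- function(data, path) {
  data <- validate_lot_table(data)
  sch <- lot_schema()
  out <- data |>
    mutate(across(all_of(sch$logical_cols), ~ as.integer(.x)),
           across(all_of(sch$integer_cols), ~ as.integer(.x)))
  tryCatch(
    readr::write_csv(out, path, na = "", progress = FALSE),
    error = function(e) abort(paste0("Cannot write: ", path, " (", conditionMessage(e), ")"),
                              class = "extarm_io_error")
  )
  invisible(path)
}

#' Cohort size summary of an analysis set
#'
#' @param data A LOT table.
#' @return A one-row tibble with `n_trial` (trial patients = trial LOTs),
#'   `n_control_lots`, and `n_control_patients`.
#' @export
lot_counts <- function(data) {
  ctrl <- data |> filter(.data$cohort == "RWPC")
  tibble(
    n_trial            = sum(data$cohort == "TRIAL"),
    n_control_lots     = nrow(ctrl),
    n_control_patients = n_distinct(ctrl$patient_id)
  )
}

#' Validate analysis-set invariants
#'
#' Beyond record-level validity: no retained control LOT contains amivantamab,
#' and only control patients may contribute more than one LOT.
#'
#' @param data A LOT table.
#' @return `data` invisibly, or an error.
#' @export
validate_analysis_set <- function(data) {
  data <- validate_lot_table(data)
  bad_ami <- data$cohort == "RWPC" & data$contains_amivantamab
  if (any(bad_ami)) {
    abort("RWPC records containing amivantamab are not allowed in an analysis set",
          class = "extarm_validation_error")
  }
  dup <- data |> count(.data$patient_id) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    trial_dup <- data |>
      filter(.data$patient_id %in% dup$patient_id, .data$cohort == "TRIAL")
    if (nrow(trial_dup) > 0) {
      abort("Repeated patient_id in the TRIAL stratum", class = "extarm_validation_error")
    }
  }
  invisible(data)
}
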