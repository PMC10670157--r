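#' Pipeline configuration
#'
#' Collects everything a full run needs: where the input comes from (a LOT
#' CSV, or the synthetic generator when `input` is NULL), which stages run,
#' eligibility rules, the adjustment covariates, estimator options, seed and
#' verbosity. Can be read from a YAML file via `pipeline_config_from_yaml()`.
#'
#' @param input Optional path to a LOT CSV; when NULL the synthetic generator
#'   supplies the cohort.
#' @param out_dir Artifact directory (created if absent).
#' @param sim A [sim_config()] or argument list for it (used when `input` is
#'   NULL; its seed is overridden by `seed`).
#' @param covariates Adjustment covariates.
#' @param rules An [eligibility_rules()] object.
#' @param cr Cluster-robust flavour, `CR0` or `CR1`.
#' @param conf_level Confidence level.
#' @param seed Integer seed for the whole run.
#' @param stages Stages to run, in pipeline order.
#' @param verbose Print stage narration.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, out_dir = "extarm-artifacts",
                            sim = sim_config(), covariates = lot_covariates(),
                            rules = eligibility_rules(), cr = "CR0",
                            conf_level = 0.95, seed = 1L,
                            stages = c("simulate", "assemble", "impute",
                                       "weight", "estimate", "report"),
                            verbose = FALSE) {
  bad <- setdiff(covariates, lot_covariates())
  if (length(bad) > 0) {
    abort(paste0("Unknown covariate(s) in config: ", paste(bad, collapse = ", ")),
          class = "extarm_config_error")
  }
  if (!is.null(input) && !file.exists(input)) {
    abort(paste0("Input file not found: ", input), class = "extarm_config_error")
  }
  if (!inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)
  sim$seed <- as.integer(seed)
  structure(
    list(input = input, out_dir = out_dir, sim = sim, covariates = covariates,
         rules = rules, cr = match.arg(cr, c("CR0", "CR1")),
         conf_level = conf_level, seed = as.integer(seed),
         stages = stages, verbose = isTRUE(verbose)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path Path to a YAML serialization of the configuration.
#' @export
pipeline_config_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  sim <- if (!is.null(cfg$sim)) do.call(sim_config, cfg$sim) else sim_config()
  pipeline_config(
    input = cfg$input, out_dir = cfg$out_dir %||% "extarm-artifacts",
    sim = sim, covariates = cfg$covariates %||% lot_covariates(),
    rules = do.call(eligibility_rules, cfg$rules %||% list()),
    cr = cfg$cr %||% "CR0", conf_level = cfg$conf_level %||% 0.95,
    seed = cfg$seed %||% 1L,
    stages = cfg$stages %||% c("simulate", "assemble", "impute", "weight",
                               "estimate", "report"),
    verbose = cfg$verbose %||% FALSE
  )
}

pipeline_log <- function(config, ...) {
  if (config$verbose) message(...)
  invisible(NULL)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  path
}

#' Run the full pipeline
#'
#' Executes simulate (or read) -> assemble -> impute -> weight -> estimate ->
#' report, writing every intermediate table and a manifest (config hash, seed
#' and md5 checksum per artifact) into the artifact directory. Reruns with an
#' identical configuration reproduce byte-identical artifacts. A stage
#' failure stops the run; the manifest marks the failed stage and downstream
#' stages are skipped.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the `endpoint_results` bundle, the
#'   `ps_fit`, the reports of earlier stages, and the artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$out_dir, f)

  cfg_for_hash <- config
  cfg_for_hash$verbose <- NULL
  cfg_json <- jsonlite::toJSON(
    list(seed = config$seed, covariates = config$covariates,
         cr = config$cr, conf_level = config$conf_level,
         stages = config$stages, input = config$input,
         sim = unclass(config$sim), rules = unclass(config$rules)),
    auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(config_hash = md5_string(as.character(cfg_json)),
                   seed = config$seed, stages = list())
  artifacts <- character()
  state <- new.env(parent = emptyenv())

  record <- function(stage, files) {
    manifest$stages[[stage]] <<- list(
      status = "ok",
      checksums = as.list(tools::md5sum(files))
    )
    artifacts <<- c(artifacts, files)
  }
  fail <- function(stage, e) {
    manifest$stages[[stage]] <<- list(status = "failed",
                                      error = conditionMessage(e))
    write_json_file(manifest, path("manifest.json"))
    abort(paste0("Pipeline stage '", stage, "' failed: ", conditionMessage(e)),
          parent = e, class = "extarm_pipeline_error")
  }
  run_stage <- function(stage, body) {
    if (!stage %in% config$stages) return(invisible(NULL))
    pipeline_log(config, "[", stage, "] running")
    tryCatch(body(), error = function(e) fail(stage, e))
  }

  run_stage("simulate", function() {
    state$raw <- if (is.null(config$input)) {
      simulate_cohort(config$sim)
    } else {
      read_lot_table(config$input)
    }
    write_lot_table(state$raw, path("cohort.csv"))
    record("simulate", path("cohort.csv"))
    pipeline_log(config, "  ", nrow(state$raw), " LOT records in")
  })

  run_stage("assemble", function() {
    res <- assemble_cohort(state$raw, config$rules)
    state$assembled <- res$data
    write_lot_table(res$data, path("analysis.csv"))
    write_json_file(list(
      input_lots = res$report$input_lots, retained = res$report$retained,
      excluded_by_rule = setNames(as.list(res$report$excluded_by_rule$n_excluded),
                                  res$report$excluded_by_rule$rule)
    ), path("eligibility.json"))
    record("assemble", c(path("analysis.csv"), path("eligibility.json")))
    state$eligibility <- res$report
    pipeline_log(config, "  ", res$report$retained, " of ",
                 res$report$input_lots, " LOTs retained")
  })

  run_stage("impute", function() {
    res <- impute_metastases(state$assembled)
    state$imputed <- res$data
    state$audit <- res$audit
    write_lot_table(res$data, path("imputed.csv"))
    write_json_file(unclass(res$audit), path("imputation_audit.json"))
    record("impute", c(path("imputed.csv"), path("imputation_audit.json")))
    pipeline_log(config, "  ", res$audit$n_missing_before,
                 " missing blocks, ", res$audit$n_missing_after, " after imputation")
  })

  run_stage("weight", function() {
    complete <- rowSums(is.na(state$imputed[config$covariates])) == 0
    state$fit <- fit_propensity(state$imputed[complete, , drop = FALSE],
                                config$covariates) |>
      att_weights()
    readr::write_csv(weight_table(state$fit), path("weights.csv"),
                     progress = FALSE)
    bal <- balance_table(state$fit, unimputed = state$assembled)
    state$balance <- bal
    readr::write_csv(as_tibble(bal), path("balance.csv"), progress = FALSE)
    record("weight", c(path("weights.csv"), path("balance.csv")))
    g <- glance(bal)
    pipeline_log(config, sprintf("  max |SMD| %.3f unweighted -> %.3f weighted",
                                 g$max_abs_smd_unweighted, g$max_abs_smd_weighted))
  })

  run_stage("estimate", function() {
    state$results <- run_all_endpoints(state$fit, config$covariates,
                                       cr = config$cr,
                                       conf_level = config$conf_level)
    eff <- state$results$effects
    write_json_file(purrr::transpose(as.list(eff)), path("results.json"))
    record("estimate", path("results.json"))
    for (row in seq_len(nrow(eff))) {
      e <- eff[row, ]
      pipeline_log(config, sprintf("  %s %s (%s): %.2f (%.2f, %.2f)",
                                   e$endpoint, e$measure, e$method,
                                   e$estimate, e$ci_low, e$ci_high))
    }
  })

  run_stage("report", function() {
    files <- render_reports(state$results, config$out_dir,
                            balance = state$balance)
    record("report", files)
  })

  write_json_file(manifest, path("manifest.json"))
  invisible(list(results = state$results, fit = state$fit,
                 balance = state$balance, audit = state$audit,
                 eligibility = state$eligibility,
                 manifest = manifest, artifacts = artifacts,
                 out_dir = config$out_dir))
}

md5_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}

#' Render publication-style tables and plot data
#'
#' Writes, for whatever parts of the bundle are present: one Kaplan-Meier
#' data file per endpoint holding both the unadjusted and ATT-adjusted
#' curves, a balance table, an effects table (medians carry `NR` when the
#' curve never crosses one half), and per-endpoint forest-plot data with
#' reference-level rows. Missing pieces are skipped and logged, not fatal.
#'
#' @param results An `endpoint_results` bundle (may be partial).
#' @param out_dir Output directory.
#' @param balance Optional `balance_table` to include.
#' @param verbose Print a line per omission.
#' @return Character vector of written file paths, invisibly.
#' @export
render_reports <- function(results, out_dir = ".", balance = NULL,
                           verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  note <- function(...) if (verbose) message(...)

  for (ep in c("pfs", "ttnt", "os")) {
    curves <- results$km[[ep]]
    if (is.null(curves)) {
      note("KM data for ", ep, " absent; skipped")
      next
    }
    df <- bind_rows(
      as_tibble(curves$unadjusted) |> mutate(method = "unadjusted"),
      as_tibble(curves$att) |> mutate(method = "att")
    ) |> select("method", everything())
    f <- file.path(out_dir, paste0("km_", ep, ".csv"))
    readr::write_csv(df, f, progress = FALSE)
    written <- c(written, f)
  }

  if (!is.null(results$effects)) {
    f <- file.path(out_dir, "effects.csv")
    readr::write_csv(results$effects, f, progress = FALSE)
    written <- c(written, f)
  } else {
    note("effects table absent; skipped")
  }

  if (!is.null(results$medians)) {
    med <- results$medians |>
      mutate(median_label = ifelse(.data$median_defined,
                                   sprintf("%.2f", .data$median_months), "NR"))
    f <- file.path(out_dir, "medians.csv")
    readr::write_csv(med, f, progress = FALSE)
    written <- c(written, f)
  }

  if (!is.null(balance)) {
    f <- file.path(out_dir, "balance_report.csv")
    readr::write_csv(as_tibble(balance), f, progress = FALSE)
    written <- c(written, f)
  }

  for (ep in names(results$forests %||% list())) {
    f <- file.path(out_dir, paste0("forest_", ep, ".csv"))
    readr::write_csv(results$forests[[ep]], f, progress = FALSE)
    written <- c(written, f)
  }
  invisible(written)
}
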