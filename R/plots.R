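#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_point geom_errorbarh
#'   geom_vline geom_col labs theme_minimal facet_wrap position_dodge
#'   scale_y_continuous coord_cartesian
NULL

#' @export
ggplot2::autoplot

#' Kaplan-Meier step plot
#'
#' @param object A `km_curves` object from [weighted_km()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.km_curves <- function(object, ...) {
  lab <- toupper(attr(object, "endpoint") %||% "time-to-event")
  df <- as_tibble(object) |>
    group_by(.data$cohort) |>
    group_modify(~ bind_rows(tibble(time = 0, surv = 1, ci_low = 1, ci_high = 1),
                             .x |> select("time", "surv", "ci_low", "ci_high"))) |>
    ungroup()
  ggplot(df, aes(x = .data$time, y = .data$surv, colour = .data$cohort)) +
    geom_step() +
    geom_step(aes(y = .data$ci_low), linetype = "dotted", na.rm = TRUE) +
    geom_step(aes(y = .data$ci_high), linetype = "dotted", na.rm = TRUE) +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "Days from index date", y = "Survival probability",
         title = paste0(lab, " (", attr(object, "method") %||% "", ")"),
         colour = NULL) +
    theme_minimal()
}

#' Covariate-balance (love) plot
#'
#' Absolute per-level standardized mean differences before and after ATT
#' weighting, with reference lines at 0.1 and 0.18.
#'
#' @param object A `balance_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.balance_table <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(label = paste(.data$covariate, .data$level, sep = ": ")) |>
    select("label", "smd_unweighted", "smd_weighted") |>
    tidyr::pivot_longer(-"label", names_to = "stage", values_to = "smd") |>
    mutate(stage = ifelse(.data$stage == "smd_unweighted",
                          "unweighted", "ATT-weighted"))
  ggplot(df, aes(x = abs(.data$smd), y = .data$label, colour = .data$stage)) +
    geom_vline(xintercept = c(0.1, 0.18), linetype = "dashed",
               colour = "grey60") +
    geom_point() +
    labs(x = "|standardized mean difference|", y = NULL, colour = NULL) +
    theme_minimal()
}

#' Forest plot of per-term hazard or odds ratios
#'
#' @param object A `cox_effect` (or any tibble shaped like its `$forest`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cox_effect <- function(object, ...) {
  df <- object$forest |>
    mutate(label = paste(.data$covariate, .data$level, sep = ": "),
           label = factor(.data$label, levels = rev(unique(.data$label))))
  ggplot(df |> filter(!.data$reference),
         aes(x = .data$estimate, y = .data$label)) +
    geom_vline(xintercept = 1, linetype = "dashed", colour = "grey60") +
    geom_point() +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0.2) +
    labs(x = paste0(toupper(object$endpoint), " hazard ratio (",
                    object$method, ")"),
         y = NULL) +
    theme_minimal()
}
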