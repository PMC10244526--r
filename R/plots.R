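#' Forest plot of a disproportionality analysis
#'
#' Point estimates with their 95% intervals per event, faceted by exposure
#' group. For the ROR the x axis is log-scaled with the null at 1; for the
#' IC the axis is linear with the null at 0. Events whose lower bound clears
#' the null with at least the minimum report count are the flagged signals.
#'
#' @param object A `faers_disprop` from [disproportionality()].
#' @param statistic `"ror"` or `"ic"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.faers_disprop <- function(object, statistic = c("ror", "ic"), ...) {
  statistic <- arg_match(statistic)
  df <- tidy(object)
  if (statistic == "ror") {
    df <- df |> rename(est = "ror", lo = "ror_025", hi = "ror_975",
                       signal = "signal_by_ror")
    null_at <- 1
  } else {
    df <- df |> rename(est = "ic", lo = "ic_025", hi = "ic_975",
                       signal = "signal_by_ic")
    null_at <- 0
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$est, y = .data$event,
                                        colour = .data$signal)) +
    ggplot2::geom_vline(xintercept = null_at, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                             na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$exposure_group)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b",
                                            `FALSE` = "grey30"),
                                 name = "signal") +
    ggplot2::labs(x = toupper(statistic), y = NULL)
  if (statistic == "ror") p <- p + ggplot2::scale_x_log10()
  p
}

#' Stacked-bar plot of outcome severity profiles
#'
#' Outcome category percentages per exposure group, one panel per stratum
#' (overall or SMQ category), most severe categories at the base.
#'
#' @param object A `faers_outcomes` from [outcome_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.faers_outcomes <- function(object, ...) {
  df <- tidy(object) |> filter(!is.na(.data$pct))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$exposure_group, y = .data$pct,
                                   fill = .data$outcome)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(ggplot2::vars(.data$stratum)) +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = -1) +
    ggplot2::labs(x = NULL, y = "% of cases", fill = "outcome") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
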