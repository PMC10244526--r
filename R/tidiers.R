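#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a disproportionality result
#'
#' Returns the analysis as a plain tibble, one row per (exposure group,
#' event), with the contingency cells, both point estimates' intervals and
#' the signal flags.
#'
#' @param x A `faers_disprop` from [disproportionality()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.faers_disprop <- function(x, ...) {
  as_tibble(x) |>
    select("level", "event", "smq_code", "exposure_group", "a", "b", "c", "d",
           "n_expected", "ror", "ror_025", "ror_975", "ic", "ic_025",
           "ic_975", "n_reports", "signal_by_ror", "signal_by_ic")
}

#' One-row summary of a disproportionality result
#'
#' @param x A `faers_disprop`.
#' @param ... Unused.
#' @return A tibble with the analysis settings and signal counts under each
#'   criterion.
#' @export
glance.faers_disprop <- function(x, ...) {
  tibble(
    level = attr(x, "level"), comparator = attr(x, "comparator"),
    counting = attr(x, "counting"), min_reports = attr(x, "min_reports"),
    n_tables = nrow(x),
    n_signal_ror = sum(x$signal_by_ror),
    n_signal_ic = sum(x$signal_by_ic)
  )
}

#' Tidy an outcome profile
#'
#' @param x A `faers_outcomes` from [outcome_profile()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.faers_outcomes <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of an outcome profile
#'
#' @param x A `faers_outcomes`.
#' @param ... Unused.
#' @return A tibble with stratification mode, strata and case totals.
#' @export
glance.faers_outcomes <- function(x, ...) {
  tibble(
    by = attr(x, "by"),
    n_strata = n_distinct(x$stratum),
    n_groups = n_distinct(x$exposure_group),
    n_cases = as_tibble(x) |>
      distinct(.data$exposure_group, .data$stratum, .data$denominator) |>
      pull(.data$denominator) |> sum()
  )
}
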