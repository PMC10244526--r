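#' Outcome severity precedence
#'
#' A case can carry several outcome codes, but severity tabulations assign
#' each case to exactly one category (so column percentages sum to 100).
#' The default precedence puts fatal and life-threatening outcomes first:
#' death > life-threatening > disability > congenital anomaly >
#' hospitalisation > other serious > unknown. Override by passing any
#' permutation of the seven categories to [outcome_profile()].
#'
#' @return Character vector of the seven categories, most severe first.
#' @export
outcome_precedence <- function() {
  c("death", "life_threatening", "disability", "congenital_anomaly",
    "hospitalization", "other_serious", "unknown")
}

# one outcome category per case id (named character vector)
primary_outcome_by_case <- function(cohort, precedence = outcome_precedence()) {
  if (!setequal(precedence, outcome_levels())) {
    abort("`precedence` must be a permutation of the seven outcome categories")
  }
  key <- cohort$cases |> select("report_id", "case_id")
  ranked <- cohort$outcomes |>
    inner_join(key, by = "report_id") |>
    mutate(rank = match(.data$outcome, precedence)) |>
    slice_min(.data$rank, n = 1, by = "case_id", with_ties = FALSE)
  out <- setNames(rep("unknown", nrow(cohort$cases)), cohort$cases$case_id)
  out[ranked$case_id] <- ranked$outcome
  out
}

#' Profile outcome severity by exposure group
#'
#' Tabulates outcome categories among cardiovascular cases per exposure
#' group, overall or within each SMQ category. Each case contributes to
#' exactly one category, chosen by severity precedence; the denominator is
#' the number of cases in the stratum, so counts sum to the denominator and
#' percentages to ~100. A stratum with no cases is kept with a zero
#' denominator and `NA` percentages.
#'
#' @param cohort A `faers_cohort`.
#' @param by `"overall"` (all cardiovascular cases) or `"smq"` (one stratum
#'   per SMQ category).
#' @param groups Exposure groups to profile.
#' @param precedence Severity order, see [outcome_precedence()].
#' @return A `faers_outcomes` tibble with columns `exposure_group`,
#'   `stratum`, `smq_code`, `outcome`, `n`, `denominator`, `pct`
#'   (1 decimal place; `NA` when the denominator is zero).
#' @examples
#' sim <- synth_generate(synth_config(seed = 3, n_cases = c(
#'   ICI_alone = 200, AGI_alone = 200, combination = 100, neither = 1000)))
#' archive <- read_drug_archive(faersignal_example("drug_archive.tsv"))
#' smq <- read_smq_map(faersignal_example("smq_map_synthetic.tsv"))
#' cohort <- sim$reports |> clean_reports(archive) |> build_cohorts(smq)
#' outcome_profile(cohort)
#' @export
outcome_profile <- function(cohort, by = c("overall", "smq"),
                            groups = c("ICI_alone", "AGI_alone", "combination"),
                            precedence = outcome_precedence()) {
  stopifnot(inherits(cohort, "faers_cohort"))
  by <- arg_match(by)
  prim <- primary_outcome_by_case(cohort, precedence)
  base <- cohort$cases |>
    filter(.data$is_cv_case, .data$exposure_group %in% groups) |>
    mutate(outcome = prim[.data$case_id]) |>
    select("case_id", "exposure_group", "outcome")
  strata <- if (by == "overall") {
    base |> mutate(stratum = "overall", smq_code = NA_integer_)
  } else {
    base |>
      inner_join(cohort$smq_units |> select("case_id", "smq_code", "smq_name"),
                 by = "case_id", relationship = "many-to-many") |>
      rename(stratum = "smq_name")
  }
  grid <- expand.grid(
    exposure_group = groups,
    stratum = if (by == "overall") "overall" else cv_smq_catalog()$smq_name,
    outcome = outcome_levels(),
    stringsAsFactors = FALSE
  ) |> as_tibble()
  if (by == "smq") {
    grid <- grid |> left_join(cv_smq_catalog() |> rename(stratum = "smq_name"),
                              by = "stratum")
  } else {
    grid$smq_code <- NA_integer_
  }
  counts <- strata |>
    count(.data$exposure_group, .data$stratum, .data$outcome) |>
    mutate(exposure_group = as.character(.data$exposure_group))
  denoms <- strata |>
    count(.data$exposure_group, .data$stratum, name = "denominator") |>
    mutate(exposure_group = as.character(.data$exposure_group))
  out <- grid |>
    left_join(counts, by = c("exposure_group", "stratum", "outcome")) |>
    left_join(denoms, by = c("exposure_group", "stratum")) |>
    mutate(n = coalesce(.data$n, 0L),
           denominator = coalesce(.data$denominator, 0L),
           pct = ifelse(.data$denominator > 0,
                        round(100 * .data$n / .data$denominator, 1), NA_real_),
           outcome = factor(.data$outcome, levels = precedence)) |>
    arrange(.data$stratum, .data$exposure_group, .data$outcome) |>
    select("exposure_group", "stratum", "smq_code", "outcome", "n",
           "denominator", "pct")
  new_tibble(out, class = "faers_outcomes", by = by, precedence = precedence)
}

#' Combined death + life-threatening frequency
#'
#' The share of cases whose outcome is death or life-threatening, per
#' exposure group and stratum, computed as the sum of the two (already
#' rounded) percentages of an outcome profile.
#'
#' @param profile A `faers_outcomes` tibble from [outcome_profile()].
#' @return A tibble with columns `exposure_group`, `stratum`, `smq_code`,
#'   `pct_death_lt`.
#' @examples
#' # 38.4% death + 10.8% life-threatening -> 49.2%
#' @export
combined_death_lt <- function(profile) {
  stopifnot(inherits(profile, "faers_outcomes"))
  as_tibble(profile) |>
    filter(.data$outcome %in% c("death", "life_threatening")) |>
    summarise(pct_death_lt = sum(.data$pct),
              .by = c("exposure_group", "stratum", "smq_code"))
}
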