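#' Keep only the most recent version of each case
#'
#' Spontaneous reports arrive as successive versions of a case: duplicates
#' submitted by different sources and follow-ups with updated information.
#' For each case id, exactly one report version survives — the maximal one
#' under the version key, by default the FDA receipt date with the
#' (lexicographically largest) report id as tiebreak. The operation is
#' idempotent, and an empty input yields an empty output.
#'
#' @param x A `faers_reports` object.
#' @param version_key Character vector of `demo` columns defining a total
#'   order within each case; later elements break ties.
#' @return A deduplicated `faers_reports`; the number of dropped versions is
#'   appended to the `counts` log.
#' @examples
#' sim <- synth_generate(synth_config(seed = 1, n_cases = c(
#'   ICI_alone = 20, AGI_alone = 20, combination = 10, neither = 50)))
#' dedup_reports(sim$reports)
#' @export
dedup_reports <- function(x, version_key = c("fda_date", "report_id")) {
  stopifnot(inherits(x, "faers_reports"))
  if (!all(version_key %in% names(x$demo))) {
    abort("`version_key` must name demographics columns")
  }
  demo <- x$demo |>
    arrange(.data$case_id, across(all_of(version_key), desc)) |>
    distinct(.data$case_id, .keep_all = TRUE)
  dropped <- nrow(x$demo) - nrow(demo)
  keep <- demo$report_id
  out <- new_faers_reports(
    demo,
    x$drugs |> filter(.data$report_id %in% keep),
    x$reactions |> filter(.data$report_id %in% keep),
    x$outcomes |> filter(.data$report_id %in% keep),
    x$indications |> filter(.data$report_id %in% keep),
    c(x$counts, list(dedup = c(`in` = nrow(x$demo), kept = nrow(demo),
                               dropped = dropped)))
  )
  out
}

#' Keep suspect drug mentions only
#'
#' Exposure is classified from drugs the reporter designated as *suspect*;
#' mentions with role *concomitant* or *interacting* are removed. Reports
#' left with no suspect drug cannot be classified and are dropped entirely.
#'
#' @param x A `faers_reports` object (normally already deduplicated).
#' @return A `faers_reports` whose `drugs` table contains suspect mentions
#'   only; drop counts appended to the log.
#' @export
filter_suspect <- function(x) {
  stopifnot(inherits(x, "faers_reports"))
  drugs <- x$drugs |> filter(.data$role == "suspect")
  keep <- unique(drugs$report_id)
  dropped_reports <- sum(!(x$demo$report_id %in% keep))
  out <- new_faers_reports(
    x$demo |> filter(.data$report_id %in% keep),
    drugs,
    x$reactions |> filter(.data$report_id %in% keep),
    x$outcomes |> filter(.data$report_id %in% keep),
    x$indications |> filter(.data$report_id %in% keep),
    c(x$counts, list(suspect_filter = c(
      `in` = nrow(x$demo), kept = nrow(x$demo) - dropped_reports,
      dropped = dropped_reports,
      drug_rows_removed = nrow(x$drugs) - nrow(drugs))))
  )
  out
}

#' Classify exposure groups from suspect drugs
#'
#' Matches each (suspect) drug mention against the drug-name archive after
#' normalisation and resolves every report to one of four exposure groups —
#' a pure function of the suspect drug classes present: ICI only →
#' `ICI_alone`; AGI only → `AGI_alone`; both → `combination`; neither →
#' `neither` (the background comparator). Unmatched drug names are simply
#' non-ICI/non-AGI and leave the classification unchanged.
#'
#' @param x A deduplicated, suspect-filtered `faers_reports`.
#' @param archive Drug-name archive from [read_drug_archive()].
#' @return A `faers_cases` object: list of tibbles `cases` (one row per case
#'   with demographics, `exposure_group`, `has_ici`, `has_agi`, `year`),
#'   `drugs` (with matched `drug_class` / `canonical_name`), `reactions`,
#'   `outcomes`, `indications`, and the `counts` log.
#' @export
classify_exposure <- function(x, archive) {
  stopifnot(inherits(x, "faers_reports"))
  drugs <- x$drugs |>
    mutate(name_norm = normalize_name(.data$drugname)) |>
    left_join(archive |> select("name_norm", "drug_class", "canonical_name"),
              by = "name_norm")
  ici_ids <- unique(drugs$report_id[drugs$drug_class %in% "ICI"])
  agi_ids <- unique(drugs$report_id[drugs$drug_class %in% "AGI"])
  cases <- x$demo |>
    mutate(
      has_ici = .data$report_id %in% ici_ids,
      has_agi = .data$report_id %in% agi_ids,
      exposure_group = factor(
        case_when(.data$has_ici & .data$has_agi ~ "combination",
                  .data$has_ici ~ "ICI_alone",
                  .data$has_agi ~ "AGI_alone",
                  .default = "neither"),
        levels = exposure_levels()),
      year = as.POSIXlt(.data$fda_date)$year + 1900L
    )
  structure(
    list(cases = cases, drugs = drugs, reactions = x$reactions,
         outcomes = x$outcomes, indications = x$indications,
         counts = c(x$counts, list(classified = table(cases$exposure_group)))),
    class = "faers_cases"
  )
}

#' @export
print.faers_cases <- function(x, ...) {
  cat("<faers_cases>", nrow(x$cases), "cases\n")
  print(table(x$cases$exposure_group))
  invisible(x)
}

#' Run the full three-step cleaning
#'
#' Convenience wrapper chaining [dedup_reports()], [filter_suspect()] and
#' [classify_exposure()] in the canonical order.
#'
#' @inheritParams dedup_reports
#' @inheritParams classify_exposure
#' @return A `faers_cases` object.
#' @export
clean_reports <- function(x, archive, version_key = c("fda_date", "report_id")) {
  x |>
    dedup_reports(version_key = version_key) |>
    filter_suspect() |>
    classify_exposure(archive)
}

#' Restrict a cleaned case set to given indications
#'
#' Keeps cases with at least one reported indication matching any of the
#' given terms by case-insensitive substring. Used for the cancer-restricted
#' strata (see [cancer_indication_terms()]).
#'
#' @param x A `faers_cases` object.
#' @param terms Character vector of indication terms.
#' @return A filtered `faers_cases`.
#' @export
restrict_to_indications <- function(x, terms = cancer_indication_terms()) {
  stopifnot(inherits(x, "faers_cases"))
  ind <- normalize_name(x$indications$indication)
  hit <- rep(FALSE, length(ind))
  for (tm in normalize_name(terms)) {
    hit <- hit | str_detect(ind, fixed(tm))
  }
  keep <- unique(x$indications$report_id[hit])
  out <- x
  out$cases <- x$cases |> filter(.data$report_id %in% keep)
  for (tb in c("drugs", "reactions", "outcomes", "indications")) {
    out[[tb]] <- x[[tb]] |> filter(.data$report_id %in% keep)
  }
  out$counts <- c(x$counts, list(indication_restricted = c(
    `in` = nrow(x$cases), kept = nrow(out$cases),
    dropped = nrow(x$cases) - nrow(out$cases))))
  out
}

#' Indication terms for the malignant-tumour stratum
#'
#' The seven cancer indications tabulated per exposure group, as substring
#' match terms.
#'
#' @return Character vector of terms.
#' @export
cancer_indication_terms <- function() {
  c("non-small cell lung", "renal cell", "hepatocellular", "colorectal",
    "endometrial", "breast cancer", "melanoma")
}

#' Build the cardiovascular analysis cohorts
#'
#' Turns a cleaned, classified case set into the unit streams the
#' disproportionality statistics are computed from. The analysis unit is the
#' *report*: a (case, PT) pair, each distinct PT of a case counted once; at
#' SMQ level, additionally a (case, SMQ) pair counted once per case per SMQ,
#' so within-case PT multiplicity inside one SMQ cannot inflate that SMQ's
#' signal. A case is a cardiovascular AE case iff at least one of its PTs
#' maps into any of the nine SMQ categories, and its cardiovascular report
#' count is its number of distinct cardiovascular PTs — so report counts are
#' at least case counts per group, with equality iff every cardiovascular
#' case carries exactly one cardiovascular PT.
#'
#' @param x A `faers_cases` object from [classify_exposure()] /
#'   [clean_reports()].
#' @param smq_map SMQ membership map from [read_smq_map()].
#' @return A `faers_cohort` object: tibbles `cases` (with `is_cv_case`,
#'   `n_cv_reports`), `pt_units` ((case, PT) pairs with `is_cv` and group),
#'   `smq_units` ((case, SMQ) pairs with group), `outcomes`, `indications`,
#'   a per-group `counts` summary, and the `smq_map` used.
#' @examples
#' sim <- synth_generate(synth_config(seed = 7, n_cases = c(
#'   ICI_alone = 50, AGI_alone = 50, combination = 20, neither = 200)))
#' archive <- read_drug_archive(faersignal_example("drug_archive.tsv"))
#' smq <- read_smq_map(faersignal_example("smq_map_synthetic.tsv"))
#' cohort <- sim$reports |> clean_reports(archive) |> build_cohorts(smq)
#' cohort$counts
#' @export
build_cohorts <- function(x, smq_map) {
  stopifnot(inherits(x, "faers_cases"))
  lut <- smq_map |> distinct(.data$pt_norm, .data$smq_code, .data$smq_name)
  key <- x$cases |> select("report_id", "case_id", "exposure_group")
  pt_units <- x$reactions |>
    mutate(pt_norm = normalize_name(.data$pt)) |>
    inner_join(key, by = "report_id") |>
    distinct(.data$case_id, .data$pt_norm, .keep_all = TRUE) |>
    mutate(is_cv = .data$pt_norm %in% lut$pt_norm) |>
    select("case_id", "exposure_group", "pt", "pt_norm", "is_cv")
  smq_units <- pt_units |>
    inner_join(lut, by = "pt_norm", relationship = "many-to-many") |>
    distinct(.data$case_id, .data$smq_code, .keep_all = TRUE) |>
    select("case_id", "exposure_group", "smq_code", "smq_name")
  case_cv <- pt_units |>
    filter(.data$is_cv) |>
    count(.data$case_id, name = "n_cv_reports")
  cases <- x$cases |>
    left_join(case_cv, by = "case_id") |>
    mutate(n_cv_reports = coalesce(.data$n_cv_reports, 0L),
           is_cv_case = .data$n_cv_reports > 0)
  counts <- cases |>
    summarise(n_cases = n(), n_cv_cases = sum(.data$is_cv_case),
              n_cv_reports = sum(.data$n_cv_reports),
              .by = "exposure_group") |>
    arrange(.data$exposure_group)
  structure(
    list(cases = cases, pt_units = pt_units, smq_units = smq_units,
         outcomes = x$outcomes, indications = x$indications,
         counts = counts, smq_map = smq_map, log = x$counts),
    class = "faers_cohort"
  )
}

#' @export
print.faers_cohort <- function(x, ...) {
  cat("<faers_cohort>\n")
  print(x$counts)
  invisible(x)
}

# age bands used in the cohort summary
age_band <- function(age) {
  case_when(is.na(age) ~ "Unknown",
            age < 18 ~ "< 18 years",
            age < 65 ~ "18-65 years",
            .default = ">= 65 years")
}

#' Summarise cohort characteristics by exposure group
#'
#' Baseline tabulation of the cardiovascular cases per exposure group: age
#' bands, sex, reporter type, outcome categories (one per case by severity
#' precedence), the seven cancer indications, country and receipt year.
#' Age-band percentages use cases with known age as denominator (the unknown
#' row uses the group total), all other percentages the group total.
#'
#' @param cohort A `faers_cohort`.
#' @param groups Exposure groups to tabulate (default: the three treated
#'   groups).
#' @return A tibble with columns `section`, `category`, `exposure_group`,
#'   `n`, `pct` (1 decimal place).
#' @export
cohort_summary <- function(cohort,
                           groups = c("ICI_alone", "AGI_alone", "combination")) {
  stopifnot(inherits(cohort, "faers_cohort"))
  cc <- cohort$cases |>
    filter(.data$is_cv_case, .data$exposure_group %in% groups) |>
    mutate(exposure_group = factor(.data$exposure_group, levels = groups))
  totals <- cc |> count(.data$exposure_group, name = "n_total")
  tab <- function(section, var_values, denom = NULL) {
    d <- cc |>
      mutate(category = var_values) |>
      count(.data$exposure_group, .data$category) |>
      left_join(totals, by = "exposure_group")
    if (!is.null(denom)) d <- d |> mutate(n_total = denom[as.character(.data$exposure_group)])
    d |>
      mutate(section = section,
             pct = round(100 * .data$n / .data$n_total, 1)) |>
      select("section", "category", "exposure_group", "n", "pct")
  }
  n_avail <- cc |> filter(!is.na(.data$age_years)) |> count(.data$exposure_group)
  avail <- setNames(n_avail$n, as.character(n_avail$exposure_group))
  bands <- age_band(cc$age_years)
  age_rows <- bind_rows(
    tab("age_group", bands) |> filter(.data$category != "Unknown") |>
      mutate(pct = round(100 * .data$n / avail[as.character(.data$exposure_group)], 1)),
    tab("age_group", bands) |> filter(.data$category == "Unknown")
  )
  prim <- primary_outcome_by_case(cohort)
  outc_rows <- tab("outcome", prim[cc$case_id])
  ind <- cohort$indications |>
    inner_join(cc |> select("report_id", "exposure_group"), by = "report_id") |>
    mutate(indication_norm = normalize_name(.data$indication))
  ind_rows <- purrr::map(cancer_indication_terms(), function(tm) {
    ind |>
      filter(str_detect(.data$indication_norm, fixed(normalize_name(tm)))) |>
      distinct(.data$report_id, .data$exposure_group) |>
      count(.data$exposure_group) |>
      left_join(totals, by = "exposure_group") |>
      mutate(section = "indication", category = tm,
             pct = round(100 * .data$n / .data$n_total, 1)) |>
      select("section", "category", "exposure_group", "n", "pct")
  }) |> list_rbind()
  bind_rows(
    age_rows,
    tab("sex", cc$sex),
    tab("reporter", cc$reporter_type),
    outc_rows,
    ind_rows,
    tab("country", cc$country),
    tab("year", as.character(cc$year))
  ) |> arrange(.data$section, .data$category, .data$exposure_group)
}
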