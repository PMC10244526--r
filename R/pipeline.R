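#' Configure a full pipeline run
#'
#' Bundles every input and option of [run_faers()]: the input file set, its
#' dialect, the two auxiliary dictionaries, comparator and counting-unit
#' modes, the indication terms for the cancer-restricted stratum, the output
#' directory and the display precision. All referenced paths must exist at
#' validation time.
#'
#' @param input Directory with the FAERS-dialect file set (or a named vector
#'   of five file paths, see [read_faers()]).
#' @param archive Path to the drug-name archive TSV.
#' @param smq_map Path to the PT-to-SMQ membership TSV.
#' @param out_dir Output directory for the result bundle.
#' @param dialect A [faers_dialect()].
#' @param comparator,counting,min_reports As in [disproportionality()].
#' @param indication_terms Terms for [restrict_to_indications()].
#' @param version_key Version ordering for [dedup_reports()].
#' @param digits Display precision for statistics written to TSV.
#' @return A `faers_run_config` object.
#' @export
faers_run_config <- function(input, archive, smq_map, out_dir,
                             dialect = faers_dialect(),
                             comparator = c("neither", "other_reports"),
                             counting = c("per_smq_once", "per_pt"),
                             min_reports = 3,
                             indication_terms = cancer_indication_terms(),
                             version_key = c("fda_date", "report_id"),
                             digits = 3) {
  comparator <- arg_match(comparator)
  counting <- arg_match(counting)
  for (p in c(if (length(input) == 1 && is.null(names(input))) input else unname(input),
              archive, smq_map)) {
    if (!file.exists(p)) abort(paste0("input path does not exist: ", p))
  }
  structure(
    list(input = input, archive = archive, smq_map = smq_map,
         out_dir = out_dir, dialect = dialect, comparator = comparator,
         counting = counting, min_reports = min_reports,
         indication_terms = indication_terms, version_key = version_key,
         digits = digits),
    class = "faers_run_config"
  )
}

round_stats <- function(df, digits) {
  df |> mutate(across(where(is.double), \(v) round(v, digits)))
}

#' Run the full analysis end-to-end
#'
#' Orchestrates ingestion, three-step cleaning, cohort construction,
#' overall / per-SMQ / per-PT disproportionality, outcome profiling, and
#' the indication-restricted analysis, and writes the result bundle:
#'
#' * `cohort_summary.tsv` — baseline tabulation per exposure group;
#' * `disprop_overall.tsv`, `disprop_smq.tsv`, `disprop_pt.tsv` —
#'   forest-ready disproportionality tables with both signal criteria;
#' * `outcomes.tsv` — outcome severity profiles, overall and per SMQ;
#' * `disprop_indication.tsv` — overall + per-SMQ analysis restricted to
#'   the cancer indications;
#' * `manifest.json` — package version, configuration hash, stage-by-stage
#'   record counts (in = kept + dropped at every cleaning stage).
#'
#' A rerun with the same configuration produces identical outputs (there is
#' no hidden randomness). Any stage failure aborts with the stage name and
#' removes partial outputs (everything is staged to a temporary directory
#' and only moved into `out_dir` on success).
#'
#' @param config A [faers_run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `disprop`, `outcomes`, `indication`, `manifest`, `paths`).
#' @export
run_faers <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "faers_run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  say <- function(...) if (!quiet) inform(paste0(...))

  say("ingest")
  archive <- stage("read_archive", read_drug_archive(config$archive))
  smq_map <- stage("read_smq_map", read_smq_map(config$smq_map))
  reports <- stage("read_reports",
                   read_faers(config$input, config$dialect, quiet = quiet))
  say("clean")
  deduped <- stage("deduplicate", dedup_reports(reports, config$version_key))
  suspects <- stage("suspect_filter", filter_suspect(deduped))
  cases <- stage("classify_exposure", classify_exposure(suspects, archive))
  say("cohorts")
  cohort <- stage("build_cohorts", build_cohorts(cases, smq_map))
  say("disproportionality")
  dis <- list(
    overall = stage("disprop_overall", disproportionality(
      cohort, "overall", config$comparator, config$counting,
      min_reports = config$min_reports)),
    smq = stage("disprop_smq", disproportionality(
      cohort, "smq", config$comparator, config$counting,
      min_reports = config$min_reports)),
    pt = stage("disprop_pt", disproportionality(
      cohort, "pt", config$comparator, config$counting,
      min_reports = config$min_reports))
  )
  say("outcomes")
  outc <- stage("outcomes", bind_rows(
    as_tibble(outcome_profile(cohort, "overall")),
    as_tibble(outcome_profile(cohort, "smq"))
  ))
  say("indication-restricted")
  ind_cases <- stage("indication_restrict",
                     restrict_to_indications(cases, config$indication_terms))
  ind_cohort <- stage("indication_cohorts", build_cohorts(ind_cases, smq_map))
  ind <- stage("disprop_indication", bind_rows(
    as_tibble(disproportionality(ind_cohort, "overall", config$comparator,
                                 config$counting, min_reports = config$min_reports)),
    as_tibble(disproportionality(ind_cohort, "smq", config$comparator,
                                 config$counting, min_reports = config$min_reports))
  ))
  summary_tab <- stage("cohort_summary", cohort_summary(cohort))

  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  manifest <- list(
    package = "faersignal",
    version = as.character(packageVersion("faersignal")),
    config_hash = hash(cfg_for_hash),
    comparator = config$comparator, counting = config$counting,
    min_reports = config$min_reports,
    stages = list(
      reports_in = reports$counts$reports_in,
      dedup = as.list(deduped$counts$dedup),
      suspect_filter = as.list(suspects$counts$suspect_filter[1:3]),
      exposure_groups = as.list(cases$counts$classified),
      cohort = cohort$counts,
      indication_restricted = as.list(ind_cases$counts$indication_restricted)
    )
  )

  staging <- tempfile("faersignal-run-")
  dir.create(staging)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  d <- config$digits
  write_tsv(summary_tab, file.path(staging, "cohort_summary.tsv"))
  write_tsv(round_stats(as_tibble(dis$overall), d),
            file.path(staging, "disprop_overall.tsv"))
  write_tsv(round_stats(as_tibble(dis$smq), d),
            file.path(staging, "disprop_smq.tsv"))
  write_tsv(round_stats(as_tibble(dis$pt), d),
            file.path(staging, "disprop_pt.tsv"))
  write_tsv(outc, file.path(staging, "outcomes.tsv"))
  write_tsv(round_stats(ind, d), file.path(staging, "disprop_indication.tsv"))
  jsonlite::write_json(manifest, file.path(staging, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- dir(staging)
  ok <- file.copy(file.path(staging, artifacts), config$out_dir,
                  overwrite = TRUE)
  if (!all(ok)) abort("failed to move outputs into out_dir")
  say("wrote ", length(artifacts), " artifacts to ", config$out_dir)
  invisible(list(cohort = cohort, disprop = dis, outcomes = outc,
                 indication = ind, manifest = manifest,
                 paths = file.path(config$out_dir, artifacts)))
}
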