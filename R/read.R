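new_faers_reports <- function(demo, drugs, reactions, outcomes, indications,
                              counts = list()) {
  structure(
    list(demo = demo, drugs = drugs, reactions = reactions,
         outcomes = outcomes, indications = indications, counts = counts),
    class = "faers_reports"
  )
}

#' @export
print.faers_reports <- function(x, ...) {
  cat("<faers_reports>", nrow(x$demo), "report versions,",
      n_distinct(x$demo$case_id), "cases\n")
  cat("  drug mentions:", nrow(x$drugs),
      " reactions:", nrow(x$reactions),
      " outcomes:", nrow(x$outcomes),
      " indications:", nrow(x$indications), "\n")
  invisible(x)
}

read_one_table <- function(path, dialect, table) {
  if (!file.exists(path)) abort(paste0("input file does not exist: ", path))
  dat <- tryCatch(
    read_delim(path, delim = dialect$delim, col_types = cols(.default = col_character()),
               trim_ws = FALSE, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(paste0("malformed ", table, " table '", path, "': ",
                                     conditionMessage(e)))
  )
  want <- dialect$columns[[table]]
  missing_cols <- setdiff(want, names(dat))
  if (length(missing_cols) > 0) {
    abort(paste0("malformed ", table, " table '", path, "': missing column(s) ",
                 paste(missing_cols, collapse = ", ")))
  }
  dat[want]
}

recode_or <- function(x, codes, default) {
  out <- unname(codes[x])
  out[is.na(out)] <- default
  out
}

#' Read a FAERS-style quarterly extract into a report stream
#'
#' Reads the five delimited tables of a FAERS-style extract (demographics,
#' drugs, reactions, outcomes, indications), validates them, and joins the
#' child tables to the demographics table by the version-specific report id.
#' Child rows whose report id has no demographics row fail the join and are
#' dropped with a message; the in/kept/dropped counts per table are retained
#' in the returned object. One `RawReport` corresponds to one demographics
#' row; a report may legitimately have no reaction rows at this stage (such
#' reports simply contribute nothing downstream).
#'
#' Duplicate report ids within the demographics table are a format error —
#' the report id is the version key, so it must be unique within a batch.
#' Deduplication of *cases* (several report versions sharing a case id) is a
#' separate, later stage: see [dedup_reports()].
#'
#' @param path Directory containing the five files named by the dialect, or a
#'   named character vector of file paths (names `demo`, `drug`, `reac`,
#'   `outc`, `indi`).
#' @param dialect A [faers_dialect()] describing delimiter, file and column
#'   names, and code books.
#' @param quiet Suppress the per-table record-count messages.
#' @return A `faers_reports` object: a list of five tibbles (`demo`, `drugs`,
#'   `reactions`, `outcomes`, `indications`) in the package's internal
#'   vocabulary, plus a `counts` log.
#' @seealso [write_faers()] for the inverse, [clean_reports()] for the
#'   cleaning stages.
#' @export
read_faers <- function(path, dialect = faers_dialect(), quiet = FALSE) {
  tables <- c("demo", "drug", "reac", "outc", "indi")
  if (length(path) == 1L && is.null(names(path))) {
    paths <- setNames(file.path(path, dialect$files[tables]), tables)
  } else {
    if (!setequal(names(path), tables)) {
      abort("`path` must be a directory or a vector named demo, drug, reac, outc, indi")
    }
    paths <- path[tables]
  }
  raw <- lapply(tables, function(tb) read_one_table(paths[[tb]], dialect, tb))
  names(raw) <- tables

  dcols <- dialect$columns$demo
  demo_raw <- raw$demo
  if (anyDuplicated(demo_raw[[dcols[1]]])) {
    dup <- demo_raw[[dcols[1]]][duplicated(demo_raw[[dcols[1]]])][1]
    abort(paste0("duplicate report id '", dup, "' in demographics table '",
                 paths[["demo"]], "'"))
  }
  age <- suppressWarnings(as.numeric(demo_raw[[dcols[4]]]))
  age[!is.na(age) & age < 0] <- NA_real_
  country <- str_squish(demo_raw[[dcols[7]]])
  country[is.na(country) | country == ""] <- "unknown"
  demo <- tibble(
    report_id = demo_raw[[dcols[1]]],
    case_id = demo_raw[[dcols[2]]],
    fda_date = as.Date(demo_raw[[dcols[3]]], format = dialect$date_format),
    age_years = age,
    sex = recode_or(demo_raw[[dcols[5]]], dialect$sex_codes, "unknown"),
    reporter_type = recode_or(demo_raw[[dcols[6]]], dialect$reporter_codes, "unknown"),
    country = country
  )
  if (anyNA(demo$fda_date)) {
    abort(paste0("unparseable receipt date in demographics table '",
                 paths[["demo"]], "' (expected format ", dialect$date_format, ")"))
  }

  gcols <- dialect$columns$drug
  role <- unname(dialect$role_codes[raw$drug[[gcols[3]]]])
  if (anyNA(role)) {
    bad <- raw$drug[[gcols[3]]][is.na(role)][1]
    abort(paste0("unknown drug role code '", bad, "' in drug table '",
                 paths[["drug"]], "'"))
  }
  drugs <- tibble(report_id = raw$drug[[gcols[1]]],
                  drugname = raw$drug[[gcols[2]]], role = role)

  rcols <- dialect$columns$reac
  reactions <- tibble(report_id = raw$reac[[rcols[1]]], pt = raw$reac[[rcols[2]]])

  ocols <- dialect$columns$outc
  outcome <- unname(dialect$outcome_codes[raw$outc[[ocols[2]]]])
  if (anyNA(outcome) && nrow(raw$outc) > 0) {
    warn(paste0("dropping ", sum(is.na(outcome)),
                " outcome row(s) with unmapped codes in '", paths[["outc"]], "'"))
  }
  outcomes <- tibble(report_id = raw$outc[[ocols[1]]], outcome = outcome) |>
    filter(!is.na(.data$outcome))

  icols <- dialect$columns$indi
  indications <- tibble(report_id = raw$indi[[icols[1]]],
                        indication = raw$indi[[icols[2]]])

  # child rows that fail the join against demographics are dropped, counted
  keep_child <- function(tb, label) {
    orphan <- !(tb$report_id %in% demo$report_id)
    list(kept = tb[!orphan, ], dropped = sum(orphan), label = label)
  }
  kd <- keep_child(drugs, "drug"); ke <- keep_child(reactions, "reaction")
  ko <- keep_child(outcomes, "outcome"); ki <- keep_child(indications, "indication")
  counts <- list(
    reports_in = nrow(demo),
    drug_rows = c(`in` = nrow(drugs), kept = nrow(kd$kept), dropped = kd$dropped),
    reaction_rows = c(`in` = nrow(reactions), kept = nrow(ke$kept), dropped = ke$dropped),
    outcome_rows = c(`in` = nrow(outcomes), kept = nrow(ko$kept), dropped = ko$dropped),
    indication_rows = c(`in` = nrow(indications), kept = nrow(ki$kept), dropped = ki$dropped)
  )
  if (!quiet) {
    inform(paste0("read_faers: ", nrow(demo), " report versions; orphan child rows dropped: ",
                  kd$dropped + ke$dropped + ko$dropped + ki$dropped))
  }
  new_faers_reports(demo, kd$kept, ke$kept, ko$kept, ki$kept, counts)
}

#' Write a report stream back to FAERS-dialect files
#'
#' Inverse of [read_faers()]: serialises a `faers_reports` object to the five
#' delimited tables described by the dialect. Internal categories are mapped
#' back through the dialect's code books (first matching code wins;
#' `unknown` values become empty fields, which read back as `unknown`).
#' Used by the synthetic generator and for round-trip testing.
#'
#' @param x A `faers_reports` object.
#' @param dir Output directory (created if needed).
#' @inheritParams read_faers
#' @return `dir`, invisibly.
#' @export
write_faers <- function(x, dir, dialect = faers_dialect()) {
  stopifnot(inherits(x, "faers_reports"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  inv_role <- invert_codes(dialect$role_codes)
  inv_outc <- invert_codes(dialect$outcome_codes)
  inv_rept <- invert_codes(dialect$reporter_codes)
  inv_sex <- invert_codes(dialect$sex_codes)
  blank_unknown <- function(v) ifelse(is.na(v) | v == "unknown", "", v)

  demo <- tibble(
    !!dialect$columns$demo[1] := x$demo$report_id,
    !!dialect$columns$demo[2] := x$demo$case_id,
    !!dialect$columns$demo[3] := format(x$demo$fda_date, dialect$date_format),
    !!dialect$columns$demo[4] := ifelse(is.na(x$demo$age_years), "",
                                        format(x$demo$age_years, trim = TRUE)),
    !!dialect$columns$demo[5] := blank_unknown(unname(inv_sex[x$demo$sex])),
    !!dialect$columns$demo[6] := blank_unknown(unname(inv_rept[x$demo$reporter_type])),
    !!dialect$columns$demo[7] := blank_unknown(x$demo$country)
  )
  drug <- tibble(
    !!dialect$columns$drug[1] := x$drugs$report_id,
    !!dialect$columns$drug[2] := x$drugs$drugname,
    !!dialect$columns$drug[3] := unname(inv_role[x$drugs$role])
  )
  reac <- tibble(!!dialect$columns$reac[1] := x$reactions$report_id,
                 !!dialect$columns$reac[2] := x$reactions$pt)
  outc <- tibble(!!dialect$columns$outc[1] := x$outcomes$report_id,
                 !!dialect$columns$outc[2] := unname(inv_outc[x$outcomes$outcome]))
  indi <- tibble(!!dialect$columns$indi[1] := x$indications$report_id,
                 !!dialect$columns$indi[2] := x$indications$indication)
  out <- list(demo = demo, drug = drug, reac = reac, outc = outc, indi = indi)
  for (tb in names(out)) {
    write_delim(out[[tb]], file.path(dir, dialect$files[[tb]]),
                delim = dialect$delim, na = "")
  }
  invisible(dir)
}

#' Read the drug-name archive
#'
#' The archive maps every known name variant of the study drugs — generic
#' names, brand names, research codes, and curated misspelling aliases — to a
#' drug class (`ICI` or `AGI`) and a canonical generic name. Name variants
#' are normalised with [normalize_name()]; a normalised variant mapped to
#' conflicting classes or canonical names is a data error.
#'
#' @param path TSV file with columns `name_variant`, `drug_class`,
#'   `canonical_name`.
#' @return A tibble with columns `name_variant`, `name_norm`, `drug_class`,
#'   `canonical_name`.
#' @examples
#' archive <- read_drug_archive(faersignal_example("drug_archive.tsv"))
#' table(archive$drug_class)
#' @export
read_drug_archive <- function(path) {
  dat <- read_tsv(path, col_types = cols(.default = col_character()),
                  show_col_types = FALSE, progress = FALSE)
  need <- c("name_variant", "drug_class", "canonical_name")
  if (!all(need %in% names(dat))) {
    abort(paste0("drug archive '", path, "' must have columns ",
                 paste(need, collapse = ", ")))
  }
  bad_class <- setdiff(unique(dat$drug_class), c("ICI", "AGI"))
  if (length(bad_class) > 0) {
    abort(paste0("unknown drug_class value(s) in '", path, "': ",
                 paste(bad_class, collapse = ", ")))
  }
  out <- dat |>
    mutate(name_norm = normalize_name(.data$name_variant),
           canonical_name = normalize_name(.data$canonical_name)) |>
    distinct(.data$name_norm, .data$drug_class, .data$canonical_name,
             .keep_all = TRUE) |>
    select("name_variant", "name_norm", "drug_class", "canonical_name")
  conflicts <- out |>
    summarise(n = n_distinct(paste(.data$drug_class, .data$canonical_name)),
              .by = "name_norm") |>
    filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    abort(paste0("conflicting archive entries for name variant(s): ",
                 paste(head(conflicts$name_norm, 5), collapse = ", ")))
  }
  out
}

#' Validate a PT-to-SMQ membership table
#'
#' Checks and canonicalises a preferred-term to SMQ membership table against
#' the nine narrow cardiovascular SMQ categories of [cv_smq_catalog()]. Only
#' narrow-scope rows are retained (narrow members are the high-specificity
#' terms; broad members are screening terms and are out of scope here); rows
#' carrying an SMQ code outside the nine-category universe are skipped with a
#' warning, and a warning lists any of the nine codes with no members.
#'
#' @param dat Data frame with columns `pt`, `smq_code`, `smq_name`, `scope`.
#' @return A tibble with columns `pt`, `pt_norm`, `smq_code` (integer),
#'   `smq_name` (canonical catalogue name), `scope`.
#' @export
as_smq_map <- function(dat) {
  need <- c("pt", "smq_code", "smq_name", "scope")
  if (!all(need %in% names(dat))) {
    abort(paste0("SMQ map must have columns ", paste(need, collapse = ", ")))
  }
  dat <- as_tibble(dat) |> mutate(smq_code = as.integer(.data$smq_code))
  non_narrow <- dat |> filter(tolower(.data$scope) != "narrow")
  if (nrow(non_narrow) > 0) {
    warn(paste0("skipping ", nrow(non_narrow), " non-narrow SMQ map row(s)"))
  }
  catalog <- cv_smq_catalog()
  dat <- dat |> filter(tolower(.data$scope) == "narrow")
  unknown <- dat |> filter(!.data$smq_code %in% catalog$smq_code)
  if (nrow(unknown) > 0) {
    warn(paste0("skipping ", nrow(unknown), " row(s) with SMQ code(s) outside ",
                "the nine cardiovascular categories: ",
                paste(unique(unknown$smq_code), collapse = ", ")))
  }
  out <- dat |>
    filter(.data$smq_code %in% catalog$smq_code) |>
    mutate(pt_norm = normalize_name(.data$pt)) |>
    select(-"smq_name") |>
    left_join(catalog, by = "smq_code") |>
    distinct(.data$pt_norm, .data$smq_code, .keep_all = TRUE) |>
    select("pt", "pt_norm", "smq_code", "smq_name", "scope")
  absent <- setdiff(catalog$smq_code, out$smq_code)
  if (length(absent) > 0) {
    warn(paste0("SMQ map has no members for ", length(absent), " SMQ(s): ",
                paste(absent, collapse = ", ")))
  }
  out
}

#' Read a PT-to-SMQ membership table from TSV
#'
#' @param path TSV file with columns `pt`, `smq_code`, `smq_name`, `scope`.
#' @return See [as_smq_map()].
#' @examples
#' smq <- read_smq_map(faersignal_example("smq_map_synthetic.tsv"))
#' dplyr::count(smq, smq_name)
#' @export
read_smq_map <- function(path) {
  dat <- read_tsv(path, col_types = cols(.default = col_character()),
                  show_col_types = FALSE, progress = FALSE)
  if (nrow(dat) == 0 && !all(c("pt", "smq_code", "smq_name", "scope") %in% names(dat))) {
    dat <- tibble(pt = character(), smq_code = character(),
                  smq_name = character(), scope = character())
  }
  as_smq_map(dat)
}
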