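#' Describe the on-disk layout of a FAERS-style quarterly extract
#'
#' FAERS quarterly ASCII extracts ship one `$`-delimited table per record
#' kind: demographics, drugs, reactions, outcomes and indications, joined by a
#' version-specific report identifier. The dialect object captures everything
#' the readers need to know about such a file set — the delimiter, the file
#' name for each table, the column names carrying each field, and the code
#' books translating FAERS role / outcome / reporter / sex codes into the
#' package's internal vocabulary. A TSV layout is obtained by setting
#' `delim = "\t"`.
#'
#' @param delim Single-character field delimiter (default `"$"`, the FAERS
#'   ASCII convention).
#' @param files Named character vector giving the file name of each table
#'   within the input directory; names must be `demo`, `drug`, `reac`,
#'   `outc`, `indi`.
#' @param columns Named list mapping each table to the column names used in
#'   the files, in internal order (see Details).
#' @param date_format `strptime` format of the FDA receipt date column.
#' @param role_codes Named character vector mapping drug-role codes to the
#'   three FAERS roles `suspect`, `concomitant`, `interacting`.
#' @param outcome_codes Named character vector mapping outcome codes to the
#'   internal outcome categories.
#' @param reporter_codes Named character vector mapping reporter occupation
#'   codes to `health_professional` / `non_health_professional`.
#' @param sex_codes Named character vector mapping sex codes to
#'   `male` / `female`.
#'
#' @details Internal column order per table:
#' * `demo`: report id, case id, receipt date, age (years), sex, reporter
#'   occupation, country;
#' * `drug`: report id, drug name, role code;
#' * `reac`: report id, preferred term;
#' * `outc`: report id, outcome code;
#' * `indi`: report id, indication text.
#'
#' Unmapped reporter, sex or country values are read as `"unknown"`; an
#' unmapped drug-role code is a format error (every drug mention must carry
#' one of the three FAERS roles).
#'
#' @return An object of class `faers_dialect`.
#' @examples
#' faers_dialect()
#' faers_dialect(delim = "\t", files = c(
#'   demo = "demo.tsv", drug = "drug.tsv", reac = "reac.tsv",
#'   outc = "outc.tsv", indi = "indi.tsv"
#' ))
#' @export
faers_dialect <- function(delim = "$",
                          files = c(demo = "DEMO.txt", drug = "DRUG.txt",
                                    reac = "REAC.txt", outc = "OUTC.txt",
                                    indi = "INDI.txt"),
                          columns = list(
                            demo = c("primaryid", "caseid", "fda_dt", "age",
                                     "sex", "occp_cod", "occr_country"),
                            drug = c("primaryid", "drugname", "role_cod"),
                            reac = c("primaryid", "pt"),
                            outc = c("primaryid", "outc_cod"),
                            indi = c("primaryid", "indi_pt")
                          ),
                          date_format = "%Y%m%d",
                          role_codes = c(PS = "suspect", SS = "suspect",
                                         C = "concomitant", I = "interacting"),
                          outcome_codes = c(DE = "death",
                                            LT = "life_threatening",
                                            HO = "hospitalization",
                                            DS = "disability",
                                            CA = "congenital_anomaly",
                                            OT = "other_serious"),
                          reporter_codes = c(MD = "health_professional",
                                             PH = "health_professional",
                                             HP = "health_professional",
                                             CN = "non_health_professional",
                                             LW = "non_health_professional"),
                          sex_codes = c(M = "male", F = "female")) {
  if (!is_string(delim) || nchar(delim) != 1L) {
    abort("`delim` must be a single character")
  }
  tables <- c("demo", "drug", "reac", "outc", "indi")
  if (!setequal(names(files), tables)) {
    abort("`files` must be named demo, drug, reac, outc, indi")
  }
  if (!setequal(names(columns), tables)) {
    abort("`columns` must be named demo, drug, reac, outc, indi")
  }
  n_cols <- c(demo = 7L, drug = 3L, reac = 2L, outc = 2L, indi = 2L)
  for (tb in tables) {
    if (length(columns[[tb]]) != n_cols[[tb]]) {
      abort(paste0("`columns$", tb, "` must have ", n_cols[[tb]], " names"))
    }
  }
  if (!all(role_codes %in% c("suspect", "concomitant", "interacting"))) {
    abort("`role_codes` values must be suspect/concomitant/interacting")
  }
  if (!all(outcome_codes %in% setdiff(outcome_levels(), "unknown"))) {
    abort("`outcome_codes` values must be outcome categories")
  }
  structure(
    list(delim = delim, files = files[tables], columns = columns[tables],
         date_format = date_format, role_codes = role_codes,
         outcome_codes = outcome_codes, reporter_codes = reporter_codes,
         sex_codes = sex_codes),
    class = "faers_dialect"
  )
}

#' @export
print.faers_dialect <- function(x, ...) {
  cat("<faers_dialect>  delim:", encodeString(x$delim, quote = "'"), "\n")
  cat("  files:", paste(names(x$files), x$files, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# first code mapping to each internal value, used when writing files back out
invert_codes <- function(codes) {
  codes[!duplicated(codes)] |> (\(u) setNames(names(u), u))()
}
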