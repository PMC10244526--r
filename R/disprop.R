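check_cells <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0, na.rm = TRUE)) abort("contingency cells must be non-negative")
  n_total <- a + b + c + d
  if (any(n_total == 0)) abort("undefined input: contingency table with N_total = 0")
  invisible(n_total)
}

#' Expected report count of a 2x2 contingency table
#'
#' For a (drug, event) contingency table with cells `a` (target drug, target
#' event), `b` (target drug, other events), `c` (other drugs, target event)
#' and `d` (other drugs, other events), the expected count under independent
#' reporting is `N_expected = N_drug * N_event / N_total` with
#' `N_drug = a + b`, `N_event = a + c`, `N_total = a + b + c + d`.
#' Vectorised over cells.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @return Numeric vector of expected counts.
#' @export
expected_count <- function(a, b, c, d) {
  n_total <- check_cells(a, b, c, d)
  (a + b) * (a + c) / n_total
}

#' Shrinkage-transformed reporting odds ratio
#'
#' The observed-to-expected reporting ratio with a +0.5 shrinkage on both
#' counts: `ROR = (N_observed + 0.5) / (N_expected + 0.5)`. The shrinkage
#' keeps the estimate defined for empty cells and pulls small-count
#' estimates towards the null value 1.
#'
#' @inheritParams expected_count
#' @return Positive numeric vector.
#' @examples
#' shrunk_ror(10, 90, 100, 9900)
#' shrunk_ror(0, 0, 0, 100)  # empty margins shrink to exactly 1
#' @export
shrunk_ror <- function(a, b, c, d) {
  (a + 0.5) / (expected_count(a, b, c, d) + 0.5)
}

#' Information component
#'
#' `IC = log2[(N_observed + 0.5) / (N_expected + 0.5)]`, in bits. Shares the
#' shrunk observed/expected core with [shrunk_ror()], so
#' `IC = log2(shrunk ROR)` identically.
#'
#' @inheritParams expected_count
#' @return Numeric vector (bits).
#' @export
info_component <- function(a, b, c, d) {
  log2(shrunk_ror(a, b, c, d))
}

#' 95% credibility interval of the information component
#'
#' Closed-form shrinkage approximation of the IC posterior interval, driven
#' only by the IC value and the observed count:
#' \deqn{IC_{025} = IC - 3.3 (a+0.5)^{-1/2} - 2 (a+0.5)^{-3/2}}
#' \deqn{IC_{975} = IC + 2.4 (a+0.5)^{-1/2} - 0.5 (a+0.5)^{-3/2}}
#' The interval is asymmetric around IC and its width shrinks to zero as the
#' observed count grows. Vectorised.
#'
#' @param ic Information component values (bits).
#' @param n_observed Observed report counts (the `a` cell), `>= 0`.
#' @return A tibble with columns `ic_025` and `ic_975`.
#' @examples
#' ic_credible_interval(0.605, 5263)
#' @export
ic_credible_interval <- function(ic, n_observed) {
  if (any(n_observed < 0)) abort("`n_observed` must be non-negative")
  s <- (n_observed + 0.5)^(-0.5)
  s3 <- (n_observed + 0.5)^(-1.5)
  tibble(ic_025 = ic - 3.3 * s - 2 * s3,
         ic_975 = ic + 2.4 * s - 0.5 * s3)
}

#' Wald 95% confidence interval for the ROR
#'
#' The classic odds-ratio Wald interval
#' `exp(ln(ROR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`, applied around the
#' supplied point estimate (by default the shrunk estimate). With any zero
#' cell the standard error is undefined and both bounds are returned as `NA`
#' while the point estimate remains defined through the shrinkage.
#'
#' @inheritParams expected_count
#' @param ror Point estimate(s) to centre the interval on.
#' @return A tibble with columns `ror_025` and `ror_975`.
#' @examples
#' ror_wald_ci(10, 10, 10, 10)
#' @export
ror_wald_ci <- function(a, b, c, d, ror = shrunk_ror(a, b, c, d)) {
  check_cells(a, b, c, d)
  se <- ifelse(a > 0 & b > 0 & c > 0 & d > 0,
               sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  tibble(ror_025 = ror * exp(-1.96 * se),
         ror_975 = ror * exp(1.96 * se))
}

#' Apply the signal rule
#'
#' A (drug, event) combination is flagged when the lower 95% bound exceeds
#' the null with at least `min_reports` observed reports:
#' `signal_by_ror = ror_025 > 1`, `signal_by_ic = ic_025 > 0`, each
#' additionally requiring `n_reports >= min_reports` (default 3).
#' Inequalities are strict; undefined (`NA`) bounds never flag.
#'
#' @param n_reports Observed report counts (the `a` cell).
#' @param ror_025,ic_025 Lower interval bounds.
#' @param min_reports Minimum report count for a signal.
#' @return A tibble with logical columns `signal_by_ror`, `signal_by_ic`.
#' @export
signal_flags <- function(n_reports, ror_025, ic_025, min_reports = 3) {
  tibble(
    signal_by_ror = !is.na(ror_025) & ror_025 > 1 & n_reports >= min_reports,
    signal_by_ic = !is.na(ic_025) & ic_025 > 0 & n_reports >= min_reports
  )
}

# append all disproportionality statistics to a tibble of a/b/c/d cells
add_disprop_stats <- function(cells, estimate = "shrunk", min_reports = 3) {
  cells <- cells |>
    mutate(
      n_drug = .data$a + .data$b,
      n_event = .data$a + .data$c,
      n_total = .data$a + .data$b + .data$c + .data$d,
      n_expected = expected_count(.data$a, .data$b, .data$c, .data$d),
      ror = if (estimate == "classic") {
        (.data$a * .data$d) / (.data$b * .data$c)
      } else {
        shrunk_ror(.data$a, .data$b, .data$c, .data$d)
      },
      ic = info_component(.data$a, .data$b, .data$c, .data$d),
      n_reports = .data$a
    )
  cells |>
    bind_cols(ic_credible_interval(cells$ic, cells$a),
              ror_wald_ci(cells$a, cells$b, cells$c, cells$d, ror = cells$ror)) |>
    (\(df) bind_cols(df, signal_flags(df$n_reports, df$ror_025, df$ic_025,
                                      min_reports = min_reports)))()
}

#' Disproportionality analysis over the cohorts
#'
#' Assembles the 2x2 contingency table for each (exposure group, event)
#' pair and computes the shrunk ROR, the IC, their 95% intervals and the
#' signal flags. The counting unit is the report — a distinct (case, PT)
#' pair — and, at SMQ level under the default `counting = "per_smq_once"`,
#' a (case, SMQ) pair counted once per case per SMQ on the target side
#' (`counting = "per_pt"` counts every member PT pair instead). The
#' comparator supplying the `c`/`d` cells is, by default, the reports of the
#' `neither` group — the database without either drug class; the
#' `other_reports` alternative uses all reports outside the target group.
#'
#' Levels:
#' * `"overall"`: one row per group, target event = any cardiovascular PT;
#' * `"smq"`: one row per group and SMQ category;
#' * `"pt"`: one row per group and PT (default: every cardiovascular PT in
#'   the map observed in the data; override via `events`).
#'
#' @param cohort A `faers_cohort` from [build_cohorts()].
#' @param level `"overall"`, `"smq"` or `"pt"`.
#' @param comparator `"neither"` (default) or `"other_reports"`.
#' @param counting `"per_smq_once"` (default) or `"per_pt"`; affects SMQ
#'   level only.
#' @param groups Target exposure groups.
#' @param events Optional character vector of PTs to analyse at `"pt"`
#'   level.
#' @param estimate `"shrunk"` (the observed/expected shrinkage estimate, the
#'   default) or `"classic"` (the plain odds-ratio `(a*d)/(b*c)`, provided
#'   for comparison only; intervals are always computed around the chosen
#'   point estimate, the IC is always the shrunk form).
#' @param min_reports Minimum report count for the signal rule.
#' @return A `faers_disprop` tibble: one row per (group, event) with cells
#'   `a`,`b`,`c`,`d`, margins, `n_expected`, `ror`, `ror_025`, `ror_975`,
#'   `ic`, `ic_025`, `ic_975`, `n_reports`, `signal_by_ror`, `signal_by_ic`.
#' @examples
#' sim <- synth_generate(synth_config(seed = 1, n_cases = c(
#'   ICI_alone = 300, AGI_alone = 300, combination = 150, neither = 3000)))
#' archive <- read_drug_archive(faersignal_example("drug_archive.tsv"))
#' smq <- read_smq_map(faersignal_example("smq_map_synthetic.tsv"))
#' cohort <- sim$reports |> clean_reports(archive) |> build_cohorts(smq)
#' disproportionality(cohort, level = "overall")
#' @export
disproportionality <- function(cohort,
                               level = c("overall", "smq", "pt"),
                               comparator = c("neither", "other_reports"),
                               counting = c("per_smq_once", "per_pt"),
                               groups = c("ICI_alone", "AGI_alone", "combination"),
                               events = NULL,
                               estimate = c("shrunk", "classic"),
                               min_reports = 3) {
  stopifnot(inherits(cohort, "faers_cohort"))
  level <- arg_match(level)
  comparator <- arg_match(comparator)
  counting <- arg_match(counting)
  estimate <- arg_match(estimate)

  pt_units <- cohort$pt_units
  smq_units <- cohort$smq_units
  rows <- purrr::map(groups, function(g) {
    tg_pt <- pt_units |> filter(.data$exposure_group == g)
    tg_smq <- smq_units |> filter(.data$exposure_group == g)
    if (comparator == "neither") {
      cp_pt <- pt_units |> filter(.data$exposure_group == "neither")
      cp_smq <- smq_units |> filter(.data$exposure_group == "neither")
    } else {
      cp_pt <- pt_units |> filter(.data$exposure_group != g)
      cp_smq <- smq_units |> filter(.data$exposure_group != g)
    }
    if (nrow(cp_pt) == 0) {
      abort(paste0("empty comparator ('", comparator, "') for group ", g))
    }
    n_tg <- nrow(tg_pt)
    n_cp <- nrow(cp_pt)
    if (level == "overall") {
      tibble(level = "overall", event = "Any cardiovascular event",
             smq_code = NA_integer_, exposure_group = g,
             a = sum(tg_pt$is_cv), b = n_tg - sum(tg_pt$is_cv),
             c = sum(cp_pt$is_cv), d = n_cp - sum(cp_pt$is_cv))
    } else if (level == "smq") {
      lut <- cohort$smq_map |> distinct(.data$pt_norm, .data$smq_code)
      pmap(cv_smq_catalog(), function(smq_code, smq_name) {
        member <- lut$pt_norm[lut$smq_code == smq_code]
        in_tg <- sum(tg_pt$pt_norm %in% member)
        in_cp <- sum(cp_pt$pt_norm %in% member)
        a <- if (counting == "per_smq_once") {
          sum(tg_smq$smq_code == smq_code)
        } else in_tg
        cc <- if (counting == "per_smq_once") {
          sum(cp_smq$smq_code == smq_code)
        } else in_cp
        tibble(level = "smq", event = smq_name, smq_code = smq_code,
               exposure_group = g, a = a, b = n_tg - in_tg,
               c = cc, d = n_cp - in_cp)
      }) |> list_rbind()
    } else {
      evs <- if (is.null(events)) {
        sort(unique(intersect(c(tg_pt$pt_norm, cp_pt$pt_norm),
                              cohort$smq_map$pt_norm)))
      } else {
        normalize_name(events)
      }
      ta <- tg_pt |> count(.data$pt_norm, name = "a")
      ca <- cp_pt |> count(.data$pt_norm, name = "c")
      tibble(pt_norm = evs) |>
        left_join(ta, by = "pt_norm") |>
        left_join(ca, by = "pt_norm") |>
        mutate(level = "pt", event = .data$pt_norm, smq_code = NA_integer_,
               exposure_group = g,
               a = coalesce(.data$a, 0L), c = coalesce(.data$c, 0L),
               b = n_tg - .data$a, d = n_cp - .data$c) |>
        select("level", "event", "smq_code", "exposure_group",
               "a", "b", "c", "d")
    }
  })
  res <- list_rbind(rows) |>
    add_disprop_stats(estimate = estimate, min_reports = min_reports)
  new_tibble(res, class = "faers_disprop",
             level = level, comparator = comparator, counting = counting,
             estimate = estimate, min_reports = min_reports)
}

#' @export
print.faers_disprop <- function(x, ..., digits = 3) {
  cat("# Disproportionality analysis (level: ", attr(x, "level"),
      ", comparator: ", attr(x, "comparator"),
      ", counting: ", attr(x, "counting"), ")\n", sep = "")
  y <- as_tibble(x) |>
    mutate(across(c("n_expected", "ror", "ror_025", "ror_975",
                    "ic", "ic_025", "ic_975"), \(v) round(v, digits)))
  print(y, ...)
  invisible(x)
}
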