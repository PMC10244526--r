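# non-study drugs used for background exposure and concomitant mentions;
# deliberately absent from the drug archive
filler_drugs <- function() {
  c("Aspirin", "Metformin", "Atorvastatin", "Omeprazole", "Levothyroxine",
    "Lisinopril", "Paracetamol", "Amlodipine", "Prednisone", "Furosemide")
}

# non-cardiovascular preferred terms for the background PT mix
filler_pts <- function() {
  c("Nausea", "Fatigue", "Diarrhoea", "Rash", "Pyrexia", "Headache",
    "Vomiting", "Decreased appetite", "Anaemia", "Pruritus", "Arthralgia",
    "Cough", "Constipation", "Dizziness", "Insomnia")
}

#' Default PT universe for the synthetic generator
#'
#' Every PT of the supplied SMQ map at a small per-case baseline inclusion
#' rate, plus fifteen common non-cardiovascular filler PTs at a higher rate,
#' so that cardiovascular reports are a minority of the stream as in real
#' spontaneous-report data.
#'
#' @param smq_map SMQ membership map; defaults to the packaged synthetic map.
#' @param cv_rate,filler_rate Per-case baseline inclusion probabilities.
#' @return A tibble with columns `pt`, `base_rate`.
#' @export
default_pt_universe <- function(smq_map = NULL, cv_rate = 0.004,
                                filler_rate = 0.08) {
  smq_map <- smq_map %||% read_smq_map(faersignal_example("smq_map_synthetic.tsv"))
  bind_rows(
    smq_map |> distinct(.data$pt) |> mutate(base_rate = cv_rate),
    tibble(pt = filler_pts(), base_rate = filler_rate)
  )
}

#' Default per-group SMQ reporting-rate multipliers
#'
#' Relative reporting rates applied to the member PTs of each SMQ per
#' exposure group, loosely emulating the study conditions: checkpoint
#' inhibitors over-report myocarditis/pericarditis and cardiomyopathy;
#' angiogenesis inhibitors over-report hypertension, embolic/thrombotic
#' events and cardiac failure; the combination over-reports hypertension and
#' embolic/thrombotic events most strongly while its myocarditis excess is
#' weaker than with checkpoint inhibitors alone.
#'
#' @return A tibble with columns `exposure_group`, `smq_code`, `rho`.
#' @export
default_smq_multipliers <- function() {
  tribble(
    ~exposure_group, ~smq_code, ~rho,
    "ICI_alone",   20000239L, 3.2,
    "ICI_alone",   20000150L, 1.6,
    "ICI_alone",   20000130L, 1.3,
    "ICI_alone",   20000081L, 1.25,
    "AGI_alone",   20000147L, 3.4,
    "AGI_alone",   20000081L, 1.5,
    "AGI_alone",   20000004L, 1.4,
    "AGI_alone",   20000130L, 1.4,
    "AGI_alone",   20000150L, 1.3,
    "combination", 20000147L, 3.9,
    "combination", 20000081L, 2.0,
    "combination", 20000239L, 1.6,
    "combination", 20000150L, 1.5,
    "combination", 20000043L, 1.4
  )
}

# per-group outcome category mixes (rows: groups, cols: categories); the
# three treated groups follow the observed FAERS severity mixes for these
# drug classes, the background is a generic spontaneous-report mix
default_outcome_probs <- function() {
  m <- rbind(
    ICI_alone   = c(0.271, 0.069, 0.358, 0.005, 0.000, 0.183, 0.114),
    AGI_alone   = c(0.172, 0.037, 0.314, 0.005, 0.000, 0.274, 0.198),
    combination = c(0.167, 0.028, 0.330, 0.003, 0.000, 0.159, 0.313),
    neither     = c(0.080, 0.030, 0.250, 0.010, 0.001, 0.350, 0.279)
  )
  colnames(m) <- outcome_levels()
  m
}

# per-group indication mixes; "none" means no indication row is written
default_indication_probs <- function() {
  list(
    ICI_alone = c("Non-small cell lung cancer" = 0.255,
                  "Renal cell carcinoma" = 0.076,
                  "Hepatocellular carcinoma" = 0.008,
                  "Colorectal cancer" = 0.014,
                  "Endometrial cancer" = 0.004,
                  "Breast cancer" = 0.022,
                  "Malignant melanoma" = 0.165,
                  "Gastric cancer" = 0.100, none = 0.356),
    AGI_alone = c("Non-small cell lung cancer" = 0.031,
                  "Renal cell carcinoma" = 0.206,
                  "Hepatocellular carcinoma" = 0.066,
                  "Colorectal cancer" = 0.136,
                  "Endometrial cancer" = 0.006,
                  "Breast cancer" = 0.030,
                  "Malignant melanoma" = 0.002,
                  "Gastric cancer" = 0.100, none = 0.423),
    combination = c("Non-small cell lung cancer" = 0.114,
                    "Renal cell carcinoma" = 0.281,
                    "Hepatocellular carcinoma" = 0.120,
                    "Colorectal cancer" = 0.023,
                    "Endometrial cancer" = 0.167,
                    "Breast cancer" = 0.006,
                    "Malignant melanoma" = 0.022,
                    "Gastric cancer" = 0.050, none = 0.217),
    neither = c("Hypertension" = 0.10, "Rheumatoid arthritis" = 0.10,
                "Type 2 diabetes mellitus" = 0.10, "Migraine" = 0.05,
                "Breast cancer" = 0.03, "Colorectal cancer" = 0.02,
                none = 0.60)
  )
}

#' Configure the synthetic FAERS-like generator
#'
#' Fixes every parameter of the generative model: group sizes, the duplicate
#' (report-version) process, drug roles and name variants, the PT universe
#' with per-(group, event) relative reporting rates, outcome and indication
#' mixes, demographics and the receipt-year range. Validation happens here,
#' before anything is generated or written.
#'
#' The reaction model is per-PT Bernoulli inclusion: a case in group g
#' includes PT j with probability `min(1, base_rate_j * rho_gj)`,
#' independently across PTs, where the relative reporting rate `rho_gj`
#' multiplies an SMQ-level factor (the largest factor over SMQs containing
#' j) and an optional PT-level factor. Expected contingency cells are then
#' exactly linear in rho — see [expected_table()].
#'
#' @param seed Integer seed; the whole generated file set is a deterministic
#'   function of the configuration.
#' @param n_cases Named integer vector of case counts for `ICI_alone`,
#'   `AGI_alone`, `combination` and the `neither` background.
#' @param dup_rate Mean number of extra report versions per case (Poisson,
#'   capped at `max_versions`).
#' @param max_versions Maximum report versions per case.
#' @param version_reaction_keep Probability that a reaction of the final
#'   version already appears in an earlier version (follow-ups add
#'   information).
#' @param p_second_class_drug Probability a treated case reports a second
#'   suspect drug of the same class.
#' @param conco_rate Mean number of concomitant filler-drug mentions.
#' @param p_interacting Probability a non-suspect mention carries the
#'   `interacting` rather than `concomitant` role.
#' @param p_offclass_conco Probability a single-class case additionally
#'   mentions a drug of the *other* study class with a concomitant role
#'   (which must not affect its exposure group).
#' @param pt_universe Tibble of `pt`, `base_rate` baseline inclusion
#'   probabilities.
#' @param smq_map SMQ membership map used to tag cardiovascular PTs.
#' @param smq_multipliers Tibble `exposure_group`, `smq_code`, `rho`.
#' @param pt_multipliers Optional tibble `exposure_group`, `pt`, `rho` of
#'   PT-level relative reporting rates (multiplied on top of any SMQ
#'   factor).
#' @param outcome_probs Group-by-category outcome probability matrix.
#' @param p_secondary_outcome Probability that a fatal or life-threatening
#'   case also carries a hospitalisation code.
#' @param indication_probs Per-group named probability vectors over
#'   indication texts (`none` = no indication row).
#' @param age_mean,age_sd,p_age_missing Age model.
#' @param sex_probs,reporter_probs,country_probs Named categorical mixes.
#' @param year_range Receipt-year range (final year restricted to Q1).
#' @param archive Drug-name archive used to emit name variants.
#' @return A validated `synth_config` object.
#' @export
synth_config <- function(seed = 20140101,
                         n_cases = c(ICI_alone = 1900L, AGI_alone = 4700L,
                                     combination = 400L, neither = 30000L),
                         dup_rate = 0.25, max_versions = 4L,
                         version_reaction_keep = 0.7,
                         p_second_class_drug = 0.15,
                         conco_rate = 0.7, p_interacting = 0.1,
                         p_offclass_conco = 0.05,
                         pt_universe = NULL,
                         smq_map = NULL,
                         smq_multipliers = default_smq_multipliers(),
                         pt_multipliers = NULL,
                         outcome_probs = default_outcome_probs(),
                         p_secondary_outcome = 0.1,
                         indication_probs = default_indication_probs(),
                         age_mean = 65, age_sd = 12, p_age_missing = 0.22,
                         sex_probs = c(male = 0.52, female = 0.40, unknown = 0.08),
                         reporter_probs = c(health_professional = 0.65,
                                            non_health_professional = 0.33,
                                            unknown = 0.02),
                         country_probs = c(US = 0.45, JP = 0.12, FR = 0.06,
                                           DE = 0.05, CA = 0.04, GB = 0.03,
                                           IT = 0.03, CN = 0.03, OTHER = 0.19),
                         year_range = c(2014L, 2022L),
                         archive = NULL) {
  smq_map <- smq_map %||% read_smq_map(faersignal_example("smq_map_synthetic.tsv"))
  pt_universe <- pt_universe %||% default_pt_universe(smq_map)
  archive <- archive %||% read_drug_archive(faersignal_example("drug_archive.tsv"))

  if (!setequal(names(n_cases), exposure_levels())) {
    abort("`n_cases` must be named ICI_alone, AGI_alone, combination, neither")
  }
  if (any(n_cases < 0)) abort("`n_cases` must be non-negative")
  probs <- c(version_reaction_keep, p_second_class_drug, p_interacting,
             p_offclass_conco, p_secondary_outcome, p_age_missing,
             pt_universe$base_rate)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (any(smq_multipliers$rho < 0)) abort("multipliers must be >= 0")
  if (!is.null(pt_multipliers) && any(pt_multipliers$rho < 0)) {
    abort("multipliers must be >= 0")
  }
  covered <- smq_map |>
    filter(.data$pt_norm %in% normalize_name(pt_universe$pt)) |>
    distinct(.data$smq_code)
  if (!all(cv_smq_catalog()$smq_code %in% covered$smq_code)) {
    abort("`pt_universe` must cover all nine cardiovascular SMQ categories")
  }
  if (!all(rownames(outcome_probs) %in% exposure_levels()) ||
      !identical(colnames(outcome_probs), outcome_levels())) {
    abort("`outcome_probs` must have exposure-group rows and the seven outcome columns")
  }
  structure(
    list(seed = as.integer(seed),
         n_cases = n_cases[exposure_levels()],
         dup_rate = dup_rate, max_versions = as.integer(max_versions),
         version_reaction_keep = version_reaction_keep,
         p_second_class_drug = p_second_class_drug,
         conco_rate = conco_rate, p_interacting = p_interacting,
         p_offclass_conco = p_offclass_conco,
         pt_universe = as_tibble(pt_universe), smq_map = smq_map,
         smq_multipliers = smq_multipliers, pt_multipliers = pt_multipliers,
         outcome_probs = outcome_probs,
         p_secondary_outcome = p_secondary_outcome,
         indication_probs = indication_probs,
         age_mean = age_mean, age_sd = age_sd, p_age_missing = p_age_missing,
         sex_probs = sex_probs, reporter_probs = reporter_probs,
         country_probs = country_probs,
         year_range = as.integer(year_range), archive = archive),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config> seed", x$seed, "\n  cases:",
      paste(names(x$n_cases), x$n_cases, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Per-(group, PT) inclusion probabilities of the generative model
#'
#' @param config A `synth_config`.
#' @return A tibble with columns `pt`, `pt_norm` and one probability column
#'   per exposure group.
#' @export
inclusion_probs <- function(config) {
  uni <- config$pt_universe |> mutate(pt_norm = normalize_name(.data$pt))
  membership <- config$smq_map |> distinct(.data$pt_norm, .data$smq_code)
  out <- uni
  for (g in exposure_levels()) {
    sm <- config$smq_multipliers |> filter(.data$exposure_group == g)
    rho <- rep(1, nrow(uni))
    if (nrow(sm) > 0) {
      rho_smq <- membership |>
        inner_join(sm, by = "smq_code") |>
        summarise(rho = max(.data$rho), .by = "pt_norm")
      idx <- match(uni$pt_norm, rho_smq$pt_norm)
      rho[!is.na(idx)] <- rho_smq$rho[idx[!is.na(idx)]]
    }
    if (!is.null(config$pt_multipliers)) {
      pm <- config$pt_multipliers |>
        filter(.data$exposure_group == g) |>
        mutate(pt_norm = normalize_name(.data$pt))
      j <- match(uni$pt_norm, pm$pt_norm)
      rho[!is.na(j)] <- rho[!is.na(j)] * pm$rho[j[!is.na(j)]]
    }
    out[[g]] <- pmin(uni$base_rate * rho, 1)
  }
  out |> select("pt", "pt_norm", all_of(exposure_levels()))
}

# sample archive name variants (with cosmetic mangling) for canonical drugs
sample_variants <- function(archive, canonical, n_per = 1L) {
  arch_split <- split(archive$name_variant, archive$canonical_name)
  raw <- map_chr(canonical, function(cn) {
    v <- arch_split[[cn]]
    v[sample.int(length(v), 1L)]
  })
  style <- sample(c("as_is", "upper", "padded"), length(raw), replace = TRUE,
                  prob = c(0.6, 0.3, 0.1))
  ifelse(style == "upper", toupper(raw),
         ifelse(style == "padded", paste0(" ", raw, "  "), raw))
}

#' Generate a synthetic FAERS-like report stream with known ground truth
#'
#' Draws a full report stream — cases with duplicate/follow-up versions,
#' suspect and concomitant drug mentions under messy name variants, PT sets,
#' outcome codes, indications and demographics — from a [synth_config()],
#' and records the exact ground truth alongside. The stream is a
#' deterministic function of the configuration (same config, byte-identical
#' output).
#'
#' Earlier report versions are degraded copies of the final version: each
#' final reaction appears in an earlier version with probability
#' `version_reaction_keep`, and outcome/indication rows appear only on the
#' final version, so keeping the most recent version recovers the complete
#' case.
#'
#' @param config A `synth_config`.
#' @param dir Optional output directory; when given, the FAERS-dialect file
#'   set and a `ground_truth.json` ledger are written there.
#' @param dialect Dialect used when writing files.
#' @return A `faers_sim` object: `reports` (a `faers_reports` stream with
#'   all versions), `truth` (ledger: per-case tibble, per-group summary, the
#'   inclusion-probability table), and the `config`.
#' @examples
#' sim <- synth_generate(synth_config(seed = 11, n_cases = c(
#'   ICI_alone = 30, AGI_alone = 30, combination = 10, neither = 100)))
#' sim$truth$per_group
#' @export
synth_generate <- function(config, dir = NULL, dialect = faers_dialect()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  probs <- inclusion_probs(config)
  arch <- config$archive
  ici_canon <- sort(unique(arch$canonical_name[arch$drug_class == "ICI"]))
  agi_canon <- sort(unique(arch$canonical_name[arch$drug_class == "AGI"]))
  cv_pts <- unique(config$smq_map$pt_norm)

  demo_l <- list(); drug_l <- list(); reac_l <- list(); outc_l <- list()
  indi_l <- list(); truth_l <- list()
  case_counter <- 0L

  for (g in exposure_levels()) {
    n <- config$n_cases[[g]]
    if (n == 0L) next
    case_id <- sprintf("C%07d", case_counter + seq_len(n))
    case_counter <- case_counter + n

    # demographics
    age <- pmin(pmax(round(rnorm(n, config$age_mean, config$age_sd)), 1), 95)
    age[runif(n) < config$p_age_missing] <- NA
    sex <- sample(names(config$sex_probs), n, TRUE, config$sex_probs)
    reporter <- sample(names(config$reporter_probs), n, TRUE, config$reporter_probs)
    country <- sample(names(config$country_probs), n, TRUE, config$country_probs)
    yr <- sample(seq(config$year_range[1], config$year_range[2]), n, TRUE)
    day <- ifelse(yr == config$year_range[2],
                  sample.int(80L, n, TRUE), sample.int(330L, n, TRUE))
    base_date <- as.Date(paste0(yr, "-01-01")) + day

    # suspect drugs per case
    susp <- list()
    if (g %in% c("ICI_alone", "combination")) {
      cn <- sample(ici_canon, n, TRUE)
      susp$ici <- tibble(idx = seq_len(n), drugname = sample_variants(arch, cn),
                         role = "suspect")
      extra <- which(g == "ICI_alone" & runif(n) < config$p_second_class_drug)
      if (length(extra) > 0) {
        cn2 <- sample(ici_canon, length(extra), TRUE)
        susp$ici2 <- tibble(idx = extra, drugname = sample_variants(arch, cn2),
                            role = "suspect")
      }
    }
    if (g %in% c("AGI_alone", "combination")) {
      cn <- sample(agi_canon, n, TRUE)
      susp$agi <- tibble(idx = seq_len(n), drugname = sample_variants(arch, cn),
                         role = "suspect")
      extra <- which(g == "AGI_alone" & runif(n) < config$p_second_class_drug)
      if (length(extra) > 0) {
        cn2 <- sample(agi_canon, length(extra), TRUE)
        susp$agi2 <- tibble(idx = extra, drugname = sample_variants(arch, cn2),
                            role = "suspect")
      }
    }
    if (g == "neither") {
      n_susp <- 1L + rpois(n, 0.5)
      susp$bg <- tibble(idx = rep(seq_len(n), n_susp),
                        drugname = sample(filler_drugs(), sum(n_susp), TRUE),
                        role = "suspect")
    }
    # concomitant / interacting mentions never affect classification
    n_conco <- rpois(n, config$conco_rate)
    conco <- tibble(idx = rep(seq_len(n), n_conco),
                    drugname = sample(filler_drugs(), sum(n_conco), TRUE))
    conco$role <- ifelse(runif(nrow(conco)) < config$p_interacting,
                         "interacting", "concomitant")
    off <- NULL
    if (g %in% c("ICI_alone", "AGI_alone")) {
      oidx <- which(runif(n) < config$p_offclass_conco)
      if (length(oidx) > 0) {
        pool <- if (g == "ICI_alone") agi_canon else ici_canon
        ocn <- sample(pool, length(oidx), TRUE)
        off <- tibble(idx = oidx, drugname = sample_variants(arch, ocn),
                      role = "concomitant")
      }
    }
    drugs_g <- bind_rows(c(susp, list(conco = conco, off = off))) |>
      mutate(case_id = case_id[.data$idx]) |>
      arrange(.data$idx) |>
      select("case_id", "drugname", "role")

    # reactions: independent Bernoulli inclusion per PT
    p_g <- probs[[g]]
    hits <- lapply(seq_len(nrow(probs)), function(j) {
      if (p_g[j] <= 0) return(NULL)
      w <- which(runif(n) < p_g[j])
      if (length(w) == 0) return(NULL)
      tibble(idx = w, pt = probs$pt[j])
    })
    reac_g <- bind_rows(hits)
    if (nrow(reac_g) == 0) reac_g <- tibble(idx = integer(), pt = character())
    reac_g <- reac_g |> mutate(case_id = case_id[.data$idx])

    # outcomes and indications (final version only)
    prim <- sample(colnames(config$outcome_probs), n, TRUE,
                   config$outcome_probs[g, ])
    second <- prim %in% c("death", "life_threatening") &
      runif(n) < config$p_secondary_outcome
    ip <- config$indication_probs[[g]]
    indi <- sample(names(ip), n, TRUE, ip)

    # report versions: final carries the full case, earlier ones are thinned
    nv <- 1L + pmin(rpois(n, config$dup_rate), config$max_versions - 1L)
    vers <- tibble(idx = rep(seq_len(n), nv),
                   v = sequence(nv),
                   nv = rep(nv, nv)) |>
      mutate(case_id = case_id[.data$idx],
             report_id = paste0(.data$case_id, "-", sprintf("%02d", .data$v)),
             fda_date = base_date[.data$idx] - 7L * (.data$nv - .data$v),
             is_final = .data$v == .data$nv)
    demo_g <- vers |>
      mutate(age_years = as.numeric(age[.data$idx]), sex = sex[.data$idx],
             reporter_type = reporter[.data$idx], country = country[.data$idx]) |>
      select("report_id", "case_id", "fda_date", "age_years", "sex",
             "reporter_type", "country")
    drug_vg <- vers |>
      select("case_id", "report_id") |>
      inner_join(drugs_g, by = "case_id", relationship = "many-to-many") |>
      select("report_id", "drugname", "role")
    reac_vg <- vers |>
      select("case_id", "report_id", "is_final") |>
      inner_join(reac_g |> select("case_id", "pt"), by = "case_id",
                 relationship = "many-to-many") |>
      filter(.data$is_final | runif(n()) < config$version_reaction_keep) |>
      select("report_id", "pt")
    final_id <- vers$report_id[vers$is_final]
    outc_g <- bind_rows(
      tibble(report_id = final_id[prim != "unknown"],
             outcome = prim[prim != "unknown"]),
      tibble(report_id = final_id[second], outcome = "hospitalization")
    )
    indi_g <- tibble(report_id = final_id[indi != "none"],
                     indication = indi[indi != "none"])

    n_pts <- tabulate(reac_g$idx, nbins = n)
    is_cv <- normalize_name(reac_g$pt) %in% cv_pts
    n_cv <- tabulate(reac_g$idx[is_cv], nbins = n)
    truth_l[[g]] <- tibble(
      case_id = case_id, exposure_group = g, n_versions = nv,
      final_report_id = final_id, year = yr,
      outcome_category = prim,
      indication = ifelse(indi == "none", NA_character_, indi),
      n_pts = n_pts, n_cv_pts = n_cv
    )
    demo_l[[g]] <- demo_g; drug_l[[g]] <- drug_vg; reac_l[[g]] <- reac_vg
    outc_l[[g]] <- outc_g; indi_l[[g]] <- indi_g
  }

  reports <- new_faers_reports(
    list_rbind(demo_l), list_rbind(drug_l), list_rbind(reac_l),
    list_rbind(outc_l), list_rbind(indi_l),
    counts = list(generated = sum(map_int(demo_l, nrow)))
  )
  truth_cases <- list_rbind(truth_l)
  truth <- list(
    cases = truth_cases,
    per_group = truth_cases |>
      summarise(n_cases = n(), n_cv_cases = sum(.data$n_cv_pts > 0),
                n_cv_reports = sum(.data$n_cv_pts), .by = "exposure_group"),
    inclusion_probs = probs
  )
  if (!is.null(dir)) {
    write_faers(reports, dir, dialect)
    jsonlite::write_json(
      list(seed = config$seed,
           per_group = truth$per_group,
           cases = truth$cases,
           inclusion_probs = truth$inclusion_probs),
      file.path(dir, "ground_truth.json"), dataframe = "columns", digits = NA
    )
  }
  structure(list(reports = reports, truth = truth, config = config),
            class = "faers_sim")
}

#' @export
print.faers_sim <- function(x, ...) {
  cat("<faers_sim> seed", x$config$seed, "\n")
  print(x$truth$per_group)
  invisible(x)
}

#' Expected contingency table under the generative model
#'
#' Closed-form expectations of the 2x2 cells that [disproportionality()]
#' would assemble for a given (exposure group, event) pair on a cleanly
#' ingested stream from [synth_generate()], exact under the Bernoulli
#' inclusion model: with inclusion probability `p_gj` for PT j in group g,
#' the expected target-cell count is `n_g * sum(p_gj)` over the member PTs
#' (or `n_g * (1 - prod(1 - p_gj))` for an SMQ counted once per case), and
#' the off-cells are the complementary pair sums. Expectations double when
#' group sizes double, and under unit multipliers the implied shrunk ROR
#' tends to 1 as group sizes grow.
#'
#' @param config A `synth_config`.
#' @param event A PT (level `"pt"`), an SMQ code or name (level `"smq"`), or
#'   ignored for level `"overall"`.
#' @param group Target exposure group.
#' @param level,counting,comparator As in [disproportionality()].
#' @return A one-row tibble with expected `a`, `b`, `c`, `d`, margins and
#'   `n_expected`.
#' @export
expected_table <- function(config, event, group,
                           level = c("pt", "smq", "overall"),
                           counting = c("per_smq_once", "per_pt"),
                           comparator = "neither") {
  stopifnot(inherits(config, "synth_config"))
  level <- arg_match(level)
  counting <- arg_match(counting)
  probs <- inclusion_probs(config)
  member <- switch(
    level,
    pt = probs$pt_norm == normalize_name(event),
    smq = {
      catalog <- cv_smq_catalog()
      code <- if (is.numeric(event) || grepl("^[0-9]+$", event)) {
        as.integer(event)
      } else {
        catalog$smq_code[match(event, catalog$smq_name)]
      }
      mem <- config$smq_map$pt_norm[config$smq_map$smq_code == code]
      probs$pt_norm %in% mem
    },
    overall = probs$pt_norm %in% unique(config$smq_map$pt_norm)
  )
  cell <- function(g, once) {
    n <- config$n_cases[[g]]
    p <- probs[[g]]
    a <- if (once) n * (1 - prod(1 - p[member])) else n * sum(p[member])
    b <- n * sum(p[!member])
    c(a = a, b = b)
  }
  once <- level == "smq" && counting == "per_smq_once"
  tg <- cell(group, once)
  cp_groups <- if (comparator == "neither") "neither" else
    setdiff(exposure_levels(), group)
  cp <- Reduce(`+`, lapply(cp_groups, cell, once = once))
  tibble(a = tg[["a"]], b = tg[["b"]], c = cp[["a"]], d = cp[["b"]]) |>
    mutate(n_drug = .data$a + .data$b, n_event = .data$a + .data$c,
           n_total = .data$a + .data$b + .data$c + .data$d,
           n_expected = .data$n_drug * .data$n_event / .data$n_total)
}
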