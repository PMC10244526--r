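#' The nine narrow cardiovascular SMQ categories
#'
#' Catalogue of the nine Standardised MedDRA Query (SMQ) categories used to
#' define cardiovascular adverse events throughout the package, all taken at
#' narrow (high-specificity) scope: cardiac arrhythmias, cardiac failure,
#' cardiomyopathy, embolic and thrombotic events, hypertension, ischaemic
#' heart disease, noninfectious myocarditis/pericarditis, pulmonary
#' hypertension, and torsade de pointes/QT prolongation. The member PT lists
#' are user-supplied (MedDRA is licensed); this catalogue fixes the code and
#' name universe that any supplied map is validated against.
#'
#' @return A tibble with columns `smq_code` (integer) and `smq_name`.
#' @examples
#' cv_smq_catalog()
#' @export
cv_smq_catalog <- function() {
  tibble(
    smq_code = c(20000049L, 20000004L, 20000150L, 20000081L, 20000147L,
                 20000043L, 20000239L, 20000130L, 20000001L),
    smq_name = c("Cardiac arrhythmias", "Cardiac failure", "Cardiomyopathy",
                 "Embolic and thrombotic events", "Hypertension",
                 "Ischaemic heart disease",
                 "Noninfectious myocarditis/pericarditis",
                 "Pulmonary hypertension",
                 "Torsade de pointes/QT prolongation")
  )
}

#' SMQ categories containing a preferred term
#'
#' Membership lookup against a loaded SMQ map. Matching is by normalised PT
#' name (case-insensitive, whitespace-collapsed). A PT may belong to several
#' SMQs; all are returned, and each SMQ-level analysis treats the PT
#' independently.
#'
#' @param smq_map An SMQ map from [read_smq_map()] / [as_smq_map()].
#' @param pt Character vector of preferred terms.
#' @return A tibble with columns `pt`, `smq_code`, `smq_name` — one row per
#'   (queried PT, SMQ) membership; zero rows for non-cardiovascular PTs.
#' @examples
#' smq <- read_smq_map(faersignal_example("smq_map_synthetic.tsv"))
#' smqs_of(smq, "Torsade de pointes")
#' smqs_of(smq, "Nausea")
#' @export
smqs_of <- function(smq_map, pt) {
  tibble(pt = pt, pt_norm = normalize_name(pt)) |>
    inner_join(smq_map |> distinct(.data$pt_norm, .data$smq_code, .data$smq_name),
               by = "pt_norm", relationship = "many-to-many") |>
    select("pt", "smq_code", "smq_name")
}

#' Is a preferred term cardiovascular?
#'
#' `TRUE` iff the PT belongs to at least one of the nine narrow
#' cardiovascular SMQ categories in the supplied map. Vectorised.
#'
#' @inheritParams smqs_of
#' @return Logical vector the length of `pt`.
#' @examples
#' smq <- read_smq_map(faersignal_example("smq_map_synthetic.tsv"))
#' is_cardiovascular(smq, c("Pulmonary hypertension", "Nausea", ""))
#' @export
is_cardiovascular <- function(smq_map, pt) {
  normalize_name(pt) %in% smq_map$pt_norm
}
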