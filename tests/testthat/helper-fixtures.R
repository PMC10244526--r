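# shared auxiliary tables (packaged fixtures)
pkg_archive <- function() read_drug_archive(faersignal_example("drug_archive.tsv"))
pkg_smq <- function() read_smq_map(faersignal_example("smq_map_synthetic.tsv"))

tiny_sim <- function(seed, n = c(ICI_alone = 60, AGI_alone = 60,
                                 combination = 30, neither = 300), ...) {
  synth_generate(synth_config(seed = seed, n_cases = n, ...))
}

build_test_cohort <- function(sim) {
  build_cohorts(clean_reports(sim$reports, pkg_archive()), pkg_smq())
}

# write a small hand-rolled FAERS-dialect fixture; each argument is a
# character vector of already-$-joined data rows (no header)
write_faers_fixture <- function(dir, demo, drug, reac,
                                outc = character(), indi = character()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c("primaryid$caseid$fda_dt$age$sex$occp_cod$occr_country", demo),
             file.path(dir, "DEMO.txt"))
  writeLines(c("primaryid$drugname$role_cod", drug), file.path(dir, "DRUG.txt"))
  writeLines(c("primaryid$pt", reac), file.path(dir, "REAC.txt"))
  writeLines(c("primaryid$outc_cod", outc), file.path(dir, "OUTC.txt"))
  writeLines(c("primaryid$indi_pt", indi), file.path(dir, "INDI.txt"))
  dir
}
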