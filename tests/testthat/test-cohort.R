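test_that("deduplication keeps the most recent version of each case", {
  dir <- write_faers_fixture(
    withr::local_tempdir(),
    demo = c("R1$A$20200101$60$M$MD$US",   # case A v1
             "R2$A$20200601$60$M$MD$US",   # case A v2, later receipt date
             "R3$B$20190501$50$F$CN$FR",
             "R4$C$20210101$70$M$MD$JP"),
    drug = sprintf("R%d$Aspirin$PS", 1:4),
    reac = sprintf("R%d$Nausea", 1:4)
  )
  x <- read_faers(dir, quiet = TRUE)
  d <- dedup_reports(x)
  expect_setequal(d$demo$report_id, c("R2", "R3", "R4"))
  expect_equal(unname(d$counts$dedup[["dropped"]]), 1)
  # idempotent
  d2 <- dedup_reports(d)
  expect_equal(d2$demo, d$demo)
  expect_equal(nrow(dedup_reports(filter_suspect(d))$demo), nrow(d$demo))
})

test_that("dedup ties on date break by report id and empty input passes", {
  dir <- write_faers_fixture(
    withr::local_tempdir(),
    demo = c("R01$A$20200101$60$M$MD$US", "R02$A$20200101$60$M$MD$US"),
    drug = c("R01$Aspirin$PS", "R02$Aspirin$PS"),
    reac = character()
  )
  x <- read_faers(dir, quiet = TRUE)
  expect_equal(dedup_reports(x)$demo$report_id, "R02")
})

test_that("dedup recovers exactly the planted case count", {
  sim <- tiny_sim(7, n = c(ICI_alone = 80, AGI_alone = 80,
                           combination = 40, neither = 300),
                  dup_rate = 0.8)
  expect_gt(nrow(sim$reports$demo), sum(sim$config$n_cases))  # duplicates exist
  d <- dedup_reports(sim$reports)
  expect_equal(nrow(d$demo), sum(sim$config$n_cases))
  # survivor is the generator's final version for every case
  expect_setequal(d$demo$report_id, sim$truth$cases$final_report_id)
})

test_that("suspect filtering drives exposure; concomitant/interacting do not", {
  dir <- write_faers_fixture(
    withr::local_tempdir(),
    demo = c("R1$A$20200101$60$M$MD$US",
             "R2$B$20200101$55$F$MD$US",
             "R3$C$20200101$50$M$MD$US"),
    drug = c("R1$pembrolizumab$PS", "R1$Aspirin$C",
             "R2$nivolumab$C", "R2$Aspirin$PS",   # only ICI mention is concomitant
             "R3$Aspirin$C", "R3$Metformin$I"),   # no suspect drug at all
    reac = c("R1$Myocarditis", "R2$Myocarditis", "R3$Nausea")
  )
  x <- read_faers(dir, quiet = TRUE) |> dedup_reports() |> filter_suspect()
  expect_setequal(x$demo$report_id, c("R1", "R2"))  # R3 dropped
  expect_true(all(x$drugs$role == "suspect"))
  cases <- classify_exposure(x, pkg_archive())
  grp <- setNames(as.character(cases$cases$exposure_group), cases$cases$case_id)
  expect_equal(unname(grp["A"]), "ICI_alone")
  expect_equal(unname(grp["B"]), "neither")  # concomitant ICI removed
})

test_that("exposure classification is a pure function of suspect classes", {
  dir <- write_faers_fixture(
    withr::local_tempdir(),
    demo = c("R1$A$20200101$60$M$MD$US", "R2$B$20200101$60$M$MD$US",
             "R3$C$20200101$60$M$MD$US", "R4$D$20200101$60$M$MD$US"),
    drug = c("R1$nivolumab$PS", "R1$cabozantinib$PS",
             "R2$atezolizumab$PS",
             "R3$Aspirin$PS",
             "R4$LENVATINIB $SS"),
    reac = sprintf("R%d$Nausea", 1:4)
  )
  cases <- read_faers(dir, quiet = TRUE) |> clean_reports(pkg_archive())
  grp <- setNames(as.character(cases$cases$exposure_group), cases$cases$case_id)
  expect_equal(unname(grp[c("A", "B", "C", "D")]),
               c("combination", "ICI_alone", "neither", "AGI_alone"))
})

test_that("cardiovascular case/report counting is per distinct CV PT", {
  dir <- write_faers_fixture(
    withr::local_tempdir(),
    demo = c("R1$A$20200101$60$M$MD$US", "R2$B$20200101$60$M$MD$US"),
    drug = c("R1$pembrolizumab$PS", "R2$pembrolizumab$PS"),
    reac = c("R1$Myocarditis", "R1$Pericarditis", "R1$Nausea",
             "R1$Myocarditis",                      # duplicate PT within case
             "R2$Nausea", "R2$Rash")
  )
  cohort <- read_faers(dir, quiet = TRUE) |>
    clean_reports(pkg_archive()) |>
    build_cohorts(pkg_smq())
  cts <- cohort$counts
  ici <- cts[cts$exposure_group == "ICI_alone", ]
  expect_equal(ici$n_cases, 2)
  expect_equal(ici$n_cv_cases, 1)   # only case A has CV PTs
  expect_equal(ici$n_cv_reports, 2) # Myocarditis + Pericarditis, deduped
})

test_that("exposure groups partition the cases and reports bound cases", {
  sim <- tiny_sim(21)
  cohort <- build_test_cohort(sim)
  cases <- cohort$cases
  expect_equal(sum(table(cases$exposure_group)), nrow(cases))
  expect_false(anyNA(cases$exposure_group))
  cts <- cohort$counts
  expect_true(all(cts$n_cv_reports >= cts$n_cv_cases))
  expect_equal(sum(cts$n_cases), nrow(cases))
})

test_that("cleaned cohort counts reconcile with the generator ledger", {
  sim <- tiny_sim(33, n = c(ICI_alone = 120, AGI_alone = 120,
                            combination = 60, neither = 500))
  cohort <- build_test_cohort(sim)
  got <- cohort$counts |>
    dplyr::mutate(exposure_group = as.character(exposure_group)) |>
    dplyr::arrange(exposure_group)
  want <- sim$truth$per_group |> dplyr::arrange(exposure_group)
  expect_equal(got, want, ignore_attr = TRUE)
})

test_that("indication restriction keeps cancer cases by substring match", {
  dir <- write_faers_fixture(
    withr::local_tempdir(),
    demo = c("R1$A$20200101$60$M$MD$US", "R2$B$20200101$60$M$MD$US",
             "R3$C$20200101$60$M$MD$US"),
    drug = sprintf("R%d$pembrolizumab$PS", 1:3),
    reac = sprintf("R%d$Myocarditis", 1:3),
    indi = c("R1$Renal cell carcinoma", "R2$Hypertension")
  )
  cases <- read_faers(dir, quiet = TRUE) |> clean_reports(pkg_archive())
  kept <- restrict_to_indications(cases)
  expect_equal(kept$cases$case_id, "A")  # B non-cancer, C no indication
})

test_that("cohort summary tabulates sections with sane percentages", {
  sim <- tiny_sim(5, n = c(ICI_alone = 150, AGI_alone = 150,
                           combination = 80, neither = 400))
  cohort <- build_test_cohort(sim)
  tab <- cohort_summary(cohort)
  expect_true(all(c("age_group", "sex", "reporter", "outcome",
                    "indication", "country", "year") %in% tab$section))
  expect_true(all(tab$pct >= 0 & tab$pct <= 100, na.rm = TRUE))
  # outcome section counts per group sum to the group's CV case total
  outc <- tab[tab$section == "outcome", ]
  per_group <- tapply(outc$n, outc$exposure_group, sum)
  cv <- cohort$counts
  for (g in names(per_group)) {
    expect_equal(unname(per_group[[g]]),
                 cv$n_cv_cases[cv$exposure_group == g])
  }
})
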