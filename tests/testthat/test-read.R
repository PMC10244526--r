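test_that("a complete fixture reads into one RawReport per demographics row", {
  dir <- write_faers_fixture(
    withr::local_tempdir(),
    demo = c("R1$A$20200101$63$M$MD$US",
             "R2$B$20200315$$F$CN$",
             "R3$C$20201201$70$$$JP"),
    drug = c("R1$Keytruda$PS", "R1$Aspirin$C",
             "R2$bevacizumab$PS", "R3$nivolumab$SS"),
    reac = c("R1$Myocarditis", "R2$Hypertension", "R3$Nausea"),
    outc = c("R1$DE"),
    indi = c("R1$Malignant melanoma")
  )
  x <- read_faers(dir, quiet = TRUE)
  expect_s3_class(x, "faers_reports")
  expect_equal(nrow(x$demo), 3)
  expect_equal(x$demo$fda_date[1], as.Date("2020-01-01"))
  expect_equal(x$demo$age_years, c(63, NA, 70))
  expect_equal(x$demo$sex, c("male", "female", "unknown"))
  expect_equal(x$demo$reporter_type,
               c("health_professional", "non_health_professional", "unknown"))
  expect_equal(x$demo$country, c("US", "unknown", "JP"))
  # role codes resolve to the three FAERS roles; SS is also suspect
  expect_equal(sort(unique(x$drugs$role)), c("concomitant", "suspect"))
})

test_that("a report without reaction rows passes through ingestion", {
  dir <- write_faers_fixture(
    withr::local_tempdir(),
    demo = sprintf("R%d$C%d$20200101$60$M$MD$US", 1:4, 1:4),
    drug = sprintf("R%d$Aspirin$PS", 1:4),
    reac = c("R1$Nausea", "R2$Rash", "R4$Myocarditis")
  )
  x <- read_faers(dir, quiet = TRUE)
  expect_equal(nrow(x$demo), 4)
  expect_false("R3" %in% x$reactions$report_id)
  expect_equal(unname(x$counts$reaction_rows[["dropped"]]), 0)
})

test_that("orphan child rows are dropped and counted", {
  dir <- write_faers_fixture(
    withr::local_tempdir(),
    demo = "R1$A$20200101$60$M$MD$US",
    drug = c("R1$Aspirin$PS", "R9$Aspirin$PS"),
    reac = c("R1$Nausea", "R9$Rash", "R8$Rash")
  )
  x <- read_faers(dir, quiet = TRUE)
  expect_equal(unname(x$counts$drug_rows[["dropped"]]), 1)
  expect_equal(unname(x$counts$reaction_rows[["dropped"]]), 2)
  expect_equal(nrow(x$drugs), 1)
})

test_that("format errors name the offending file", {
  dir <- write_faers_fixture(
    withr::local_tempdir(),
    demo = c("R1$A$20200101$60$M$MD$US", "R1$A$20200601$60$M$MD$US"),
    drug = "R1$Aspirin$PS", reac = "R1$Nausea"
  )
  expect_error(read_faers(dir, quiet = TRUE), "duplicate report id")
  expect_error(read_faers(dir, quiet = TRUE), "DEMO")

  dir2 <- write_faers_fixture(
    withr::local_tempdir(),
    demo = "R1$A$20200101$60$M$MD$US",
    drug = "R1$Aspirin$XX", reac = "R1$Nausea"
  )
  expect_error(read_faers(dir2, quiet = TRUE), "unknown drug role code")

  dir3 <- withr::local_tempdir()
  write_faers_fixture(dir3,
                      demo = "R1$A$20200101$60$M$MD$US",
                      drug = "R1$Aspirin$PS", reac = "R1$Nausea")
  writeLines(c("primaryid$drugname", "R1$Aspirin"), file.path(dir3, "DRUG.txt"))
  expect_error(read_faers(dir3, quiet = TRUE), "missing column")
})

test_that("generator output round-trips through write + read unchanged", {
  sim <- tiny_sim(101, n = c(ICI_alone = 100, AGI_alone = 100,
                             combination = 50, neither = 400))
  dir <- withr::local_tempdir()
  write_faers(sim$reports, dir)
  back <- read_faers(dir, quiet = TRUE)
  ord <- function(df) df[do.call(order, df), , drop = FALSE]
  for (tb in c("demo", "drugs", "reactions", "outcomes", "indications")) {
    expect_equal(ord(as.data.frame(back[[tb]])),
                 ord(as.data.frame(sim$reports[[tb]])),
                 ignore_attr = TRUE)
  }
})

test_that("drug archive normalises variants and rejects conflicts", {
  arch <- pkg_archive()
  hit <- function(nm) arch$canonical_name[match(normalize_name(nm), arch$name_norm)]
  expect_equal(hit("Pembrolizumab"), "pembrolizumab")
  expect_equal(hit("KEYTRUDA"), "pembrolizumab")
  expect_equal(hit(" keytruda  "), "pembrolizumab")
  expect_setequal(unique(arch$drug_class), c("ICI", "AGI"))

  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name_variant\tdrug_class\tcanonical_name",
               "bevacizumab\tAGI\tbevacizumab",
               "BEVACIZUMAB \tICI\tbevacizumab"), f)
  expect_error(read_drug_archive(f), "conflicting")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  rows <- c(paste0("ici", 1:5, "\tICI\tici", 1:5),
            paste0("agi", 1:5, "\tAGI\tagi", 1:5))
  writeLines(c("name_variant\tdrug_class\tcanonical_name", rows), f2)
  a2 <- read_drug_archive(f2)
  expect_equal(nrow(a2), 10)
  expect_equal(sort(unique(a2$drug_class)), c("AGI", "ICI"))

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name_variant\tdrug_class\tcanonical_name",
               "foo\tNSAID\tfoo"), f3)
  expect_error(read_drug_archive(f3), "unknown drug_class")
})

test_that("SMQ map loading filters scope and validates the nine codes", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pt\tsmq_code\tsmq_name\tscope",
               "Myocarditis\t20000239\tNoninfectious myocarditis/pericarditis\tnarrow",
               "Some PT\t20000239\tNoninfectious myocarditis/pericarditis\tbroad",
               "Other PT\t20099999\tNot a CV SMQ\tnarrow"), f)
  expect_warning(expect_warning(expect_warning(
    m <- read_smq_map(f), "non-narrow"), "outside"), "no members for 8")
  expect_equal(nrow(m), 1)
  expect_equal(m$smq_code, 20000239L)
  expect_false("some pt" %in% m$pt_norm)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("pt\tsmq_code\tsmq_name\tscope", f2)
  expect_warning(m2 <- read_smq_map(f2), "no members for 9")
  expect_equal(nrow(m2), 0)
})
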