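test_that("the shrunk ROR matches direct arithmetic on frozen tables", {
  # a = 10, b = 90, c = 100, d = 9900
  n_exp <- 100 * 110 / 10100
  expect_equal(shrunk_ror(10, 90, 100, 9900), 10.5 / (n_exp + 0.5))
  expect_equal(expected_count(10, 90, 100, 9900), n_exp)
  # observed equals expected -> exactly 1 (a=10, b=90, c=90, d=810)
  expect_equal(shrunk_ror(10, 90, 90, 810), 1)
  expect_equal(info_component(10, 90, 90, 810), 0)
  # empty margins shrink to the null
  expect_equal(shrunk_ror(0, 0, 0, 100), 1)
  expect_error(shrunk_ror(0, 0, 0, 0), "N_total = 0")
  expect_error(shrunk_ror(-1, 1, 1, 1), "non-negative")
})

test_that("IC is identically log2 of the shrunk ROR", {
  set.seed(4711)
  for (i in 1:200) {
    cells <- rpois(4, lambda = sample(c(0.5, 5, 50, 500), 4, TRUE))
    if (sum(cells) == 0) next
    expect_equal(info_component(cells[1], cells[2], cells[3], cells[4]),
                 log2(shrunk_ror(cells[1], cells[2], cells[3], cells[4])))
  }
  # and on reported three-decimal values the identity still holds
  expect_equal(round(log2(c(1.521, 1.262, 1.100)), 3), c(0.605, 0.336, 0.138))
})

test_that("IC interval brackets the point estimate and tightens with n", {
  ics <- c(-2, 0, 0.605, 3)
  ns <- c(1, 3, 10, 100, 5263, 1e6)
  for (ic in ics) {
    prev_width <- Inf
    for (n in ns) {
      ci <- ic_credible_interval(ic, n)
      expect_lt(ci$ic_025, ic)
      expect_gt(ci$ic_975, ic)
      width <- ci$ic_975 - ci$ic_025
      expect_lt(width, prev_width)
      prev_width <- width
    }
  }
  # width vanishes as the observed count grows
  ci <- ic_credible_interval(0.5, 1e10)
  expect_equal(ci$ic_025, 0.5, tolerance = 1e-4)
  expect_equal(ci$ic_975, 0.5, tolerance = 1e-4)
  expect_error(ic_credible_interval(0, -1), "non-negative")
})

test_that("Wald ROR interval matches the closed form and handles zero cells", {
  ci <- ror_wald_ci(10, 10, 10, 10)
  expect_equal(ci$ror_025, exp(-1.96 * sqrt(0.4)))
  expect_equal(ci$ror_975, exp(1.96 * sqrt(0.4)))
  # zero cell: bounds undefined, point estimate still defined via shrinkage
  ci0 <- ror_wald_ci(0, 10, 10, 10)
  expect_true(is.na(ci0$ror_025) && is.na(ci0$ror_975))
  expect_true(is.finite(shrunk_ror(0, 10, 10, 10)))
  # halving all cells widens the interval (on the log scale, around any point)
  set.seed(99)
  for (i in 1:50) {
    cells <- 2 * (1 + rpois(4, 20))
    wide <- ror_wald_ci(cells[1] / 2, cells[2] / 2, cells[3] / 2, cells[4] / 2)
    narrow <- ror_wald_ci(cells[1], cells[2], cells[3], cells[4])
    expect_gt(log(wide$ror_975 / wide$ror_025),
              log(narrow$ror_975 / narrow$ror_025))
  }
})

test_that("interval ordering holds whenever all cells are positive", {
  set.seed(123)
  for (i in 1:100) {
    cells <- 1 + rpois(4, sample(c(2, 20, 200), 4, TRUE))
    a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
    ror <- shrunk_ror(a, b, cc, d)
    rci <- ror_wald_ci(a, b, cc, d, ror = ror)
    expect_true(rci$ror_025 <= ror && ror <= rci$ror_975)
    ic <- info_component(a, b, cc, d)
    ici <- ic_credible_interval(ic, a)
    expect_true(ici$ic_025 < ic && ic < ici$ic_975)
  }
})

test_that("shrinkage pulls the estimate towards the null", {
  set.seed(55)
  for (i in 1:100) {
    cells <- rpois(4, sample(c(1, 10, 100), 4, TRUE))
    a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
    if (sum(cells) == 0) next
    n_exp <- expected_count(a, b, cc, d)
    if (a == 0 || n_exp == 0) next
    expect_lte(abs(log(shrunk_ror(a, b, cc, d))), abs(log(a / n_exp)) + 1e-12)
  }
})

test_that("the signal rule requires at least 3 reports and strict bounds", {
  # overwhelming disproportionality with 2 reports never flags
  f2 <- signal_flags(n_reports = 2, ror_025 = 50, ic_025 = 5)
  expect_false(f2$signal_by_ror)
  expect_false(f2$signal_by_ic)
  # 3 reports with positive lower IC bound flags under the IC criterion
  f3 <- signal_flags(n_reports = 3, ror_025 = 0.8, ic_025 = 0.2)
  expect_true(f3$signal_by_ic)
  expect_false(f3$signal_by_ror)
  # boundaries are strict; NA bounds never flag
  expect_false(signal_flags(10, ror_025 = 1, ic_025 = 0)$signal_by_ic)
  expect_false(signal_flags(10, ror_025 = 1, ic_025 = 0)$signal_by_ror)
  expect_false(signal_flags(10, ror_025 = NA, ic_025 = NA)$signal_by_ror)
  f <- signal_flags(5263, ror_025 = 1.478, ic_025 = 0.559)
  expect_true(f$signal_by_ror && f$signal_by_ic)
})

test_that("an event absent from both sides yields the shrinkage null", {
  sim <- tiny_sim(61)
  cohort <- build_test_cohort(sim)
  res <- disproportionality(cohort, "pt", events = "Kounis syndrome")
  expect_equal(res$a, rep(0L, 3))
  expect_equal(res$ror, rep(1, 3))
  expect_equal(res$ic, rep(0, 3))
  expect_false(any(res$signal_by_ic))
})

test_that("an empty comparator is an error", {
  sim <- tiny_sim(62, n = c(ICI_alone = 40, AGI_alone = 40,
                            combination = 20, neither = 0))
  cohort <- build_test_cohort(sim)
  expect_error(disproportionality(cohort, "overall"), "empty comparator")
})

test_that("the classic odds-ratio option differs from the shrunk estimate", {
  sim <- tiny_sim(63)
  cohort <- build_test_cohort(sim)
  shrunk <- disproportionality(cohort, "overall")
  classic <- disproportionality(cohort, "overall", estimate = "classic")
  expect_equal(classic$ror, (classic$a * classic$d) / (classic$b * classic$c))
  expect_false(isTRUE(all.equal(shrunk$ror, classic$ror)))
  # the IC stays the shrunk form either way
  expect_equal(classic$ic, shrunk$ic)
})

test_that("pipeline cells equal brute-force enumeration on a small batch", {
  sim <- tiny_sim(64, n = c(ICI_alone = 100, AGI_alone = 100,
                            combination = 50, neither = 400))
  cases <- clean_reports(sim$reports, pkg_archive())
  smq <- pkg_smq()
  cohort <- build_cohorts(cases, smq)
  res <- disproportionality(cohort, "smq", counting = "per_smq_once")
  lut <- smq
  for (i in sample(nrow(res), 6)) {
    member <- lut$pt[lut$smq_code == res$smq_code[i]]
    want <- brute_cells(cases, smq, res$exposure_group[i], member, once = TRUE)
    expect_equal(c(a = res$a[i], b = res$b[i], c = res$c[i], d = res$d[i]),
                 want, ignore_attr = TRUE)
  }
})
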