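# Frozen oracle values for the reference table a=10, b=90, c=100, d=9900,
# computed with the independent scalar implementation in helper-oracles.R.
ref_table <- tibble::tibble(a = 10L, b = 90L, c = 100L, d = 9900L)

test_that("disproportionality statistics match frozen oracle values", {
  r <- ror_stats(ref_table)
  expect_equal(r$ror, 11.0)
  expect_equal(r$ror025, 5.5595146, tolerance = 1e-6)
  expect_equal(r$ror975, 21.764485, tolerance = 1e-6)
  p <- prr_stats(ref_table)
  expect_equal(p$prr, 10.0)
  expect_equal(p$chi2_yates, 66.326943, tolerance = 1e-6)
  i <- ic_stats(ref_table)
  expect_equal(i$ic, 2.7240993, tolerance = 1e-6)
  expect_equal(i$ic025, 1.6351593, tolerance = 1e-6)
})

test_that("symmetric null tables give unit ratios and zero-centred IC", {
  null_tab <- tibble::tibble(a = 5L, b = 5L, c = 5L, d = 5L)
  expect_equal(ror_stats(null_tab)$ror, 1.0)
  expect_equal(prr_stats(null_tab)$prr, 1.0)
  expect_gte(prr_stats(null_tab)$chi2_yates, 0)  # Yates term floored
  # empty-event table: E = 0 and IC collapses to log2(0.5/0.5) = 0
  empty_ev <- tibble::tibble(a = 0L, b = 0L, c = 0L, d = 100L)
  expect_equal(ic_stats(empty_ev)$ic, 0)
})

test_that("zero cells flag ROR and PRR undefined instead of being patched", {
  z <- tibble::tibble(a = 3L, b = 0L, c = 2L, d = 5L)
  expect_true(is.na(ror_stats(z)$ror))
  z2 <- tibble::tibble(a = 3L, b = 4L, c = 0L, d = 5L)
  expect_true(is.na(prr_stats(z2)$prr))
  # degenerate comparator: c = d = 0
  z3 <- tibble::tibble(a = 3L, b = 4L, c = 0L, d = 0L)
  res <- judge_signal(z3)
  expect_false(res$is_signal)
  expect_match(res$failed_criteria, "ror025")
})

test_that("statistics agree with the brute-force oracle on random tables", {
  withr::with_seed(11, {
    tabs <- tibble::tibble(
      a = sample(0:50, 400, TRUE), b = sample(0:50, 400, TRUE),
      c = sample(0:50, 400, TRUE), d = sample(0:50, 400, TRUE)
    )
  })
  impl <- ic_stats(prr_stats(ror_stats(tabs)))
  for (i in seq_len(nrow(tabs))) {
    o <- brute_disprop(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    expect_equal(impl$ror[i], o$ror, tolerance = 1e-9)
    expect_equal(impl$prr[i], o$prr, tolerance = 1e-9)
    expect_equal(impl$chi2_yates[i], o$chi2, tolerance = 1e-9)
    expect_equal(impl$ic[i], o$ic, tolerance = 1e-9)
    expect_equal(impl$ic025[i], o$ic025, tolerance = 1e-9)
  }
})

test_that("transposition, scaling and monotonicity properties hold", {
  withr::with_seed(5, {
    tabs <- tibble::tibble(a = sample(1:50, 50, TRUE), b = sample(1:50, 50, TRUE),
                           c = sample(1:50, 50, TRUE), d = sample(1:50, 50, TRUE))
  })
  fwd <- ic_stats(prr_stats(ror_stats(tabs)))
  swp <- ror_stats(tibble::tibble(a = tabs$c, b = tabs$d, c = tabs$a, d = tabs$b))
  expect_equal(swp$ror, 1 / fwd$ror, tolerance = 1e-12)
  swp_chi <- prr_stats(tibble::tibble(a = tabs$c, b = tabs$d, c = tabs$a, d = tabs$b))
  expect_equal(swp_chi$chi2_yates, fwd$chi2_yates, tolerance = 1e-12)

  k <- 7L
  scl <- prr_stats(ror_stats(tibble::tibble(a = k * tabs$a, b = k * tabs$b,
                                            c = k * tabs$c, d = k * tabs$d)))
  expect_equal(scl$ror, fwd$ror, tolerance = 1e-12)
  expect_equal(scl$prr, fwd$prr, tolerance = 1e-12)
  expect_true(all(scl$chi2_yates >= fwd$chi2_yates - 1e-9))

  up <- ic_stats(prr_stats(ror_stats(dplyr::mutate(tabs, a = a + 1L))))
  expect_true(all(up$ror > fwd$ror))
  expect_true(all(up$prr > fwd$prr))
  # IC monotonicity holds in the surveillance regime (event counts small
  # against both margins, exposed arm a minority); it provably fails when
  # a dominates the event margin
  withr::with_seed(6, {
    rare <- tibble::tibble(a = sample(1:20, 50, TRUE), b = sample(500:2000, 50, TRUE),
                           c = sample(50:200, 50, TRUE), d = sample(500:2000, 50, TRUE))
  })
  expect_true(all(ic_stats(dplyr::mutate(rare, a = a + 1L))$ic >
                    ic_stats(rare)$ic))
})

test_that("the conjunction rule fires iff all five criteria hold", {
  # huge ROR but a = 2 fails the co-occurrence floor
  small_a <- judge_signal(tibble::tibble(a = 2L, b = 1L, c = 1L, d = 1000L))
  expect_false(small_a$is_signal)
  expect_match(small_a$failed_criteria, "\\ba\\b")
  # reference table passes everything
  expect_true(judge_signal(ref_table)$is_signal)
  # balanced null table fails
  expect_false(judge_signal(tibble::tibble(a = 5L, b = 5L, c = 5L, d = 5L))$is_signal)
})

test_that("the exact gamma-quantile IC variant orders consistently", {
  i_noren <- ic_stats(ref_table, variant = "noren")
  i_gamma <- ic_stats(ref_table, variant = "gamma")
  expect_equal(i_noren$ic, i_gamma$ic)  # point estimate shared
  expect_lt(i_gamma$ic025, i_gamma$ic)
  expect_equal(i_noren$ic025, i_gamma$ic025, tolerance = 0.1)
  # judge_signal consumes the selected variant
  expect_true(judge_signal(ref_table, ic_variant = "gamma")$is_signal)
})

test_that("contingency tables count each report once per cell", {
  cohort <- tibble::tibble(caseid = c("E1", "E2", "E3", "F1", "F2"),
                           arm = c(rep("ICI_Chemo", 3), rep("Only_Chemo", 2)))
  reactions <- tibble::tibble(
    caseid = c("E1", "E1", "E2", "F1"),  # E1 lists the PT twice
    pt = c("Seizure", "Seizure", "Seizure", "Seizure")
  )
  t1 <- build_contingency(cohort, reactions, "Seizure")
  expect_equal(t1$a, 2L)
  expect_equal(t1$b, 1L)
  expect_equal(t1$c, 1L)
  expect_equal(t1$d, 1L)
  # absent event -> a = c = 0 but a valid table
  t0 <- build_contingency(cohort, reactions, "Rash")
  expect_equal(c(t0$a, t0$c), c(0L, 0L))
})

test_that("detect_signals reproduces per-event tables over a small cohort", {
  cohort <- tibble::tibble(caseid = sprintf("S%02d", 1:10),
                           arm = rep(c("ICI_Chemo", "Only_Chemo"), each = 5))
  reactions <- tibble::tibble(
    caseid = c("S01", "S02", "S03", "S06", "S01", "S07"),
    pt = c("Seizure", "Seizure", "Seizure", "Seizure", "Rash", "Rash")
  )
  res <- detect_signals(cohort, reactions)
  sez <- res[res$event_pt == "Seizure", ]
  expect_equal(c(sez$a, sez$b, sez$c, sez$d), c(3L, 2L, 1L, 4L))
  expect_equal(nrow(res), 2L)
})
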