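tto_store <- function(event_dt, start_dt, partial_start = FALSE) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  demo <- demo_row("T1", event_dt = event_dt)
  drug <- data.frame(primaryid = "T11", caseid = "T1", drug_seq = "1",
                     role_cod = "PS", drugname = "NIVOLUMAB")
  reac <- data.frame(primaryid = "T11", caseid = "T1", pt = "Seizure")
  ther <- data.frame(primaryid = "T11", caseid = "T1", dsg_drug_seq = "1",
                     start_dt = start_dt)
  write_fixture_quarter(dir, demo, drug, reac, ther = ther)
  deduplicate_reports(read_faers_quarter(dir))
}

test_that("time to onset is plain date arithmetic from the earliest PS start", {
  rec <- compute_tto(tto_store("20200131", "20200101"))
  expect_equal(rec$tto_days, 30)
  expect_false(rec$imprecise)
})

test_that("negative intervals are excluded and partial dates flagged", {
  expect_message(rec <- compute_tto(tto_store("20191231", "20200101")),
                 "event date before therapy start")
  expect_equal(nrow(rec), 0L)
  # year-precision start completes to Jan 1 and flags the record
  rec2 <- compute_tto(tto_store("20200401", "2020"))
  expect_equal(rec2$tto_days, 91)
  expect_true(rec2$imprecise)
})

test_that("earliest vs latest therapy anchor is honoured", {
  dir <- withr::local_tempdir()
  demo <- demo_row("T2", event_dt = "20200301")
  drug <- data.frame(primaryid = rep("T21", 2), caseid = rep("T2", 2),
                     drug_seq = c("1", "2"), role_cod = c("PS", "PS"),
                     drugname = c("NIVOLUMAB", "TEMOZOLOMIDE"))
  reac <- data.frame(primaryid = "T21", caseid = "T2", pt = "Seizure")
  ther <- data.frame(primaryid = rep("T21", 2), caseid = rep("T2", 2),
                     dsg_drug_seq = c("1", "2"),
                     start_dt = c("20200101", "20200201"))
  write_fixture_quarter(dir, demo, drug, reac, ther = ther)
  store <- deduplicate_reports(read_faers_quarter(dir))
  expect_equal(compute_tto(store, anchor = "earliest")$tto_days, 60)
  expect_equal(compute_tto(store, anchor = "latest")$tto_days, 29)
})

test_that("identical groups test near the null, shifted groups reject", {
  withr::with_seed(21, {
    base <- rlnorm(50, log(40), 0.8)
    tto <- tibble::tibble(
      caseid = as.character(1:150),
      tto_days = c(base, base, base + 1000),
      imprecise = FALSE,
      grp = rep(c("g1", "g2", "g3"), each = 50)
    )
  })
  res <- compare_tto(tto, "grp")
  expect_equal(nrow(res), 3L)  # three pairwise comparisons
  same <- res[res$group1 == "g1" & res$group2 == "g2", ]
  expect_gt(same$p_value, 0.9)
  shifted <- res[res$group2 == "g3", ]
  expect_true(all(shifted$p_value < 0.01))
})

test_that("tiny groups are skipped and cdf export is a proper step function", {
  tto <- tibble::tibble(caseid = as.character(1:4),
                        tto_days = c(1, 2, 3, 4), imprecise = FALSE,
                        grp = c("a", "a", "a", "b"))
  expect_message(res <- compare_tto(tto, "grp"), "skipping")
  expect_true(is.na(res$p_value))
  cdf <- tto_cdf(tto, "grp")
  expect_equal(cdf$cdf[cdf$group == "a"], c(1, 2, 3) / 3)
  expect_true(all(cdf$cdf > 0 & cdf$cdf <= 1))
})

test_that("logistic fits match an independent reference optimizer", {
  withr::with_seed(33, {
    n <- 400
    x1 <- rnorm(n)
    x2 <- rbinom(n, 1, 0.4)
    eta <- -1 + 0.8 * x1 - 0.5 * x2
    y <- rbinom(n, 1, plogis(eta))
  })
  df <- tibble::tibble(y = y, x1 = x1, x2 = x2)
  fit <- fit_logistic(df, "y", c("x1", "x2"), model = "multi")
  est <- log(tidy(fit)$odds_ratio)
  ref <- oracle_logistic(cbind(1, x1, x2), y)
  expect_equal(est, ref[2:3], tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("null covariates cover OR = 1 and degenerate outcomes error", {
  withr::with_seed(99, {
    df <- tibble::tibble(y = rbinom(500, 1, 0.3), x = rnorm(500))
  })
  td <- tidy(fit_logistic(df, "y", "x", model = "uni"))
  expect_true(td$ci_low <= 1 && td$ci_high >= 1)
  expect_error(fit_logistic(tibble::tibble(y = rep(0L, 50), x = rnorm(50)),
                            "y", "x"), "degenerate")
  expect_error(fit_logistic(df[1:5, ], "y", "x"), "at least 10")
})

test_that("univariable mode fits one model per covariate", {
  withr::with_seed(13, {
    df <- tibble::tibble(y = rbinom(300, 1, 0.4), x1 = rnorm(300),
                         x2 = rnorm(300), x3 = rnorm(300))
  })
  fit <- fit_logistic(df, "y", c("x1", "x2", "x3"), model = "uni")
  expect_equal(nrow(tidy(fit)), 3L)
  expect_equal(glance(fit)$n_fits, 3L)
})

test_that("true odds ratios are recovered from a simulated cohort", {
  sim <- generate_faers(faers_sim_config(n_cases = 2000L, seed = 77))
  tr <- sim$manifest$truth
  tr <- tr[tr$age_group != "unknown", ]
  tr$age_group <- factor(tr$age_group, levels = c("<45", "45-64", ">64"))
  tr$arm <- factor(tr$arm, levels = c("ICI_Chemo", "Only_Chemo"))
  fit <- fit_logistic(tr, "death", c("age_group", "arm"), model = "multi")
  td <- tidy(fit)
  est <- td$odds_ratio[td$term == "age_group>64"]
  expect_gt(est, 2.0)
  expect_lt(est, 3.1)
})

test_that("the modelling table codes references as documented", {
  sim <- generate_faers(faers_sim_config(n_cases = 500L, seed = 3))
  cases <- standardize_drug_names(
    suppressMessages(deduplicate_reports(sim$quarters)),
    default_drug_name_map())
  coh <- suppressMessages(assign_cohort(cases, default_drug_class_map()))
  design <- prepare_logistic_data(coh, cases, "Autoimmune encephalitis")
  expect_setequal(levels(design$age_group), c("<45", "45-64", ">64"))
  expect_equal(levels(design$sex)[1], "female")
  expect_equal(levels(design$arm)[1], "ICI_Chemo")
  expect_true(all(design$death %in% 0:1))
})
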