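test_that("partial and malformed dates parse to earliest consistent day", {
  out <- parse_faers_date(c("20200131", "202002", "2021", "20200230", "junk", NA))
  expect_equal(out$date[1:3],
               as.Date(c("2020-01-31", "2020-02-01", "2021-01-01")))
  expect_equal(out$imprecise[1:3], c(FALSE, TRUE, TRUE))
  expect_true(all(is.na(out$date[4:6])))  # Feb 30 is not a calendar date
})

test_that("a quarter reads with counts preserved, roles kept, orphans dropped", {
  dir <- fixture_quarter_dir()
  q <- read_faers_quarter(dir)
  expect_s3_class(q, "faers_quarter")
  expect_equal(nrow(q$demo), 3L)
  expect_setequal(unique(q$drug$role_cod), "PS")
  expect_equal(sum(q$log$n_orphan), 0L)

  # a REAC row pointing at a primaryid absent from DEMO is dropped and logged
  reac_orphan <- rbind(q$reac, data.frame(primaryid = "ZZZ", caseid = "Z9",
                                          pt = "Rash"))
  dir2 <- withr::local_tempdir()
  write_fixture_quarter(dir2, demo = q$demo, drug = q$drug,
                        reac = reac_orphan, outc = q$outc, ther = q$ther,
                        indi = q$indi)
  expect_message(q2 <- read_faers_quarter(dir2), "absent from DEMO")
  expect_equal(nrow(q2$reac), nrow(q$reac))
  expect_equal(q2$log$n_orphan[q2$log$table == "reac"], 1L)
})

test_that("a missing mandatory file is a hard error naming the file", {
  dir <- fixture_quarter_dir()
  file.remove(file.path(dir, "outc.txt"))
  expect_error(read_faers_quarter(dir), "OUTC")
})

test_that("dedup keeps max caseversion, then latest receipt, then max primaryid", {
  demo <- rbind(
    demo_row("C1", primaryid = "C11", caseversion = "1", fda_dt = "20200101"),
    demo_row("C1", primaryid = "C12", caseversion = "2", fda_dt = "20200101"),
    demo_row("C2", primaryid = "C21", caseversion = "1", fda_dt = "20200101"),
    demo_row("C2", primaryid = "C22", caseversion = "1", fda_dt = "20200601"),
    demo_row("C3", primaryid = "C31", caseversion = "1", fda_dt = "20200101"),
    demo_row("C3", primaryid = "C35", caseversion = "1", fda_dt = "20200101")
  )
  reac <- data.frame(primaryid = demo$primaryid, caseid = demo$caseid,
                     pt = "Nausea")
  dir <- withr::local_tempdir()
  write_fixture_quarter(dir, demo, reac = reac)
  cases <- deduplicate_reports(read_faers_quarter(dir))
  expect_equal(nrow(cases$cases), 3L)
  winner <- setNames(cases$cases$primaryid, cases$cases$caseid)
  expect_equal(winner[["C1"]], "C12")  # higher version
  expect_equal(winner[["C2"]], "C22")  # later receipt
  expect_equal(winner[["C3"]], "C35")  # larger primaryid
})

test_that("deleted caseids never survive, under any quarter ordering", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_fixture_quarter(dir1, demo_row("D1"),
                        reac = data.frame(primaryid = "D11", caseid = "D1",
                                          pt = "Rash"))
  write_fixture_quarter(dir2, demo_row("D2"),
                        reac = data.frame(primaryid = "D21", caseid = "D2",
                                          pt = "Rash"),
                        deleted = "D1")
  q1 <- read_faers_quarter(dir1); q2 <- read_faers_quarter(dir2)
  for (quarters in list(list(q1, q2), list(q2, q1))) {
    cases <- deduplicate_reports(quarters)
    expect_equal(cases$cases$caseid, "D2")
  }
})

test_that("dedup is idempotent and preserves all-unique inputs", {
  dir <- fixture_quarter_dir()
  q <- read_faers_quarter(dir)
  cases <- deduplicate_reports(q)
  expect_equal(nrow(cases$cases), 3L)  # all caseids unique
  # re-deduplicating the already-normalized store is a fixed point: rebuild
  # a quarter from the store and dedup again
  cases2 <- deduplicate_reports(list(q, q))
  expect_equal(cases2$cases, cases$cases)
  expect_equal(deduplicate_reports(list()), deduplicate_reports(list()))
})

test_that("drug name standardization folds case, whitespace and trailing dots", {
  dir <- fixture_quarter_dir()
  cases <- deduplicate_reports(read_faers_quarter(dir))
  map <- data.frame(verbatim = c("nivolumab", "OPDIVO", "temozolomide", "Temodar"),
                    standard = c("nivolumab", "nivolumab", "temozolomide",
                                 "temozolomide"))
  std <- standardize_drug_names(cases, map)
  expect_setequal(std$drugs$standardized_name, c("nivolumab", "temozolomide"))
  cov <- attr(std, "drug_name_coverage")
  expect_true(all(cov$matched))

  # unmatched names pass through verbatim and are flagged in the coverage report
  map_small <- data.frame(verbatim = "nivolumab", standard = "nivolumab")
  std2 <- standardize_drug_names(cases, map_small)
  expect_true("TEMOZOLOMIDE" %in% std2$drugs$standardized_name)
  cov2 <- attr(std2, "drug_name_coverage")
  expect_false(all(cov2$matched))
  expect_warning(standardize_drug_names(cases, data.frame()), "empty")
})

test_that("case store round-trips through the JSON-lines sidecar", {
  dir <- fixture_quarter_dir()
  cases <- standardize_drug_names(deduplicate_reports(read_faers_quarter(dir)),
                                  default_drug_name_map())
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_case_store(cases, path)
  back <- read_case_store(path)
  for (part in c("cases", "drugs", "reactions", "outcomes", "therapies",
                 "indications")) {
    expect_equal(as.data.frame(back[[part]]), as.data.frame(cases[[part]]),
                 info = part)
  }
})
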