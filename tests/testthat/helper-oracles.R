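# Independent scalar oracles and tiny fixture builders used across tests.

# Brute-force disproportionality statistics for a single 2x2 table,
# written as plain scalar arithmetic in log space, independent of the
# vectorised implementation under test.
brute_disprop <- function(a, b, c, d) {
  n <- a + b + c + d
  out <- list(ror = NA_real_, ror025 = NA_real_, ror975 = NA_real_,
              prr = NA_real_, chi2 = NA_real_, ic = NA_real_, ic025 = NA_real_)
  if (a > 0 && b > 0 && c > 0 && d > 0) {
    lr <- log(a) + log(d) - log(b) - log(c)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    out$ror <- exp(lr)
    out$ror025 <- exp(lr - 1.96 * se)
    out$ror975 <- exp(lr + 1.96 * se)
  }
  if ((a + b) > 0 && (c + d) > 0 && c > 0) {
    out$prr <- (a / (a + b)) / (c / (c + d))
  }
  if ((a + b) > 0 && (c + d) > 0 && (a + c) > 0 && (b + d) > 0) {
    yates <- abs(a * d - b * c) - n / 2
    if (yates < 0) yates <- 0
    out$chi2 <- n * yates * yates /
      ((a + b) * (c + d) * (a + c) * (b + d))
  }
  if (n > 0) {
    e <- (a + b) * (a + c) / n
    out$ic <- log((a + 0.5) / (e + 0.5)) / log(2)
    out$ic025 <- out$ic - 3.3 / sqrt(a + 0.5) - 2.4 / (a + 0.5)^1.5
  }
  out
}

# Naive double-loop ssGSEA for one sample and one gene set: ranks genes,
# walks the ordered list position by position.
brute_ssgsea <- function(expr_vec, set_genes, tau = 0.25) {
  genes <- names(expr_vec)
  r <- rank(expr_vec, ties.method = "average")
  ord <- order(r, decreasing = TRUE)
  inset <- genes[ord] %in% set_genes
  n <- length(genes)
  m <- sum(inset)
  denom_in <- 0
  for (i in seq_len(n)) if (inset[i]) denom_in <- denom_in + r[ord][i]^tau
  score <- 0
  cum_in <- 0
  cum_out <- 0
  for (i in seq_len(n)) {
    if (inset[i]) cum_in <- cum_in + r[ord][i]^tau else cum_out <- cum_out + 1
    score <- score + (cum_in / denom_in - cum_out / (n - m))
  }
  unname(score)
}

# Exhaustive running-sum enrichment score (weight w) by hand.
brute_es <- function(stats_vec, set_genes, w = 1) {
  ord <- order(stats_vec, decreasing = TRUE)
  s <- stats_vec[ord]
  inset <- names(s) %in% set_genes
  n <- length(s)
  m <- sum(inset)
  denom <- sum(abs(s[inset])^w)
  run <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    acc <- if (inset[i]) acc + abs(s[i])^w / denom else acc - 1 / (n - m)
    run[i] <- acc
  }
  unname(run[which.max(abs(run))])
}

# Direct maximum-likelihood logistic fit through optim(), as an
# independent reference optimizer.
oracle_logistic <- function(X, y) {
  nll <- function(beta) {
    eta <- as.numeric(X %*% beta)
    -sum(y * eta - log1p(exp(eta)))
  }
  optim(rep(0, ncol(X)), nll, method = "BFGS",
        control = list(maxit = 1000, reltol = 1e-14))$par
}

# Write a minimal FAERS-style quarter to a directory; `rows` is a named
# list of data frames overriding the defaults.
write_fixture_quarter <- function(dir, demo, drug = NULL, reac = NULL,
                                  outc = NULL, ther = NULL, indi = NULL,
                                  deleted = character(0)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  empty <- list(
    drug = data.frame(primaryid = character(), caseid = character(),
                      drug_seq = character(), role_cod = character(),
                      drugname = character()),
    reac = data.frame(primaryid = character(), caseid = character(),
                      pt = character()),
    outc = data.frame(primaryid = character(), caseid = character(),
                      outc_cod = character()),
    ther = data.frame(primaryid = character(), caseid = character(),
                      dsg_drug_seq = character(), start_dt = character()),
    indi = data.frame(primaryid = character(), caseid = character(),
                      indi_drug_seq = character(), indi_pt = character())
  )
  or_empty <- function(x, nm) if (is.null(x)) empty[[nm]] else x
  tabs <- list(demo = demo, drug = or_empty(drug, "drug"),
               reac = or_empty(reac, "reac"), outc = or_empty(outc, "outc"),
               ther = or_empty(ther, "ther"), indi = or_empty(indi, "indi"))
  for (nm in names(tabs)) {
    readr::write_delim(tabs[[nm]], file.path(dir, paste0(nm, ".txt")), delim = "$")
  }
  writeLines(deleted, file.path(dir, "deleted.txt"))
  dir
}

demo_row <- function(caseid, primaryid = paste0(caseid, "1"),
                     caseversion = "1", fda_dt = "20200301",
                     event_dt = "20200201", age = "60", age_cod = "YR",
                     sex = "M") {
  data.frame(primaryid = primaryid, caseid = caseid,
             caseversion = caseversion, fda_dt = fda_dt,
             event_dt = event_dt, age = age, age_cod = age_cod, sex = sex)
}

# Three-case quarter: two ICI_Chemo (one with the target PT), one chemo-only.
fixture_quarter_dir <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  demo <- rbind(demo_row("A1"), demo_row("A2", age = "40"),
                demo_row("A3", sex = "F"))
  drug <- data.frame(
    primaryid = c("A11", "A11", "A21", "A21", "A31"),
    caseid = c("A1", "A1", "A2", "A2", "A3"),
    drug_seq = c("1", "2", "1", "2", "1"),
    role_cod = c("PS", "PS", "PS", "PS", "PS"),
    drugname = c("NIVOLUMAB.", "TEMOZOLOMIDE", "Opdivo ", "TEMODAR",
                 "temozolomide")
  )
  reac <- data.frame(
    primaryid = c("A11", "A11", "A21", "A31"),
    caseid = c("A1", "A1", "A2", "A3"),
    pt = c("Seizure", "Nausea", "Nausea", "Nausea")
  )
  ther <- data.frame(primaryid = c("A11", "A21", "A31"),
                     caseid = c("A1", "A2", "A3"),
                     dsg_drug_seq = c("1", "1", "1"),
                     start_dt = c("20200101", "20200101", "2020"))
  indi <- data.frame(primaryid = c("A11", "A21", "A31"),
                     caseid = c("A1", "A2", "A3"),
                     indi_drug_seq = c("1", "1", "1"),
                     indi_pt = c("Glioblastoma", "Glioma", "Astrocytoma"))
  outc <- data.frame(primaryid = "A11", caseid = "A1", outc_cod = "DE")
  write_fixture_quarter(dir, demo, drug, reac, outc, ther, indi)
}

# Build a minimal in-memory case store around a drugs tibble (columns
# caseid, drug_seq, role, std); every case gets one reaction so the store
# satisfies the non-empty-reactions invariant.
empty_case_store_for_test <- function(drugs) {
  ids <- unique(drugs$caseid)
  structure(list(
    cases = tibble::tibble(caseid = ids, caseversion = 1L,
                           primaryid = paste0(ids, "1"),
                           receipt_date = as.Date("2020-03-01"),
                           event_date = as.Date("2020-02-01"),
                           event_imprecise = FALSE, age = 60, sex = "male"),
    drugs = tibble::tibble(caseid = drugs$caseid, drug_seq = drugs$drug_seq,
                           role = drugs$role, verbatim_name = drugs$std,
                           standardized_name = drugs$std),
    reactions = tibble::tibble(caseid = ids, pt = "Nausea"),
    outcomes = tibble::tibble(caseid = character(), code = character()),
    therapies = tibble::tibble(caseid = character(), drug_seq = character(),
                               start_date = as.Date(character()),
                               imprecise = logical()),
    indications = tibble::tibble(caseid = drugs$caseid,
                                 drug_seq = drugs$drug_seq,
                                 term = "Glioblastoma"),
    log = NULL
  ), class = "faers_cases")
}
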