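# Seeded generator of FAERS-like quarterly files with known ground truth.
#
# The generator emulates the structure of the real quarterly extracts — six
# "$"-delimited tables plus a Deleted-case list — for a two-arm cohort of
# nervous-system-cancer reports (checkpoint inhibitor + chemotherapy vs
# chemotherapy only). Event probabilities are planted on the odds scale so
# the true reporting odds ratio of each planted preferred term is exact by
# construction, and every planted quantity is recorded in a manifest.

#' Packaged default drug name, class and indication lookup tables
#'
#' Small plain-text lookups shipped with the package: verbatim-to-standard
#' drug names (trade and generic spellings), standardized-name-to-class
#' (PD1 / PDL1 / CTLA4 / CHEMO / OTHER), and indication term to high-level
#' group term, standing in for the licensed MedDRA hierarchy.
#'
#' @return A tibble.
#' @export
default_drug_name_map <- function() {
  readr::read_csv(system.file("extdata", "drug_name_map.csv",
                              package = "iraesignal"),
                  show_col_types = FALSE)
}

#' @rdname default_drug_name_map
#' @export
default_drug_class_map <- function() {
  readr::read_csv(system.file("extdata", "drug_class_map.csv",
                              package = "iraesignal"),
                  show_col_types = FALSE)
}

#' @rdname default_drug_name_map
#' @export
default_indication_lookup <- function() {
  readr::read_csv(system.file("extdata", "indication_hlgt.csv",
                              package = "iraesignal"),
                  show_col_types = FALSE)
}

#' Target high-level group term for the nervous-system-cancer cohort
#' @return Character scalar.
#' @export
nsc_target_hlgt <- function() {
  "Nervous system neoplasms malignant and unspecified NEC"
}

default_background_events <- function() {
  tibble::tibble(
    pt = c("Nausea", "Vomiting", "Fatigue", "Headache", "Pyrexia",
           "Anaemia", "Thrombocytopenia", "Neutropenia", "Constipation",
           "Decreased appetite", "Dizziness", "Rash", "Diarrhoea",
           "Oedema peripheral", "Insomnia", "Pain", "Dyspnoea",
           "Cough", "Asthenia", "Malignant neoplasm progression"),
    prob = c(0.14, 0.09, 0.12, 0.10, 0.07, 0.06, 0.05, 0.05, 0.04,
             0.04, 0.04, 0.03, 0.05, 0.02, 0.02, 0.03, 0.02, 0.01,
             0.01, 0.01)
  )
}

#' Configuration for the synthetic FAERS generator
#'
#' Defaults describe the emulated study conditions: a two-arm
#' nervous-system-cancer cohort with one planted immune-related event at
#' true reporting odds ratio 10 sized to an expected co-occurrence count
#' of about 30, background events drawn per report as Poisson(2) extra
#' preferred terms, death risk driven by age and regimen on the odds
#' scale, log-normal time-to-onset by age group, and report duplication /
#' deletion at realistic FAERS rates. Checkpoint-inhibitor regimens form
#' a 10% minority of reports: immunotherapy is rare in nervous-system
#' cancer, and the exposed fraction caps the information component at
#' `log2(1/fraction)` — a balanced 50/50 split would make `IC025 > 1`
#' unattainable for any event, however disproportionate.
#'
#' @param n_cases number of distinct cases before duplication/deletion.
#' @param seed mandatory RNG seed.
#' @param arm_fractions named fractions for `ICI_Chemo` / `Only_Chemo`.
#' @param regimen_mix named fractions over ICI regimens (within the ICI arm).
#' @param planted_events tibble (`pt`, `baseline_prob`, `true_ror`):
#'   comparator-arm report probability and the planted odds ratio
#'   `odds(p_exposed)/odds(p_comparator)`.
#' @param background_events tibble (`pt`, `prob`) sampled as extra terms.
#' @param background_lambda Poisson mean of extra background terms.
#' @param age_mean,age_sd,age_missing_rate age model (years).
#' @param death_base_prob death probability in the reference stratum
#'   (age `<45`, `ICI_Chemo`).
#' @param death_or_age45_64,death_or_age_gt64,death_or_only_chemo true
#'   odds ratios of the death model.
#' @param tto_meanlog named log-scale TTO means per age group (days);
#'   `tto_sdlog` the common log-sd.
#' @param tto_sdlog log-sd of TTO.
#' @param duplicate_rate fraction of cases re-submitted as a later version.
#' @param deleted_rate fraction of cases listed in the Deleted file.
#' @param off_indication_rate fraction of cases with a non-target
#'   indication (exercise the indication filter).
#' @param partial_date_rate fraction of therapy start dates emitted with
#'   month precision only.
#' @param name_noise_rate fraction of drug rows with verbatim spelling
#'   noise (case, whitespace, trailing punctuation, trade names).
#' @param n_quarters number of quarterly files the cases are spread over.
#' @return A list of class `faers_sim_config`.
#' @export
faers_sim_config <- function(
    n_cases = 5000L,
    seed,
    arm_fractions = c(ICI_Chemo = 0.10, Only_Chemo = 0.90),
    regimen_mix = c(PD1_Chemo = 0.45, PDL1_Chemo = 0.20, CTLA4_Chemo = 0.15,
                    PD1_CTLA4_Chemo = 0.12, `Combined-ICI_Chemo` = 0.08),
    planted_events = tibble::tibble(pt = "Autoimmune encephalitis",
                                    baseline_prob = 0.0068,
                                    true_ror = 10),
    background_events = default_background_events(),
    background_lambda = 2,
    age_mean = 58, age_sd = 16, age_missing_rate = 0.05,
    death_base_prob = 0.12,
    death_or_age45_64 = 1.5, death_or_age_gt64 = 2.5,
    death_or_only_chemo = 2.0,
    tto_meanlog = c(`<45` = log(40), `45-64` = log(90), `>64` = log(45)),
    tto_sdlog = 0.8,
    duplicate_rate = 0.10,
    deleted_rate = 0.02,
    off_indication_rate = 0.05,
    partial_date_rate = 0.03,
    name_noise_rate = 0.30,
    n_quarters = 1L) {
  if (missing(seed)) abort("seed is mandatory for the synthetic generator")
  stopifnot(n_cases >= 1, abs(sum(arm_fractions) - 1) < 1e-8,
            abs(sum(regimen_mix) - 1) < 1e-8,
            all(planted_events$baseline_prob > 0 & planted_events$baseline_prob < 1),
            all(planted_events$true_ror > 0),
            all(dplyr::between(c(duplicate_rate, deleted_rate,
                                 off_indication_rate, partial_date_rate,
                                 name_noise_rate), 0, 1)))
  p0 <- planted_events$baseline_prob
  odds1 <- planted_events$true_ror * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  if (any(p1 > 0.99)) {
    abort("infeasible planted odds: exposed reporting probability exceeds 0.99")
  }
  planted_events$p_exposed <- p1
  cfg <- list(
    n_cases = as.integer(n_cases), seed = as.integer(seed),
    arm_fractions = arm_fractions, regimen_mix = regimen_mix,
    planted_events = planted_events, background_events = background_events,
    background_lambda = background_lambda,
    age_mean = age_mean, age_sd = age_sd, age_missing_rate = age_missing_rate,
    death_base_prob = death_base_prob,
    death_or_age45_64 = death_or_age45_64,
    death_or_age_gt64 = death_or_age_gt64,
    death_or_only_chemo = death_or_only_chemo,
    tto_meanlog = tto_meanlog, tto_sdlog = tto_sdlog,
    duplicate_rate = duplicate_rate, deleted_rate = deleted_rate,
    off_indication_rate = off_indication_rate,
    partial_date_rate = partial_date_rate,
    name_noise_rate = name_noise_rate,
    n_quarters = as.integer(n_quarters)
  )
  structure(cfg, class = "faers_sim_config")
}

regimen_drugs <- list(
  PD1_Chemo = "nivolumab",
  PDL1_Chemo = "atezolizumab",
  CTLA4_Chemo = "ipilimumab",
  PD1_CTLA4_Chemo = c("nivolumab", "ipilimumab"),
  `Combined-ICI_Chemo` = c("atezolizumab", "tremelimumab")
)

trade_names <- c(nivolumab = "Opdivo", pembrolizumab = "Keytruda",
                 atezolizumab = "Tecentriq", ipilimumab = "Yervoy",
                 durvalumab = "Imfinzi", temozolomide = "Temodar")

noisy_name <- function(std, noise) {
  out <- toupper(std)
  n <- length(out)
  style <- ifelse(noise, sample(c("trade", "dot", "space", "lower"), n, replace = TRUE), "none")
  has_trade <- std %in% names(trade_names)
  out[style == "trade" & has_trade] <- toupper(trade_names[std[style == "trade" & has_trade]])
  out[style == "dot"] <- paste0(out[style == "dot"], ".")
  out[style == "space"] <- paste0(" ", out[style == "space"], " ")
  out[style == "lower"] <- std[style == "lower"]
  out
}

date_to_faers <- function(d, partial = rep(FALSE, length(d))) {
  out <- format(d, "%Y%m%d")
  out[partial] <- format(d[partial], "%Y%m")
  out
}

#' Generate synthetic FAERS quarters with a ground-truth manifest
#'
#' @param config a [faers_sim_config()].
#' @return An object of class `faers_sim`: `quarters` (a list of
#'   `faers_quarter` objects ready for [deduplicate_reports()]),
#'   `manifest` (every planted quantity: planted events with exact
#'   exposed/comparator probabilities, per-case true arms, death-model
#'   odds ratios, TTO parameters, unique retained caseids), and the
#'   `config`.
#' @export
generate_faers <- function(config) {
  stopifnot(inherits(config, "faers_sim_config"))
  withr::with_seed(config$seed, generate_faers_impl(config))
}

generate_faers_impl <- function(config) {
  n <- config$n_cases
  caseid <- sprintf("C%07d", seq_len(n))
  arm <- sample(names(config$arm_fractions), n, replace = TRUE,
                prob = config$arm_fractions)
  regimen <- ifelse(arm == "Only_Chemo", "Only_Chemo",
                    sample(names(config$regimen_mix), n, replace = TRUE,
                           prob = config$regimen_mix))
  age <- pmin(pmax(rnorm(n, config$age_mean, config$age_sd), 18), 95)
  age[runif(n) < config$age_missing_rate] <- NA_real_
  age_group <- assign_age_group(age)
  sex <- sample(c("M", "F", "UNK"), n, replace = TRUE, prob = c(0.54, 0.44, 0.02))
  off_ind <- runif(n) < config$off_indication_rate
  target_inds <- c("Glioblastoma", "Glioma", "Astrocytoma", "Neuroblastoma",
                   "Brain neoplasm")
  indication <- ifelse(off_ind, "Melanoma",
                       sample(target_inds, n, replace = TRUE,
                              prob = c(0.35, 0.25, 0.15, 0.15, 0.10)))

  # death model on the odds scale
  lo <- log(config$death_base_prob / (1 - config$death_base_prob)) +
    log(config$death_or_age45_64) * (!is.na(age) & age_group == "45-64") +
    log(config$death_or_age_gt64) * (!is.na(age) & age_group == ">64") +
    log(config$death_or_only_chemo) * (arm == "Only_Chemo")
  death <- rbinom(n, 1L, stats::plogis(lo)) == 1L

  # therapy start, time to onset, receipt
  start <- as.Date("2013-01-01") + floor(runif(n, 0, 3652))
  ml <- config$tto_meanlog[as.character(age_group)]
  ml[is.na(ml)] <- mean(config$tto_meanlog)
  tto <- round(rlnorm(n, meanlog = ml, sdlog = config$tto_sdlog))
  event <- start + tto
  receipt <- event + floor(runif(n, 10, 100))

  # reactions: planted events per arm on the exact planted odds, plus
  # Poisson background terms shared across arms
  exposed <- arm == "ICI_Chemo"
  planted <- purrr::pmap_dfr(config$planted_events,
    function(pt, baseline_prob, true_ror, p_exposed) {
      p <- ifelse(exposed, p_exposed, baseline_prob)
      hit <- runif(n) < p
      tibble::tibble(caseid = caseid[hit], pt = pt)
    })
  n_bg <- rpois(n, config$background_lambda)
  need <- n_bg == 0 & !caseid %in% planted$caseid
  n_bg[need] <- 1L  # a report must report something
  bg <- tibble::tibble(
    caseid = rep(caseid, n_bg),
    pt = sample(config$background_events$pt, sum(n_bg), replace = TRUE,
                prob = config$background_events$prob)
  )
  reac <- dplyr::distinct(dplyr::bind_rows(planted, bg))

  # drugs: PS checkpoint inhibitor(s) per regimen + PS chemotherapy,
  # one concomitant row for realism
  ici <- regimen_drugs[regimen]
  ici[arm == "Only_Chemo"] <- list(character(0))
  drug_rows <- tibble::tibble(
    caseid = rep(caseid, lengths(ici) + 2L),
    std = unlist(purrr::map2(ici, seq_len(n), ~ c(.x, "temozolomide", "dexamethasone"))),
    role = unlist(purrr::map(lengths(ici), ~ c(rep("PS", .x + 1L), "C")))
  ) |>
    dplyr::mutate(drug_seq = as.character(stats::ave(rep(1L, dplyr::n()),
                                                     .data$caseid, FUN = seq_along)))
  drug_rows$drugname <- noisy_name(drug_rows$std,
                                   runif(nrow(drug_rows)) < config$name_noise_rate)

  ps_rows <- dplyr::filter(drug_rows, .data$role == "PS")
  start_of <- setNames(start, caseid)
  partial <- runif(nrow(ps_rows)) < config$partial_date_rate
  ther <- tibble::tibble(
    caseid = ps_rows$caseid,
    dsg_drug_seq = ps_rows$drug_seq,
    start_dt = date_to_faers(start_of[ps_rows$caseid], partial)
  )
  ind_of <- setNames(indication, caseid)
  indi <- tibble::tibble(
    caseid = ps_rows$caseid,
    indi_drug_seq = ps_rows$drug_seq,
    indi_pt = ind_of[ps_rows$caseid]
  )
  outc <- tibble::tibble(caseid = caseid[death], outc_cod = "DE")

  # versions: everyone has version 1; a duplicated subset is re-submitted
  # later as version 2 under a new primaryid
  dup <- runif(n) < config$duplicate_rate
  demo1 <- tibble::tibble(
    caseid = caseid, caseversion = "1",
    primaryid = paste0(caseid, "1"),
    fda_dt = date_to_faers(receipt),
    event_dt = date_to_faers(event),
    age = ifelse(is.na(age), "", as.character(round(age))),
    age_cod = ifelse(is.na(age), "", "YR"),
    sex = sex
  )
  demo2 <- demo1[dup, ] |>
    dplyr::mutate(caseversion = "2",
                  primaryid = paste0(.data$caseid, "2"),
                  fda_dt = date_to_faers(receipt[dup] + 45))
  demo <- dplyr::bind_rows(demo1, demo2)

  with_pid <- function(tb) {
    v1 <- dplyr::mutate(tb, primaryid = paste0(.data$caseid, "1"))
    v2 <- dplyr::mutate(tb[tb$caseid %in% caseid[dup], ],
                        primaryid = paste0(.data$caseid, "2"))
    dplyr::bind_rows(v1, v2)
  }
  drug_tb <- with_pid(dplyr::select(drug_rows, "caseid", "drug_seq",
                                    "role_cod" = "role", "drugname"))
  reac_tb <- with_pid(dplyr::rename(reac, pt = "pt"))
  outc_tb <- with_pid(outc)
  ther_tb <- with_pid(ther)
  indi_tb <- with_pid(indi)

  deleted <- caseid[runif(n) < config$deleted_rate]

  # spread demo versions over quarters; child rows follow their primaryid
  qs <- paste0("q", seq_len(config$n_quarters))
  q_of <- setNames(sample(qs, nrow(demo), replace = TRUE), demo$primaryid)
  order_cols <- function(tb, table) dplyr::select(tb, dplyr::all_of(faers_required_cols[[table]]))
  quarters <- purrr::map(qs, function(q) {
    ids <- demo$primaryid[q_of[demo$primaryid] == q]
    structure(list(
      demo = order_cols(demo[demo$primaryid %in% ids, ], "demo"),
      drug = order_cols(drug_tb[drug_tb$primaryid %in% ids, ], "drug"),
      reac = order_cols(reac_tb[reac_tb$primaryid %in% ids, ], "reac"),
      outc = order_cols(outc_tb[outc_tb$primaryid %in% ids, ], "outc"),
      ther = order_cols(ther_tb[ther_tb$primaryid %in% ids, ], "ther"),
      indi = order_cols(indi_tb[indi_tb$primaryid %in% ids, ], "indi"),
      deleted = if (q == qs[[1]]) deleted else character(0),
      log = NULL
    ), class = "faers_quarter")
  })
  names(quarters) <- qs

  manifest <- list(
    seed = config$seed,
    n_cases = n,
    planted_events = config$planted_events,
    unique_caseids = setdiff(caseid, deleted),
    deleted_caseids = deleted,
    truth = tibble::tibble(caseid = caseid, arm = arm, regimen = regimen,
                           age = age, age_group = as.character(age_group),
                           sex = sex, indication = indication,
                           death = death, tto_days = as.numeric(tto),
                           duplicated = dup, deleted = caseid %in% deleted),
    death_model = list(base_prob = config$death_base_prob,
                       or_age45_64 = config$death_or_age45_64,
                       or_age_gt64 = config$death_or_age_gt64,
                       or_only_chemo = config$death_or_only_chemo),
    tto_model = list(meanlog = as.list(config$tto_meanlog),
                     sdlog = config$tto_sdlog)
  )
  structure(list(quarters = quarters, manifest = manifest, config = config),
            class = "faers_sim")
}

#' @export
print.faers_sim <- function(x, ...) {
  cat("<faers_sim> ", x$manifest$n_cases, " cases over ",
      length(x$quarters), " quarter(s); ",
      nrow(x$manifest$planted_events), " planted event(s)\n", sep = "")
  invisible(x)
}

#' Write a synthetic FAERS simulation to disk
#'
#' One subdirectory per quarter holding the six "$"-delimited tables and
#' (first quarter) the Deleted list, plus `manifest.json` at the top
#' level. The files are byte-identical across runs with the same config.
#'
#' @param sim a `faers_sim` from [generate_faers()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_faers_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "faers_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (q in names(sim$quarters)) {
    qd <- file.path(dir, q)
    dir.create(qd, showWarnings = FALSE)
    qt <- sim$quarters[[q]]
    for (tb in faers_tables) {
      readr::write_delim(qt[[tb]], file.path(qd, paste0(tb, ".txt")), delim = "$")
    }
    readr::write_lines(qt$deleted, file.path(qd, "deleted.txt"))
  }
  manifest <- sim$manifest
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, na = "null", digits = NA,
                       dataframe = "rows")
  invisible(dir)
}

#' Read a written simulation's quarters back through the standard reader
#'
#' @param dir directory written by [write_faers_sim()].
#' @param dialect a [faers_dialect()].
#' @return List of `faers_quarter` objects.
#' @export
read_faers_sim <- function(dir, dialect = faers_dialect()) {
  qdirs <- list.dirs(dir, recursive = FALSE)
  purrr::map(setNames(qdirs, basename(qdirs)), read_faers_quarter,
             dialect = dialect)
}
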