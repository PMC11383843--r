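# Reading, cleaning and deduplicating FAERS-style quarterly ASCII files.
#
# The FDA distributes each quarter as six "$"-delimited tables sharing the
# (primaryid, caseid) key: DEMO (demographics/administrative), DRUG (one row
# per reported drug with a role code), REAC (MedDRA preferred terms), OUTC
# (outcome codes), THER (therapy start dates) and INDI (indications). A
# separate Deleted file lists caseids withdrawn by the FDA.

#' File dialect for FAERS-style quarterly ASCII tables
#'
#' @param delim field delimiter (FDA distribution uses `"$"`).
#' @param header logical; whether the files carry a header line.
#' @return A list of class `faers_dialect`.
#' @export
faers_dialect <- function(delim = "$", header = TRUE) {
  structure(list(delim = delim, header = header), class = "faers_dialect")
}

faers_tables <- c("demo", "drug", "reac", "outc", "ther", "indi")

faers_required_cols <- list(
  demo = c("primaryid", "caseid", "caseversion", "fda_dt", "event_dt",
           "age", "age_cod", "sex"),
  drug = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname"),
  reac = c("primaryid", "caseid", "pt"),
  outc = c("primaryid", "caseid", "outc_cod"),
  ther = c("primaryid", "caseid", "dsg_drug_seq", "start_dt"),
  indi = c("primaryid", "caseid", "indi_drug_seq", "indi_pt")
)

locate_faers_file <- function(dir_path, table) {
  hits <- list.files(dir_path, pattern = paste0("^", table, ".*\\.(txt|TXT)$"),
                     ignore.case = TRUE, full.names = TRUE)
  if (length(hits) == 0L) return(NA_character_)
  sort(hits)[1L]
}

read_faers_table <- function(path, table, dialect) {
  raw <- readr::read_delim(
    path, delim = dialect$delim,
    col_names = dialect$header,
    col_types = readr::cols(.default = readr::col_character()),
    trim_ws = TRUE, progress = FALSE, show_col_types = FALSE
  )
  if (!dialect$header) names(raw) <- faers_required_cols[[table]][seq_along(raw)]
  names(raw) <- stringr::str_to_lower(names(raw))
  missing <- setdiff(faers_required_cols[[table]], names(raw))
  if (length(missing) > 0L) {
    abort(sprintf("%s file '%s' lacks required column(s): %s",
                  toupper(table), basename(path), paste(missing, collapse = ", ")))
  }
  n_malformed <- nrow(readr::problems(raw))
  raw <- dplyr::select(raw, dplyr::all_of(faers_required_cols[[table]]))
  attr(raw, "n_malformed") <- n_malformed
  raw
}

#' Read one FAERS-style quarter from a directory
#'
#' Looks for the six mandatory tables (files named `demo*.txt`,
#' `drug*.txt`, ... case-insensitively) plus an optional `deleted*.txt`
#' holding one withdrawn caseid per line. Rows of non-DEMO tables whose
#' `primaryid` does not appear in DEMO violate referential integrity; they
#' are dropped and counted in the quarter's cleaning log rather than
#' aborting the read. Unparseable dates are kept as missing fields.
#'
#' @param dir_path directory containing the quarter's files.
#' @param dialect a [faers_dialect()].
#' @return An object of class `faers_quarter`: a list with the six raw
#'   tibbles, the `deleted` caseid character vector, and a `log` tibble of
#'   per-table malformed/orphan row counts.
#' @export
read_faers_quarter <- function(dir_path, dialect = faers_dialect()) {
  stopifnot(inherits(dialect, "faers_dialect"))
  if (!dir.exists(dir_path)) abort(sprintf("directory '%s' does not exist", dir_path))
  paths <- setNames(vapply(faers_tables, locate_faers_file, character(1),
                           dir_path = dir_path), faers_tables)
  if (anyNA(paths)) {
    abort(sprintf("missing mandatory FAERS file(s) in '%s': %s", dir_path,
                  paste(toupper(names(paths)[is.na(paths)]), collapse = ", ")))
  }
  tables <- purrr::imap(paths, ~ read_faers_table(.x, .y, dialect))

  known <- unique(tables$demo$primaryid)
  log <- purrr::imap_dfr(tables, function(tb, name) {
    orphans <- if (name == "demo") 0L else sum(!tb$primaryid %in% known)
    tibble::tibble(table = name,
                   n_rows = nrow(tb),
                   n_malformed = attr(tb, "n_malformed") %||% 0L,
                   n_orphan = orphans)
  })
  tables[-1L] <- purrr::map(tables[-1L], ~ dplyr::filter(.x, .data$primaryid %in% known))
  tables <- purrr::map(tables, function(tb) {
    attr(tb, "n_malformed") <- NULL
    tb
  })
  n_orph <- sum(log$n_orphan)
  if (n_orph > 0L) {
    inform(sprintf("dropped %d row(s) whose primaryid is absent from DEMO", n_orph))
  }

  deleted_path <- list.files(dir_path, pattern = "^deleted.*\\.(txt|TXT)$",
                             ignore.case = TRUE, full.names = TRUE)
  deleted <- if (length(deleted_path) > 0L) {
    unique(stringr::str_trim(readr::read_lines(deleted_path[1L], progress = FALSE)))
  } else {
    character(0)
  }
  deleted <- deleted[nzchar(deleted)]

  structure(c(tables, list(deleted = deleted, log = log)),
            class = "faers_quarter")
}

#' @export
print.faers_quarter <- function(x, ...) {
  cat("<faers_quarter> ", nrow(x$demo), " demo rows, ",
      length(unique(x$demo$caseid)), " caseids, ",
      length(x$deleted), " deleted caseids\n", sep = "")
  invisible(x)
}

new_faers_cases <- function(cases, drugs, reactions, outcomes, therapies,
                            indications, log = NULL) {
  structure(list(cases = cases, drugs = drugs, reactions = reactions,
                 outcomes = outcomes, therapies = therapies,
                 indications = indications, log = log),
            class = "faers_cases")
}

#' @export
print.faers_cases <- function(x, ...) {
  cat("<faers_cases> ", nrow(x$cases), " deduplicated cases; ",
      nrow(x$drugs), " drug rows, ", nrow(x$reactions), " reaction rows\n",
      sep = "")
  invisible(x)
}

#' Deduplicate FAERS quarters into a normalized case store
#'
#' FAERS cases are re-submitted across quarters as new versions under the
#' same `caseid`. One report is retained per `caseid`: the row with the
#' highest `caseversion`, ties broken by latest FDA receipt date, then by
#' lexically largest `primaryid` — the conventional deterministic FAERS
#' dedup rule. Every caseid listed in any quarter's Deleted file is removed
#' regardless of quarter order. Cases left without any reaction row are
#' dropped (a report must report something) and counted in the log.
#'
#' @param quarters a `faers_quarter` or list of them.
#' @return A `faers_cases` object: flat tibbles `cases` (caseid,
#'   caseversion, primaryid, receipt_date, event_date, event_imprecise,
#'   age, sex), `drugs`, `reactions`, `outcomes`, `therapies`,
#'   `indications`, all keyed by caseid, plus a cleaning `log`.
#' @export
deduplicate_reports <- function(quarters) {
  if (inherits(quarters, "faers_quarter")) quarters <- list(quarters)
  stopifnot(all(vapply(quarters, inherits, logical(1), "faers_quarter")))
  if (length(quarters) == 0L) {
    return(empty_case_store())
  }

  demo <- purrr::map_dfr(quarters, "demo") |> dplyr::distinct()
  deleted <- unique(unlist(purrr::map(quarters, "deleted")))

  if (nrow(demo) == 0L) return(empty_case_store())

  rd <- parse_faers_date(demo$fda_dt)
  ed <- parse_faers_date(demo$event_dt)
  demo <- demo |>
    dplyr::mutate(
      caseversion = suppressWarnings(as.integer(.data$caseversion)),
      caseversion = dplyr::coalesce(.data$caseversion, 1L),
      receipt_date = rd$date,
      event_date = ed$date,
      event_imprecise = ed$imprecise,
      age = normalize_age_years(.data$age, .data$age_cod),
      sex = normalize_sex(.data$sex)
    )

  winners <- demo |>
    dplyr::arrange(.data$caseid, dplyr::desc(.data$caseversion),
                   dplyr::desc(.data$receipt_date), dplyr::desc(.data$primaryid)) |>
    dplyr::distinct(.data$caseid, .keep_all = TRUE) |>
    dplyr::filter(!.data$caseid %in% deleted)

  keep_ids <- winners$primaryid
  pick <- function(field) {
    purrr::map_dfr(quarters, field) |>
      dplyr::distinct() |>
      dplyr::filter(.data$primaryid %in% keep_ids)
  }

  drugs <- pick("drug") |>
    dplyr::transmute(caseid = .data$caseid,
                     drug_seq = .data$drug_seq,
                     role = stringr::str_to_upper(stringr::str_trim(.data$role_cod)),
                     verbatim_name = .data$drugname,
                     standardized_name = .data$drugname)
  reactions <- pick("reac") |>
    dplyr::transmute(caseid = .data$caseid, pt = stringr::str_trim(.data$pt)) |>
    dplyr::filter(nzchar(.data$pt)) |>
    dplyr::distinct()
  outcomes <- pick("outc") |>
    dplyr::transmute(caseid = .data$caseid,
                     code = stringr::str_to_upper(stringr::str_trim(.data$outc_cod))) |>
    dplyr::distinct()
  ther_dates <- pick("ther")
  td <- parse_faers_date(ther_dates$start_dt)
  therapies <- ther_dates |>
    dplyr::transmute(caseid = .data$caseid,
                     drug_seq = .data$dsg_drug_seq,
                     start_date = td$date,
                     imprecise = td$imprecise) |>
    dplyr::filter(!is.na(.data$start_date))
  indications <- pick("indi") |>
    dplyr::transmute(caseid = .data$caseid,
                     drug_seq = .data$indi_drug_seq,
                     term = stringr::str_trim(.data$indi_pt)) |>
    dplyr::distinct()

  with_reaction <- unique(reactions$caseid)
  n_no_reaction <- sum(!winners$caseid %in% with_reaction)
  winners <- dplyr::filter(winners, .data$caseid %in% with_reaction)

  cases <- winners |>
    dplyr::select("caseid", "caseversion", "primaryid", "receipt_date",
                  "event_date", "event_imprecise", "age", "sex") |>
    dplyr::arrange(.data$caseid)
  keep <- cases$caseid
  trim <- function(tb) dplyr::filter(tb, .data$caseid %in% keep)

  log <- tibble::tibble(
    n_raw_demo_rows = nrow(demo),
    n_unique_caseids = dplyr::n_distinct(demo$caseid),
    n_deleted_removed = sum(unique(demo$caseid) %in% deleted),
    n_dropped_no_reaction = n_no_reaction,
    n_retained = nrow(cases)
  )
  new_faers_cases(cases, trim(drugs), trim(reactions), trim(outcomes),
                  trim(therapies), trim(indications), log = log)
}

empty_case_store <- function() {
  new_faers_cases(
    cases = tibble::tibble(caseid = character(), caseversion = integer(),
                           primaryid = character(),
                           receipt_date = as.Date(character()),
                           event_date = as.Date(character()),
                           event_imprecise = logical(),
                           age = numeric(), sex = character()),
    drugs = tibble::tibble(caseid = character(), drug_seq = character(),
                           role = character(), verbatim_name = character(),
                           standardized_name = character()),
    reactions = tibble::tibble(caseid = character(), pt = character()),
    outcomes = tibble::tibble(caseid = character(), code = character()),
    therapies = tibble::tibble(caseid = character(), drug_seq = character(),
                               start_date = as.Date(character()),
                               imprecise = logical()),
    indications = tibble::tibble(caseid = character(), drug_seq = character(),
                                 term = character()),
    log = tibble::tibble(n_retained = 0L)
  )
}

#' Standardize verbatim drug names against a lookup table
#'
#' Reporters spell drug names freely ("NIVOLUMAB.", "Opdivo ", trade vs
#' generic). Matching is case-insensitive after trimming, collapsing
#' internal whitespace and stripping trailing punctuation, applied to both
#' the map keys and the verbatim names. Unmatched names pass through
#' verbatim and are tallied in the coverage report attached as the
#' `"drug_name_coverage"` attribute.
#'
#' @param cases a `faers_cases` store.
#' @param name_map data frame with columns `verbatim` and `standard`.
#' @return The case store with `standardized_name` filled in.
#' @export
standardize_drug_names <- function(cases, name_map) {
  stopifnot(inherits(cases, "faers_cases"))
  if (is.null(name_map) || nrow(name_map) == 0L) {
    warn("empty drug name map; verbatim names passed through unchanged")
    return(cases)
  }
  stopifnot(all(c("verbatim", "standard") %in% names(name_map)))
  map <- tibble::tibble(key = normalize_drug_key(name_map$verbatim),
                        standard = as.character(name_map$standard)) |>
    dplyr::distinct(.data$key, .keep_all = TRUE)

  drugs <- cases$drugs |>
    dplyr::mutate(.key = normalize_drug_key(.data$verbatim_name)) |>
    dplyr::left_join(map, by = c(".key" = "key")) |>
    dplyr::mutate(standardized_name = dplyr::coalesce(.data$standard, .data$verbatim_name)) |>
    dplyr::select(-".key", -"standard")

  coverage <- drugs |>
    dplyr::count(.data$verbatim_name, .data$standardized_name, name = "n_rows") |>
    dplyr::mutate(matched = .data$standardized_name != .data$verbatim_name |
                    normalize_drug_key(.data$verbatim_name) %in% map$key) |>
    dplyr::arrange(dplyr::desc(.data$n_rows))

  cases$drugs <- drugs
  attr(cases, "drug_name_coverage") <- coverage
  cases
}

#' Tidy a case store into one row per case
#'
#' @param x a `faers_cases` store.
#' @param ... unused.
#' @return A tibble with one row per deduplicated case and list-columns for
#'   drugs, reactions, outcomes, therapy starts and indications.
#' @export
tidy.faers_cases <- function(x, ...) {
  nest_by_case <- function(tb) {
    split(dplyr::select(tb, -"caseid"), factor(tb$caseid, levels = x$cases$caseid))
  }
  tibble::as_tibble(x$cases) |>
    dplyr::mutate(
      drugs = unname(nest_by_case(x$drugs)),
      reactions = purrr::map(unname(nest_by_case(x$reactions)), "pt"),
      outcomes = purrr::map(unname(nest_by_case(x$outcomes)), "code"),
      therapy_starts = unname(nest_by_case(x$therapies)),
      indications = unname(nest_by_case(x$indications))
    )
}

#' @export
glance.faers_cases <- function(x, ...) {
  tibble::tibble(
    n_cases = nrow(x$cases),
    n_drug_rows = nrow(x$drugs),
    n_reaction_rows = nrow(x$reactions),
    n_distinct_pts = dplyr::n_distinct(x$reactions$pt),
    n_death_outcomes = sum(x$outcomes$code == "DE")
  )
}

date_chr <- function(d) ifelse(is.na(d), NA_character_, format(d, "%Y-%m-%d"))

#' Write a case store to a JSON-lines sidecar file
#'
#' One JSON object per line per case; [read_case_store()] round-trips the
#' store exactly.
#'
#' @param cases a `faers_cases` store.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_case_store <- function(cases, path) {
  stopifnot(inherits(cases, "faers_cases"))
  td <- tidy(cases)
  lines <- purrr::map_chr(seq_len(nrow(td)), function(i) {
    row <- td[i, ]
    ther <- row$therapy_starts[[1]]
    jsonlite::toJSON(list(
      caseid = row$caseid, caseversion = row$caseversion,
      primaryid = row$primaryid,
      receipt_date = date_chr(row$receipt_date),
      event_date = date_chr(row$event_date),
      event_imprecise = row$event_imprecise,
      age = row$age, sex = row$sex,
      drugs = row$drugs[[1]],
      reactions = row$reactions[[1]],
      outcomes = row$outcomes[[1]],
      therapies = dplyr::mutate(ther, start_date = date_chr(.data$start_date)),
      indications = row$indications[[1]]
    ), auto_unbox = TRUE, na = "null", digits = NA)
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a case store back from its JSON-lines sidecar
#'
#' @param path file written by [write_case_store()].
#' @return A `faers_cases` store.
#' @export
read_case_store <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  recs <- purrr::map(lines, jsonlite::fromJSON)
  as_date_safe <- function(x) as.Date(x %||% NA_character_)
  chr1 <- function(f) purrr::map_chr(recs, ~ .x[[f]] %||% NA_character_)
  cases <- tibble::tibble(
    caseid = chr1("caseid"),
    caseversion = purrr::map_int(recs, ~ as.integer(.x$caseversion %||% NA_integer_)),
    primaryid = chr1("primaryid"),
    receipt_date = as_date_safe(purrr::map_chr(recs, ~ .x$receipt_date %||% NA_character_)),
    event_date = as_date_safe(purrr::map_chr(recs, ~ .x$event_date %||% NA_character_)),
    event_imprecise = purrr::map_lgl(recs, ~ as.logical(.x$event_imprecise %||% NA)),
    age = purrr::map_dbl(recs, ~ as.numeric(.x$age %||% NA_real_)),
    sex = chr1("sex")
  )
  bind_part <- function(field, template) {
    purrr::map2_dfr(recs, cases$caseid, function(r, id) {
      part <- r[[field]]
      if (is.null(part) || NROW(part) == 0L) return(template[0, ])
      tb <- tibble::as_tibble(part)
      dplyr::bind_cols(tibble::tibble(caseid = rep(id, nrow(tb))), tb)
    })
  }
  empty <- empty_case_store()
  drugs <- bind_part("drugs", empty$drugs)
  reactions <- purrr::map2_dfr(recs, cases$caseid, function(r, id) {
    pts <- unlist(r$reactions)
    tibble::tibble(caseid = rep(id, length(pts)), pt = as.character(pts))
  })
  outcomes <- purrr::map2_dfr(recs, cases$caseid, function(r, id) {
    cds <- unlist(r$outcomes)
    tibble::tibble(caseid = rep(id, length(cds)), code = as.character(cds))
  })
  therapies <- bind_part("therapies", dplyr::mutate(empty$therapies,
                                                    start_date = as.character(.data$start_date)))
  if (nrow(therapies) > 0L) {
    therapies <- dplyr::mutate(therapies, start_date = as.Date(.data$start_date))
  } else {
    therapies <- empty$therapies
  }
  indications <- bind_part("indications", empty$indications)
  new_faers_cases(cases, drugs, reactions, outcomes, therapies, indications)
}
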