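# Cohort construction: restrict to the target indication, classify primary
# suspect (PS) drugs into checkpoint-inhibitor classes, and assign each case
# to an exposure arm (ICI + chemotherapy vs chemotherapy only).

ici_classes <- c("PD1", "PDL1", "CTLA4")

#' Restrict a case store to a target indication group
#'
#' A spontaneous report is retained when at least one indication attached
#' to a primary suspect (PS) drug maps, through the user-supplied
#' indication-to-HLGT lookup, into the target high-level group term(s).
#' Matching is case-insensitive exact on both the indication term and the
#' HLGT. Only PS-drug indications count, mirroring the PS-drug restriction
#' applied throughout the analysis.
#'
#' @param cases a `faers_cases` store.
#' @param target_terms character vector of target HLGT strings (non-empty).
#' @param hlgt_lookup data frame with columns `term` (indication preferred
#'   term) and `hlgt`; stands in for the licensed MedDRA hierarchy.
#' @return The filtered `faers_cases` store.
#' @export
filter_indication <- function(cases, target_terms, hlgt_lookup) {
  stopifnot(inherits(cases, "faers_cases"))
  if (length(target_terms) == 0L) abort("target_terms must be non-empty")
  if (is.null(hlgt_lookup) || nrow(hlgt_lookup) == 0L) {
    abort("indication-to-HLGT lookup is empty; cannot resolve HLGT membership")
  }
  stopifnot(all(c("term", "hlgt") %in% names(hlgt_lookup)))
  lk <- tibble::tibble(term_key = stringr::str_to_lower(stringr::str_trim(hlgt_lookup$term)),
                       hlgt = stringr::str_to_lower(stringr::str_trim(hlgt_lookup$hlgt)))
  targets <- stringr::str_to_lower(stringr::str_trim(target_terms))

  ps_keys <- cases$drugs |>
    dplyr::filter(.data$role == "PS") |>
    dplyr::select("caseid", "drug_seq")
  keep_ids <- cases$indications |>
    dplyr::inner_join(ps_keys, by = c("caseid", "drug_seq")) |>
    dplyr::mutate(term_key = stringr::str_to_lower(stringr::str_trim(.data$term))) |>
    dplyr::inner_join(lk, by = "term_key", relationship = "many-to-many") |>
    dplyr::filter(.data$hlgt %in% targets) |>
    dplyr::pull("caseid") |>
    unique()

  subset_case_store(cases, keep_ids)
}

subset_case_store <- function(cases, keep_ids) {
  trim <- function(tb) dplyr::filter(tb, .data$caseid %in% keep_ids)
  new_faers_cases(trim(cases$cases), trim(cases$drugs), trim(cases$reactions),
                  trim(cases$outcomes), trim(cases$therapies),
                  trim(cases$indications), log = cases$log)
}

#' Assign age groups used in subgroup analyses
#'
#' Groups are `<45`, `45-64` (closed interval, both endpoints included),
#' `>64`, and `unknown` for missing ages.
#'
#' @param age numeric vector of ages in years (NA allowed).
#' @return A factor with levels `<45`, `45-64`, `>64`, `unknown`.
#' @export
assign_age_group <- function(age) {
  out <- dplyr::case_when(
    is.na(age) ~ "unknown",
    age < 45 ~ "<45",
    age <= 64 ~ "45-64",
    TRUE ~ ">64"
  )
  factor(out, levels = c("<45", "45-64", ">64", "unknown"))
}

regimen_from_classes <- function(class_set) {
  s <- sort(intersect(class_set, ici_classes))
  if (length(s) == 0L) return(NA_character_)
  if (identical(s, "PD1")) return("PD1_Chemo")
  if (identical(s, "PDL1")) return("PDL1_Chemo")
  if (identical(s, "CTLA4")) return("CTLA4_Chemo")
  if (identical(s, c("CTLA4", "PD1"))) return("PD1_CTLA4_Chemo")
  "Combined-ICI_Chemo"
}

#' Assign exposure arms and regimens from primary suspect drugs
#'
#' Each case's PS drugs are classified through `class_map`
#' (standardized name to one of PD1, PDL1, CTLA4, CHEMO, OTHER; unmapped
#' names default to OTHER). A case with at least one PS checkpoint
#' inhibitor is `ICI_Chemo`; with chemotherapy only it is `Only_Chemo`;
#' with neither it is excluded and counted in the attached exclusion
#' attribute. The regimen refines the ICI arm by the set of ICI classes
#' present: single-class regimens, the PD1+CTLA4 doublet, and
#' `Combined-ICI_Chemo` for any other multi-class combination.
#'
#' @param cases a `faers_cases` store (drug names standardized).
#' @param class_map data frame with columns `standardized_name` and
#'   `class`.
#' @return A tibble (one row per retained case): `caseid`, `arm`,
#'   `regimen`, `age_group`, `sex`, `age`. Excluded caseids are in
#'   `attr(, "excluded")`.
#' @export
assign_cohort <- function(cases, class_map) {
  stopifnot(inherits(cases, "faers_cases"))
  stopifnot(all(c("standardized_name", "class") %in% names(class_map)))
  cmap <- tibble::tibble(
    key = normalize_drug_key(class_map$standardized_name),
    class = stringr::str_to_upper(as.character(class_map$class))
  ) |> dplyr::distinct(.data$key, .keep_all = TRUE)

  ps <- cases$drugs |>
    dplyr::filter(.data$role == "PS") |>
    dplyr::mutate(key = normalize_drug_key(.data$standardized_name)) |>
    dplyr::left_join(cmap, by = "key") |>
    dplyr::mutate(class = dplyr::coalesce(.data$class, "OTHER"))

  by_case <- ps |>
    dplyr::summarise(
      has_ici = any(.data$class %in% ici_classes),
      has_chemo = any(.data$class == "CHEMO"),
      regimen = regimen_from_classes(.data$class),
      .by = "caseid"
    )

  excluded <- by_case |>
    dplyr::filter(!.data$has_ici, !.data$has_chemo) |>
    dplyr::pull("caseid")
  no_ps <- setdiff(cases$cases$caseid, ps$caseid)
  excluded <- union(excluded, no_ps)
  if (length(excluded) > 0L) {
    inform(sprintf("excluded %d case(s) with no PS checkpoint-inhibitor or chemotherapy drug",
                   length(excluded)))
  }

  cohort <- by_case |>
    dplyr::filter(.data$has_ici | .data$has_chemo) |>
    dplyr::mutate(
      arm = ifelse(.data$has_ici, "ICI_Chemo", "Only_Chemo"),
      regimen = ifelse(.data$has_ici, .data$regimen, "Only_Chemo")
    ) |>
    dplyr::select("caseid", "arm", "regimen") |>
    dplyr::left_join(dplyr::select(cases$cases, "caseid", "sex", "age"), by = "caseid") |>
    dplyr::mutate(age_group = assign_age_group(.data$age)) |>
    dplyr::select("caseid", "arm", "regimen", "age_group", "sex", "age") |>
    dplyr::arrange(.data$caseid)

  attr(cohort, "excluded") <- excluded
  cohort
}
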