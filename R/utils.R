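# Internal helpers shared across modules.

#' Parse FAERS-style dates, tolerating partial precision
#'
#' FAERS date fields are numeric strings of 4 (`YYYY`), 6 (`YYYYMM`) or 8
#' (`YYYYMMDD`) digits. Partial dates are completed to the earliest
#' consistent day (January 1 / day 1) and flagged imprecise so downstream
#' time-to-onset consumers can exclude them.
#'
#' @param x character vector of raw date strings.
#' @return A tibble with columns `date` (Date, `NA` where unparseable) and
#'   `imprecise` (logical, `NA` where `date` is `NA`).
#' @examples
#' parse_faers_date(c("20200131", "202001", "2020", "bogus"))
#' @export
parse_faers_date <- function(x) {
  x <- stringr::str_trim(as.character(x))
  x[!stringr::str_detect(x, "^\\d{4}(\\d{2}(\\d{2})?)?$") | is.na(x)] <- NA_character_
  full <- dplyr::case_when(
    is.na(x) ~ NA_character_,
    nchar(x) == 4L ~ paste0(x, "0101"),
    nchar(x) == 6L ~ paste0(x, "01"),
    TRUE ~ x
  )
  date <- as.Date(full, format = "%Y%m%d")  # invalid calendar dates -> NA
  tibble::tibble(
    date = date,
    imprecise = ifelse(is.na(date), NA, nchar(x) < 8L)
  )
}

# Normalize a drug name key: trim, collapse internal whitespace, strip
# trailing punctuation, case-fold. Used for both map keys and lookups so
# matching is symmetric.
normalize_drug_key <- function(x) {
  x <- stringr::str_squish(as.character(x))
  x <- stringr::str_remove(x, "[[:punct:]]+$")
  stringr::str_to_lower(x)
}

# Age in years from FAERS age + age-unit code; implausible ages -> NA.
normalize_age_years <- function(age, age_cod) {
  age <- suppressWarnings(as.numeric(age))
  unit <- stringr::str_to_upper(stringr::str_trim(as.character(age_cod)))
  mult <- dplyr::case_when(
    unit %in% c("YR", "YEAR", "") | is.na(unit) ~ 1,
    unit == "DEC" ~ 10,
    unit == "MON" ~ 1 / 12,
    unit == "WK" ~ 1 / 52.1775,
    unit == "DY" ~ 1 / 365.25,
    unit == "HR" ~ 1 / 8766,
    TRUE ~ NA_real_
  )
  yrs <- age * mult
  yrs[!is.na(yrs) & (yrs < 0 | yrs > 120)] <- NA_real_
  yrs
}

# Standardize sex codes to male/female/unknown.
normalize_sex <- function(x) {
  x <- stringr::str_to_upper(stringr::str_trim(as.character(x)))
  dplyr::case_when(
    x %in% c("M", "MALE") ~ "male",
    x %in% c("F", "FEMALE") ~ "female",
    TRUE ~ "unknown"
  )
}

# Derive a stream of sub-seeds from one master seed, staying within the
# 32-bit integer range expected by set.seed().
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  (as.integer(seed) + 104729L * seq_len(n)) %% 2147483647L
}

`%||%` <- rlang::`%||%`
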