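# Disproportionality statistics on 2x2 report tables and the five-way
# conjunction signal rule.
#
# For one adverse event (MedDRA PT) and one exposure split the table is
#
#                     event PT   other events
#   exposed arm          a            b
#   comparator arm       c            d
#
# with N = a + b + c + d. Reports are counted once per cell regardless of
# how many times a PT is listed within a report (report-level counting).

#' Default signal criteria quintuple
#'
#' A preferred term is declared a signal only when all five criteria hold:
#' `a >= min_a`, `ROR025 >= ror025_min`, `IC025 > ic025_min`,
#' `PRR > prr_min` and Yates chi-square `>= chi2_min`. A criterion whose
#' statistic is undefined (zero cell) counts as failed rather than being
#' patched by a continuity correction.
#'
#' @param min_a minimum co-occurrence count a (default 3).
#' @param ror025_min lower 95% ROR bound threshold (default 1).
#' @param ic025_min lower IC credibility bound threshold, strict (default 1).
#' @param prr_min PRR threshold, strict (default 2).
#' @param chi2_min Yates chi-square threshold (default 4).
#' @return Named list of thresholds.
#' @export
signal_criteria <- function(min_a = 3, ror025_min = 1, ic025_min = 1,
                            prr_min = 2, chi2_min = 4) {
  list(min_a = min_a, ror025_min = ror025_min, ic025_min = ic025_min,
       prr_min = prr_min, chi2_min = chi2_min)
}

#' Build the 2x2 contingency table for one event
#'
#' @param cohort cohort tibble from [assign_cohort()] with `caseid`, `arm`.
#' @param reactions long tibble (`caseid`, `pt`) of case reactions.
#' @param event_pt the target preferred term (case-sensitive exact).
#' @param exposed,comparator arm labels forming the exposure split.
#' @return One-row tibble with columns `event_pt`, `a`, `b`, `c`, `d`, `n`.
#' @export
build_contingency <- function(cohort, reactions, event_pt,
                              exposed = "ICI_Chemo", comparator = "Only_Chemo") {
  stopifnot(all(c("caseid", "arm") %in% names(cohort)),
            all(c("caseid", "pt") %in% names(reactions)))
  with_pt <- unique(reactions$caseid[reactions$pt == event_pt])
  exp_ids <- cohort$caseid[cohort$arm == exposed]
  cmp_ids <- cohort$caseid[cohort$arm == comparator]
  a <- sum(exp_ids %in% with_pt)
  c_ <- sum(cmp_ids %in% with_pt)
  tibble::tibble(event_pt = event_pt,
                 a = a, b = length(exp_ids) - a,
                 c = c_, d = length(cmp_ids) - c_,
                 n = length(exp_ids) + length(cmp_ids))
}

#' Reporting odds ratio with 95% confidence bounds
#'
#' `ROR = (a d)/(b c)`; Wald bounds
#' `exp(ln ROR -/+ 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. Any zero cell makes
#' all three values undefined (`NA`); no continuity correction is applied.
#'
#' @param data data frame with integer columns `a`, `b`, `c`, `d`.
#' @return `data` with columns `ror`, `ror025`, `ror975` appended.
#' @export
ror_stats <- function(data) {
  a <- as.numeric(data$a); b <- as.numeric(data$b)
  c <- as.numeric(data$c); d <- as.numeric(data$d)
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  ror <- ror025 <- ror975 <- rep(NA_real_, length(a))
  ror[ok] <- (a[ok] * d[ok]) / (b[ok] * c[ok])
  se <- sqrt(1 / a[ok] + 1 / b[ok] + 1 / c[ok] + 1 / d[ok])
  ror025[ok] <- exp(log(ror[ok]) - 1.96 * se)
  ror975[ok] <- exp(log(ror[ok]) + 1.96 * se)
  dplyr::mutate(tibble::as_tibble(data), ror = ror, ror025 = ror025, ror975 = ror975)
}

#' Proportional reporting ratio and Yates chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`, requiring both margins positive and
#' `c > 0`. The chi-square with Yates continuity correction is
#' `N (|ad - bc| - N/2)^2 / [(a+b)(c+d)(a+c)(b+d)]` with the corrected
#' numerator floored at zero; it is undefined when any margin is zero.
#'
#' @param data data frame with integer columns `a`, `b`, `c`, `d`.
#' @return `data` with columns `prr`, `chi2_yates` appended.
#' @export
prr_stats <- function(data) {
  a <- as.numeric(data$a); b <- as.numeric(data$b)
  c <- as.numeric(data$c); d <- as.numeric(data$d)
  n <- a + b + c + d
  prr <- rep(NA_real_, length(a))
  okp <- (a + b) > 0 & (c + d) > 0 & c > 0
  prr[okp] <- (a[okp] / (a[okp] + b[okp])) / (c[okp] / (c[okp] + d[okp]))
  chi2 <- rep(NA_real_, length(a))
  okc <- (a + b) > 0 & (c + d) > 0 & (a + c) > 0 & (b + d) > 0
  num <- pmax(abs(a * d - b * c) - n / 2, 0)
  chi2[okc] <- (n[okc] * num[okc]^2) /
    ((a + b)[okc] * (c + d)[okc] * (a + c)[okc] * (b + d)[okc])
  dplyr::mutate(tibble::as_tibble(data), prr = prr, chi2_yates = chi2)
}

#' Information component with lower credibility bound
#'
#' Shrinkage observed-to-expected information component:
#' `E = (a+b)(a+c)/N`, `IC = log2((a + 0.5)/(E + 0.5))`. Two variants of
#' the lower 2.5% bound are offered: `"noren"` (default) uses the closed
#' approximation `IC - 3.3 (a+0.5)^{-1/2} - 2.4 (a+0.5)^{-3/2}`;
#' `"gamma"` uses the exact 2.5% quantile of the
#' Gamma(a + 0.5, rate = E + 0.5) posterior on the log2 scale.
#'
#' @param data data frame with integer columns `a`, `b`, `c`, `d`.
#' @param variant `"noren"` or `"gamma"`.
#' @return `data` with columns `ic`, `ic025` appended.
#' @export
ic_stats <- function(data, variant = c("noren", "gamma")) {
  variant <- match.arg(variant)
  a <- as.numeric(data$a); b <- as.numeric(data$b)
  c <- as.numeric(data$c); d <- as.numeric(data$d)
  n <- a + b + c + d
  ic <- ic025 <- rep(NA_real_, length(a))
  ok <- n > 0
  e <- (a + b)[ok] * (a + c)[ok] / n[ok]
  ic[ok] <- log2((a[ok] + 0.5) / (e + 0.5))
  if (variant == "noren") {
    ic025[ok] <- ic[ok] - 3.3 * (a[ok] + 0.5)^(-0.5) - 2.4 * (a[ok] + 0.5)^(-1.5)
  } else {
    ic025[ok] <- log2(qgamma(0.025, shape = a[ok] + 0.5, rate = e + 0.5))
  }
  dplyr::mutate(tibble::as_tibble(data), ic = ic, ic025 = ic025)
}

#' Apply the five-way conjunction signal rule to contingency tables
#'
#' Computes ROR, PRR/chi-square and IC statistics and evaluates the
#' conjunction: a signal requires every criterion in `criteria` to hold;
#' an undefined statistic fails its criterion.
#'
#' @param data data frame with columns `a`, `b`, `c`, `d` (and optionally
#'   `event_pt`).
#' @param criteria a [signal_criteria()] list.
#' @param ic_variant IC lower-bound variant passed to [ic_stats()].
#' @return A `signal_table` tibble: the input counts, all statistics,
#'   per-criterion logical flags, `is_signal`, and `failed_criteria` (comma
#'   separated labels, empty when a signal).
#' @export
judge_signal <- function(data, criteria = signal_criteria(),
                         ic_variant = c("noren", "gamma")) {
  ic_variant <- match.arg(ic_variant)
  out <- tibble::as_tibble(data) |>
    ror_stats() |>
    prr_stats() |>
    ic_stats(variant = ic_variant) |>
    dplyr::mutate(
      crit_a = .data$a >= criteria$min_a,
      crit_ror = !is.na(.data$ror025) & .data$ror025 >= criteria$ror025_min,
      crit_ic = !is.na(.data$ic025) & .data$ic025 > criteria$ic025_min,
      crit_prr = !is.na(.data$prr) & .data$prr > criteria$prr_min,
      crit_chi2 = !is.na(.data$chi2_yates) & .data$chi2_yates >= criteria$chi2_min,
      is_signal = .data$crit_a & .data$crit_ror & .data$crit_ic &
        .data$crit_prr & .data$crit_chi2
    )
  labels <- c(crit_a = "a", crit_ror = "ror025", crit_ic = "ic025",
              crit_prr = "prr", crit_chi2 = "chi2_yates")
  fails <- purrr::pmap_chr(out[names(labels)], function(...) {
    paste(labels[!c(...)], collapse = ",")
  })
  out <- dplyr::mutate(out, failed_criteria = fails)
  class(out) <- c("signal_table", class(out))
  out
}

#' Run disproportionality signal detection over a cohort
#'
#' Builds the 2x2 table for each candidate preferred term (by default
#' every PT observed in the cohort) under the exposed-vs-comparator split
#' and applies [judge_signal()].
#'
#' @param cohort cohort tibble from [assign_cohort()].
#' @param reactions long tibble (`caseid`, `pt`).
#' @param events candidate PTs; `NULL` means all observed PTs.
#' @param criteria a [signal_criteria()] list.
#' @param exposed,comparator arm labels.
#' @param ic_variant IC lower-bound variant.
#' @return A `signal_table` tibble, one row per candidate PT, sorted by
#'   descending ROR within signals first.
#' @export
detect_signals <- function(cohort, reactions, events = NULL,
                           criteria = signal_criteria(),
                           exposed = "ICI_Chemo", comparator = "Only_Chemo",
                           ic_variant = c("noren", "gamma")) {
  ic_variant <- match.arg(ic_variant)
  keep <- cohort$caseid[cohort$arm %in% c(exposed, comparator)]
  reactions <- dplyr::filter(reactions, .data$caseid %in% keep) |>
    dplyr::distinct(.data$caseid, .data$pt)
  if (is.null(events)) events <- sort(unique(reactions$pt))
  arm_of <- setNames(cohort$arm, cohort$caseid)
  n_exp <- sum(cohort$arm == exposed)
  n_cmp <- sum(cohort$arm == comparator)
  counts <- reactions |>
    dplyr::mutate(arm = arm_of[.data$caseid]) |>
    dplyr::filter(.data$pt %in% events) |>
    dplyr::count(.data$pt, .data$arm) |>
    tidyr::pivot_wider(names_from = "arm", values_from = "n", values_fill = 0L)
  for (col in c(exposed, comparator)) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  tables <- tibble::tibble(event_pt = events) |>
    dplyr::left_join(counts, by = c(event_pt = "pt")) |>
    dplyr::mutate(
      a = dplyr::coalesce(.data[[exposed]], 0L),
      c = dplyr::coalesce(.data[[comparator]], 0L),
      b = n_exp - .data$a,
      d = n_cmp - .data$c,
      n = n_exp + n_cmp
    ) |>
    dplyr::select("event_pt", "a", "b", "c", "d", "n")
  judge_signal(tables, criteria = criteria, ic_variant = ic_variant) |>
    dplyr::arrange(dplyr::desc(.data$is_signal), dplyr::desc(.data$ror))
}

#' @export
glance.signal_table <- function(x, ...) {
  tibble::tibble(
    n_events = nrow(x),
    n_signals = sum(x$is_signal),
    n_exposed = if (nrow(x) > 0L) x$a[1] + x$b[1] else 0L,
    n_comparator = if (nrow(x) > 0L) x$c[1] + x$d[1] else 0L
  )
}

#' Write a signal table to CSV
#'
#' @param x a `signal_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(x, path) {
  cols <- intersect(c("event_pt", "a", "b", "c", "d", "ror", "ror025", "ror975",
                      "prr", "chi2_yates", "ic", "ic025", "is_signal",
                      "failed_criteria"), names(x))
  readr::write_csv(dplyr::select(tibble::as_tibble(x), dplyr::all_of(cols)), path)
  invisible(path)
}
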