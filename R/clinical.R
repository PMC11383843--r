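# Time-to-onset analysis and logistic-regression subgroup modelling.

#' Compute time to onset per case
#'
#' Time to onset (TTO) is the number of days from the start of therapy to
#' the adverse event date. The event date is taken from the case record;
#' the therapy anchor is the earliest (default) or latest primary suspect
#' therapy start. Cases missing either date yield no record; negative
#' intervals (event before therapy) are excluded and counted in the
#' `"n_negative_excluded"` attribute. Records built from any partial date
#' carry `imprecise = TRUE` so callers can drop them.
#'
#' @param cases a `faers_cases` store.
#' @param cohort optional cohort tibble; when given, TTO records are
#'   restricted and annotated with `arm`, `regimen`, `age_group`, `sex`.
#' @param anchor `"earliest"` or `"latest"` therapy start.
#' @param ps_only restrict therapy starts to PS drugs (default TRUE).
#' @return A tibble with `caseid`, `tto_days`, `imprecise` (+ cohort
#'   columns when `cohort` is supplied).
#' @export
compute_tto <- function(cases, cohort = NULL,
                        anchor = c("earliest", "latest"), ps_only = TRUE) {
  stopifnot(inherits(cases, "faers_cases"))
  anchor <- match.arg(anchor)
  ther <- cases$therapies
  if (ps_only) {
    ps_keys <- cases$drugs |>
      dplyr::filter(.data$role == "PS") |>
      dplyr::select("caseid", "drug_seq")
    ther <- dplyr::inner_join(ther, ps_keys, by = c("caseid", "drug_seq"))
  }
  if (nrow(ther) == 0L) {
    rec <- tibble::tibble(caseid = character(), tto_days = numeric(),
                          imprecise = logical())
    if (!is.null(cohort)) rec <- dplyr::inner_join(rec, cohort, by = "caseid")
    attr(rec, "n_negative_excluded") <- 0L
    return(rec)
  }
  pick_fn <- if (anchor == "earliest") which.min else which.max
  anchors <- ther |>
    dplyr::filter(!is.na(.data$start_date)) |>
    dplyr::summarise(
      start_date = .data$start_date[pick_fn(.data$start_date)],
      start_imprecise = .data$imprecise[pick_fn(.data$start_date)],
      .by = "caseid"
    )
  rec <- cases$cases |>
    dplyr::select("caseid", "event_date", "event_imprecise") |>
    dplyr::inner_join(anchors, by = "caseid") |>
    dplyr::filter(!is.na(.data$event_date), !is.na(.data$start_date)) |>
    dplyr::mutate(
      tto_days = as.numeric(.data$event_date - .data$start_date),
      imprecise = dplyr::coalesce(.data$event_imprecise, FALSE) |
        dplyr::coalesce(.data$start_imprecise, FALSE)
    )
  n_neg <- sum(rec$tto_days < 0)
  if (n_neg > 0L) {
    inform(sprintf("excluded %d TTO record(s) with event date before therapy start", n_neg))
  }
  rec <- rec |>
    dplyr::filter(.data$tto_days >= 0) |>
    dplyr::select("caseid", "tto_days", "imprecise")
  if (!is.null(cohort)) {
    rec <- dplyr::inner_join(rec, cohort, by = "caseid")
  }
  attr(rec, "n_negative_excluded") <- n_neg
  rec
}

#' Pairwise rank-based comparison of time-to-onset between groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test for every unordered
#' pair of group labels. Pairs with a group of fewer than two records are
#' skipped and logged.
#'
#' @param tto tibble from [compute_tto()].
#' @param group name of the grouping column (e.g. `"age_group"`, `"sex"`).
#' @param exclude_imprecise drop records built from partial dates.
#' @return Tibble with `group1`, `group2`, `n1`, `n2`, `statistic` (the
#'   Mann-Whitney U), `p_value`.
#' @export
compare_tto <- function(tto, group, exclude_imprecise = FALSE) {
  stopifnot(group %in% names(tto), "tto_days" %in% names(tto))
  if (exclude_imprecise) tto <- dplyr::filter(tto, !.data$imprecise)
  g <- as.character(tto[[group]])
  tto <- tto[!is.na(g) & g != "unknown", ]
  g <- g[!is.na(g) & g != "unknown"]
  labs <- sort(unique(g))
  if (length(labs) < 2L) abort("need at least two non-empty groups")
  pairs <- utils::combn(labs, 2L, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    x <- tto$tto_days[g == pr[1]]
    y <- tto$tto_days[g == pr[2]]
    if (length(x) < 2L || length(y) < 2L) {
      inform(sprintf("skipping pair %s vs %s: group with <2 records", pr[1], pr[2]))
      return(tibble::tibble(group1 = pr[1], group2 = pr[2],
                            n1 = length(x), n2 = length(y),
                            statistic = NA_real_, p_value = NA_real_))
    }
    wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   n1 = length(x), n2 = length(y),
                   statistic = unname(wt$statistic), p_value = wt$p.value)
  })
}

#' Empirical cumulative distribution points of TTO per group
#'
#' @param tto tibble from [compute_tto()].
#' @param group grouping column name.
#' @return Tibble (`group`, `tto_days`, `cdf`) suitable for step plots.
#' @export
tto_cdf <- function(tto, group) {
  stopifnot(group %in% names(tto))
  tto |>
    dplyr::filter(!is.na(.data[[group]])) |>
    dplyr::arrange(.data$tto_days) |>
    dplyr::mutate(group = as.character(.data[[group]])) |>
    dplyr::mutate(cdf = dplyr::row_number() / dplyr::n(), .by = "group") |>
    dplyr::select("group", "tto_days", "cdf")
}

#' Univariable and multivariable logistic regression
#'
#' Fits binomial-family generalized linear models (maximum likelihood via
#' iteratively reweighted least squares) of a binary outcome on clinical
#' covariates. `model = "uni"` fits one single-covariate model per
#' covariate; `model = "multi"` fits all covariates jointly. Odds ratios
#' with Wald 95% confidence bounds and p-values are reported per
#' non-intercept term. Factor reference levels follow the conventional
#' coding: age `<45`, sex female, regimen/arm `ICI_Chemo` when the columns
#' are factors ordered that way (see [prepare_logistic_data()]).
#'
#' @param data data frame of cases.
#' @param outcome name of the binary (0/1 or logical) outcome column.
#' @param covariates character vector of covariate column names.
#' @param model `"uni"` or `"multi"`.
#' @param max_iter IRLS iteration cap; non-convergence or apparent
#'   separation flags the fit and withholds its terms.
#' @return An object of class `irae_logit` with [tidy()] and [glance()]
#'   methods.
#' @export
fit_logistic <- function(data, outcome, covariates,
                         model = c("multi", "uni"), max_iter = 100L) {
  model <- match.arg(model)
  stopifnot(outcome %in% names(data), all(covariates %in% names(data)))
  data <- data[complete.cases(data[c(outcome, covariates)]), , drop = FALSE]
  y <- data[[outcome]]
  if (is.logical(y)) data[[outcome]] <- as.integer(y)
  uy <- unique(data[[outcome]])
  if (!all(uy %in% c(0, 1))) abort("outcome must be binary 0/1 or logical")
  if (length(uy) < 2L) abort("degenerate outcome: all values identical")
  if (nrow(data) < 10L) abort("need at least 10 complete cases")

  fit_one <- function(covs) {
    fml <- stats::as.formula(paste(outcome, "~", paste(covs, collapse = " + ")))
    fit <- suppressWarnings(glm(fml, data = data, family = binomial(),
                                control = stats::glm.control(maxit = max_iter)))
    separated <- any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)
    converged <- fit$converged && !separated
    terms <- if (converged) {
      est <- coef(fit)
      se <- sqrt(diag(stats::vcov(fit)))
      p <- 2 * stats::pnorm(-abs(est / se))
      keep <- names(est) != "(Intercept)"
      tibble::tibble(
        term = names(est)[keep],
        odds_ratio = exp(est[keep]),
        ci_low = exp(est[keep] - 1.96 * se[keep]),
        ci_high = exp(est[keep] + 1.96 * se[keep]),
        p_value = p[keep]
      )
    } else {
      tibble::tibble(term = character(), odds_ratio = numeric(),
                     ci_low = numeric(), ci_high = numeric(),
                     p_value = numeric())
    }
    list(fit = fit, terms = terms, converged = converged)
  }

  fits <- if (model == "multi") {
    list(all = fit_one(covariates))
  } else {
    setNames(purrr::map(covariates, ~ fit_one(.x)), covariates)
  }
  structure(list(fits = fits, model = model, outcome = outcome,
                 covariates = covariates, n_used = nrow(data)),
            class = "irae_logit")
}

#' @export
print.irae_logit <- function(x, ...) {
  cat("<irae_logit> ", x$model, "variable logistic regression of '",
      x$outcome, "' on ", length(x$covariates), " covariate(s), n = ",
      x$n_used, "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @describeIn fit_logistic one row per term: odds ratio, Wald 95% CI,
#'   p-value, and which model (`uni`/`multi`) it came from.
#' @param x an `irae_logit` object.
#' @param ... unused.
#' @export
tidy.irae_logit <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(f, nm) {
    dplyr::mutate(f$terms, model = x$model,
                  converged = f$converged)
  })
}

#' @describeIn fit_logistic one-row fit summary.
#' @export
glance.irae_logit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    n_used = x$n_used,
    n_fits = length(x$fits),
    all_converged = all(purrr::map_lgl(x$fits, "converged"))
  )
}

#' Assemble the standard logistic design table from pipeline objects
#'
#' Joins cohort assignments, the death outcome (outcome code `DE`), and
#' irAE occurrence (any signalled PT reported by the case) into one
#' modelling table with conventional factor coding: age group reference
#' `<45`, sex reference `female`, arm reference `ICI_Chemo`.
#'
#' @param cohort cohort tibble from [assign_cohort()].
#' @param cases a `faers_cases` store.
#' @param signal_pts character vector of signalled preferred terms.
#' @return A tibble with columns `caseid`, `death`, `irae`, `age_group`,
#'   `sex`, `arm`, `regimen`.
#' @export
prepare_logistic_data <- function(cohort, cases, signal_pts) {
  death_ids <- unique(cases$outcomes$caseid[cases$outcomes$code == "DE"])
  irae_ids <- unique(cases$reactions$caseid[cases$reactions$pt %in% signal_pts])
  cohort |>
    dplyr::filter(.data$age_group != "unknown", .data$sex %in% c("male", "female")) |>
    dplyr::transmute(
      caseid = .data$caseid,
      death = as.integer(.data$caseid %in% death_ids),
      irae = as.integer(.data$caseid %in% irae_ids),
      age_group = factor(as.character(.data$age_group),
                         levels = c("<45", "45-64", ">64")),
      sex = factor(.data$sex, levels = c("female", "male")),
      arm = factor(.data$arm, levels = c("ICI_Chemo", "Only_Chemo")),
      regimen = .data$regimen
    )
}
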