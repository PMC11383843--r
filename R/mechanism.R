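# Expression-based mechanism screening: per-sample ssGSEA pathway scores,
# median aggregation per cancer type, Spearman screening against observed
# event-level reporting odds ratios, and exhaustive bivariate linear model
# selection by likelihood-ratio test.

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of gene identifiers.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(stringr::str_trim(lines))]
  sets <- purrr::map(lines, function(ln) {
    parts <- stringr::str_split(ln, "\t")[[1]]
    unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
  })
  names(sets) <- purrr::map_chr(lines, ~ stringr::str_split(.x, "\t")[[1]][1])
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::imap_chr(sets, ~ paste(c(.y, .y, .x), collapse = "\t"))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Single-sample gene set enrichment scores
#'
#' For each sample, genes are ranked by expression (descending; average
#' ranks on ties). Walking down the ranked list, the score of a gene set
#' is the sum over all positions of the difference between the weighted
#' in-set cumulative distribution — member genes weighted by their rank
#' statistic raised to `tau` — and the uniform out-of-set cumulative
#' distribution. Scores are sums of ECDF differences with no further
#' division; `normalize = TRUE` additionally min-max rescales each set's
#' scores across samples. The score depends on expression only through
#' within-sample ranks, so any strictly increasing per-sample transform
#' leaves it unchanged.
#'
#' @param expr numeric gene-by-sample matrix with rownames (genes) and
#'   colnames (samples).
#' @param gene_sets named list of character vectors of gene identifiers.
#' @param tau rank-weight exponent (default 0.25).
#' @param normalize min-max normalize scores across samples per set.
#' @return A tibble with columns `sample`, `gene_set`, `score`.
#' @export
ssgsea_score <- function(expr, gene_sets, tau = 0.25, normalize = FALSE) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  if (anyDuplicated(rownames(expr))) abort("duplicate gene identifiers in matrix")
  if (!is.list(gene_sets)) gene_sets <- list(set = gene_sets)
  genes <- rownames(expr)
  n <- length(genes)

  member <- purrr::map(gene_sets, function(gs) {
    idx <- which(genes %in% gs)
    if (length(idx) == 0L) NULL else idx
  })
  dropped <- names(member)[purrr::map_lgl(member, is.null)]
  if (length(dropped) > 0L) {
    inform(sprintf("gene set(s) with no overlap with the matrix skipped: %s",
                   paste(dropped, collapse = ", ")))
  }
  member <- member[!purrr::map_lgl(member, is.null)]
  if (length(member) == 0L) abort("no gene set overlaps the expression matrix")
  if (any(purrr::map_int(member, length) == n)) {
    abort("a gene set covers every gene in the matrix; out-of-set ECDF undefined")
  }

  score_mat <- matrix(NA_real_, nrow = length(member), ncol = ncol(expr),
                      dimnames = list(names(member), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    r <- rank(expr[, j], ties.method = "average")      # high expression -> high rank
    ord <- order(r, decreasing = TRUE)
    w <- r[ord]^tau
    for (k in seq_along(member)) {
      inset <- logical(n)
      inset[member[[k]]] <- TRUE
      inset <- inset[ord]
      win <- w * inset
      p_in <- cumsum(win) / sum(win)
      p_out <- cumsum(!inset) / (n - sum(inset))
      score_mat[k, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- apply(score_mat, 1L, function(x) diff(range(x)))
    score_mat <- sweep(score_mat, 1L, apply(score_mat, 1L, min), "-")
    score_mat <- sweep(score_mat, 1L, ifelse(rng == 0, 1, rng), "/")
  }
  tibble::as_tibble(score_mat, rownames = "gene_set") |>
    tidyr::pivot_longer(-"gene_set", names_to = "sample", values_to = "score")
}

#' Median pathway scores and gene expression per cancer type
#'
#' @param scores tibble from [ssgsea_score()] with a `cancer_type` column,
#'   or one that can gain it via `sample_info`.
#' @param sample_info optional tibble (`sample`, `cancer_type`).
#' @return Tibble (`cancer_type`, `gene_set`, `median_score`).
#' @export
median_pathway_scores <- function(scores, sample_info = NULL) {
  if (!is.null(sample_info)) {
    scores <- dplyr::inner_join(scores, sample_info, by = "sample")
  }
  stopifnot("cancer_type" %in% names(scores))
  dplyr::summarise(scores, median_score = median(.data$score),
                   .by = c("cancer_type", "gene_set"))
}

#' Screen pathways by Spearman correlation with observed RORs
#'
#' Correlates each pathway's median score across cancer types with the
#' types' observed event-level reporting odds ratios (Spearman, average
#' ranks on ties, two-sided p). Pathways with constant scores are skipped.
#'
#' @param score_table tibble (`cancer_type`, `gene_set`, `median_score`)
#'   from [median_pathway_scores()].
#' @param rors tibble (`cancer_type`, `ror`) of observed RORs.
#' @param alpha two-sided significance threshold (default 0.05,
#'   unadjusted; set `adjust = "BH"` for Benjamini-Hochberg).
#' @param adjust `"none"` or `"BH"`.
#' @return Tibble (`gene_set`, `n_types`, `rs`, `p_value`, `sign`,
#'   `significant`) sorted by p.
#' @export
screen_pathways <- function(score_table, rors, alpha = 0.05,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(all(c("cancer_type", "gene_set", "median_score") %in% names(score_table)),
            all(c("cancer_type", "ror") %in% names(rors)))
  joined <- dplyr::inner_join(score_table, rors, by = "cancer_type")
  n_types <- dplyr::n_distinct(joined$cancer_type)
  if (n_types < 5L) abort("need at least 5 cancer types for correlation screening")
  out <- joined |>
    dplyr::summarise(
      n_types = dplyr::n(),
      rs = if (sd(.data$median_score) == 0) NA_real_ else
        unname(suppressWarnings(cor.test(.data$median_score, .data$ror,
                                         method = "spearman")$estimate)),
      p_value = if (sd(.data$median_score) == 0) NA_real_ else
        suppressWarnings(cor.test(.data$median_score, .data$ror,
                                  method = "spearman")$p.value),
      .by = "gene_set"
    )
  skipped <- out$gene_set[is.na(out$rs)]
  if (length(skipped) > 0L) {
    inform(sprintf("pathway(s) with constant scores skipped: %s",
                   paste(skipped, collapse = ", ")))
  }
  out <- dplyr::filter(out, !is.na(.data$rs))
  padj <- if (adjust == "BH") p.adjust(out$p_value, "BH") else out$p_value
  out |>
    dplyr::mutate(sign = ifelse(.data$rs >= 0, "positive", "negative"),
                  significant = padj < alpha) |>
    dplyr::arrange(.data$p_value)
}

#' Exhaustive bivariate linear model search with likelihood-ratio tests
#'
#' For every unordered pair of candidate predictors, fits the bivariate
#' linear model `ror ~ x1 + x2` by least squares and compares it by
#' likelihood-ratio test (chi-square, 1 df, on twice the Gaussian
#' log-likelihood difference) against both nested univariate models. The
#' Spearman correlation between fitted and observed RORs measures
#' predictive power; pairs are ranked by it, ties broken by the smaller of
#' the two LRT p-values. Nearly collinear pairs (|r| > 0.999) are skipped.
#'
#' @param predictors tibble: `cancer_type` column plus one numeric column
#'   per candidate variable, or a types-by-variables numeric matrix.
#' @param rors tibble (`cancer_type`, `ror`).
#' @param log_ror model `log(ror)` instead of the raw ratio scale.
#' @return An object of class `bivariate_search` (a tibble, one row per
#'   fitted pair) with columns `x1`, `x2`, `beta0`, `beta1`, `beta2`,
#'   `log_lik`, `lrt_p_vs_x1`, `lrt_p_vs_x2`, `rs_pred_obs`,
#'   `rs_x1_only`, `rs_x2_only`.
#' @export
bivariate_search <- function(predictors, rors, log_ror = FALSE) {
  if (is.matrix(predictors)) {
    predictors <- tibble::as_tibble(predictors, rownames = "cancer_type")
  }
  stopifnot("cancer_type" %in% names(predictors),
            all(c("cancer_type", "ror") %in% names(rors)))
  vars <- setdiff(names(predictors), "cancer_type")
  if (length(vars) < 2L) abort("need at least 2 candidate predictors")
  df <- dplyr::inner_join(predictors, rors, by = "cancer_type")
  if (nrow(df) <= 3L) abort("3 or fewer cancer types: bivariate model would be saturated")
  y <- if (log_ror) log(df$ror) else df$ror

  uni <- purrr::map(setNames(vars, vars), function(v) {
    f <- lm(y ~ x, data = data.frame(y = y, x = df[[v]]))
    list(ll = as.numeric(logLik(f)),
         rs = suppressWarnings(cor(stats::fitted(f), y, method = "spearman")))
  })

  pairs <- utils::combn(vars, 2L, simplify = FALSE)
  fits <- purrr::map_dfr(pairs, function(pr) {
    x1 <- df[[pr[1]]]; x2 <- df[[pr[2]]]
    r12 <- suppressWarnings(cor(x1, x2))
    if (!is.na(r12) && abs(r12) > 0.999) {
      inform(sprintf("skipping collinear pair %s / %s (|r| > 0.999)", pr[1], pr[2]))
      return(NULL)
    }
    fit <- lm(y ~ x1 + x2, data = data.frame(y = y, x1 = x1, x2 = x2))
    ll <- as.numeric(logLik(fit))
    lrt_p <- function(ll_nested) {
      stat <- max(2 * (ll - ll_nested), 0)
      pchisq(stat, df = 1L, lower.tail = FALSE)
    }
    tibble::tibble(
      x1 = pr[1], x2 = pr[2],
      beta0 = unname(coef(fit)[1]),
      beta1 = unname(coef(fit)[2]),
      beta2 = unname(coef(fit)[3]),
      log_lik = ll,
      lrt_p_vs_x1 = lrt_p(uni[[pr[1]]]$ll),
      lrt_p_vs_x2 = lrt_p(uni[[pr[2]]]$ll),
      rs_pred_obs = suppressWarnings(cor(stats::fitted(fit), y, method = "spearman")),
      rs_x1_only = uni[[pr[1]]]$rs,
      rs_x2_only = uni[[pr[2]]]$rs
    )
  })
  fits <- fits |>
    dplyr::mutate(min_lrt_p = pmin(.data$lrt_p_vs_x1, .data$lrt_p_vs_x2)) |>
    dplyr::arrange(dplyr::desc(.data$rs_pred_obs), .data$min_lrt_p) |>
    dplyr::select(-"min_lrt_p")
  class(fits) <- c("bivariate_search", class(fits))
  attr(fits, "n_types") <- nrow(df)
  attr(fits, "response") <- if (log_ror) "log(ror)" else "ror"
  fits
}

#' @export
glance.bivariate_search <- function(x, ...) {
  best <- x[1, ]
  tibble::tibble(
    n_pairs = nrow(x),
    n_types = attr(x, "n_types"),
    best_x1 = best$x1, best_x2 = best$x2,
    best_rs = best$rs_pred_obs,
    best_min_lrt_p = min(best$lrt_p_vs_x1, best$lrt_p_vs_x2)
  )
}

#' Screen genes against RORs and run preranked enrichment
#'
#' Correlates each gene's median expression across cancer types with the
#' observed RORs (Spearman), ranks genes by the correlation coefficient,
#' and tests each annotation set by preranked gene set enrichment:
#' weighted running-sum enrichment score (weight 1, i.e. member increments
#' proportional to |rs|), significance by gene-label permutation,
#' Benjamini-Hochberg correction across sets.
#'
#' @param gene_medians tibble (`cancer_type`, `gene`, `median_expr`) or a
#'   genes-by-types matrix.
#' @param rors tibble (`cancer_type`, `ror`).
#' @param annotation_sets named list of gene identifier vectors; sets with
#'   fewer than 3 ranked members are skipped.
#' @param n_perm number of gene-label permutations (default 1000).
#' @param seed permutation RNG seed.
#' @return List with `gene_screen` (per-gene `rs`, `p_value`) and
#'   `enrichment` (per-set `es`, `p_value`, `padj`, `n_members`).
#' @export
gene_screen_and_gsea <- function(gene_medians, rors, annotation_sets,
                                 n_perm = 1000L, seed = 1L) {
  if (is.matrix(gene_medians)) {
    gene_medians <- tibble::as_tibble(gene_medians, rownames = "gene") |>
      tidyr::pivot_longer(-"gene", names_to = "cancer_type",
                          values_to = "median_expr")
  }
  stopifnot(all(c("cancer_type", "gene", "median_expr") %in% names(gene_medians)))
  joined <- dplyr::inner_join(gene_medians, rors, by = "cancer_type")
  screen <- joined |>
    dplyr::summarise(
      rs = suppressWarnings(cor(.data$median_expr, .data$ror, method = "spearman")),
      p_value = suppressWarnings(cor.test(.data$median_expr, .data$ror,
                                          method = "spearman")$p.value),
      .by = "gene"
    ) |>
    dplyr::filter(!is.na(.data$rs)) |>
    dplyr::arrange(dplyr::desc(.data$rs))

  stats_vec <- setNames(screen$rs, screen$gene)
  enr <- preranked_gsea(stats_vec, annotation_sets, n_perm = n_perm, seed = seed)
  list(gene_screen = screen, enrichment = enr)
}
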