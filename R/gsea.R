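# Preranked gene set enrichment: classic weighted Kolmogorov-Smirnov
# running sum with gene-label permutation p-values.

#' Running-sum enrichment score of a gene set on a ranked list
#'
#' Genes are ordered by decreasing ranking statistic. Walking down the
#' list, member genes increment the running sum by their |statistic|^`weight`
#' (normalized to sum to one over members) and non-members decrement it by
#' 1/(n - m). The enrichment score is the running-sum value of maximal
#' absolute magnitude.
#'
#' @param stats named numeric vector of ranking statistics (names = genes).
#' @param gene_set character vector of member gene identifiers.
#' @param weight statistic exponent (default 1).
#' @return The signed enrichment score (numeric scalar).
#' @export
enrichment_score <- function(stats, gene_set, weight = 1) {
  stopifnot(!is.null(names(stats)))
  ord <- order(stats, decreasing = TRUE)
  s <- stats[ord]
  inset <- names(s) %in% gene_set
  m <- sum(inset)
  n <- length(s)
  if (m == 0L || m == n) abort("gene set must be a proper non-empty subset of the ranking")
  w <- abs(s)^weight * inset
  denom_in <- sum(w)
  step_in <- if (denom_in > 0) w / denom_in else inset / m
  run <- cumsum(step_in - (!inset) / (n - m))
  unname(run[which.max(abs(run))])
}

#' Preranked gene set enrichment over a collection of sets
#'
#' For each annotation set with at least `min_size` ranked members,
#' computes the running-sum enrichment score and a permutation p-value by
#' re-labelling: each permutation reassigns the set membership to a random
#' draw of the same size from the ranked genes, and the p-value is the
#' fraction of permutation scores at least as extreme in absolute value
#' (with the +1 correction). Benjamini-Hochberg adjustment is applied
#' across sets.
#'
#' @param stats named numeric vector of ranking statistics.
#' @param gene_sets named list of gene identifier vectors.
#' @param weight statistic exponent (default 1).
#' @param n_perm number of permutations (default 1000).
#' @param min_size minimum ranked members per set (default 3).
#' @param seed RNG seed for the permutations.
#' @return Tibble (`gene_set`, `n_members`, `es`, `p_value`, `padj`).
#' @export
preranked_gsea <- function(stats, gene_sets, weight = 1, n_perm = 1000L,
                           min_size = 3L, seed = 1L) {
  stopifnot(!is.null(names(stats)), is.list(gene_sets))
  sizes <- purrr::map_int(gene_sets, ~ sum(names(stats) %in% .x))
  skipped <- names(gene_sets)[sizes < min_size]
  if (length(skipped) > 0L) {
    inform(sprintf("annotation set(s) with <%d ranked members skipped: %s",
                   min_size, paste(skipped, collapse = ", ")))
  }
  gene_sets <- gene_sets[sizes >= min_size]
  sizes <- sizes[sizes >= min_size]
  if (length(gene_sets) == 0L) {
    return(tibble::tibble(gene_set = character(), n_members = integer(),
                          es = numeric(), p_value = numeric(), padj = numeric()))
  }

  # permutation null is shared across sets of equal size
  genes <- names(stats)
  null_by_size <- withr::with_seed(seed, {
    purrr::map(setNames(unique(sizes), unique(sizes)), function(m) {
      vapply(seq_len(n_perm), function(i) {
        enrichment_score(stats, sample(genes, m), weight = weight)
      }, numeric(1))
    })
  })

  out <- purrr::imap_dfr(gene_sets, function(gs, nm) {
    es <- enrichment_score(stats, gs, weight = weight)
    null_es <- null_by_size[[as.character(sum(genes %in% gs))]]
    p <- (1 + sum(abs(null_es) >= abs(es))) / (n_perm + 1)
    tibble::tibble(gene_set = nm, n_members = sum(genes %in% gs),
                   es = es, p_value = p)
  })
  dplyr::mutate(out, padj = p.adjust(.data$p_value, "BH")) |>
    dplyr::arrange(.data$p_value)
}
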