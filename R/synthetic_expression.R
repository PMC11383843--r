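# Seeded generator of expression cohorts (one genes-by-samples matrix per
# cancer type) with a pathway whose activity is planted to correlate with
# per-type event reporting odds ratios at a chosen strength.

#' Configuration for the synthetic expression generator
#'
#' Emulates a multi-cohort design: `n_types` cancer types, each a
#' genes-by-samples matrix of standard-normal log-expression noise. The
#' member genes of one planted gene set are shifted per type by a latent
#' factor built to correlate with the type's observed reporting odds
#' ratio at strength `rho`; all other genes are pure noise, and extra
#' null gene sets are drawn from them. Rank-based scoring makes the
#' Gaussian marginal immaterial.
#'
#' @param n_types number of cancer types (refused below 5; correlation
#'   across fewer types is meaningless).
#' @param samples_per_type samples per cohort (warn below 10).
#' @param n_genes genes per matrix.
#' @param set_size genes per gene set.
#' @param n_null_sets number of unplanted noise sets.
#' @param rho target Spearman-scale correlation between the planted set's
#'   median score and the per-type RORs (|rho| <= 1).
#' @param effect_size per-gene shift (in noise SDs) per unit latent factor.
#' @param sigma residual expression noise SD.
#' @param rors per-type observed RORs; default a geometric spread over
#'   [2, 25], the range seen across nervous-system cancer types.
#' @param seed mandatory RNG seed.
#' @return A list of class `expression_sim_config`.
#' @export
expression_sim_config <- function(
    n_types = 20L,
    samples_per_type = 15L,
    n_genes = 1000L,
    set_size = 20L,
    n_null_sets = 10L,
    rho = 0.8,
    effect_size = 1,
    sigma = 1,
    rors = NULL,
    seed) {
  if (missing(seed)) abort("seed is mandatory for the synthetic generator")
  if (n_types < 5L) abort("fewer than 5 cancer types: correlation screening is meaningless")
  stopifnot(abs(rho) <= 1, sigma > 0, set_size >= 2,
            (n_null_sets + 1) * set_size <= n_genes)
  if (is.null(rors)) {
    rors <- exp(seq(log(2), log(25), length.out = n_types))
  }
  stopifnot(length(rors) == n_types, all(rors > 0))
  structure(list(
    n_types = as.integer(n_types),
    samples_per_type = as.integer(samples_per_type),
    n_genes = as.integer(n_genes), set_size = as.integer(set_size),
    n_null_sets = as.integer(n_null_sets), rho = rho,
    effect_size = effect_size, sigma = sigma, rors = rors,
    seed = as.integer(seed)
  ), class = "expression_sim_config")
}

#' Generate synthetic expression cohorts with a planted pathway signal
#'
#' @param config an [expression_sim_config()].
#' @return An object of class `expression_sim`: `expr` (one
#'   genes-by-samples matrix), `sample_info` tibble (`sample`,
#'   `cancer_type`), `gene_sets` (named list; `planted_pathway` first),
#'   `rors` tibble (`cancer_type`, `ror`), and a `manifest` recording
#'   rho, the latent per-type factors, the planted member genes and seed.
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "expression_sim_config"))
  withr::with_seed(config$seed, generate_expression_impl(config))
}

generate_expression_impl <- function(config) {
  nt <- config$n_types
  ns <- config$samples_per_type
  ng <- config$n_genes
  types <- sprintf("type%02d", seq_len(nt))
  genes <- sprintf("gene%04d", seq_len(ng))
  samples <- paste0(rep(types, each = ns), "_s", rep(seq_len(ns), nt))

  # latent per-type factor: correlated with the ROR ranks at strength rho
  # (population correlation; independent noise keeps the rho = 0 case a
  # genuine null rather than an exactly-orthogonal one)
  z <- as.numeric(scale(rank(log(config$rors))))
  u <- config$rho * z + sqrt(max(0, 1 - config$rho^2)) * rnorm(nt)

  expr <- matrix(rnorm(ng * nt * ns, sd = config$sigma), nrow = ng,
                 dimnames = list(genes, samples))
  member_idx <- seq_len(config$set_size)
  shift <- rep(u, each = ns) * config$effect_size
  expr[member_idx, ] <- expr[member_idx, ] +
    matrix(shift, nrow = length(member_idx), ncol = nt * ns, byrow = TRUE)

  pool <- setdiff(seq_len(ng), member_idx)
  null_sets <- purrr::map(seq_len(config$n_null_sets), function(i) {
    genes[pool[((i - 1) * config$set_size + 1):(i * config$set_size)]]
  })
  gene_sets <- c(list(planted_pathway = genes[member_idx]),
                 setNames(null_sets, sprintf("null_set%02d", seq_len(config$n_null_sets))))

  structure(list(
    expr = expr,
    sample_info = tibble::tibble(sample = samples,
                                 cancer_type = rep(types, each = ns)),
    gene_sets = gene_sets,
    rors = tibble::tibble(cancer_type = types, ror = config$rors),
    manifest = list(seed = config$seed, rho = config$rho,
                    latent_factor = setNames(u, types),
                    planted_set = "planted_pathway",
                    planted_genes = genes[member_idx],
                    rors = setNames(config$rors, types)),
    config = config
  ), class = "expression_sim")
}

#' @export
print.expression_sim <- function(x, ...) {
  cat("<expression_sim> ", ncol(x$expr), " samples over ",
      nrow(x$rors), " cancer types; planted rho = ",
      x$manifest$rho, "\n", sep = "")
  invisible(x)
}

#' Write an expression simulation to disk
#'
#' Per-type expression TSVs (genes in rows), gene sets as GMT, RORs as
#' CSV and the manifest as JSON.
#'
#' @param sim an `expression_sim`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_expression_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "expression_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ct in sim$rors$cancer_type) {
    cols <- sim$sample_info$sample[sim$sample_info$cancer_type == ct]
    tb <- tibble::as_tibble(sim$expr[, cols, drop = FALSE], rownames = "gene")
    readr::write_tsv(tb, file.path(dir, paste0(ct, "_expression.tsv")))
  }
  write_gmt(sim$gene_sets, file.path(dir, "gene_sets.gmt"))
  readr::write_csv(sim$rors, file.path(dir, "rors.csv"))
  jsonlite::write_json(sim$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read expression cohorts written by [write_expression_sim()]
#'
#' @param dir directory of per-type `*_expression.tsv` files plus
#'   `gene_sets.gmt` and `rors.csv`.
#' @return List with `expr`, `sample_info`, `gene_sets`, `rors`.
#' @export
read_expression_dir <- function(dir) {
  files <- list.files(dir, pattern = "_expression\\.tsv$", full.names = TRUE)
  if (length(files) == 0L) abort(sprintf("no *_expression.tsv files in '%s'", dir))
  mats <- purrr::map(files, function(f) {
    tb <- readr::read_tsv(f, show_col_types = FALSE, progress = FALSE)
    m <- as.matrix(tb[, -1])
    rownames(m) <- tb[[1]]
    m
  })
  types <- stringr::str_remove(basename(files), "_expression\\.tsv$")
  expr <- do.call(cbind, mats)
  sample_info <- tibble::tibble(
    sample = unlist(purrr::map(mats, colnames)),
    cancer_type = rep(types, purrr::map_int(mats, ncol))
  )
  gmt <- file.path(dir, "gene_sets.gmt")
  rors_csv <- file.path(dir, "rors.csv")
  list(
    expr = expr, sample_info = sample_info,
    gene_sets = if (file.exists(gmt)) read_gmt(gmt) else NULL,
    rors = if (file.exists(rors_csv)) {
      readr::read_csv(rors_csv, show_col_types = FALSE)
    } else {
      NULL
    }
  )
}
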