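# End-to-end orchestration: simulate (or ingest) -> cohort -> signals ->
# clinical -> mechanism, emitting a result bundle of CSVs, a run log and a
# machine-readable summary.

#' Build a validated pipeline run configuration
#'
#' @param out_dir output directory for the result bundle.
#' @param seed RNG seed used by every stochastic stage.
#' @param faers_dir directory of FAERS-style quarter subdirectories; when
#'   `NULL` the synthetic generator supplies the reports.
#' @param expression_dir directory of expression TSVs + GMT + RORs; when
#'   `NULL` the synthetic expression generator is used.
#' @param sim_config optional [faers_sim_config()] (defaults to the
#'   standard study conditions with `seed`).
#' @param expr_config optional [expression_sim_config()].
#' @param name_map,class_map,hlgt_lookup lookup tables (default packaged).
#' @param target_hlgt target indication HLGT(s).
#' @param criteria [signal_criteria()] quintuple.
#' @param ic_variant `"noren"` or `"gamma"`.
#' @param tto_anchor `"earliest"` or `"latest"` therapy start.
#' @param screening_alpha mechanism screening threshold.
#' @param log_ror model mechanism RORs on the log scale.
#' @return A validated list of class `irae_run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       faers_dir = NULL, expression_dir = NULL,
                       sim_config = NULL, expr_config = NULL,
                       name_map = default_drug_name_map(),
                       class_map = default_drug_class_map(),
                       hlgt_lookup = default_indication_lookup(),
                       target_hlgt = nsc_target_hlgt(),
                       criteria = signal_criteria(),
                       ic_variant = "noren",
                       tto_anchor = "earliest",
                       screening_alpha = 0.05,
                       log_ror = FALSE) {
  for (d in c(faers_dir, expression_dir)) {
    if (!is.null(d) && !dir.exists(d)) abort(sprintf("input directory '%s' does not exist", d))
  }
  if (is.null(name_map) || nrow(name_map) == 0L) abort("name_map is empty")
  if (is.null(class_map) || nrow(class_map) == 0L) abort("class_map is empty")
  if (is.null(hlgt_lookup) || nrow(hlgt_lookup) == 0L) abort("hlgt_lookup is empty")
  stopifnot(all(unlist(criteria) > 0), screening_alpha > 0, screening_alpha < 1)
  structure(list(
    out_dir = out_dir, seed = as.integer(seed),
    faers_dir = faers_dir, expression_dir = expression_dir,
    sim_config = sim_config, expr_config = expr_config,
    name_map = name_map, class_map = class_map, hlgt_lookup = hlgt_lookup,
    target_hlgt = target_hlgt, criteria = criteria,
    ic_variant = ic_variant, tto_anchor = tto_anchor,
    screening_alpha = screening_alpha, log_ror = log_ror
  ), class = "irae_run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the [run_config()] arguments; lookup-table keys
#' (`name_map`, `class_map`, `hlgt_lookup`) give CSV paths. Unknown keys
#' are rejected.
#'
#' @param path YAML file.
#' @return An `irae_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("out_dir", "seed", "faers_dir", "expression_dir", "name_map",
             "class_map", "hlgt_lookup", "target_hlgt", "criteria",
             "ic_variant", "tto_anchor", "screening_alpha", "log_ror")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L) abort(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  read_csv_arg <- function(key, default) {
    if (is.null(raw[[key]])) return(default)
    if (!file.exists(raw[[key]])) abort(sprintf("%s file '%s' does not exist", key, raw[[key]]))
    readr::read_csv(raw[[key]], show_col_types = FALSE)
  }
  run_config(
    out_dir = raw$out_dir %||% abort("config must set out_dir"),
    seed = raw$seed %||% 1L,
    faers_dir = raw$faers_dir, expression_dir = raw$expression_dir,
    name_map = read_csv_arg("name_map", default_drug_name_map()),
    class_map = read_csv_arg("class_map", default_drug_class_map()),
    hlgt_lookup = read_csv_arg("hlgt_lookup", default_indication_lookup()),
    target_hlgt = raw$target_hlgt %||% nsc_target_hlgt(),
    criteria = if (is.null(raw$criteria)) signal_criteria() else do.call(signal_criteria, raw$criteria),
    ic_variant = raw$ic_variant %||% "noren",
    tto_anchor = raw$tto_anchor %||% "earliest",
    screening_alpha = raw$screening_alpha %||% 0.05,
    log_ror = isTRUE(raw$log_ror)
  )
}

#' Run the full irAE analysis pipeline
#'
#' Stages: `simulate` (or ingest from `faers_dir`), `ingest`
#' (dedup + name standardization), `cohort`, `signals`, `clinical`
#' (TTO + logistic models), `mechanism` (ssGSEA, screening, bivariate
#' search, gene GSEA). Each stage writes its CSVs under `out_dir`; a run
#' log and a summary JSON close the bundle. A hard error in a stage
#' aborts with the stage name; outputs of completed stages remain on
#' disk.
#'
#' @param config an `irae_run_config` (or a YAML path).
#' @param stages subset of stages to run (default all).
#' @return Invisibly, a list with the in-memory stage results and the
#'   summary.
#' @export
run_pipeline <- function(config, stages = c("ingest", "cohort", "signals",
                                            "clinical", "mechanism")) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "irae_run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", sprintf(...))
    cat(msg, "\n", file = log_path, append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  res <- list()
  log_line("run start, seed %d", config$seed)
  yaml::write_yaml(list(seed = config$seed, target_hlgt = config$target_hlgt,
                        criteria = config$criteria, ic_variant = config$ic_variant,
                        tto_anchor = config$tto_anchor,
                        screening_alpha = config$screening_alpha,
                        log_ror = config$log_ror),
                   file.path(config$out_dir, "config_echo.yaml"))

  # -- ingest ---------------------------------------------------------
  res$cases <- stage("ingest", {
    quarters <- if (!is.null(config$faers_dir)) {
      read_faers_sim(config$faers_dir)
    } else {
      sim <- generate_faers(config$sim_config %||% faers_sim_config(seed = config$seed))
      res$sim_manifest <- sim$manifest
      sim$quarters
    }
    cases <- deduplicate_reports(quarters)
    suppressMessages(standardize_drug_names(cases, config$name_map))
  })
  log_line("ingest: %d deduplicated cases", nrow(res$cases$cases))

  if ("cohort" %in% stages || any(c("signals", "clinical") %in% stages)) {
    res$cohort <- stage("cohort", {
      in_ind <- filter_indication(res$cases, config$target_hlgt, config$hlgt_lookup)
      res$cases_in_indication <- in_ind
      suppressMessages(assign_cohort(in_ind, config$class_map))
    })
    readr::write_csv(res$cohort, file.path(config$out_dir, "cohort.csv"))
    log_line("cohort: %d cases (%d ICI_Chemo / %d Only_Chemo)",
             nrow(res$cohort), sum(res$cohort$arm == "ICI_Chemo"),
             sum(res$cohort$arm == "Only_Chemo"))
  }

  if ("signals" %in% stages) {
    res$signals <- stage("signals", {
      detect_signals(res$cohort, res$cases_in_indication$reactions,
                     criteria = config$criteria,
                     ic_variant = config$ic_variant)
    })
    write_signal_table(res$signals, file.path(config$out_dir, "signals.csv"))
    log_line("signals: %d of %d events flagged", sum(res$signals$is_signal),
             nrow(res$signals))
  }

  if ("clinical" %in% stages) {
    res$clinical <- stage("clinical", {
      signal_pts <- res$signals$event_pt[res$signals$is_signal]
      tto <- suppressMessages(
        compute_tto(res$cases_in_indication, cohort = res$cohort,
                    anchor = config$tto_anchor))
      tto_tests <- compare_tto(tto, "age_group")
      design <- prepare_logistic_data(res$cohort, res$cases_in_indication,
                                      signal_pts)
      fits <- list()
      if (length(unique(design$death)) == 2L) {
        fits$death_uni <- fit_logistic(design, "death",
                                       c("irae", "age_group", "sex", "arm"),
                                       model = "uni")
        fits$death_multi <- fit_logistic(design, "death",
                                         c("irae", "age_group", "sex", "arm"),
                                         model = "multi")
      }
      if (length(unique(design$irae)) == 2L) {
        fits$irae_uni <- fit_logistic(design, "irae",
                                      c("age_group", "sex", "arm"), model = "uni")
        fits$irae_multi <- fit_logistic(design, "irae",
                                        c("age_group", "sex", "arm"), model = "multi")
      }
      list(tto = tto, tto_tests = tto_tests, design = design, fits = fits)
    })
    readr::write_csv(res$clinical$tto, file.path(config$out_dir, "tto.csv"))
    readr::write_csv(res$clinical$tto_tests, file.path(config$out_dir, "tto_tests.csv"))
    readr::write_csv(tto_cdf(res$clinical$tto, "age_group"),
                     file.path(config$out_dir, "tto_cdf.csv"))
    logit_tbl <- purrr::imap_dfr(res$clinical$fits,
                                 ~ dplyr::mutate(tidy(.x), fit = .y))
    readr::write_csv(logit_tbl, file.path(config$out_dir, "logistic.csv"))
    log_line("clinical: %d TTO records, %d logistic fits",
             nrow(res$clinical$tto), length(res$clinical$fits))
  }

  if ("mechanism" %in% stages) {
    res$mechanism <- stage("mechanism", {
      ed <- if (!is.null(config$expression_dir)) {
        read_expression_dir(config$expression_dir)
      } else {
        sim <- generate_expression(config$expr_config %||%
                                     expression_sim_config(seed = config$seed))
        res$expr_manifest <- sim$manifest
        list(expr = sim$expr, sample_info = sim$sample_info,
             gene_sets = sim$gene_sets, rors = sim$rors)
      }
      scores <- ssgsea_score(ed$expr, ed$gene_sets)
      med <- median_pathway_scores(scores, ed$sample_info)
      screen <- suppressMessages(
        screen_pathways(med, ed$rors, alpha = config$screening_alpha))
      sig <- screen$gene_set[screen$significant]
      biv <- if (length(sig) >= 2L) {
        preds <- med |>
          dplyr::filter(.data$gene_set %in% sig) |>
          tidyr::pivot_wider(names_from = "gene_set", values_from = "median_score")
        bivariate_search(preds, ed$rors, log_ror = config$log_ror)
      } else {
        NULL
      }
      # gene-level screen over planted + null member genes
      med_expr <- tibble::as_tibble(ed$expr, rownames = "gene") |>
        tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "expr") |>
        dplyr::inner_join(ed$sample_info, by = "sample") |>
        dplyr::summarise(median_expr = median(.data$expr),
                         .by = c("cancer_type", "gene"))
      genes_in_sets <- unique(unlist(ed$gene_sets))
      gsea <- suppressMessages(gene_screen_and_gsea(
        dplyr::filter(med_expr, .data$gene %in% genes_in_sets),
        ed$rors, ed$gene_sets, seed = config$seed))
      list(scores = scores, medians = med, screen = screen,
           bivariate = biv, gene_screen = gsea$gene_screen,
           enrichment = gsea$enrichment)
    })
    readr::write_csv(res$mechanism$screen,
                     file.path(config$out_dir, "pathway_screen.csv"))
    if (!is.null(res$mechanism$bivariate)) {
      readr::write_csv(tibble::as_tibble(res$mechanism$bivariate),
                       file.path(config$out_dir, "bivariate_models.csv"))
    }
    readr::write_csv(res$mechanism$gene_screen,
                     file.path(config$out_dir, "gene_screen.csv"))
    readr::write_csv(res$mechanism$enrichment,
                     file.path(config$out_dir, "gene_set_enrichment.csv"))
    log_line("mechanism: %d pathways screened, %d significant",
             nrow(res$mechanism$screen), sum(res$mechanism$screen$significant))
  }

  summary <- list(
    seed = config$seed,
    n_cases_deduplicated = nrow(res$cases$cases),
    n_cohort = if (!is.null(res$cohort)) nrow(res$cohort) else NULL,
    n_events_tested = if (!is.null(res$signals)) nrow(res$signals) else NULL,
    flagged_signals = if (!is.null(res$signals)) {
      res$signals$event_pt[res$signals$is_signal]
    } else {
      NULL
    },
    best_bivariate_pair = if (!is.null(res$mechanism$bivariate) &&
                              nrow(res$mechanism$bivariate) > 0L) {
      as.list(glance(res$mechanism$bivariate))
    } else {
      NULL
    }
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  res$summary <- summary
  log_line("run complete")
  invisible(res)
}
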