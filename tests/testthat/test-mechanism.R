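rand_expr <- function(ng = 20, ns = 10, seed = 1) {
  withr::with_seed(seed, {
    matrix(rnorm(ng * ns), nrow = ng,
           dimnames = list(sprintf("g%02d", 1:ng), sprintf("s%02d", 1:ns)))
  })
}

test_that("ssGSEA matches the naive double-loop oracle", {
  expr <- rand_expr(20, 10, seed = 42)
  sets <- list(setA = c("g01", "g05", "g12"),
               setB = c("g03", "g04", "g07", "g19"))
  scores <- ssgsea_score(expr, sets)
  for (s in colnames(expr)) {
    for (nm in names(sets)) {
      got <- scores$score[scores$sample == s & scores$gene_set == nm]
      expect_equal(got, brute_ssgsea(expr[, s], sets[[nm]]), tolerance = 1e-9)
    }
  }
})

test_that("ssGSEA is invariant under strictly increasing transforms", {
  expr <- rand_expr(30, 6, seed = 7)
  sets <- list(s1 = rownames(expr)[c(2, 9, 17, 25)])
  base <- ssgsea_score(expr, sets)
  for (f in list(function(x) exp(x), function(x) 3 * x + 100,
                 function(x) x^3)) {
    tr <- ssgsea_score(f(expr), sets)
    expect_equal(tr$score, base$score, tolerance = 1e-12)
  }
})

test_that("sets at the top of the ranking score positive, at the bottom negative", {
  expr <- matrix(10:1, nrow = 10,
                 dimnames = list(paste0("g", 1:10), "s1"))
  top <- ssgsea_score(expr, list(s = c("g1", "g2")))   # highest expression
  bottom <- ssgsea_score(expr, list(s = c("g9", "g10")))
  expect_gt(top$score, 0)
  expect_lt(bottom$score, 0)
})

test_that("degenerate gene sets are refused or skipped with a message", {
  expr <- rand_expr(10, 3)
  expect_error(ssgsea_score(expr, list(all = rownames(expr))), "every gene")
  expect_message(
    sc <- ssgsea_score(expr, list(none = c("zz1", "zz2"),
                                  ok = rownames(expr)[1:3])),
    "skipped")
  expect_setequal(unique(sc$gene_set), "ok")
  bad <- expr
  rownames(bad) <- rep("g1", nrow(bad))
  expect_error(ssgsea_score(bad, list(s = "g1")), "duplicate")
})

test_that("pathway screening recovers perfect monotone relations and ties", {
  types <- sprintf("t%02d", 1:8)
  rors <- tibble::tibble(cancer_type = types, ror = c(1, 2, 3, 4, 5, 6, 7, 8))
  tbl <- dplyr::bind_rows(
    tibble::tibble(cancer_type = types, gene_set = "up", median_score = rors$ror * 2),
    tibble::tibble(cancer_type = types, gene_set = "down", median_score = -rors$ror),
    tibble::tibble(cancer_type = types, gene_set = "tied",
                   median_score = c(1, 1, 2, 3, 4, 5, 6, 7))
  )
  scr <- screen_pathways(tbl, rors)
  expect_equal(scr$rs[scr$gene_set == "up"], 1, ignore_attr = TRUE)
  expect_equal(scr$rs[scr$gene_set == "down"], -1, ignore_attr = TRUE)
  # tie handled by average ranks: compare to direct rank computation
  tied <- c(1, 1, 2, 3, 4, 5, 6, 7)
  expect_equal(scr$rs[scr$gene_set == "tied"],
               cor(rank(tied), rank(rors$ror)), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(scr$sign[scr$gene_set == "down"], "negative")
})

test_that("screening refuses too few types and skips constant pathways", {
  rors4 <- tibble::tibble(cancer_type = paste0("t", 1:4), ror = 1:4)
  tbl4 <- tibble::tibble(cancer_type = paste0("t", 1:4), gene_set = "p",
                         median_score = 1:4)
  expect_error(screen_pathways(tbl4, rors4), "at least 5")
  types <- paste0("t", 1:6)
  tbl <- dplyr::bind_rows(
    tibble::tibble(cancer_type = types, gene_set = "flat", median_score = 1),
    tibble::tibble(cancer_type = types, gene_set = "ok", median_score = 1:6)
  )
  expect_message(scr <- screen_pathways(tbl, tibble::tibble(cancer_type = types,
                                                            ror = 6:1)),
                 "constant")
  expect_setequal(scr$gene_set, "ok")
})

test_that("bivariate search fits every pair and recovers planted coefficients", {
  withr::with_seed(8, {
    nt <- 20
    x1 <- rnorm(nt); x2 <- rnorm(nt)
    ror <- 1 + 2 * x1 - x2 + rnorm(nt, sd = 0.1)
    # a predictor exactly orthogonal to the response and to x1 adds zero
    # explained variance, so its LRT against the x1-only model is null
    x3 <- unname(resid(lm(rnorm(nt) ~ x1 + ror)))
  })
  preds <- tibble::tibble(cancer_type = paste0("t", 1:20),
                          x1 = x1, x2 = x2, x3 = x3)
  rors <- tibble::tibble(cancer_type = paste0("t", 1:20), ror = ror)
  res <- bivariate_search(preds, rors)
  expect_equal(nrow(res), 3L)  # k(k-1)/2 for k = 3
  best <- res[1, ]
  expect_setequal(c(best$x1, best$x2), c("x1", "x2"))
  b1 <- if (best$x1 == "x1") best$beta1 else best$beta2
  expect_gt(b1, 1.8); expect_lt(b1, 2.2)
  expect_lt(best$lrt_p_vs_x1, 0.05)
  expect_lt(best$lrt_p_vs_x2, 0.05)
  # predictive power of the pair dominates both univariate fits
  expect_gte(best$rs_pred_obs, best$rs_x1_only)
  expect_gte(best$rs_pred_obs, best$rs_x2_only)
  # a pure-noise partner adds nothing over the informative single model
  noise_pair <- res[(res$x1 == "x1" & res$x2 == "x3"), ]
  expect_gt(noise_pair$lrt_p_vs_x1, 0.05)
})

test_that("bivariate search refuses saturated designs and skips collinear pairs", {
  small <- tibble::tibble(cancer_type = paste0("t", 1:3),
                          x1 = rnorm(3), x2 = rnorm(3))
  rors3 <- tibble::tibble(cancer_type = paste0("t", 1:3), ror = 1:3)
  expect_error(bivariate_search(small, rors3), "saturated")
  withr::with_seed(2, {
    x <- rnorm(10)
    preds <- tibble::tibble(cancer_type = paste0("t", 1:10),
                            x1 = x, x2 = x, x3 = rnorm(10))
  })
  rors <- tibble::tibble(cancer_type = paste0("t", 1:10), ror = rnorm(10) + 2)
  expect_message(res <- bivariate_search(preds, rors), "collinear")
  expect_equal(nrow(res), 2L)  # x1/x2 dropped
})

test_that("LRT statistics are nonnegative with chi-square(1) p-values", {
  withr::with_seed(14, {
    preds <- tibble::tibble(cancer_type = paste0("t", 1:12),
                            x1 = rnorm(12), x2 = rnorm(12))
    rors <- tibble::tibble(cancer_type = paste0("t", 1:12),
                           ror = rnorm(12) + 3)
  })
  res <- bivariate_search(preds, rors)
  expect_true(all(res$lrt_p_vs_x1 >= 0 & res$lrt_p_vs_x1 <= 1))
  expect_true(all(res$lrt_p_vs_x2 >= 0 & res$lrt_p_vs_x2 <= 1))
})

test_that("gene screening plus enrichment recovers a constructed signal", {
  withr::with_seed(55, {
    nt <- 12
    types <- paste0("t", 1:nt)
    rors <- tibble::tibble(cancer_type = types, ror = sort(runif(nt, 1, 20)))
    genes <- sprintf("g%03d", 1:40)
    med <- purrr::map_dfr(genes, function(g) {
      corr <- as.integer(substr(g, 2, 4)) <= 10   # first 10 genes track ROR
      tibble::tibble(cancer_type = types, gene = g,
                     median_expr = if (corr) rors$ror + rnorm(nt, sd = 0.5)
                                   else rnorm(nt))
    })
  })
  sets <- list(tracking = genes[1:10], random = genes[25:34])
  out <- gene_screen_and_gsea(med, rors, sets, n_perm = 500, seed = 9)
  scr <- out$gene_screen
  expect_true(mean(scr$rs[scr$gene %in% genes[1:10]]) >
                mean(scr$rs[scr$gene %in% genes[11:40]]))
  enr <- out$enrichment
  expect_gt(enr$es[enr$gene_set == "tracking"], 0)
  expect_lt(enr$p_value[enr$gene_set == "tracking"],
            enr$p_value[enr$gene_set == "random"])
})
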