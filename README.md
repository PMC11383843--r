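# iraesignal

Pharmacovigilance signal detection and mechanism screening for
immune-related adverse events (irAEs) of checkpoint-inhibitor therapy,
built around FAERS-style spontaneous-report data and multi-cohort gene
expression.

Immune checkpoint inhibitors (anti-PD-1 / anti-PD-L1 / anti-CTLA-4)
release the brakes on T-cell activity, and the same mechanism produces
toxicity from immune over-activation. In nervous-system cancer these
drugs are used rarely and almost always with chemotherapy, so their
adverse-event profile has to be read out of spontaneous-report
databases. `iraesignal` provides the complete workflow for doing that,
plus the downstream "why" analysis on expression data, plus a seeded
synthetic-data generator so every stage can be exercised offline with
known ground truth.

## What it computes

**Disproportionality.** For each adverse-event preferred term, a 2×2
report table comparing ICI + chemotherapy against chemotherapy-only
reports within the same indication, and three statistics:

- reporting odds ratio ROR = (a·d)/(b·c) with Wald 95% bounds
  exp(ln ROR ± 1.96·√(1/a + 1/b + 1/c + 1/d)),
- proportional reporting ratio PRR = [a/(a+b)]/[c/(c+d)] with the
  Yates-corrected χ² = N(|ad−bc|−N/2)²/[(a+b)(c+d)(a+c)(b+d)],
- shrinkage information component IC = log₂((a+0.5)/(E+0.5)),
  E = (a+b)(a+c)/N, with its lower 2.5% credibility bound.

A term is declared a signal only when all five criteria hold:
**a ≥ 3, ROR025 ≥ 1, IC025 > 1, PRR > 2, χ²_yates ≥ 4.**

**Clinical structure.** Time-to-onset (event date minus earliest
primary-suspect therapy start) compared across age/sex subgroups by
Mann–Whitney tests with CDF exports, and univariable/multivariable
logistic regression of death on irAE occurrence, age group, sex and
regimen.

**Mechanism.** ssGSEA pathway scores per patient (rank-weighted ECDF
running sum, τ = 0.25), medians per cancer type, Spearman screening
against per-type irAE RORs, exhaustive bivariate linear models ranked
by predicted-vs-observed Spearman correlation with likelihood-ratio
tests against both nested models, and preranked permutation GSEA of
ROR-correlated genes.

## Worked example

Generate a synthetic FAERS-like cohort (the generator plants one true
irAE at reporting odds ratio 10), run it through the full pipeline:

```r
library(iraesignal)
library(dplyr)

sim <- generate_faers(faers_sim_config(seed = 42))
cases <- deduplicate_reports(sim$quarters) |>
  standardize_drug_names(default_drug_name_map())
glance(cases)
#> # A tibble: 1 × 5
#>   n_cases n_drug_rows n_reaction_rows n_distinct_pts n_death_outcomes
#>     <int>       <int>           <int>          <int>            <int>
#> 1    4898       10433            9972             21             1485

nsc <- filter_indication(cases, nsc_target_hlgt(), default_indication_lookup())
cohort <- assign_cohort(nsc, default_drug_class_map())
count(cohort, arm)
#> # A tibble: 2 × 2
#>   arm            n
#>   <chr>      <int>
#> 1 ICI_Chemo    500
#> 2 Only_Chemo  4150

signals <- detect_signals(cohort, nsc$reactions)
signals |> filter(is_signal) |>
  select(event_pt, a, ror, ror025, prr, chi2_yates, ic025)
#> # A tibble: 1 × 7
#>   event_pt                    a   ror ror025   prr chi2_yates ic025
#>   <chr>                   <int> <dbl>  <dbl> <dbl>      <dbl> <dbl>
#> 1 Autoimmune encephalitis    28  6.25   3.81  5.96       65.0  1.25
```

Of the 21 preferred terms in the cohort, only the planted event
survives the five-way conjunction: 28 exposed co-reports, observed ROR
6.25 (95% CI lower bound 3.81; the generating odds ratio is 10, and a
single 500-report exposed arm estimates it with this much noise), PRR
5.96, Yates χ² 65 and IC025 1.25 — every criterion clears its
threshold. The clinical models then recover the planted risk factors:

```r
design <- prepare_logistic_data(cohort, nsc, signals$event_pt[signals$is_signal])
fit_logistic(design, "death", c("irae", "age_group", "sex", "arm"),
             model = "multi") |> tidy()
#> # A tibble: 5 × 7
#>   term           odds_ratio ci_low ci_high  p_value model converged
#>   <chr>               <dbl>  <dbl>   <dbl>    <dbl> <chr> <lgl>
#> 1 irae                 2.26  1.33     3.84 2.45e- 3 multi TRUE
#> 2 age_group45-64       1.41  1.17     1.69 3.19e- 4 multi TRUE
#> 3 age_group>64         2.14  1.77     2.58 6.05e-15 multi TRUE
#> 4 sexmale              1.02  0.895    1.17 7.49e- 1 multi TRUE
#> 5 armOnly_Chemo        2.57  1.98     3.32 1.02e-12 multi TRUE
```

Age over 64 and chemotherapy-only regimens come out as death risk
factors (generator truths 2.5 and 2.0), sex is null as planted. The
mechanism side works the same way from
`generate_expression()` / `ssgsea_score()` / `screen_pathways()` /
`bivariate_search()`; see the vignette in `vignettes/` for the science
and every tunable default, and `inst/cli/irae-pipeline.R` for the
one-command YAML-driven pipeline (`run_pipeline()`).

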