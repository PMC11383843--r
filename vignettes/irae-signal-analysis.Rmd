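---
title: "Disproportionality analysis and mechanism screening for immune-related adverse events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality analysis and mechanism screening for immune-related adverse events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(iraesignal)
library(dplyr)
```

## The problem

Immune checkpoint inhibitors (ICIs) — anti-PD-1, anti-PD-L1 and
anti-CTLA-4 antibodies — act by releasing the brakes on T-cell activity.
The same mechanism produces immune-related adverse events (irAEs):
toxicities from over-activation of the immune system against normal
tissue. In nervous-system cancer (NSC: glioma, glioblastoma,
astrocytoma, neuroblastoma, ...) ICIs are used rarely and mostly in
combination with chemotherapy, so their toxicity profile in this
population is poorly characterized and cannot be read off clinical
trials.

Spontaneous-report databases in the style of the FDA Adverse Event
Reporting System (FAERS) offer a route: compare the reporting pattern of
patients on ICI + chemotherapy (`ICI_Chemo`) against patients on
chemotherapy alone (`Only_Chemo`) within the same indication, and flag
preferred terms (PTs) reported disproportionately often under ICI
exposure. `iraesignal` implements that full workflow — quarterly-file
ingestion, deduplication, cohort construction, three-algorithm
disproportionality with a conjunction rule, time-to-onset (TTO) and
logistic subgroup models — plus an expression-based mechanism screen
that correlates pathway activity across cancer types with each type's
irAE reporting odds ratio. A seeded synthetic-data generator emulates
every input, so the entire pipeline is testable offline with known
ground truth.

## Report ingestion and deduplication

FAERS-style quarters arrive as six `$`-delimited tables (DEMO, DRUG,
REAC, OUTC, THER, INDI) keyed by `(primaryid, caseid)`, plus a Deleted
file of withdrawn caseids. Cases are resubmitted across quarters as new
versions, so deduplication matters more than in most tabular pipelines:
the package keeps, per `caseid`, the record with the highest
`caseversion`, breaking ties by latest receipt date and then by lexically
largest `primaryid`. This rule is the conventional deterministic choice
for FAERS work; the upstream description of practice does not pin one
down, so the tiebreak order is documented here rather than assumed.

Partial dates (`YYYY` or `YYYYMM`) are completed to the earliest
consistent day and flagged `imprecise`; TTO consumers can exclude
flagged records. Ages are normalized to years from the age/unit pair
(decades, months, weeks, days), with implausible values (> 120 y) set
missing. Verbatim drug names are standardized by a case-, whitespace-
and trailing-punctuation-insensitive lookup; unmatched names pass
through and are tallied in a coverage report, because silently dropping
them would bias arm assignment.

## Cohort construction

Only primary suspect (PS) drugs determine exposure. A case enters the
`ICI_Chemo` arm when at least one PS drug maps to an ICI class (PD1,
PDL1, CTLA4), and `Only_Chemo` when its PS drugs are chemotherapy only;
cases with neither are excluded and logged rather than forced into an
arm. Regimens refine the ICI arm by the set of ICI classes present:
`PD1_Chemo`, `PDL1_Chemo`, `CTLA4_Chemo`, the `PD1_CTLA4_Chemo`
doublet, and `Combined-ICI_Chemo` for any other multi-class
combination. Indication filtering is case-insensitive exact matching of
PS-drug indications through a user-supplied term-to-HLGT lookup (the
MedDRA hierarchy itself is licensed and must be supplied; the packaged
CSV is a small synthetic stand-in covering the nervous-system terms).

Age groups are `<45`, `45-64` and `>64`; the middle interval is closed
on both ends, a choice the printed group labels leave open.

## The three statistics and the conjunction rule

For each PT, reports are counted once per cell of the 2×2 table (a =
exposed with the event, b = exposed without, c/d likewise for the
comparator; N = a+b+c+d):

- **ROR** = (a·d)/(b·c), with Wald bounds
  `exp(ln ROR ± 1.96·sqrt(1/a + 1/b + 1/c + 1/d))`.
- **PRR** = [a/(a+b)] / [c/(c+d)], with the Yates-corrected chi-square
  `N(|ad − bc| − N/2)² / [(a+b)(c+d)(a+c)(b+d)]`, the corrected
  numerator floored at zero.
- **IC** = log₂((a+0.5)/(E+0.5)) with E = (a+b)(a+c)/N, the shrinkage
  observed-to-expected information component. Its lower 2.5% bound uses
  the closed approximation `IC − 3.3(a+0.5)^(−1/2) − 2.4(a+0.5)^(−3/2)`
  by default; an exact Gamma-quantile variant
  (`log₂ q₀.₀₂₅[Gamma(a+0.5, rate = E+0.5)]`) is available via
  `ic_variant = "gamma"` and feeds the same conjunction rule.

A PT is a signal only when **all five** criteria hold: a ≥ 3,
ROR025 ≥ 1, IC025 > 1, PRR > 2 and χ²_yates ≥ 4. Zero cells leave ROR
and PRR undefined and their criteria failed — no continuity correction
is applied, because the conjunction already demands a ≥ 3 and patching
zeros would only manufacture borderline signals.

```{r}
judge_signal(tibble::tibble(a = 10L, b = 90L, c = 100L, d = 9900L)) |>
  select(a:d, ror, ror025, prr, chi2_yates, ic, ic025, is_signal)
```

### A design note on the IC and arm balance

Within a two-arm design, E ≥ a·(a+b)/N, so IC ≤ log₂(N/(a+b)): the
information component is capped by the log inverse of the exposed
fraction. With a balanced 50/50 split the cap is 1 and **IC025 > 1 can
never fire, for any event, however disproportionate**. The criterion is
only meaningful when the exposed arm is a minority — which is also the
realistic situation here, since ICI use in nervous-system cancer is
rare. The synthetic generator therefore defaults to a 10% ICI arm;
users applying the conjunction rule to near-balanced designs should
expect the IC criterion to be the binding one.

A related subtlety: IC is not monotone in a when a dominates the event
margin (raising a also raises E through the (a+c) factor). In the
surveillance regime — event counts small against both margins — it is
strictly increasing, and the test suite pins exactly that regime.

## Time-to-onset and prognosis models

TTO is the event date minus the earliest PS therapy start (configurable
to latest); negative intervals are excluded and logged, and records
derived from partial dates stay flagged. Group differences use
two-sided Mann–Whitney tests per pair of groups — the natural rank test
for right-skewed onset-time distributions — with empirical CDF exports
for plotting.

Prognosis is modelled as death (outcome code `DE`) by binomial-family
GLM (maximum likelihood via IRLS), in two modes: univariable (one
covariate at a time) and multivariable (jointly). Odds ratios carry
Wald 95% intervals. Reference levels are age `<45`, female sex, and
the `ICI_Chemo` arm, so a reported OR > 1 for `Only_Chemo` reads as
"chemotherapy-only regimens are a risk factor". Apparent separation
(|coefficient| > 15 on the logit scale) or non-convergence within 100
IRLS iterations flags the fit and withholds its terms.

## Mechanism screening

The mechanism pipeline asks whether pathway activity across cancer
types tracks each type's irAE reporting odds ratio:

1. **ssGSEA** scores each sample against each gene set: genes are
   ranked by expression (descending, average ranks on ties) and the
   score is the sum over the ranked list of the difference between the
   weighted in-set cumulative distribution (member genes weighted by
   rank^τ, τ = 0.25) and the uniform out-of-set cumulative
   distribution. The score is a sum of ECDF differences with no further
   normalization; an optional min-max rescaling across samples is off
   by default. Because only within-sample ranks enter, any strictly
   increasing transform of a sample's expression leaves its score
   unchanged — so the Gaussian marginals of the synthetic cohorts are
   immaterial.
2. **Median aggregation**: one score per (cancer type, pathway), the
   median over the type's samples; likewise median expression per gene.
3. **Spearman screening** against the observed per-type RORs, two-sided
   p < 0.05, unadjusted — matching the fidelity of the original
   analysis style; Benjamini–Hochberg adjustment is available but off
   by default. The candidate list is whatever survives screening; its
   size is data-dependent, never hard-coded.
4. **Bivariate search**: for every unordered pair of surviving
   candidates, `ror ~ x1 + x2` by least squares; each pair is compared
   against both nested univariate models by likelihood-ratio test
   (χ², 1 df, on twice the Gaussian log-likelihood difference), and
   ranked by the Spearman correlation of fitted vs observed RORs, ties
   by the smaller LRT p. The response is the raw ROR by default (the
   log scale is a config switch); nearly collinear pairs (|r| > 0.999)
   are skipped; designs with ≤ 3 types are refused as saturated.
5. **Preranked GSEA** of genes correlated with the RORs: classic
   running-sum enrichment score (weight 1), significance by gene-label
   permutation (the set re-drawn at the same size, ≥ 1000 permutations,
   +1-corrected two-sided p), BH across sets.

```{r}
sim <- generate_expression(expression_sim_config(seed = 11))
scores <- ssgsea_score(sim$expr, sim$gene_sets)
screen <- median_pathway_scores(scores, sim$sample_info) |>
  screen_pathways(sim$rors)
head(screen, 3)
```

## The synthetic generators

`generate_faers()` emits the exact quarterly dialect the reader parses,
plus a manifest of every planted quantity. Its defaults are the
emulated study conditions, fixed once:

- 5000 cases; 10% `ICI_Chemo` (see the IC design note), regimen mix
  dominated by PD-1 monotherapy combinations;
- one planted irAE ("Autoimmune encephalitis") at true ROR 10 on the
  odds scale — comparator probability 0.0068, exposed probability
  solved from `odds₁ = ROR · odds₀`, sized for an expected
  co-occurrence count near 30;
- Poisson(2) additional background PTs per report from a 20-term
  frequency table, identical in both arms, so the b/d cells are
  realistic;
- death risk on the odds scale: baseline 12%, OR 1.5 (45–64), 2.5
  (> 64), 2.0 (chemotherapy-only) — the planted truths the logistic
  recovery tests measure against;
- log-normal TTO per age group (median 90 days for 45–64 vs 40/45 for
  the younger/older groups, σ_log = 0.8), so the age-subgroup rank
  tests have a real effect to find;
- 10% duplicate resubmissions (version 2, later receipt), 2% deleted
  cases, 5% off-indication (melanoma) cases, 3% month-precision therapy
  dates, 30% verbatim drug-name noise (case, whitespace, trailing
  periods, trade names);
- dates uniform over 2013–2022.

`generate_expression()` builds per-type genes × samples matrices
(20 types × 15 samples × 1000 genes by default). A latent per-type
factor u = ρ·z + √(1−ρ²)·ε couples the planted set's member genes to
the standardized ROR ranks z at strength ρ (default 0.8); the noise
term is independent rather than orthogonalized, so ρ = 0 is a genuine
null, not an exactly-orthogonal one. Member genes are shifted by u per
type; all other genes are pure noise, and the null sets are drawn from
them. Default per-type RORs spread geometrically over [2, 25], the
range observed across nervous-system cancer types.

What the generators deliberately do **not** emulate: reporting-volume
seasonality, real MedDRA hierarchies, microarray platform or batch
effects, and cross-gene correlation beyond the planted factor. Passing
the recovery tests therefore demonstrates that the statistics,
filters and selection machinery do what they claim under known truth —
not that real FAERS or GEO data meet these assumptions.

One behaviour worth knowing: because single-sample enrichment is
rank-relative, strongly shifting the planted set's genes pushes every
other gene down the ranking, so null-set scores acquire a compensatory
(negative) coupling to the planted factor. At ρ = 0.8 this inflates the
apparent significance rate of null sets above α; at ρ = 0 calibration
is clean. This is a property of rank-based scoring itself, not of the
generator, and a larger background transcriptome dilutes it — one
reason the default is 1000 genes.

## Numerical choices and degenerate inputs

- Ties: average ranks everywhere (expression ranking, Spearman).
- Interval z fixed at 1.96; "025"/"975" name the 2.5%/97.5% bounds.
- Integer cells are cast to double before products (N·|ad−bc|² overflows
  32-bit integers already at moderate counts).
- Empty-event tables (a = c = 0) are valid inputs; their undefined
  statistics fail their criteria rather than erroring.
- A gene set covering the whole matrix has no out-of-set ECDF and is
  refused; sets with no overlap are skipped with a message.
- `deduplicate()` of an empty quarter list returns an empty store;
  cases left without reactions are dropped and counted.
- All generator randomness flows through a single mandatory seed;
  identical configs produce byte-identical files.

## Problem sizes used by the test suite

The simulation studies in the package's tests use sizes chosen as the
package's own standard conditions: 100 seeds × 5000 cases for
planted-signal recovery and for the null flag-rate study; 200
replicates × 2000 cases for logistic parameter recovery; 100 seeds of
20 types × 15 samples × 1000 genes for pathway recovery and null
calibration; 1000 simulations for the p-value uniformity checks; the
statistic oracles are verified on the exhaustive [0,12]⁴ table grid
plus a 50,000-table random sample of the [0,50] range.

## Limitations

Spontaneous reports carry no denominators: disproportionality measures
reporting association, not incidence or causation. The comparator here
is within-indication chemotherapy-only reporting, not the whole
database background, so signals are relative to that choice. The
"prognosis" endpoint is the death outcome code only; FAERS-style data
support no survival-time modelling. MedDRA content is user-supplied;
the packaged lookups are synthetic stand-ins sufficient for the
synthetic cohort. The discrepant published estimates one sometimes sees
for best-pair predictive correlations (fitted on the same data that
selected the pair) are an inherent optimism of exhaustive model
selection at n = 20 types; the package reports the in-sample Spearman
and the LRT p-values and leaves external validation to the user.
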