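# phenomescan

Automated phenome scans (pheWAS, MR-pheWAS, EnWAS) for biobank-style cohorts.

A phenome scan tests one trait of interest — a SNP, a weighted allele score, or
an ordinary phenotype — against *every* phenotype a cohort holds. Biobank
phenotypes are heterogeneous (repeat-measured spirometry, zero-inflated alcohol
intake, ordinal questionnaire items, multi-select fields), so no single model
fits them all. `phenomescan` automates the modelling decision per field with a
rule-based flow, runs the matching regression for each derived variable, and
returns ranked, Bonferroni-corrected results with QQ/forest plots and a
hierarchical JSON export for interactive browsing. It is aimed at
epidemiologists running hypothesis-free screens who will follow up hits with
bespoke models.

## The engine in brief

Every field, declared continuous / integer / categorical (single) /
categorical (multiple), is pushed through a decision flow onto one of four
data types, each with its regression (phenotype = dependent variable,
trait = independent, adjusted for confounders — age and sex by default, plus a
genotype-chip indicator for genetic traits, or the columns of a confounder
file):

| data type | model | estimate | p-value |
|---|---|---|---|
| continuous | linear regression on Φ⁻¹((r−½)/n) rank-normalised values | β per unit trait | Wald |
| ordered categorical | proportional-odds logistic | OR per unit trait | LRT (default) |
| unordered categorical | multinomial logistic | — | LRT, χ²(K−1) |
| binary | binomial regression | OR per unit trait | Wald |

Key rules: first time point only, array repeats averaged; categorical
negatives (prefer-not-to-answer codes) recoded to missing; heavily tied
continuous variables (modal share > 0.2) binned into 3 equal-mass ordered
categories instead of rank-normalised; integers with 2 distinct values binary,
3–20 ordered, >20 continuous; multi-valued fields expanded into one binary per
value with a choice of comparison group, unknown (negative) codes blocking
FALSE but not TRUE; variables with <500 complete cases or >1000 unordered
categories removed and counted. Results ranked by p; the threshold is
α / m where m counts non-validation results with a p-value.

## Worked example

The package ships a synthetic-cohort generator with known ground truth, so a
complete scan runs with no external data:

```r
library(phenomescan)

cfg   <- simulation_config(n_participants = 5000, seed = 2026)
paths <- write_fixture_files(cfg, "cohort")

rc <- run_config(
  phenofile = paths$pheno, traitofinterestfile = paths$trait,
  confounderfile = paths$confounders,
  variablelistfile = paths$variable_info, datacodingfile = paths$data_codings,
  categoriesfile = paths$categories, fieldmapfile = paths$field_map,
  resdir = "scan-results", genetic = TRUE, seed = 1234)

scan <- run_phenome_scan(rc)
print(scan)
#> phenome scan: 76 results, 75 counted tests, threshold 0.000667 (alpha 0.05); 19 below threshold

head(scan$results[, .(varName, data_type, n, estimate, ci_lower, ci_upper, p_value)], 5)
#>    varName  data_type     n  estimate  ci_lower  ci_upper      p_value
#> 1:    1040 CONTINUOUS  4905 0.7094478 0.6900066 0.7288890 0.000000e+00
#> 2:    1021    ORDERED  4887 1.4089999 1.3290821 1.4937232 1.290832e-31
#> 3:    1022    ORDERED  4905 0.7626721 0.7218036 0.8058545 2.003932e-22
#> 4:    3030  UNORDERED  4800        NA        NA        NA 3.212983e-22
#> 5:    3031  UNORDERED  4791        NA        NA        NA 3.347164e-21
```

Reading the output: 76 variables were tested, but the top hit (field 1040) is
the fixture's *trait-equivalent* field — flagged a priori as essentially the
trait itself, so it is reported for validation and excluded from the 75-test
multiple-testing burden (threshold 0.05/75 ≈ 6.7×10⁻⁴). Fields 1021/1022 are
zero-inflated measures the flow binned into 3 ordered categories: their
odds ratios (1.41, 0.76) per SD of the allele score carry the injected
positive and negative effects with the right signs. The unordered fields
(3030/3031) have likelihood-ratio model p-values and, by construction, no
overall estimate — which is also why they never appear in forest plots.

`scan-results/` then contains `results.tsv` (the ranked table), `qq.pdf`,
`forest-{continuous,ordered,binary}.pdf`, `viz-results.json` (category-tree
export, schema in `inst/schema/`), a flow-count table and a run log. Large
scans can be split into jobs with `num_parts`/`part_index` and combined with
`merge_scan_parts()`, which recomputes the threshold over the merged results.
A command-line wrapper lives at `inst/cli/phenomescan.R`:

```sh
Rscript inst/cli/phenomescan.R --phenofile cohort/pheno.csv \
  --traitofinterestfile cohort/trait.csv --confounderfile cohort/confounders.csv \
  --variablelistfile cohort/variable-info.tsv --datacodingfile cohort/data-codings.tsv \
  --resdir scan-results --genetic --num-parts 3 --part-index 1
```

## Documentation

The methods vignette (`vignettes/phenome-scans.Rmd`) describes the decision
flow, every tunable parameter and its default, the synthetic generator and
what it does and does not emulate, and the package's design choices and
limitations.
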