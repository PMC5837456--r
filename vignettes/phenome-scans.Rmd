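---
title: "Automated phenome scans: the decision flow, its models and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated phenome scans: the decision flow, its models and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomescan)
library(data.table)
```

## The problem

A phenome scan tests one trait of interest — a SNP, a weighted allele score
used as a Mendelian-randomization instrument, or an ordinary phenotype —
against every phenotype a cohort offers. In a biobank-style cohort those
phenotypes are wildly heterogeneous: repeat-measured spirometry, zero-inflated
alcohol intake, walking-pace questionnaire items, multi-select "what bread did
you eat" fields. No single regression fits all of them, so most scans restrict
to a homogeneous subset (for example ICD codes as binaries). `phenomescan`
instead automates the choice: a rule-based flow assigns every field a
statistical coding and the matching regression, runs the scan, and returns
ranked, multiplicity-corrected results.

## The decision flow

Fields are declared by the cohort as one of four *field types* — continuous,
integer, categorical (single) or categorical (multiple) — and the flow maps
each onto one of four *data types*, each with its regression. The phenotype is
always the dependent variable and the trait the independent variable, adjusted
for confounders (age and sex by default, plus a genotype-chip indicator for
genetic traits, or exactly the columns of a user-supplied confounder file).

| data type | regression | estimate | p-value |
|---|---|---|---|
| continuous | linear (`lm`) | trait coefficient (SD units) | Wald |
| ordered categorical | proportional odds (`MASS::polr`) | odds ratio | LRT (default) or Wald |
| unordered categorical | multinomial (`nnet::multinom`) | none | LRT, K−1 df |
| binary | binomial (`glm`) | odds ratio | Wald |

The flow itself:

1. **First occurrence, array mean.** Fields measured at several time points
   contribute only the first (instance 0; if a field has no instance-0 columns
   the smallest instance present is used and logged — the convention must cover
   files that begin at a later visit). Continuous and integer fields with
   several array repeats at that time point are averaged per participant over
   non-missing repeats.
2. **Recoding.** Data-coding reassignments run first (including sending a raw
   value to missing); then, for categorical fields only, remaining negative
   values become missing — biobank codings use negatives for
   "prefer not to answer"/"do not know", while negative *measurements* are
   legitimate; finally a declared default value fills remaining gaps (useful
   for recorded-cases-only fields where absence means "no diagnosis").
3. **Continuous pathway.** Two distinct values make the variable binary.
   Otherwise, if the single most frequent value holds more than 20% of the
   non-missing observations, the variable is binned into 3 ordered categories;
   otherwise it is inverse rank-normal transformed and tested linearly.
4. **Integer fields** follow the continuous pathway except that 2 distinct
   values are binary and 3–20 are ordered categorical in natural numeric
   order; only >20 distinct values take the continuous path. Integers on that
   path are treated exactly as true continuous variables (same dominance check,
   same binning) — the boundary rule would otherwise be discontinuous at 21
   distinct values.
5. **Categorical (single)** fields are binary at 2 distinct values; otherwise
   their data code decides ordered (ranks from the declared value ordering)
   versus unordered.
6. **Categorical (multiple)** fields expand into one binary variable per
   distinct non-negative value, named `<fieldID>#<value>`. A participant is
   TRUE for value *v* if their value set contains it. Who counts as FALSE is
   field-specific (`cat_mult_missingness`): holders of some other value,
   responders to the field, or everyone. Regardless of option, a participant
   holding a negative (unknown) code who lacks *v* is set to missing — the
   unknown value could have been *v*, so FALSE cannot be asserted.

Two scan-level filters remove variables without aborting the scan: fewer than
500 complete cases (outcome, trait and all confounders observed), and more
than 1000 categories for unordered variables (beyond what a multinomial fit
will bear). Every removal is counted; the flow counters satisfy
`entered = emitted + removed` on every run, and the same conservation holds at
the scan level, so nothing disappears silently.

## Parameters that matter

* **Dominance threshold, 0.2 (strict `>`), configurable.** Rank-normalising a
  variable whose modal value covers a large share of the sample assigns random
  ranks within that mass — pure noise. A 20% share already puts ~a fifth of
  the sample on coin-flip ranks; above that, binning is the safer coding. The
  threshold is logged with every run and exposed as `bin_threshold`.
* **Number of bins, k = 3.** Split points are placed strictly between distinct
  observed values to minimise the maximum deviation of category counts from
  n/k, ties broken towards the lowest split values (a fixed, oracle-testable
  objective; "roughly equal mass" alone does not determine the split). With
  fewer than k (but more than 2) distinct values, each value becomes its own
  category.
* **Rank-normal offset.** The transform is Φ⁻¹((r − 0.5)/n): symmetric about
  zero, never touching the 0 or 1 quantiles. Ties take uniformly random ranks
  under a run seed (default 1234), offset deterministically per field id so
  partitioned and whole scans agree bit for bit.
* **Sample-size floor 500 and category cap 1000** follow the scan-level
  filters above; both boundaries are inclusive on the admitting side (exactly
  500 cases are tested, exactly 1000 categories fit).
* **Family-wise level α = 0.05.** The threshold is α divided by the number of
  counted tests: results flagged `validation_only` (fields declared a priori
  to be aspects of the trait itself, e.g. weight in an adiposity scan) are
  tested as positive controls but never counted, and non-converged results
  carry no p-value and are not counted either. `below_threshold` uses strict
  `<`.

## Design choices where the design was open

* **Ordered-model p-values** default to a likelihood-ratio test of the trait
  term (nested `polr` fits): LRT behaves better than the Wald test when cell
  counts are thin, which ordinal questionnaire items often are. `p_method =
  "wald"` is available, and the estimate/CI are Wald either way.
* **Non-convergence** (e.g. complete separation in a logistic fit) yields a
  retained result flagged `converged = FALSE` with no p-value, rather than a
  silent drop: an auditable scan must show every variable's fate.
* **Complete-case analysis per variable**, no imputation: each regression uses
  the rows with outcome, trait and confounders all observed; a confounder
  constant on those rows (sex, for a sex-specific field) is dropped and
  logged.
* **Partitioned scans** split fields into contiguous blocks by sorted field
  id. The Bonferroni count is finalised at merge time — per-part counts would
  distort the threshold — and the merge recomputes ranking and threshold over
  the concatenated rows, which are byte-identical to a single-part run.
* **Metadata dialects.** The variable-information and data-coding files are
  tab-separated with documented fixed headers; orderings join values with `|`,
  reassignments are comma-separated `old=new` pairs with `NA` as the
  to-missing target, and chained reassignments are rejected. The hierarchy
  used by the visualization export is two TSVs (categories with parent links;
  field-to-category map), validated to be a single-rooted tree; the JSON
  document structure is published in `inst/schema/viz-results.schema.json`
  and checked by `validate_viz_json()`.

## The synthetic cohort generator

`simulation_config()` + `generate_cohort()` emit a complete, self-consistent
set of scan inputs with known ground truth. The trait emulates a weighted
allele score: 96 simulated biallelic dosages, weights drawn once, summed and
standardised to unit SD, so "per unit trait" reads as "per SD of score".
Confounders are age (uniform over the recruitment range, centred at 57 in all
link functions) and sex; both load on every phenotype (defaults: 0.02 per
year, 0.2 for sex) so that adjustment is consequential. Effects are injected
on the link scale of the regression that will test the field — a linear shift
for continuous fields, log-odds for binary, proportional-odds log-OR for
ordered (logistic latent cut at equal-mass points), category-specific utility
shifts for unordered — so recovery checks compare like with like.

The default plan holds ~60 fields spanning every branch of the flow: plain and
repeat-measured continuous fields, zero-inflated fields that must be binned,
integer fields at the 2/20/21 distinct-value boundaries, ordered and unordered
questionnaire items (with a sprinkling of negative "do not know" codes),
a default-value cases-only field, multi-select fields with unknown codes, a
95%-missing field that falls to the sample-size filter, one trait-equivalent
field and one a-priori exclusion. Nulls dominate, as in a real phenome.

What the generator does **not** emulate: real marginal distributions or
linkage structure among variants, correlation between phenotypes,
missingness that is informative rather than completely at random, and
multi-time-point structure beyond a decoy later instance. Green tests
therefore certify the engine's logic and its statistical calibration under
clean conditions — not robustness to every pathology of real cohort data.

## Validation strategy and problem sizes

The test suite checks each numerical component against an independent oracle:
rank-normalisation against direct quantile evaluation of known ranks (1e−12),
binning against exhaustive enumeration of all split pairs on vectors with ≤12
distinct values, the logistic odds ratio against the 2×2 closed form (1e−6),
the ordinal model against a coarse-to-fine grid search of the
proportional-odds likelihood (1e−3) and against plain logistic regression on
2-level outcomes (1e−6), and the multinomial LRT statistic against
log-likelihoods evaluated directly from fitted class probabilities (1e−6).

Operating characteristics are checked on seeded synthetic cohorts sized for a
single CPU: a 500-variable null scan (125 per data type, n = 1000) whose
per-type rejection rate at the 0.05 level must sit within 3 binomial standard
errors of 0.05 and whose QQ curve must track the identity; 200 replicates
(n = 1200) in which injected effects must recover the correct sign at least
95% of the time; and a 3-part partitioned scan of the default ~60-field,
n = 5000 fixture that must merge row-identically to the single-part run.

## Known limitations

* One time point per field; longitudinal aggregation is out of scope (users
  can pre-aggregate and feed the result in).
* Huge unordered codings (>1000 categories, e.g. free-text-like job codes)
  are removed rather than hierarchically merged.
* The three-bin count for dominated continuous variables is fixed rather than
  adapted to the distribution.
* Estimates from a screen of this kind are for triage: winners are inflated
  (winner's curse) and correlated phenotypes make neighbouring results
  dependent, which is why the ranked table, the QQ plot and the hierarchical
  visualization export are all oriented towards follow-up rather than final
  inference.
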