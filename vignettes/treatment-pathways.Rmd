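---
title: "Mining treatment pathways and injection intensity for RVO macular edema"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining treatment pathways and injection intensity for RVO macular edema}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvopathways)
```

## The problem

Macular edema after retinal vein occlusion (RVO) is treated with repeated
intravitreal injections of five drugs in two classes: the anti-VEGF agents
bevacizumab, ranibizumab and aflibercept, and the steroids triamcinolone and
dexamethasone. Two questions drive real-world characterization of this
treatment: *in what order* are the drugs used (treatment pathways: first,
second and further lines of therapy), and *how intensively* (average number
of injections per patient in the first and second year after treatment
start). Observational answers come from hospital EHR data standardized to
the OMOP Common Data Model and analyzed in a distributed fashion — each site
runs identical code and only aggregate counts leave the firewall.

`rvopathways` implements this analysis over a minimal CDM-shaped layout
(four flat tables: person, drug exposure, condition occurrence, observation
period), together with a synthetic-EHR generator whose closed-form expected
summaries make the whole pipeline testable without access to any private
hospital database.

## Cohort phenotype

The phenotype is applied in a fixed order by `build_cohort()`:

1. **Index date** — a patient's first exposure to any of the five target
   drugs. When two drugs start on the same day, the first drug is chosen by
   a fixed canonical ingredient order (bevacizumab, ranibizumab,
   aflibercept, triamcinolone, dexamethasone) and the tie is logged; the
   choice is arbitrary but deterministic, and same-day starts are rare.
2. **Study period** — the index date must fall in 2003-01-01..2018-12-31.
3. **Diagnosis window** — at least one RVO diagnosis in the half-open window
   `[index, index + 180 days)`. Half-open intervals are used uniformly in
   this package, so "within 180 days" excludes day 180 itself; a diagnosis
   recorded only before the index date does not qualify.
4. **Exclusion sets** — no diagnosis of exudative AMD, choroidal
   neovascularization of other cause, central serous chorioretinopathy,
   uveitis or inherited retinal disease. By default *any* record
   disqualifies (`exclusion_lookback = "any_time"`), because these are
   mostly chronic differential diagnoses; `"pre_index_only"` restricts the
   lookback to records dated on or before index.
5. **Era** — the index date assigns one of three analysis eras reflecting
   the introduction of anti-VEGF therapy: P1 (2003–2005, before off-label
   bevacizumab), P2 (2006–2011) and P3 (2012–2018, after on-label approval
   of ranibizumab for this indication).

Follow-up is `observation_period.end - index` in whole days. Overlapping or
multiple observation-period rows are merged at load into a single span per
person (earliest start to latest end); follow-up length is then a single
well-defined interval, which the year-2 denominators below depend on. A
person with events but no observation period gets an imputed period spanning
first to last event (with a warning) under the default lenient mode.

Each filtering step records its remaining count in an attrition table, so
the usual patient-selection flowchart can be reproduced exactly. Person
records are never linked across sites: a patient attending two hospitals is
two persons, matching the aggregate-only analysis model.

## Lines of therapy and pathway trees

`derive_lines()` collapses a patient's date-ordered exposure sequence into
lines of therapy by stable first-appearance deduplication: each distinct
drug opens a line, and re-prescription of a drug already used in an earlier
line does not open a new one (so bev, triam, bev, dex is the three-line
pathway bev > triam > dex). This is the one rule the rest of the pathway
machinery depends on, and the test suite checks it exhaustively against an
independent stable-dedup oracle for every sequence of up to 6 exposures over
4 drugs.

`mine_pathways()` aggregates per-patient sequences into a `pathway_tree`:
counts of every sequence prefix, truncated at `max_depth` (default 3,
matching first-to-third-line diagrams; `Inf` keeps full sequences, which can
reach 5 lines). By default all exposures from index to observation end
contribute; `window_days` can cap the pathway observation window.

Three aggregate views are derived from a tree:

* `transition_summary()` — at line level L, patients with exactly L lines
  "continued" and those with an L+1-th line "switched"; the two fractions
  partition the at-risk set. At the truncation depth deeper switches are
  invisible, so transition summaries should be read from full-depth trees.
* `switch_breakdown()` — among patients starting with a given drug (or
  class), the share whose second line is each drug, with the first-line
  subgroup as denominator.
* `to_sunburst()` / `to_sankey()` — diagram data exports. Both conserve
  counts exactly: every sunburst node's children (its extensions plus an
  explicit "stop" leaf) sum to the node's value, and every Sankey node's
  outflow equals its inflow with the remainder flowing to a terminal stop
  node. Rendering itself is out of scope; the exports are plain
  nested-JSON / node-link structures.

`merge_pathway_trees()` sums node counts across trees. Because mining is a
pure per-patient count, mining per site and merging is *exactly* equal to
mining the pooled cohort — the property that makes aggregate-only
distributed analysis lossless for these outputs, and one the pipeline
verifies on every run with more than one site.

## Injection intensity

`intensity_table()` computes the average number of injections per patient by
era, first-drug-class stratum (anti-VEGF-first / steroid-first / all) and
drug, for year 1 and year 2 after index:

* Year windows are fixed 365-day half-open intervals (`[0, 365)` and
  `[365, 730)` days from index); day 365 belongs to year 2. No leap-year
  adjustment is made, so the windows are deterministic.
* Same-day duplicates of one drug count once (bilateral same-day injections
  cannot be distinguished without laterality, which the data model omits).
* The ALL row uses all stratum members as the year-1 denominator and
  members followed at least 365 days for year 2. Under the two-year
  sensitivity scope (`min_2y_followup`) both columns first restrict to
  members followed at least 730 days, which is why every ALL row then shares
  a single denominator across the two years.
* Per-drug rows default to `drug_row_denominator = "received_in_year1"`:
  the denominator is stratum members with at least one year-1 injection of
  that drug, restricted by follow-up for the year-2 column. The published
  per-drug denominators are consistent with this rule, but no source states
  it outright, so `"all_in_stratum"` is available as the alternative; note
  that injection-total conservation between the ALL row and per-drug rows
  holds in both years only under consistent (`all_in_stratum`)
  denominators, and in year 1 under either rule.
* Cells with an empty denominator are emitted with `n = 0` and `NA` mean
  rather than dropped, so table layouts are stable.

`persistence_breakdown()` classifies each member followed at least one year
by the drug classes received in year 2 (anti-VEGF only / steroid only /
both / none), cross-tabulated by era and first-drug class.

## The synthetic generator

`simulate_cdm()` emulates the data-generating structure the analysis
assumes, patient by patient:

* era (weights default to the published per-era cohort sizes, 118 / 790 /
  2378 of 3286) and an index date uniform within the era;
* first-line drug from per-era probabilities anchored to the published
  shares (triamcinolone-dominated in P1, bevacizumab-dominated later);
* a line-switching process: after each line a further line starts with
  probability `switch_prob` (default 0.19, the published level-1 switch
  fraction), the new drug drawn from a per-current-drug target matrix
  renormalized over drugs not yet used (steroid-to-steroid switches have
  probability zero, as observed), up to 5 lines;
* injection counts: every drug in the line sequence contributes its
  line-opening injection plus Poisson(`year1_rate` − 1) further year-1
  injections — so the expected year-1 count per line drug is exactly
  `year1_rate` — and Poisson(`year2_rate`) year-2 injections. Rates default
  to values anchored to the published intensity tables. Injection days are
  distinct per drug (drawn without replacement within the year window), so
  same-day self-duplicates never arise by accident; line starts are strictly
  increasing, spaced about `interval_days_mean` apart, and always inside
  year 1;
* an RVO diagnosis inside the 180-day window with probability
  `dx_within_window_prob` (otherwise after it — such patients must be
  filtered out by the cohort builder, and the ground truth flags them), and
  an exclusion diagnosis with probability `exclusion_dx_prob`;
* right-censoring from a mixture over follow-up ranges (default mass 0.20
  below one year, 0.25 between one and two, 0.55 beyond two — the published
  cohort had 52% with more than two years), with all events after the
  observation end truncated away, exactly as a source database would not
  contain them.

The generator's ground truth records both the drawn (`true_lines`) and the
emitted (`observed_lines`) sequence; the two differ only when censoring
truncates a later line. Eligibility flags predict cohort membership exactly.

`expected_summaries()` returns the closed-form expectations of what the
pipeline estimates, by exhaustive enumeration of the at-most-five-line
switching process (at most a few hundred sequences): first-line shares, the
level-1 switch fraction, and the mean year-1 injection count, each with a
binomial or enumeration-based standard error at the configured sample size.
The headline estimands are cohort-level (eras pooled), with SEs at
`n_patients`; per-era breakdowns are also returned. Each estimand is defined
on a subset censoring cannot distort — shares over all included patients
(the first exposure is always observed), the switch fraction over members
followed at least one year (every line start lies inside year 1), and the
year-1 mean over members followed at least two years, the same denominator
as the sensitivity analysis. Recovery tests therefore compare estimator and
expectation on identical estimands, at three standard errors for stochastic
quantities and exactly for degenerate configurations (a single first-line
drug, or `switch_prob = 0`).

What the generator does *not* emulate: reimbursement-policy dynamics, drug
approval timing within an era, visit scheduling (injection days are
exchangeable within a year window rather than clustered), disease severity,
laterality, and any visual outcome. Passing recovery tests therefore shows
that the pipeline measures what it claims on data with this statistical
skeleton — not that the defaults reproduce any particular hospital's
numbers.

## Numerical and design choices

* **Problem sizes.** The recovery tests use five configurations of 5,000
  simulated patients each; structural (conservation, merge, determinism)
  checks use 300–2,000. These sizes keep binomial SEs near half a percent,
  which is the precision at which the published shares are quoted.
* **Determinism.** All randomness flows from one seed; outputs are sorted
  on explicit keys before writing, so identical inputs give byte-identical
  artifacts.
* **Degenerate inputs.** Empty tables propagate to empty (but fully typed)
  cohorts, trees and intensity tables; zero-denominator transition
  summaries raise an explicit error rather than returning NaN.
* **Dates.** ISO-8601 everywhere; dates outside 1900–2100 are treated as
  parse errors with file and line context. Code resolution is exact
  (vocabulary, code) matching against enumerated concept sets — the package
  ships synthetic placeholder codes, and no vocabulary hierarchy is
  traversed.
* **Tie-breaks.** The canonical ingredient order resolves every same-day
  ambiguity (first-drug choice and within-day exposure ordering), making
  permutation of input rows irrelevant to any output.

## Known limitations

The unit of analysis is the patient: eyes are not modeled, so bilateral
treatment inflates per-patient counts relative to per-eye counts. The
re-prescription collapse rule cannot distinguish a planned combination from
a switch-and-return. Follow-up is a single interval per person; gaps in
observation are absorbed. Whether the published per-drug year-2
denominators used the received-in-year-1 rule is inferred from printed
sample sizes, not stated — both denominator rules are provided. Transition
fractions at the truncation depth of a depth-limited tree are
underestimates; use full-depth trees for those.

## A worked example

```{r example, eval = FALSE}
library(rvopathways)

sim <- simulate_cdm(simulation_config(n_patients = 2000, seed = 7,
                                      sites = c("A", "B")))
built <- build_cohort(sim$tables)
exposures <- cohort_exposures(sim$tables, built$cohort)

tree <- mine_pathways(built$cohort, exposures, "none", max_depth = Inf)$all
transition_summary(tree, 1)
switch_breakdown(tree, "anti_VEGF")
intensity_table(built$cohort, exposures)
```

The same steps, plus diagram exports and manifest writing, are orchestrated
by `run_pipeline()`, and `make_fixture()` writes a fully worked 8-patient
micro-dataset whose every number can be traced by hand.
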