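---
title: "From plasma metabolite panels to regulatory pathways: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From plasma metabolite panels to regulatory pathways: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboreg)
```

## The problem

Parkinson's disease (PD) and vascular parkinsonism (VP) present with similar
motor syndromes but arise from different pathology — neurodegeneration of the
nigrostriatal dopaminergic system versus cerebral small-vessel disease.
Targeted plasma panels of amino acids and acylcarnitines (measured by
LC-MS/MS in micromolar concentrations) are candidate diagnostic readouts for
both, yet the significant metabolites overlap heavily between the two
diseases, limiting their direct discriminative value. The working hypothesis
this package operationalizes is that the *regulatory routes* from
disease-associated genes to the enzymes converting those metabolites differ
between the diseases even where the metabolite changes themselves do not.

The pipeline therefore has two halves:

1. **Differential screening** — per-metabolite nonparametric comparison of
   each disease group against controls with false-discovery-rate control,
   and a three-way classification of significant metabolites
   (disease-A-specific / disease-B-specific / shared).
2. **Regulatory pathway enumeration** — over a typed molecular-interaction
   graph, enumeration of all simple directed paths from disease marker
   proteins to the biosynthesis/degradation enzymes of the significant
   metabolites, constrained by declarative pathway templates, followed by
   count aggregation and an enzyme-specificity call.

## Screening model and assumptions

For each disease group $d$ and metabolite $m$, the case sample
$x_{d,m}$ is compared to the control sample $y_m$ with two complementary
nonparametric tests: the Mann–Whitney $U$ test (sensitive to location
shifts) and the two-sample Kolmogorov–Smirnov test on
$D = \sup_t |\hat F_x(t) - \hat F_y(t)|$ (sensitive to any distributional
difference). No distributional form is assumed; concentrations are analysed
on their natural scale, and missing cells are excluded pairwise per
metabolite, so effective sample sizes can differ across metabolites.

Branch policy, chosen to keep small-sample inference exact:

* Mann–Whitney uses the exact null distribution whenever the smaller group
  has at most 12 observations and the pooled data are tie-free; the
  two-sided exact p-value is twice the smaller tail probability, capped
  at 1, which equals the full permutation-enumeration p-value. Otherwise
  the normal approximation with midrank tie correction and continuity
  correction is used.
* Kolmogorov–Smirnov uses the exact conditional distribution when both
  groups have at most 12 tie-free observations, otherwise the asymptotic
  distribution. With a control group of 17, the KS p-values in the default
  design are asymptotic — a deliberate conservatism documented per row in
  the output (`ks_method`).
* If all pooled values are identical the tests are degenerate; p is set
  to 1 and flagged rather than erroring, so an all-zero analyte cannot
  crash a screen.

Benjamini–Hochberg adjustment is applied across the panel's metabolites
*separately for each test within each contrast* (not pooled across
contrasts): each disease-versus-control comparison is reported as its own
family, which matches how such case/control screens are summarised. Whether
FDR should instead span metabolite-by-test pairs is genuinely open; the
per-test scope was chosen because the two tests are not independent
evidence and pooling them into one family would make the effective FDR
level depend on their correlation.

A metabolite is called significant for a contrast by a configurable
**combination rule**: `both` (default; both BH-adjusted p-values below
$\alpha$), `either`, `mw_only`, or `ks_only`. The conjunction is the
default because requiring agreement of a rank test and an ECDF test is the
most conservative choice and, at the study design simulated here (strong
planted shifts, groups of 9/9/17), it reproduces the expected counts; the
rule actually used is recorded in every run manifest. $\alpha = 0.05$
throughout, matching the conventional FDR < 0.05 threshold.

Classification partitions the panel: a metabolite significant in both
contrasts is `shared`, in exactly one it is `<disease>_specific`,
otherwise `none`.

## The knowledge graph and pathway templates

The interaction substrate is a directed multigraph over `protein` and
`gene` nodes with eight edge kinds: `ppi` (protein–protein interaction,
stored as two directed edges; a simple path can never traverse both
directions because it may not revisit a node), five protein-level
regulation kinds (`activity_`, `degradation_`, `transport_`,
`proteolysis_`, `catalysis_regulation`), `expression_regulation`
(protein → gene only) and `encodes` (gene → protein only). Self-loops and
duplicate (source, target, type) triples are rejected at construction, so
every downstream count is well-defined.

Pathways from a marker protein to an enzyme protein must match one of four
templates (templates are data — YAML-loadable — so the defaults can be
replaced without code changes):

| id | shape |
|----|-------|
| T1 | marker —(protein-level edge)→ enzyme |
| T2 | marker —(expression_regulation)→ enzyme gene —(encodes)→ enzyme |
| T3 | marker —(protein-level)→ intermediate(s) —(protein-level)→ enzyme |
| T4 | marker —(protein-level)→ intermediate(s) —(expression_regulation)→ enzyme gene —(encodes)→ enzyme |

T3/T4 require at least one intermediate protein, so no concrete path can
match two default templates (T1/T2 are shorter by construction). The
number of intermediates $K$ defaults to 1 — published pathway diagrams of
this kind show single mediators, and enumeration cost grows
combinatorially in $K$ — but is configurable.

Intermediate proteins are *not* supplied by the user; the enumeration
discovers them. Two paths are distinct iff their (node sequence, edge-type
sequence) pairs differ, so parallel edges of different types count as
distinct regulatory routes; edge signs (up/down) are carried through to the
output but not constrained, because activation/inhibition semantics of a
mixed-kind chain are not well defined without per-step direction data. The
default figure-level quantity is the *path count*; a `dedupe = "pairs"`
mode collapses to distinct (template, marker, enzyme) pairs instead, since
"number of regulatory connections" is ambiguous between the two readings.

Enumeration is a segment-guided depth-first search: template segments are
expanded over their repeat ranges into concrete step sequences, and the
DFS only follows edges whose type and target node-type the current step
allows, pruning the final step to land on an enzyme target. The
simple-path constraint (no node revisits) guarantees termination on cyclic
graphs. All outputs are sorted lexicographically so repeated runs diff
byte-identically.

## Marker and enzyme sets

Disease marker lists are treated as sets of upper-cased gene symbols;
duplicates collapse with a warning. The partition into A-only, B-only and
shared sets satisfies `|A_only| + |shared| = |set(A)|` exactly. Significant
metabolites map to conversion enzymes through a frozen five-column table
(metabolite, enzyme protein, enzyme gene, biosynthesis/degradation role,
metabolism class). The shipped `inst/extdata/enzyme_map.tsv` is a
**synthetic stand-in**, not a database export: it covers the amino-acid and
acylcarnitine metabolism enzymes relevant to the parkinsonism case study
(ALDH2, AL1B1, BCAT1/2, P4HA1/2, P5CR1, UD11, FAS, CPT1A/B/C, ACC1,
ODPA/ODPB, OCTC, FURIN, S22A6) with plausible assignments; real analyses
should substitute a curated extraction in the same layout. Metabolites
without a mapping are reported, never silently dropped.

## Specificity calls

"Enzyme specific to a disease" is not defined numerically in the
literature this package mirrors; the operationalization here is the
dominant-group margin rule: for each enzyme, count incoming pathways per
marker group; call the top group if its count is at least `min_count`
(default 1) and at least `min_margin` (default 1.5) times the runner-up;
ties and sub-threshold margins give `mixed`. The margin ratio uses
`max(1, second)` in the denominator so an uncontested count is finite.
Both thresholds are configuration, surfaced in the run manifest, and the
calls are invariant to input order.

## What the synthetic generators emulate

The package is fully testable offline because every input has a generator:

* **Panels** (`simulate_panel()`): per-metabolite log-normal
  concentrations — the standard model for LC-MS/MS targeted panels — with
  baseline log-means drawn uniformly on log(1)–log(100) µM, a shared
  log-scale standard deviation (`cv`, default 0.3), and planted group
  shifts (`log_fold_shift`, default 2.0 natural-log units) on chosen
  effect sets. Defaults mirror the study design: groups of 9/9/17 over 44
  metabolites (14 amino acids, 30 acylcarnitines).
  `simulate_study_panel()` plants the published significance pattern — 17
  shared metabolites (Ala, Pro, Ile, Val + 13 acylcarnitines), Met
  PD-only, and C0/C6/C10/C10:1 VP-only — as a synthetic stand-in for the
  cohort table, which is not redistributable.
* **Marker lists** (`simulate_marker_lists()`): two symbol lists with an
  exact intersection size (defaults used in the analyses: 84 and 60 with
  22 shared).
* **Graphs** (`simulate_knowledge_graph()`,
  `simulate_marker_enzyme_graph()`): planted exact template instances plus
  Erdős–Rényi noise edges typed uniformly at random under the node-type
  constraints; noise never duplicates a planted (source, target, type)
  triple, so planted counts are exact in noise-free graphs.

What the generators do *not* emulate — and hence what passing tests do not
establish about real data: between-metabolite correlation (real panels are
strongly correlated within lipid classes), heteroscedastic or heavy-tailed
measurement error, batch effects, censoring at the limit of detection, the
scale-free topology and annotation biases of literature-derived interaction
networks, and any biological correctness of the enzyme map. Results on
real cohorts depend on those properties; the tests establish algorithmic
correctness, calibration under the stated model, and reproducibility.

All generators take explicit integer seeds, restore the caller's RNG state
(no global side effects), and are bit-reproducible.

## Numerical and engineering choices

* Concentrations are written with `%.17g`, so CSV/TSV round trips are
  bit-exact; missing cells are empty fields, read back as `NA` (never 0).
* XLSX input is supported read-only (via readxl); no xlsx writer is a
  package dependency, so canonical interchange is TSV.
* The SIF dialect cannot carry node types or signs; the writer emits a
  `<path>.nodes.tsv` sidecar and encodes signs as `edge_type(sign)`, and
  isolated nodes are bare-id lines (edge-TSV uses two-field lines), making
  all three graph formats round-trip exactly.
* BH adjustment delegates to `stats::p.adjust`; the exact tests delegate
  to `stats::wilcox.test`/`stats::ks.test` under the branch policy above.
  The test suite verifies both against independent full-enumeration
  oracles rather than trusting the delegation.
* A transposed profile layout (metabolites in rows) is auto-detected via
  the group column's position and pivoted.

## Problem sizes used by the test suite

The suite exercises the statistical engine against full permutation
enumeration at $n_1, n_2 \le 6$ (100 tie-free datasets), BH against the
step-up formula on 50 random vectors, null FDR calibration on 500
simulated null panels at the 9/9/17 design, planted-metabolite power on
200 replicates at shift 2.0 / cv 0.3, and path enumeration against a
brute-force all-simple-paths oracle on 100 random typed graphs of up to 12
nodes. These sizes give stable Monte-Carlo estimates (the null-FDR check
uses a 3-standard-error budget) while keeping a full run in the low
minutes on one core.

## Known limitations

* The four default templates are a reconstruction of the pathway types
  described in the source analyses' prose; richer ontologies (edge
  confidence, sign-consistent chains, longer mediator chains) require a
  user-supplied template YAML and, for signs, additional semantics not
  implemented here.
* Path counts are descriptive; no permutation null over graph topology is
  computed, so "more pathways" must not be read as statistical enrichment.
* The enzyme-specificity rule is a reasonable default, not an inference
  procedure; sensitivity to `min_margin` should be reported alongside any
  claim.
* With two disease groups sharing one control sample, the two contrasts
  are dependent; the per-contrast FDR guarantees are marginal, not joint.
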