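---
title: "Assertion datacubes and compatibility scores: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assertion datacubes and compatibility scores: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exocube)
```

## The assertion data model

Metabolite footprinting compares the extracellular metabolite pool of an
environment with and without a microorganism. `exocube` stores the curated
outcome of such experiments as a three-dimensional datacube in which one
observation is a unique (metabolite, organism, environment) triple. Two
kinds of observation coexist in one table:

* **control observations**, attached to the reserved pseudo-organism
  `"The Environment"`, state only whether the metabolite was `detected` or
  `not_detected` in the untransformed pool;
* **transformed observations** state the net action of an organism on the
  metabolite: `increased`, `decreased`, `no_change`, or `not_investigated`
  when the compound was not assessed.

Modelling the control as a pseudo-organism keeps all six states in a single
observation table and makes the control a selectable column in every view,
which is also how the one-organism view compares the compositions of several
control pools. Time points or consortia can be registered as distinct
"organisms" when a study needs them; the model imposes no interpretation on
the organism name beyond uniqueness.

Directional observations carry `log2fc`, the log2 of the spent-over-control
ratio, and a confidence score `min(|log2fc|, 5)` that drives the shading of
table cells and web connectors. The cap of 5 is part of the data model:
when a metabolite is detected on only one side a ratio against zero is
undefined, so a significant one-sided detection scores exactly the cap and
reports no fold change. Confidence is 0 for all non-directional actions.
These rules, together with key uniqueness, referential integrity and the
action/organism-type restrictions, are all enforced by `validate_cube()`,
which reports every violation rather than the first.

## The assertion engine

`assert_action()` converts replicate abundances for one metabolite into one
assertion:

1. **Detection.** Each pool is detected when at least
   `min_detected_replicates` replicate values lie strictly above
   `detection_threshold`. The strict inequality makes a threshold of 0 mean
   "any positive signal", and a value sitting exactly at the threshold does
   not count — a deliberate, documented tie-break since detection limits are
   instrument conventions, not data. The default of one replicate is
   permissive; laboratories with stricter reporting rules raise it.
2. **Nothing detected.** If neither pool is detected, no further assertion
   is determined: `not_investigated`, confidence 0. This branch also
   guarantees all-zero inputs can never reach a division.
3. **Statistical comparison.** Otherwise a two-sided test compares the
   pools. The appropriate test depends on the experimental design, so it is
   a configuration choice: Welch's t-test by default (unequal variances are
   the norm between control and spent pools), a Mann–Whitney rank-sum test
   as the nonparametric alternative. Non-significance at `alpha` is asserted
   as `no_change`.
4. **Direction and confidence.** Significant differences are `increased` or
   `decreased` by the ratio of replicate means — the fold change uses means
   as the natural summary of replicates — with
   `log2fc = log2(mean(spent)/mean(control))`, except for one-sided
   detections (cap rule above).

Two numerical edge cases are fixed by design. Zero-variance pairs, where the
t statistic is undefined, follow an exact rule: identical constant pools are
`no_change`; constant but different pools with detection are treated as
significant with the usual fold change. And equal means with a (formally)
significant p-value resolve to `no_change` — direction must be decidable.

`process_experiment()` runs the rule over every metabolite of an experiment
and emits the paired control observations (`detected`/`not_detected` from
the control pool alone). Multiple-testing correction is off by default,
mirroring simple per-metabolite testing; with
`mtc = "benjamini_hochberg"` the p-values of all metabolites on which a test
ran are corrected jointly before the `alpha` comparison. Per-metabolite
input errors are collected in an attribute instead of aborting a batch.

## Compatibility scores

Within one environment, with `D_s`/`I_s` the decrease/increase sets of
organism *s* and `P` the control pool:

* `EUS(s) = |D_s ∩ P| / |P|`,
* `FMC(s; r) = |D_s ∩ D_r| / |D_s|`,
* `FME(s; r) = |D_s ∩ I_r| / |D_s|`.

Two readings deserve a note. First, the OCS denominator is the **total**
number of metabolites the scored organism decreases, not the exclusive
difference `|D_s \ D_r|`: the bundled two-isolate demonstration requires
25/50 = 0.5 and 25/26 ≈ 0.96, which only the total reading produces (the
exclusive reading would give 1.0 in both directions). Second, the EUS
numerator intersects with `P`: a product absent from the control cannot be
consumed *from the starting pool*, so decreases of compounds outside `P`
(possible in principle with asymmetric detection) never inflate uptake.

Metabolites asserted `no_change` or `not_investigated` belong to neither
`D` nor `I` and can never enter a numerator or denominator. A score with an
empty denominator is undefined and reported as `NA` — never 0, which is a
meaningful score. Cell marks (`competition` for shared decreases, `exchange`
for decrease-vs-increase) are named rather than glyphs; their counts equal
the FMC and FME numerators by construction, which the tests assert against
a naive set-iteration oracle.

The scores are deliberately coarse screening tools: they ignore metabolite
function, growth, toxins and regulation, and a `no_change` call may hide
balanced production and consumption. They rank candidate partners; they do
not predict co-culture outcomes.

## Views and their encoding

All three slice tables and the web are generated from one shared cell rule,
so a (metabolite, organism, environment) cell is identical whichever view
contains it. Colours encode the action only (`tan`/`gray` for the control
column, `red`/`blue`/`white`/`checkered` for transformed cells); shade
encodes confidence only, linearly as `confidence/5`; no cell ever derives
colour from raw abundance. Missing combinations render `not_investigated`
(checkered) for organisms, and `not_detected` for the control column, whose
only legal states are detected/not detected.

Orientation and ordering choices that the table semantics leave open are
fixed for determinism: the one-metabolite view puts environments in rows and
organisms in columns; all orderings are lexicographic (byte-wise, locale
independent) with the control column first. The web draws an edge only for
`increased`/`decreased` — a no-change cell is no interaction — and a
metabolite node's degree counts its incident edges; control-pool metabolites
are kept as (possibly isolated) filled nodes, while hollow nodes are
products absent from the control. Exports are node-link JSON (round-trips
via `import_graph()`) and GraphML; tables export as TSV with colour and
shade as auxiliary columns.

## The synthetic generators

`generate_cube()` produces complete random cubes — every cell observed, with
a configurable action mix, a small one-sided-detection fraction and putative
flags — primarily to property-test round trips, validation and
view-consistency. `generate_experiment()` emulates the *inputs* of the
assertion engine: per-metabolite baselines drawn log-normally
(meanlog `log(1000)`, sdlog 0.5, arbitrary instrument units) and replicate
noise that is multiplicative log-normal with standard deviation `sigma` on
the log2 scale — the conventional error model for LCMS relative abundances.
Spiked metabolites have spent means exactly `2^±effect_log2` times their
control means, and the intended action is returned as ground truth. Defaults
(5 replicates per side, 10% spiked in each direction, `effect_log2 = 2`,
`sigma = 0.1`, detection threshold 10) reflect a routine isolate
footprinting experiment with a clear biological effect.

What the simulations do **not** emulate: chromatographic drift, batch
effects, co-eluting isomers, missingness beyond the detection threshold, or
correlated metabolites. Passing calibration tests therefore shows the
pipeline is statistically sound under the stated error model, not that any
particular instrument matches that model.

`worked_example_fixture()` is the one fixed, fully synthetic cube: two soil
isolates in R2A with set sizes back-solved from a reference score
demonstration (|D| of 50 and 26, 25 shared, 8 exchange metabolites one way
and none the other; the 5 increases of the larger consumer are modelled as
one-sided products absent from the control, exercising the confidence cap).
The control pool size is not derivable from the demonstration; the fixture
sets |P| = 100 so the larger consumer's EUS is 0.5. Under exact arithmetic
the second organism's EUS is then 26/100 = 0.26 while the demonstration
reports 0.3 — the two printed EUS values are not simultaneously
reconcilable with any integer pool size and the stated decrease counts, so
EUS on this fixture is treated as a consistency check, not a reproduction
target. The FMC/FME values are independent of |P| and reproduce exactly.

## Calibration and problem sizes

The suite checks, under fixed seeds: type-I error of the pipeline on null
data (1,000 metabolites, 5 replicates/side, `sigma = 0.1`, alpha 0.05, no
correction) within three binomial standard errors of 0.05; ≥ 95% correct
directional calls for spiked `|log2fc| = 2` at `sigma = 0.1`; score
equality with a brute-force oracle on 200 random cubes up to
200 × 10 × 3; and round-trip identity of the upload and database formats on
100 random cubes. These sizes were chosen to make binomial tolerances tight
enough to detect real miscalibration while keeping the whole suite fast
enough to run habitually.

## Known limitations

* Assertions are net turnover; equal production and consumption is
  indistinguishable from no interaction.
* The engine tests each metabolite marginally; designs needing ANOVA with
  post-hoc structure across many groups should compute p-values externally
  and upload assertions directly.
* Scores treat all metabolites as exchangeable units; no weighting by
  abundance, essentiality or cost.
* The SQLite layout is a clean five-table design for interchange, not a
  byte-level clone of any particular production schema.
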