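---
title: "Process modelling and discrete-event simulation of parenchyma-sparing laparoscopic liver resection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Process modelling and discrete-event simulation of parenchyma-sparing laparoscopic liver resection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(llrsim)
```

## The surgical process model

Parenchyma-sparing laparoscopic liver resection (LLR) removes a tumour with
a margin while preserving liver tissue. A procedure decomposes into phases
and *modules* — surgical steps at a fixed granularity, coded `PxxMyy`
(phase, module): ultrasound imaging `P05M02`, planning `P06M01`, trocar
placement `P07M01`, destructive isolation steps in phase `08a`
(fat/adhesion dissection, mobilization, supply-duct isolation, occlusion
and division), region marking `P10M01` and resection `P10M02` in the
treatment phase, intra-operative leakage clean-up `P11M02`, and the wrap-up
modules of phase 13. Consecutive actions within one module count as a
single occurrence. Intervals without visible surgical activity are idle
time (`IDLE`).

Procedures fall into three tumour-location categories with distinct
workflows: `S56` (Segments 5 & 6, no gallbladder removal), `S78`
(Segments 7 & 8, the posterosuperior segments that are hard to access
laparoscopically) and `S5GB` (Segment 5 with gallbladder removal).
`build_category_graph()` returns the category workflow: module nodes with
the probability of occurring at least once, free-order boxes, zero-duration
question nodes (branch points whose outcome probabilities may depend on an
execution counter, e.g. the Segments 5 & 6 mid-resection duct-division
loop), precedence chains (the cholecystectomy chain mobilization →
isolation → permanent occlusion → division is mandatory in `S5GB`), and a
most probable path. The graphs are data, not code: editable JSON documents
with a schema id, bundled under `extdata/graphs/`.

Two reconstruction choices were genuinely open. The free-order boxes are
chosen as (fat/adhesion dissection, liver mobilization) and the wrap-up
clean-up/testing/closure set, which is the weakest ordering consistent
with the workflow tables. Where the workflow table prints no percentage,
gallbladder mobilization is 1.0 (it is part of the mandatory chain) and
liver mobilization 0.4 (the value printed for the other categories).
Imaging and planning can happen at any time during a surgery; they are
modelled as insertable nodes rather than edges everywhere, which bounds
the graph size with the same expressive effect.

## Step logs and their registration rules

A `surgery_log` is one procedure's ordered, timed records (`module`,
`start_s`, `end_s`, seconds of endoscopic video time, serialized with one
decimal). Three registration rules matter downstream:

* imaging and planning run in parallel while the surgeon takes ultrasound
  images; overlapped time is attributed to imaging only, so the planning
  statistic is "planning without imaging" (`attribute_parallel_time()`);
  parallel imaging/marking counts fully for both;
* consecutive same-module records merge into one occurrence
  (`collapse_repeats()`);
* zero durations are allowed only for planning (rapid planning outside the
  camera view).

Leakage clean-up is deliberately two modules: during treatment (`P11M02`,
a complication that can happen at any time) and during wrap-up (`P13M04`,
part of a normal procedure); they are never merged. Desufflation and
incision closing happen after the endoscope is out and are untimed, so
they never appear in logs. Intra-operative preparation is a fixed
configuration constant (about an hour) excluded from endoscopic totals.

## Per-module statistics

`module_stats()` reproduces the published summary-table semantics exactly:
occurrence frequency is averaged over *all* surgeries (zeros included, so
it can be below 1), while duration statistics pool per-occurrence
attributed durations over the surgeries where the module occurred. Idle is
summarized as a per-surgery total. `phase_breakdown()` sums per-module mean
durations into phases and normalizes; fat/adhesion dissection is excluded
by default (its duration reflects patient factors such as BMI and previous
surgery more than tumour location), and idle and phase 11 are not surgical
phases (both flags are exposed because the published fractions do not state
their denominator). On the bundled parameters this arithmetic gives the
published picture: treatment ≈ 25.6 min on average and the largest phase
share, imaging < 10 min, and ≈ 86% of the treatment phase is resection.

`most_probable_path()` extracts the statistically most probable chain of
steps. Given the category graph it walks the decision points in canonical
order and keeps the *j*-th occurrence node of a module when the empirical
probability of at least *j* occurrences is ≥ 0.5 — mandatory steps are
always on the path, and the trocar count on the path is the category's
typical count. Without a graph it mines the collapsed transition
frequencies greedily, consuming one observed transition per traversal and
bounding repeats by the largest per-surgery occurrence count; ties prefer
continuing over ending, then module-code order. The free walk is exact on
small cohorts but can wander on large cohorts where imaging and planning
occur anywhere; the graph-guided form is the default for real use.

## The synthetic cohort generator

`generate_cohort()` draws whole cohorts with the statistical structure of
the study data, so every downstream stage is testable without the deposited
videos. Per module: present with its occurrence probability; if present,
the count is `round(max(1, N(occ_mean / presence, occ_sd)))`, so the
unconditional mean matches the published occurrence frequency (the
published mean averages over absent surgeries). Each occurrence draws its
duration from a zero-truncated Gaussian whose *location is calibrated*
(solved by `uniroot`) so that the truncated mean equals the published
duration mean — a generator must reproduce the observed sample means, and
an uncalibrated truncated Gaussian would inflate them, severely so for
imaging in Segments 7 & 8 (mean 1259 s, SD 1491 s). The three duct-chain
modules share one presence draw per surgery (one 60% loop in `S56`).

Occurrences are laid out in canonical workflow order; imaging, planning
and intra-operative leakage clean-up are spread evenly over the procedure.
The layout is deterministic given the sampled counts: with all SDs at
zero every generated surgery is identical, which pins down the generator's
reproducibility in tests. Idle time is drawn once per surgery (calibrated
truncated Gaussian) and distributed so that it also separates repeated
occurrences of the same module — otherwise `collapse_repeats()` would
merge them and occurrence counts would not survive analysis. Times are
built on an integer decisecond grid, which makes the CSV round trip
bit-exact.

The generator emulates category-level statistics only. It does not model
surgeon identity, patient covariates (BMI, adhesions), lesion size, or
correlations between module durations within a surgery; durations are
independent across occurrences. Passing parameter-recovery tests therefore
shows the analysis pipeline is correct on data *with the published
marginal structure*, not that real surgeries lack such correlations.

## The discrete-event simulation

`fit_models()` plugs the summary parameters directly into the simulation
distributions, as the study design prescribes: Gaussian mode uses
(mean, SD) as (μ, σ) with the negative tail removed — a skewed
distribution with a hard lower bound of zero and *no* probability atom at
zero (truncation, not clipping) — and uniform mode uses observed per-module
minima/maxima when raw logs are available, else the moment-matched bounds
`[max(0, μ − √3 σ), μ + √3 σ]`. Note the deliberate asymmetry with the
generator: the simulation takes the published values at face value (so
truncation inflates heavy-tailed cells, visibly for `S78` imaging), while
the generator calibrates. Questions take zero time. Dynamic questions use
the survival function of the occurrence-count distribution
(`dynamic_repeat_probability()`), which is non-increasing in the counter
and vanishes beyond the support.

Sampling is by inverse CDF on a uniform stream restricted to
`[Φ(−μ/σ), 1]` — the same distribution as rejection of the negative tail,
but vectorizable and, because one uniform is always consumed per draw
regardless of the scenario's parameters, matched-seed batches are
*pointwise* comparable across scenarios. Occurrence rounding is
half-away-from-zero for platform independence.

Idle time and intra-operative leakage clean-up can happen at any time;
implementing them as events would complicate the model without affecting
totals, so their per-surgery means are added as fixed constants: idle is
the published idle mean, leakage is mean duration × mean occurrence (the
per-surgery burden; a `mean_once` policy adding the mean a single time is
exposed because the source wording is ambiguous). Neither is affected by
the technology scenarios. Intra-operative preparation (~1 h) is not added
by default; totals are endoscopic-video time.

Exclusion criteria filter non-logical runs post hoc: fewer than 3 trocars,
or a resection total below half the category's minimum observed resection
time (half of 476/540/922 s). Bounds are boundary-inclusive. Each
excluded run carries exactly one primary reason (trocars checked first).

`run_batch()` (default 45,000 runs, the study's batch size) vectorizes the
per-module sampling in a fixed order from one seeded stream, so a batch is
reproducible from `(model, n_runs, seed)`; `simulate_run()` draws single
runs for inspection, and the two agree exactly in the degenerate all-SD-0
case and statistically otherwise. `check_convergence()` compares the mean
and SD of two batches; the means of two 45,000-run batches agree well
within 0.5%, while the SD difference is typically 0.3–0.5% because the
totals are heavy-tailed mixtures — a single pair near the 0.5% line is
genuinely stochastic.

## Technology scenarios

`scenario_spec()` encodes the navigation-platform scenarios: Scenario 1 is
the reference; Scenario 2 (conservative) makes resection 10% and
supply-duct isolation 25% faster, eliminates physical marking, and charges
per imaging event the technology steps 120 s (new images) + 120 s
(image-to-3D-model registration) + 60 s (segmentation); Scenario 3
(optimistic) uses 20%/50% and 120 + 60 + 30 s. Image-to-patient
registration is pre-operative and free in-run; no significant patient
repositioning is assumed.

Three semantics choices are documented and exposed:

* multipliers scale both μ and σ (and both uniform bounds): a faster
  action is proportionally less variable absent other information;
* the technology time *replaces* each ultrasound imaging event's duration
  (`imaging_policy = "replace"`); this reproduces the qualitative finding
  that the platform helps Segments 7 & 8 most *because* their imaging is
  longest, which is impossible if the time were purely added (the `"add"`
  policy is exposed for sensitivity analysis);
* a removed module keeps its occurrence sampling but contributes zero
  time — observationally identical for totals, and it keeps matched-seed
  batches pointwise comparable, which turns scenario monotonicity into an
  exact, not statistical, test.

Impact is `improvement_percent()`: 100 × (1 − mean(Scenario x) /
mean(Scenario 1)) over included runs; negative values (a scenario that
lengthens surgery) are legitimate. The most probable total duration is the
mode of a Gaussian kernel density estimate (Silverman's bandwidth) on a
1-second grid (`distribution_peak()`).

## Reproducibility and problem sizes

Everything randomized is driven by explicit integer seeds; batches and the
pipeline derive numbered substreams from one root seed, and the pipeline
log records every substream id so any single batch can be replayed. The
packaged tests exercise parameter recovery on 2,000-surgery synthetic
cohorts (3-standard-error tolerances), 45,000-run batches for the scenario
and convergence checks, and closed-form oracles (truncated-normal moments,
deterministic sums, pointwise scenario dominance) elsewhere; a full
3 × 3 × 2 category × scenario × mode grid at 45,000 runs per cell runs in
well under a minute.

## Known limitations

The simulation inherits every limitation of the summary-table
parameterization: 13 analyzed surgeries, fine-grained durations reduced to
per-module means and SDs, independence across modules and occurrences, and
scenario effects taken from expert estimates rather than measurements.
Published bar-chart percentages for the scenario improvements are not
exactly recoverable from the printed inputs under any of the exposed
policies; the package reports what the documented defaults compute and
exposes the policy switches rather than fitting to the chart. Operating
room resources, staff, and parallel activity beyond the imaging/planning
attribution rules are out of scope.
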