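---
title: "Methods: scoring conserved synthetic-lethal networks and a flap-endonuclease inhibitor screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring conserved synthetic-lethal networks and a flap-endonuclease inhibitor screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synlethnet)
```

synlethnet implements the analysis behind a cross-species strategy for
anticancer target discovery: score double-knockdown siRNA viability data for
synthetic lethality in a human cell line, compare the resulting interaction
network against predictions from budding-yeast genetics, and triage a
biochemical inhibitor screen against the most highly connected ("hub")
target. This vignette describes the models, the tunable parameters, the
numerical choices, and what the simulators do and do not emulate.

## The multiplicative interaction model and the lethality call

Viability is measured as nuclei counts per imaged well and expressed as
percent of the GAPDH-silenced control of the same experiment:
`v = 100 * count / mean(control counts)`. Per condition we report the mean,
the SEM (`sd/sqrt(n)`), and the replicate count; the control itself
normalizes to exactly 100 by construction, and viabilities above 100%
(proliferation beyond control) are not clamped.

The null expectation for a double knockdown of genes A and B is the
multiplicative model of genetic interactions: on the percent scale,

    v_pred = v_A * v_B / 100.

The interaction statistic is the **proliferative defect**,
`defect = v_pred - v_obs`, in percent-viability units: positive when the
double does worse than expected, negative for alleviating interactions. A
pair is called synthetic lethal when

    defect >= m * (average SEM of the experiment),     m = 3 by default,

with an inclusive inequality. No multiple-testing correction is applied —
the rule is a fixed noise-scaled threshold; `call_interactions(annotate_fdr
= TRUE)` adds a delta-method p-value and Benjamini–Hochberg q-value as an
annotation only.

### Which SEMs define the threshold

"Average SEM of the experiment" underdetermines which conditions enter the
average. Because count noise is proportional to signal, the SEM of a
double-knockdown condition scales with its own (possibly
interaction-suppressed) viability: averaging over *all* conditions lets
strong planted interactions shrink the very threshold used to call them, a
circularity that measurably inflates the false-positive rate on null pairs
(about 6–8% at the default noise settings versus the intended ~5%
behaviour). The package therefore averages over **non-control
single-knockdown conditions only** by default: the threshold is then a
property of assay noise, independent of the interactions under test. Under
the default study conditions this yields ~100% sensitivity for interaction
strengths well above noise and a false-positive rate near 3%. The
alternative conventions remain available via
`average_experiment_sem(conditions = "non_control")` or `"all"`, and
`call_interactions(sem_conditions = )`.

Normalization is per experiment batch (`experiment_id`); whether a batch is
one plate or one transfection day is the caller's choice — wells given to a
single `normalize_to_control()` call define the batch.

## The conservation network

Human calls are reconciled with yeast predictions into one edge per tested
central × cancer pair, carrying independent `yeast_predicted` and
`human_observed` flags. Conservation percentages are reported **of the
predicted edges**, rounded half-up to integers (16 of 22 predicted reports
73% conserved, the 6 remaining report 27%); with no predicted edges the
percentages are undefined but the tallies are still returned. Pairs with
both flags false stay in the table — absence of interaction is data, not an
exclusion. Hub ranking counts per-central-gene degree over the chosen flag,
with alphabetical tie-breaks. Human gene symbols are canonical; a packaged
yeast↔human ortholog table (`ortholog_table()`) translates yeast-labelled
inputs, and unknown symbols pass through with a warning rather than an
error.

## The plate simulator

`simulate_plate()` is the generative inverse of the scoring model. Expected
counts are `baseline_count` for the control and non-silencing conditions,
`baseline * v_g` for singles, and

    baseline * v_A * v_B * (1 - epsilon_AB)

for doubles, where `epsilon` in [0, 1] is the planted interaction strength:
`epsilon = 0` satisfies the multiplicative null exactly and `epsilon = 1` is
fully lethal. Counts are drawn from a lognormal law with mean equal to the
expectation and coefficient of variation `noise_cv`, rounded to integer
nuclei and floored at zero — counts are positive and overdispersed, and the
lognormal gives exact CV control; the choice of law is a modelling decision,
not data-derived. Generation is a pure function of the config: per-plate RNG
substreams are derived from the master seed, and wells are laid out on
consecutive 96-well plates.

`study_plate_config()` fixes the defaults to the study-shaped conditions
used throughout the tests: 3 central genes (WDHD1, FEN1, CHTF8) × 10
cancer-mutated chromosome-instability genes, single-knockdown viabilities
drawn uniformly in [0.6, 0.9], 6 wells per condition and 5% well CV. The
ten-gene partner list (SMC1A, SMC3, NIPBL, STAG1, STAG2, STAG3, RNF20,
FBXW7, MRE11A, RAD54B) follows the cohesin-heavy composition of the original
matrix; it is configurable, and no analysis depends on the identities — the
network arithmetic uses counts.

What the simulator does *not* emulate: imaging artifacts (focus,
segmentation errors), transfection-efficiency drift between batches, siRNA
off-target effects, and day effects beyond the single-batch normalization.
Passing tests therefore demonstrate correctness of the scoring arithmetic
and its calibration under well-behaved noise, not robustness to systematic
screen pathologies.

## The kinetic simulator and the screening funnel

The fluorescence-quench assay reads flap-endonuclease activity as rising
fluorescence: cleavage releases the fluorophore from its quencher. Traces
follow first-order substrate depletion,

    F(t) = baseline + f_max * (1 - exp(-k_eff * t)) + N(0, noise_sd),

with the effective rate reduced by a compound according to a logistic dose
law, `k_eff = k / (1 + (C/IC50)^hill)`; defaults are `k = 0.2/min` and reads
every 30 s over 10 minutes. Fluorescent-artifact compounds (autofluorescers
and quenchers) are modelled with an *apparent* optical IC50 — their signal
suppression is not enzymatic — plus a concentration-proportional static
fluorescence offset. A static offset alone would leave initial-rate slopes
unchanged and never produce a false primary hit, so the apparent-IC50
component is what exercises the counterscreen.

`initial_rate()` fits an OLS slope of RFU versus time. The default window is
the full read span; over 10 minutes at `k = 0.2/min` the curvature drags the
full-window slope well below the t→0 tangent `k * f_max`, so
`window_fraction` can restrict the fit to the early, nearly linear part
(at `window_fraction = 0.3` the slope is within ~15% of the tangent for
`k = 0.05/min`). Percent inhibition is `100 * (1 - slope/vehicle_slope)`,
capped above at 100.

The funnel mirrors the biochemical screening cascade: compounds at or above
the hit threshold (default 50% inhibition at the screening dose; the
original screen's criterion is unpublished and the default is configurable)
are primary hits; the quencherless-substrate counterscreen removes compounds
whose apparent inhibition persists (default ≥ 50%) when the signal is
enzyme-independent; Lipinski's rule of five removes non-drug-like compounds
(pass iff MW < 500 Da, cLogP ≤ 5, H-bond donors ≤ 5, acceptors ≤ 10; the MW
bound strict, the others inclusive; any single violation fails). With noise
off, the funnel output equals the planted true inhibitors that are
drug-like, exactly.

## Dose–response fitting

`fit_ic50()` fits the four-parameter logistic
`activity = bottom + (top - bottom) / (1 + (C/IC50)^hill)` by
Levenberg–Marquardt least squares (`minpack.lm::nls.lm`), with the IC50
parameterised as log10(IC50) so fits are exactly equivariant under
concentration-unit rescaling. Start values come from the data (plateaus from
the extremes, IC50 from the dose nearest half-maximal response, Hill slope
1); the bottom plateau is bounded at −10% activity so read noise cannot drag
it to absurd values; and tolerances are set tight (1e−15) so noiseless data
are recovered to ~1e−9 relative error. Poor fits set `converged = FALSE`
rather than raising. Two degenerate cases are flagged rather than reported
as estimates: a fitted dynamic range under 10 percentage points (flat
response — no identifiable IC50) is reported as non-converged, and an IC50
outside the tested dose range sets `ic50_in_range = FALSE`.

## Genotype selectivity

`selectivity_test()` is deliberately a thin wrapper over `stats::aov()` and
`stats::TukeyHSD()` — one-way ANOVA with Tukey's honest significant
difference — the standard analysis for comparing compound response across
genotypes (e.g. CDC4 wild type versus knockout). `tidy()` returns the
pairwise table, `glance()` the omnibus test.

## Problem sizes and determinism

All simulation-based checks run at the study-shaped size (30 gene pairs, 6
wells per condition): the test suite uses 1000 simulated experiments for the
caller's sensitivity/false-positive calibration and 500 seeded fits for IC50
recovery; `scripts/acceptance.R` recomputes the same quantities at 500
simulations per characteristic. Every stochastic component is a pure
function of a master seed (per-stream sub-seeds are derived arithmetically),
so identical configs reproduce byte-identical tables, and
`run_pipeline()` reports include the seed and a config hash.

## Known limitations

- The interaction caller assumes well counts are exchangeable replicates
  within a condition; plate-position and edge effects are not modelled.
- The defect statistic propagates no uncertainty from the control mean; with
  few control wells the threshold calibration degrades.
- The lognormal count law is a choice; heavier-tailed noise would inflate
  the false-positive rate above the calibrated values.
- The kinetic model treats inhibition as purely competitive-like rate
  scaling; mechanisms that change the plateau (substrate depletion,
  aggregation) are not simulated.
- Descriptor-based triage takes MW/cLogP/H-bond counts as inputs; no
  chemical-structure handling is attempted.
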