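---
title: "Models and methods: qHTS triage and downstream pharmacology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: qHTS triage and downstream pharmacology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qhtsflow)
```

qhtsflow re-implements, as reusable and fully testable code, the
quantitative analysis pipeline of a dose-response high-throughput screen
(qHTS) for inhibitors of neutral sphingomyelinase 2 (nSMase2), together
with the downstream pharmacology used to qualify a screening hit as an in
vivo probe: enzyme kinetics, non-compartmental pharmacokinetics, and
extracellular-vesicle (EV) / cytokine biomarker statistics. Because no raw
screening data are publicly deposited, the package ships a first-class
synthetic-data module that generates every input the pipeline consumes,
with known ground truth, so every downstream stage can be validated
end-to-end. This vignette documents the models, the tunable parameters and
their defaults, the numerical choices, and what the synthetic validation
does and does not demonstrate.

## The assay forward model

The screened enzyme hydrolyses sphingomyelin (SM) to ceramide and
phosphorylcholine; a four-enzyme coupling cascade (alkaline phosphatase,
choline oxidase, horseradish peroxidase with Amplex Red) converts the
phosphorylcholine stoichiometrically to fluorescent resorufin, so
fluorescence is proportional to accumulated product. `assay_model()`
captures this with a deliberately small parameterisation:

* Product formation follows Michaelis-Menten kinetics in SM
  (`Vmax` = 1.9 uM/h at the reference enzyme concentration of 0.1 ug
  protein/uL, `Km_SM` = 20 uM) and is linearised over the 2 h incubation.
  We do not model the cascade's internal kinetics (a non-goal):
  stoichiometric proportionality is assumed, as the assay design intends.
  A guard warns if accumulated product exceeds 10% of substrate, where
  the linearisation would be strained; the defaults accumulate 1.9 uM of
  product from 20 uM SM (9.5%).
* Fluorescence is `background_rfu` + `gain` x product. The defaults
  (background 119 RFU, gain 1253 RFU/uM) put the uninhibited working
  signal at ~2500 RFU and the signal/background ratio at 21, the
  validated operating point of the assay.
* Noise is multiplicative lognormal with CV `noise_cv` (default 5%,
  keeping RFU positive) plus additive Gaussian read noise
  (`read_noise_sd`, default 27 RFU). The additive term represents
  signal-independent detector noise; it is calibrated jointly with the CV
  so the analytic Z' of the control columns is 0.80, the assay's reported
  plate quality. A purely multiplicative 5% model would give Z' = 0.83,
  because the no-enzyme background (119 RFU) would carry almost no
  absolute noise.

`expected_rfu()` is nondecreasing in incubation time, enzyme concentration
and substrate concentration — the qualitative behaviour used to choose the
assay conditions — and this is property-tested.

## Plate geometry and the synthetic screen

`plate_layout()` reproduces the 1536-well screening geometry: column 1
carries the positive-control inhibitor (cambinol, IC50 27 uM) in a 16-dose
1:2 series from 285 uM, column 2 is the no-enzyme background, column 3 the
saturating positive control, and columns 4-48 the compound field. The
published description of the control series ("16 doses at 1:2 dilutions,
285 uM - 17 nM") is internally inconsistent — sixteen 1:2 dilutions from
285 uM end at 8.7 nM, and 17 nM corresponds to fifteen doses — so both the
dose count and the top concentration are exposed as layout parameters, and
the default keeps 16 doses from 285 uM.

`compound_library()` plants four ground-truth classes:

* **true inhibitors** (2%): IC50 log-uniform in 0.03-10 uM — the potency
  window the cascade is designed to retain, bounded above by the final
  potency gate — with maximal efficacy uniform in 75-100%;
* **counter false positives** (5%): compounds that inhibit the detection
  cascade rather than the enzyme, with their own IC50 log-uniform in
  0.1-50 uM. They suppress signal in the primary assay (the cascade is
  part of the readout) and in the counter assay, which is how the counter
  screen unmasks them;
* **promiscuous compounds** (2%): nonspecific actives carrying a boolean
  flag. The original campaign removed them by structural analysis; that
  chemoinformatic step is out of scope here, and the flag keeps the
  cascade's filtering arithmetic testable. In the main assay they behave
  like inhibitors drawn from the same potency range;
* **inactives** (the remainder).

The primary screen uses 4 doses at 5-fold dilutions from 57 uM (the
protocol's stated scheme; the same campaign's narrative also quotes
1.1/11/57/114 uM — another internal inconsistency, resolved in favour of
the protocol section). Confirmation and counter screens use 7 doses from
57 uM. All generators are pure functions of (parameters, seed): a rerun
with the same seed is bitwise identical.

## Plate QC

`z_prime()` implements Z' = 1 - 3(sd_pos + sd_neg)/|mean_pos - mean_neg|
with sample (n-1) standard deviations (the estimator is not specified in
assay-validation reports; the sample SD is the conventional choice). It is
symmetric in the arms and invariant under affine rescaling — both tested.
Controls are taken per plate rather than pooled across plates.
`positional_effect()` screens row and column medians of the compound field
against the plate median with a configurable 20% threshold; the original
report makes only the qualitative statement that the sample field was
even, so the threshold is a design choice, not a published value.

## Dose-response fitting and curve-response classes

`fit_4pl()` fits the four-parameter logistic on log10 dose,

y = bottom + (top - bottom) / (1 + 10^(hill (log10 IC50 - log10 d))),

by Levenberg-Marquardt with soft box bounds and a small multi-start grid.
The optimiser is driven through the raw residual interface
(`minpack.lm::nls.lm`) rather than the `nls` wrapper: on noise-free data
the best start converges to a machine-perfect fit, where constructing a
full `nls` object can fail a gradient rank test and silently discard the
best solution. Designs with at most four distinct doses (the primary
screen) are fitted with `bottom` fixed at 0 and hill restricted to
[0.5, 3] to avoid overfitting; richer designs are unconstrained.

`crc_classify()` assigns the curve-response class (CRC), the discrete
summary by which qHTS campaigns triage curves. The published scheme gives
examples (-1.1 complete curve/high efficacy, -1.2 complete/partial) but
not the numeric cut-offs, so the thresholds live in
`crc_thresholds()` and default to: high efficacy >= 80%, partial floor
30%, r-squared gate 0.9, plateau detected when the fitted curve comes
within 5% of the corresponding asymptote inside the tested range, and
demotion of .1 to .2 when the IC50 extrapolates more than one log beyond
the tested doses. Two classification choices deserve note:

* **Class 2 means "incomplete", not "exactly one plateau".** On a 4-dose
  primary design a genuine mid-potency inhibitor can show neither plateau
  while still defining a clean, well-fit curve. We classify any well-fit
  curve with fewer than two plateaus as class 2, and reserve class 3 for
  activity without an interpretable curve (poor fit, or fewer than two
  doses above the activity floor — a lone top-dose spike). Without this
  reading, mid-potency planted inhibitors would be unrecoverable by
  design and the noise-free round-trip (below) could not reach
  sensitivity 1.
* **Percent inhibition** is computed as 100 x (1 - rate_I/rate_0): the
  complement of the activity ratio, so that "inhibition" increases with
  effect. (The formula as literally printed in the source protocol is the
  activity ratio itself.) Reported values are clipped to [-10, 110].

`ic50_with_ci()` provides a residual-bootstrap percentile interval;
coverage at 5% noise is regression-tested (~120 simulated curves, 200
resamples each — sizes chosen to keep the default test run fast while
leaving the binomial error on the coverage estimate a few percent).

## The triage cascade

`triage_screen()` applies, in order: primary selection (top-dose response
> 50% and CRC in {-1.1, -1.2, -2.1, -2.2}), promiscuity removal,
confirmation (the 7-dose refit retains a selectable class), the counter
screen, and an inclusive potency gate (IC50 <= 10 uM). The counter filter
calls a compound bona fide when its counter curve is inactive (class 4 by
default; an efficacy-threshold rule is available because the original
"inactive in the counter assay" criterion is not spelled out), and rescues
counter-active compounds as *differential* hits when the main potency
exceeds the counter potency by at least one log unit or the counter
efficacy stays below 50% — the published rescue criterion is qualitative,
so both thresholds are configuration values. Every removed compound
carries a non-empty machine-readable reason, each stage's output is a
subset of its input (except the rescue, which only re-admits compounds the
counter filter removed), and `triage_report()` checks the conservation
identities (bona fide = confirmed - counter false positives; advanced =
bona fide + differential).

On noise-free synthetic screens the cascade recovers the planted hit set
exactly (sensitivity = specificity = 1); this is asserted in the test
suite and recomputed by the acceptance script.

## Enzyme kinetics and inhibition mode

`fit_mm()` fits v = Vmax S/(Km + S); `fit_inhibition_global()` fits the
four classical inhibition laws (competitive, noncompetitive,
uncompetitive, mixed) globally across inhibitor levels and selects the
mode by AICc, flagging the call ambiguous when the top two models are
within 2 units. The published analysis reports only the per-level
Vmax/Km pattern (Vmax falls, Km unchanged — the noncompetitive signature),
with no formal selection; AICc is our design choice, and independent
per-level fits are reported alongside the global fit so the signature can
be inspected directly. On noise-free grids all models fit essentially
exactly, so the residual sum of squares is floored at a small multiple of
the data's squared scale before the AICc comparison — below numerical
precision the parameter-count penalty must decide, which correctly
prefers the three-parameter law over the mixed model that nests it.

For a noncompetitive inhibitor the IC50 equals Ki at any substrate
concentration; the generator uses this identity (rate scaled by
1 - (E/100) I/(I + Ki)), and the test suite closes the loop by checking
that the global-fit Ki matches the fixed-substrate logistic midpoint
within 1%.

## Non-compartmental pharmacokinetics

`nca()` computes Cmax/Tmax from the pooled mean profile (destructive
composite sampling: each animal contributes one time point, so naive
pooling is forced), lambda_z by log-linear regression over the last three
quantifiable points (the point count is configurable; the source analysis
names only the software used), AUC0-t by the lin-up/log-down trapezoid
(that software's common default; plain linear available), and
AUC0-inf = AUC0-t + Clast/lambda_z. Brain tissue amounts (pmol/g) are
treated as numerically equivalent to uM assuming unit tissue density — a
reporting convention, matching the uM-labelled brain concentrations being
emulated.

The PK generator is a one-compartment first-order absorption model,
C(t) = A (e^{-ke t} - e^{-ka t}), sampled at 0.25-6 h with n = 3 per time
point. Defaults ka = 3.1/h, ke = 1.2/h place Tmax at 0.5 h and A = 34.5 uM
places plasma Cmax at 11.6 uM; the brain profile is plasma x 0.26, so the
brain/plasma AUC ratio is 0.26 by construction at any noise level. The
emulated study's printed plasma AUC0-inf (10 uM h) is *not* jointly
attainable with its printed Cmax and Tmax under any one-compartment
profile (the implied Cmax/AUC ratio exceeds what Tmax = 0.5 h allows), so
the generator matches the concentration anchors and the partition
coefficient rather than the printed AUC.

Two properties worth knowing:

* the lin-up/log-down rule is exact on exponential decay (the dense-
  sampling test requires agreement with C0/k within 0.5%);
* at the sparse 6-point design the trapezoid discretisation itself
  under-reads the analytic AUC of this curve shape by ~4%. That deficit
  is a property of the sampling design, not of the estimator, so the
  recovery test defines its estimand as the NCA value of the noise-free
  profile at the same design and requires the median noise-induced bias
  around it to stay under 3% (500 simulated studies at 10% CV).

`time_above()` reports the last downward crossing of the linearly
interpolated mean profile; at the sparse design the operational
"brain level above potency up to 4 h" statement corresponds to the last
sampling time still above threshold, which is what the acceptance script
reports. `microsome_summary()` fits first-order decay to percent-remaining
data, reports half-life infinity ("stable") when the decay constant is
indistinguishable from zero, and flags (and clips) nonphysical increasing
trends.

## Biomarker statistics

`ddct_fold_change()` implements relative qPCR quantification: per-sample
dCt against the reference gene, ddCt against the control-group mean, fold
change 2^(-ddCt). Group summaries average on the Ct scale, which is
unbiased for the planted fold under symmetric cycle noise, and the whole
pipeline is invariant to per-sample plate offsets (tested). Ct values are
validated against the plausible 0-45 cycle range.

`percent_reduction()` is 100 (1 - mean_t/mean_r) with delta-method
uncertainty. The published "+-" dispersion convention is not stated for
these endpoints; following the figure legends that do state one ("mean
+- SD"), the default propagates group SDs, with SEM propagation and a
bootstrap as alternatives. The in vivo generators plant the reported
effect sizes — a 51% reduction of stimulated astrocyte-derived EV counts
(group CV 0.19, n = 5, giving the reported +-13-point spread) and an 80%
reduction of brain neutrophil infiltration (treated-arm CV 1.0,
stimulated-arm CV 0.57, giving roughly the reported +-23) — plus a
zero-effect inactive-analog arm. The ratio-of-means estimator carries a
small (second-order, ~1/n) positive bias in mean_t/mean_r; at these CVs
it is a fraction of a percentage point for the EV endpoint and about one
point for the noisier neutrophil endpoint, visible in the Monte-Carlo
means the acceptance script reports.

`anova_tukey()` wraps the base one-way ANOVA and Tukey HSD (studentized-
range quantiles); the test suite checks the F statistic against an
explicit sums-of-squares oracle to 10 significant figures and the
two-group identity F = t^2. `ev_dose_response()` converts dose-group mean
particle counts to percent reduction of the vehicle mean and reuses the
4PL machinery, so cellular EC50/Emax estimates inherit all of its
behaviour. The in vitro EV generator defaults (vehicle baseline 1e9
particles/mL, cellular EC50 0.3 uM, Emax 90%, 4 replicates, CV 15%) are
chosen as realistic nanoparticle-tracking values; the emulated study
reports only the qualitative dose dependence.

## What the synthetic validation shows — and what it cannot

The generators emulate: control-column geometry and plate statistics,
compound classes with planted potencies, detection-cascade interference,
composite PK sampling, lognormal count dispersion, and qPCR cycle noise.
They do not emulate: plate-positional drift (the positional-effect screen
is exercised by construction, not by a drift model), structural/chemical
promiscuity (flag only), correlated within-animal plasma/brain noise,
compound solubility or aggregation artefacts, or reader saturation.
Passing the suite therefore demonstrates that the *analysis* is correct
and internally consistent under the stated noise models — not that the
models capture every failure mode of real screening data.

Problem sizes in the default test run (synthetic screens of 120-288
compounds, 500-simulation property suites, 200-resample bootstraps) were
chosen so the full suite runs in about 90 seconds; all are parameters,
and larger runs only tighten the Monte-Carlo error.

## Reproducing the headline numbers

`scripts/acceptance.R` (repository root) regenerates every headline
quantity from scratch — flowchart identities from the campaign stage
counts, exposure ratio from the printed AUCs, panel selectivity rate, and
the full set of simulated round-trips (Z', signal/background, control and
lead potencies, inhibition-mode kinetics, PK summary, biomarker effect
sizes) — and writes them as JSON. See the README for usage.
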