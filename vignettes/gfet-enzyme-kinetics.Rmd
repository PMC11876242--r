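---
title: "Inferring Michaelis-Menten parameters from GFET biosensor assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring Michaelis-Menten parameters from GFET biosensor assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(gfetkin)
```

## The measurement and the inference problem

Graphene field-effect transistors (GFETs) transduce chemistry into
current: at constant gate and drain voltage, the drain-source current
$I_{ds}$ of a liquid-gated graphene channel tracks the concentration of a
charged analyte near the surface. For peroxidase assays the analyte is
the oxidised radical cation of the chromogenic cosubstrate ABTS, the
product of the catalytic cycle, so a constant-voltage current trace is a
progress curve in disguise. Reading kinetics off such traces requires
three models stacked on top of each other:

1. a **kinetic model** of the enzyme (how product accumulates),
2. a **sensor model** (how product concentration becomes current), and
3. an **inference layer** (how noisy traces become parameter estimates
   with uncertainty).

`gfetkin` implements all three, plus a synthetic-study generator that
emulates the experimental design end to end, so every stage of the
analysis is testable against a known ground truth without any instrument
data.

## Kinetic models

### Michaelis-Menten system

The single-substrate scheme
$E + S \underset{k_2}{\overset{k_1}{\rightleftharpoons}} C
\xrightarrow{k_{cat}} E + P$
is integrated as mass-action ODEs (`simulate_mm()`). The Michaelis
constant $K_M = (k_2 + k_{cat})/k_1$ and limiting rate
$V_{max} = k_{cat} E_{tot}$ are always derived, never stored, so they
cannot drift out of sync with the elementary constants. Under the
quasi-steady-state (QSS) conditions $E_{tot} \ll S_0$ and fast complex
equilibration, the initial product-formation rate collapses to the
closed form $v = V_{max} S / (K_M + S)$ (`mm_rate()`); this equivalence
is a standing test of the integrator at 1% tolerance.

Units are fixed package-wide: concentrations in uM, time in seconds,
current in uA, voltages in mV. Conversions belong at I/O boundaries.

### Peroxidase cycle with suicide inactivation

Heme peroxidases are inactivated by their own oxidant. The catalytic
network (`simulate_peroxidase()`) carries one mass-action term per
pathway: resting enzyme + H2O2 forms compound I; compound I and then
compound II each oxidise one reducing-cosubstrate molecule (AH2),
regenerating the resting state; compound II + H2O2 forms the off-pathway
compound III; and compound III bleaches irreversibly. An optional slow
compound III -> resting decay (rate 0 by default) completes the scheme.

One structural point deserves emphasis. With only those pathways, a run
with *no* reducing cosubstrate parks the entire enzyme pool as
compound I and nothing further happens — yet reductant-free peroxide
exposure is precisely the condition under which heme bleaching is
observed experimentally. The resolution is the well-established
catalase-like side reaction CpdI + H2O2 -> CpdII, included as an
explicit rate constant `k_p1b` (set it to 0 to recover the bare
five-pathway cycle). With it, the reductant-free route
E -> CpdI -> CpdII -> CpdIII -> bleached operates on H2O2 alone, and the
classic "sufficient (500 uM) vs insufficient (75 uM) cosubstrate"
contrast emerges from the dynamics: final active-enzyme fraction is
strictly increasing in cosubstrate concentration.

No rate constants for this network are published alongside the assays
the package emulates; the defaults in `peroxidase_params()` are
literature-plausible magnitudes (~1e-2 1/(uM s) for compound-I
formation, ~1e-3–5e-3 for the slower branches) and are synthetic ground
truth, not measured values.

### Numerical choices

Integration uses the stiff solver `deSolve::lsoda` with `rtol = 1e-8`,
`atol = 1e-10`; the conservation invariants (enzyme and substrate mass
balances, checked to 10x solver tolerance at every output point) require
tight tolerances, and the systems are small enough that cost is
irrelevant. Round-off can leave concentrations at -1e-17; these are
clamped to zero on *output only*, never inside the right-hand side,
which would break mass balance.

## The sensor model

`fit_calibration()` builds the response model from (concentration,
|dI|) pairs. Amperometric calibration curves are linear at low
concentration and saturate, and reported linear ranges start at the low
end, so the detector grows a window anchored at the lowest
concentration: the largest contiguous prefix of the sorted
concentrations whose OLS fit reaches `r2_min` is the linear range.
A window of fewer than 3 points, or a response with zero variance,
is a calibration failure, raised as an error rather than a degenerate
model.

The forward map (`concentration_to_current()`) is
$I(t) = \text{baseline} + s\,\sigma(P(t)) + b + \varepsilon$, where
$\sigma$ is the identity up to the linear-range top and then a smooth
rational plateau (C1-continuous, approaching `high + width`; default
width 0.15 x high, sharp enough that the declared linear-range endpoint
is a real breakpoint), and $\varepsilon$ is seeded Gaussian noise. The
inverse map (`current_to_concentration()`) references each trace to its
own first sample — the current returns to baseline after washing, so a
per-trace reference is the natural choice — and computes
$c(t) = (|I(t) - I(0)| - b)/s$, clamped at zero, flagging (never
dropping) values outside the linear range.

Two consequences of these declared conventions matter downstream:

* The forward and inverse maps are exact inverses only when the
  calibration intercept $b$ is zero: baseline-referencing already
  removes any constant offset, so a fitted intercept is pure estimation
  error that the inverse map subtracts anyway. The synthetic truth
  transducer therefore has $b = 0$, and the pipeline keeps the fitted
  intercept small by averaging replicate calibration points.
* Samples whose $|dI|$ falls below a positive fitted intercept invert
  to exactly zero: they are **left-censored**, not observed. The
  rate-extraction stage (`extract_rates()`) excludes them from the
  slope fit; a constant concentration offset cancels in a slope, but a
  run of clamped zeros biases it badly. A trace with too few uncensored
  samples is reported as below the detection limit (rate 0).

## The synthetic study

`default_condition_grid()` enumerates the emulated design: two enzymes
(HRP at optimal pH 7, free heme at optimal pH 4), both measured at both
pH values 4 and 7, temperatures 18, 21, 24 C, and the standard
seven-point ABTS series 25, 50, 100, 250, 500, 750, 1000 uM with the
peroxide cosubstrate in excess (2.5 mM) so single-substrate kinetics
applies. One replicate reference series per enzyme at 22 C is appended,
for 98 conditions in 14 substrate series — matching the scale of roughly
one hundred experimental cases. Each condition is one substrate
concentration; a series of seven is the unit of inversion, since a
single (S, v) pair cannot identify two kinetic parameters.

The ground-truth law (`ground_truth_law()`) maps conditions to true
parameters smoothly: Arrhenius-like temperature dependence
$k_{cat} \propto e^{E_a (T - T_{ref})}$, a Gaussian pH-activity profile
of width 2 pH units, and a log-linear pH dependence of $K_M$. A smooth,
differentiable truth (rather than a lookup table) is what a surrogate
model can meaningfully be scored against. Defaults: $k_{cat,ref}$ =
100 1/s and $K_{M,ref}$ = 150 uM at 22 C (HRP/ABTS literature
magnitudes), $E_a$ = 0.08/K, $K_M$ pH slope 0.4 per pH unit,
$E_{tot}$ = 0.01 uM.

The $K_M$ pH slope deserves a note on identifiability, since it controls
the study's power. Peroxidase substrate binding involves ionisable
groups and its $K_M$ varies several-fold to an order of magnitude over a
3-pH-unit span; 0.4/pH gives an ~11-fold spread across the grid (45 to
~500 uM). Any smaller spread would sit at or below the per-series
inversion uncertainty (~5-15%), and a surrogate-recovery study against a
truth that varies less than the measurement noise is statistically
vacuous by construction.

Traces are 60 s at 2 Hz with additive Gaussian current noise (default
0.1 uA, ~5% of a mid-linear-range response at the 2 uA/uM sensitivity).
Every stochastic element draws its seed from the master seed via
labelled derivation (`derive_seed()`), so an `experiment_set` is a pure
function of its arguments: regeneration is bit-identical and
order-independent.

What the generator deliberately does **not** emulate: Dirac-voltage
transfer curves and their drift, direct electron transfer and redox
doping of the channel, nonspecific adsorption, washing artifacts, and
day-to-day sensor variability. Passing tests therefore demonstrate
correctness of the analysis chain under the declared noise model, not
robustness to every failure mode of a physical device.

## Bayesian inversion

The observation unit is a rate dataset: seven (S, v0) pairs per series.
The likelihood is Gaussian around the closed-form MM rate,
$v_{obs} \sim N(V_{max} S/(K_M+S),\ \sigma)$, with $\sigma$ inferred
jointly rather than fixed — measurement noise is never reported for such
assays, and fixing it wrongly corrupts interval coverage. Rates (not
full progress curves) are the measured quantity of the emulated
experiment; a progress-curve likelihood is a natural extension point.

Default priors are deliberately uninformative: log-uniform $K_M$ over
[1, 1e4] uM and $k_{cat}$ over [1e-2, 1e3] 1/s (spanning reported
peroxidase ranges), half-normal scale 1 on $\sigma$. Both families are
config-overridable (`prior_spec()`).

Sampling (`run_mcmc()`) is adaptive random-walk Metropolis in log
space — three parameters do not warrant gradient-based samplers, and a
dependency-free sampler is deterministic under seed by construction.
Each coordinate's proposal scale adapts in blocks of 100 iterations
during burn-in only (multiplying by $e^{(r - 0.3)}$ where $r$ is the
block acceptance rate, targeting the 0.2-0.5 band); after burn-in the
proposal is frozen, so retained draws come from a valid Markov chain.
Chains start from independent prior draws. Convergence is summarised by
split-$\widehat{R}$ per parameter (clamped at 1; threshold 1.1 for the
`converged` flag); an all-rejecting chain or $\widehat{R} > 1.2$ is a
warning recorded in the result, never an exception — a failed inversion
is data, not a crash.

Standalone defaults are 4 chains x 20,000 steps with 50% burn-in. The
pipeline inverts 14 series with 2 chains x 4,000 steps each, which for
this 3-parameter, 7-observation posterior is past the point of
diminishing returns (recovery error is statistics-limited, not
sampler-limited) and keeps a full study run in seconds.

## The MLP surrogate

`train_surrogate()` fits a fully connected network from condition
features (enzyme and substrate one-hots, pH, temperature, substrate
concentration) to the inversion labels: posterior medians of
$(\log K_M, \log k_{cat})$. Hidden layers use the rectifier; the output
layer is logistic, mapped affinely onto declared per-parameter log
ranges, which makes bounded outputs a *hard* guarantee of the
architecture rather than a hope of training. Labels live in log space
because the parameters span decades. Optimisation is Adam on the MSE of
range-normalised log labels, minibatch 32, learning rate 0.01 with
0.99/epoch decay, 800 epochs, and L2 weight decay 1e-4; the 80/20
train/test split is stratified by enzyme and both the split and the
initialisation are separately seeded. Per-epoch train and test RMSE are
recorded; with these settings the 10-epoch moving average of training
RMSE is non-increasing over the final 80% of epochs to within
floating-point jitter.

The default architecture is a single hidden layer of 16 units. This is
a deliberate capacity choice, not a limitation: on ~100-200-row tabular
studies, wide two-layer networks (e.g. 2 x 64) interpolate the training
rows and wiggle between them (held-out $R^2$ around 0.82-0.88 on a
noiseless smooth law), while the small network recovers the same law at
$R^2 > 0.97$. Width, depth, and all optimiser settings remain exposed
in the configuration for larger studies.

The interpretation of the labels is worth stating explicitly: the
surrogate is supervised with respect to the *inversion outputs*, and
label-free with respect to any experimentally measured parameter — no
measured $(K_M, k_{cat})$ exists anywhere in the loop. Diagnostics
(`regression_diagnostics()`) report per-parameter scatter, $R^2$ and
RMSE of surrogate predictions against the Bayesian labels, split by
train/test membership.

## The pipeline

`run_pipeline()` chains the stages — simulate, calibrate (triplicate
calibration points at 2% proportional noise, fitted with
`r2_min = 0.999`), extract rates, invert per series, train the
surrogate, and produce diagnostics — under a single master seed fanned
out by labelled derivation, and writes every artifact as CSV/JSON with
an MD5 manifest. Rerunning with the same configuration reproduces every
artifact hash-identically; this determinism is itself an acceptance
test. Stage toggles allow partial runs; a stage whose inputs are
missing aborts with the stage name. The per-condition report joins
truth, posterior median, and surrogate prediction for every condition.

```{r pipeline, eval = FALSE}
report <- run_pipeline(pipeline_config(master_seed = 42,
                                       out_dir = "gfetkin_run"))
report$triplets
```

## Known limitations

* The Gaussian rate likelihood ignores the (mild) heteroscedasticity
  that trace inversion induces across substrate concentrations.
* Series are inverted independently; no hierarchical pooling across
  conditions, and no model comparison or evidence estimation.
* The sensor model's soft plateau is a convenience surrogate for true
  electrochemical saturation; only its breakpoint and smoothness are
  meaningful.
* Surrogate predictions interpolate the condition grid; outside the
  training support the model warns and the logistic bounds take over,
  so extrapolations saturate rather than explode — bounded, but not
  trustworthy.
* The peroxidase network's rate constants are plausible placeholders;
  conclusions about real enzymes require calibrating them to data,
  which the Bayesian machinery here supports but the package does not
  ship.
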