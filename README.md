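# gfetkin

Enzyme-kinetics simulation and inference for graphene field-effect
transistor (GFET) biosensor assays.

## The problem

GFET biosensors read out enzymatic activity as a drain-source current:
at constant gate and drain voltage, the current through a liquid-gated
graphene channel tracks the concentration of a charged reaction product
(here the ABTS radical cation produced by heme peroxidases) near the
surface. Turning those current traces into kinetic constants is a
multi-stage inference: a calibration curve maps current change to
product concentration, initial rates are extracted from the recovered
progress curves, Michaelis-Menten parameters are inferred from
rate-versus-substrate data, and a neural-network surrogate generalises
the inferred parameters across chemical and environmental conditions.

`gfetkin` is for people building or analysing such assays: it provides
every stage of that chain, together with a synthetic-study generator
that emulates the full experimental design (two enzymes, pH 4 and 7,
temperatures 18-25 °C, a seven-point 25-1000 µM substrate series, noisy
constant-voltage traces), so the whole pipeline can be validated against
a known ground truth before an instrument ever enters the picture.

## Models at the core

**Kinetics.** The single-substrate scheme
`E + S ⇌ C → E + P` is integrated as mass-action ODEs with
K_M = (k₂ + k_cat)/k₁ and V_max = k_cat·E_tot always derived from the
elementary constants; the closed-form rate law
v = V_max·S/(K_M + S) is its quasi-steady-state limit. The heme
peroxidase catalytic cycle — compound I and II formation, reduction by a
cosubstrate, the off-pathway compound III, and irreversible bleaching
(suicide inactivation by H₂O₂) — is simulated as one mass-action term
per pathway, including the catalase-like CpdI + H₂O₂ → CpdII step that
enables reductant-free bleaching.

**Sensing.** Calibration curves |ΔI| vs concentration are fitted with
automatic linear-range detection (largest low-anchored window reaching a
target r²); current and concentration convert in both directions with
baseline referencing, saturation above the linear range, and seeded
Gaussian noise.

**Inference.** The posterior over (K_M, k_cat, σ) under a Gaussian rate
likelihood and log-uniform priors is sampled by adaptive random-walk
Metropolis in log space (deterministic under seed, split-R̂ diagnostics,
90% credible intervals). A small MLP — ReLU hidden layer, logistic
output mapped onto declared log-parameter ranges, Adam optimiser, 80/20
split — learns the map from conditions to inverted parameters.

## Worked example

Infer Michaelis-Menten parameters from a noisy seven-point rate series
(5% proportional noise, truth K_M = 150 µM, k_cat = 100 1/s):

```r
library(gfetkin)

p <- kinetic_params(k1 = 1, k2 = 50, k_cat = 100, E_total = 0.01)
p
#> Michaelis-Menten kinetic parameters
#>   k1 = 1 1/(uM s), k2 = 50 1/s, k_cat = 100 1/s, E_total = 0.01 uM
#>   derived: K_M = 150 uM, V_max = 1 uM/s

S <- c(25, 50, 100, 250, 500, 750, 1000)
set.seed(2)
v_obs <- mm_rate(S, vmax(p), km(p)) * (1 + rnorm(7, 0, 0.05))
d <- rate_dataset(S, pmax(v_obs, 0), E_total = 0.01)

post <- run_mcmc(d, seed = 8)
tidy(post)
#> # A tibble: 3 × 7
#>   parameter     mean   median      sd       q5      q95  rhat
#>   <chr>        <dbl>    <dbl>   <dbl>    <dbl>    <dbl> <dbl>
#> 1 K_M       157.     156.     23.3    122.     195.      1.01
#> 2 k_cat     102.     102.      4.36    94.8    109.      1.00
#> 3 noise_sd    0.0348   0.0316  0.0136   0.0194   0.0611  1.05
```

The posterior medians sit within a few percent of the truth and the 90%
credible intervals (q5-q95) cover it; `glance(post)` reports acceptance
rates, split-R̂ and the convergence flag, and `autoplot(post)` draws the
marginals.

The full synthetic study — 98 conditions simulated, calibrated,
inverted per substrate series, and distilled into a surrogate — runs
from one seed:

```r
report <- run_pipeline(pipeline_config(master_seed = 42,
                                       out_dir = "gfetkin_run"))
report
#> Pipeline run (master seed 42): stages [simulate, calibrate, rates, invert, train, diagnostics]
#>   12 artifact(s) in gfetkin_run
#>   surrogate held-out R^2: log K_M 0.988, log k_cat 0.990

head(report$triplets, 3)
#> # A tibble: 3 × 8
#>   condition_id      group_id K_M_true kcat_true K_M_post kcat_post K_M_surrogate
#>   <chr>             <chr>       <dbl>     <dbl>    <dbl>     <dbl>         <dbl>
#> 1 HRP_pH4_T18_r1_S… HRP_pH4…     45.2      7.65     47.2      7.62          48.8
#> 2 HRP_pH4_T18_r1_S… HRP_pH4…     45.2      7.65     47.2      7.62          48.4
#> 3 HRP_pH4_T18_r1_S… HRP_pH4…     45.2      7.65     47.2      7.62          47.6
```

Each condition carries its ground truth, the Bayesian posterior median
for its substrate series, and the surrogate prediction; the held-out R²
values score the surrogate against the Bayesian labels. Every artifact
(conditions, traces, rates, posterior summaries, surrogate weights,
RMSE history, diagnostics) is written as CSV/JSON with an MD5 manifest,
and rerunning with the same master seed reproduces all of them
hash-identically.

The methods vignette (`vignettes/gfet-enzyme-kinetics.Rmd`) documents
the models, the synthetic study design, all tunable parameters with
units and defaults, and the package's numerical choices.

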