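---
title: "Modelling the triple-oxygen isotope composition of body water"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the triple-oxygen isotope composition of body water}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxflux)
```

## The problem and the model

Animal body water is a mixture of oxygen drawn from three isotopically very
different pools: pre-formed (meteoric) water taken in by drinking and with
food, atmospheric O~2~ absorbed in the lungs and reduced to metabolic
("oxidase") water, and oxygen bound in food molecules. On the conventional
δ^18^O scale these pools overlap heavily once fractionation is accounted for,
but in the triple-oxygen system they separate cleanly: meteoric waters carry a
small positive ^17^O excess while atmospheric O~2~ carries a large negative
one (≈ −441 per meg). The excess is defined on the linearized delta scale,

$$\Delta'^{17}\mathrm{O} = \delta'^{17}\mathrm{O} - 0.528\,\delta'^{18}\mathrm{O},
\qquad \delta' = 1000\,\ln(1 + \delta/1000),$$

reported in per meg (10^−6^). Because almost all biological fractionation is
mass-dependent with slopes close to 0.528, Δ′^17^O of body water is governed
mainly by the *mixing proportions* of the source pools, which is what makes it
a tracer of drinking-water intake and metabolic rate.

`body_water_model()` implements a steady-state oxygen mass balance for one
animal over one measurement window. Six inputs (drinking water, food free
water, oxidase water, inhaled vapour, condensation water, decarboxylation
oxygen) and eight outputs (faecal bound oxygen — assumed zero, faecal water,
transcutaneous, oral and nasal vapour, exhaled CO~2~, urea oxygen, urinary
water) are each expressed in moles of oxygen atoms, with an ^18/16^α and a
triple-isotope exponent θ (α~17~ = α~18~^θ^). For each isotope the body-water
ratio is

$$R_{BW} = \frac{\sum_i f_i\,\alpha_i\,R_{\mathrm{source},i}}
               {\sum_j f_j\,\alpha_j},$$

with fractional contributions *f* within the input and output pools. The
urinary flux is the residual that closes the balance (steady state), so
conservation holds by construction; a negative residual is an error unless
explicitly allowed (see below).

```{r base}
totals <- flux_totals(o2_ml = 5582, co2_mol = 0.21417, food_kg = 0.01297,
                      water_ml = 10.44, window_hours = 96)
m <- body_water_model(flux_params(), totals)
m
round(m$input_fractions, 3)
```

## Parameters that matter

The default `flux_params()` describe a ~20 g deer mouse housed at 25 °C and
45% relative humidity on a low-salt laboratory diet, with group-mean metabolic
totals over a 96 h window (roughly one body-water turnover). The most
influential quantities, in the units used throughout:

* **z-value** (permil): ^18^O depletion of respired relative to atmospheric
  oxygen; with the oxygen utilization fraction it sets the oxidase α via
  `(1000 + (δ^18^O_air − z)/(1 − OUF)) / (1000 + δ^18^O_air)`. Default 10.5.
* **OUF** (fraction): oxygen extraction efficiency per breath, default 0.25.
  It appears twice — in the oxidase α and in the lung ventilation volume that
  scales both inhaled vapour and exhaled oral/nasal vapour.
* **Source compositions**: drinking water (−4 permil, +20 per meg),
  atmospheric O~2~ (24.046 permil, −441 per meg), ambient vapour / food free
  water (−16.41 permil, +30 per meg). Sources are specified as
  (δ^18^O, Δ′^17^O) pairs; δ^17^O is always derived.
* **θ values**: 0.5179 (respiration), 0.529 (liquid–vapour equilibrium),
  0.525 (cellulose–water), 0.5235 (transcutaneous), 0.5248 (CO~2~–water).
* **Diet**: macronutrient mass fractions set condensation water
  (11.12 mol O per kg carbohydrate: two of six glucose oxygens) and
  decarboxylation oxygen (22.24/4/6 mol O per kg carbohydrate/fat/protein),
  both scaled by digestibility × energy-extraction.
* **Surface losses**: Meeh constant 1100 cm²·kg^−2/3^ and a skin evaporation
  rate of 0.025 mg·cm^−2^·h^−1^·mmHg^−1^ against the Tetens vapour-pressure
  deficit.

Two rounded constants (Avogadro 6.03 × 10^23^, 22.4 l/mol) are used by
default so results are reproducible against the published parameterization;
`rounded_constants = FALSE` switches to CODATA values (the difference is
far below measurement precision).

## Design choices where the source material was ambiguous

Several published details admit more than one reading; the package fixes each
with a documented, configurable choice. These were settled by requiring the
base model to reproduce the published sensitivity table, which is a pure
function of printed inputs:

* **Inhaled vapour.** The published equations give the liquid–vapour
  equilibrium α but not the vapour's source pool or the direction of the
  factor. The package default treats ambient vapour as being in equilibrium
  with the pre-formed (drinking) water pool and *depleted* relative to it
  (vapour = liquid/α), the physical direction for evaporation; both the
  source (`vapour_source`) and the direction (`vapour_alpha_direction`) are
  parameters. Only this combination reproduces the published humidity and
  temperature sensitivities; the alternative readings misstate them by a
  factor of about two.
* **Leakage.** Drinker hoppers overestimate intake; a 10% bulk correction is
  standard. The model multiplies *raw* supplied water by (1 − leakage), and
  `flux_totals(water_leak_corrected = TRUE)` marks values that were already
  corrected upstream (e.g. by `correct_water_intake()`), so the correction is
  applied exactly once on either path.
* **Saturation vapour pressure.** The expression 10^(0.686 + 0.027 T) is
  physical only with T in Celsius (≈ 23 mmHg at 25 °C); a literal Kelvin
  reading appears in one published transcription and is retained behind
  `eq_sat_vap_temp_unit = "K"` for audit only.
* **Sensitivity "change".** `perturb()` reports the maximum absolute
  excursion of the two endpoint predictions *from the base prediction*, not
  the endpoint-to-endpoint difference. Symmetric ranges make the two
  definitions differ exactly twofold, and the published change magnitudes
  (e.g. for the Meeh factor and the directly overridden oxidase α) match the
  excursion definition.
* **Negative urinary residual.** Extreme sensitivity endpoints (OUF = 0.05)
  drive ventilation-scaled vapour losses past the total input, so the
  closing urinary flux goes negative. `output_fluxes()` errors by default;
  the sensitivity engine passes `allow_negative_urinary = TRUE` and keeps the
  algebraic closure with a warning, which is what the published table
  evidently did.
* **Diet table transposition.** The treatment configuration table swaps the
  protein and fat percentages relative to the base-parameter table; the
  shipped configs follow the base table (protein ≈ 25%, fat ≈ 7%, typical of
  rodent chow).

## Sensitivity analysis

`sensitivity_table()` runs one-at-a-time perturbations over the shipped
28-row specification (`sensitivity_specs()`), ranks parameters by their
effect on δ^18^O and Δ′^17^O separately (ties share a rank), and retains the
published magnitudes as `printed_*` columns for regression. The headline
structure — z-value and OUF dominating Δ′^17^O while skin evaporation rate
dominates δ^18^O, and redistribution among non-fractionating outputs having
exactly zero effect — is reproduced, with every change magnitude within 20%
of the published value or within a small absolute floor (0.3 permil / 8 per
meg) where the published value itself is small, and most rows within 5%.

```{r sens}
st <- suppressWarnings(sensitivity_table(flux_params(), totals))
head(st[order(st$cap17O_rank),
        c("label", "d18O_change", "cap17O_change", "cap17O_rank")], 5)
```

## Upstream data handling

**Phenotyping QC.** Respirometry gaps of 35–60 min are filled at the nominal
5-min cadence with the mean rate of the preceding 3 h; longer gaps with the
preceding 24 h (researcher presence around long interruptions biases shorter
baselines); gaps under 35 min are left missing and integrate as zero-length.
Filled records are flagged and never feed later fills. Daily hopper intakes
come from mass drops; days exceeding plausibility thresholds (defaults
12 ml water, 8 g food — chosen between the observed maxima of ~6 ml/5 g and
the cited gross artefacts of 25 ml/30 g) are replaced by the cage's mean of
clean days. `window_totals()` integrates a half-open window, so adjacent
windows add exactly.

**Run correction.** Two bracketing standards define an exact per-isotope
two-point stretching/offset fit; control waters gate acceptance (a run fails
with more than two controls off by ≥ 0.15 permil δ^17^O, ≥ 0.3 permil
δ^18^O, or ≥ 15 per meg Δ′^17^O). The outlier rule — single pass, > 2 SD
from the initial mean, per quantity, never removing more than 20% of
injections — is a declared stand-in for the unpublished post-processing
script's rule, and is configurable. Distillation replicates are averaged
unweighted into grand means, with the excess recomputed from grand-mean
deltas.

## The synthetic-data generator

`simulate_phenotyping()` emulates the *structure* of the experiment, not
mouse behaviour: AR(1) gas rates (φ = 0.9, innovation SD 10% of the mean)
around per-mouse draws from the treatment cell's mean ± SD, a 20% sinusoidal
diel cycle, Poisson-timed lognormal hopper events scaled to the daily total,
10% drinker leakage, and injectable gaps/spill/caching days. The four
shipped treatment cells use the published group means and SDs (e.g. control
diet at 25 °C: O~2~ 0.95 ± 0.23 ml/min, RQ 0.87 ± 0.01, food 3.48 ± 1.49
g/day, water 2.42 ± 0.40 ml/day, mass 19.19 ± 1.17 g).
`simulate_body_water()` adds measurement noise as independent Gaussians on
δ^18^O (0.1 permil) and Δ′^17^O (8 per meg, within the distillation
repeatability of ≤ 15 per meg), so the implied δ^17^O noise is strongly
correlated with δ^18^O as in real replicate data.

What passing closed-loop tests therefore show is that the pipeline recovers
truth generated *by this model under these noise assumptions* — they validate
the code and its error propagation, not the physiology. Features of real
data the generator does not attempt: circadian feeding structure beyond one
harmonic, between-day autocorrelation of intake, instrument drift within a
run, and memory effects between injections.

Problem sizes used throughout the tests (cohorts of 2–8 mice over 2–5 days,
runs of 5–11 injections) match the scale of the original experiment, and the
whole suite runs in well under a minute.

## Known limitations

* Steady state only: growing, pregnant or dehydrating animals violate the
  closure assumption, and the urinary residual then absorbs the imbalance.
* Sweating and panting are assumed absent (appropriate for mice).
* The treatment-mean model reproduces published group-mean predictions of
  Δ′^17^O_BW to within ~1 per meg, but group-mean *fractional contributions*
  of individual fluxes can differ by ~0.01–0.02 from means taken over
  individually parameterized animals, because a ratio of means is not a mean
  of ratios.
* One-at-a-time sensitivity ignores parameter interactions; no variance-based
  or Bayesian treatment is attempted.
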