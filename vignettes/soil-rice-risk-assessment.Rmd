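---
title: "Assessing heavy-metal risk in soil–rice systems with paddyrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing heavy-metal risk in soil–rice systems with paddyrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paddyrisk)
```

`paddyrisk` assesses heavy-metal contamination (Cu, Cr, Zn, Cd, Pb, As) in
paddy soil–rice systems through four linked models: soil-to-plant transfer,
soil pollution indices, ecological risk indices, and four-pathway human
health risk, with Monte Carlo uncertainty propagation on top. This vignette
explains each model, its assumptions, the parameters that matter, and the
design choices made where conventions genuinely diverge.

## Soil–plant transfer factors

The bioconcentration factor `BF_root/soil = C_root/C_soil` and the
translocation factors `TF_stem/root`, `TF_leaf/stem`, `TF_grain/stem` are
dimensionless concentration ratios on a dry-weight basis. They are
descriptive: no uptake kinetics, no speciation chemistry. Two conventions
exist for replicated designs — the ratio of group means, or the mean of
per-replicate ratios. `transfer_factors()` uses per-replicate ratios and
reports their mean ± SD, because that preserves replicate-level variance for
downstream use and matches the mean ± SD presentation conventional in this
literature; with multiplicative lognormal noise the per-replicate estimator
has a small positive expectation factor exp(σ²/2) (0.5 % at σ = 0.1), which
the recovery tests account for in their Monte Carlo error budget.

Grain does not exist before heading, so grain-based factors at tillering are
*absent*, carried as flagged records with a reason — never as zero or NaN,
which would silently poison means and rankings. `rank_metals()` orders the
six metals by a factor value with ties broken by the fixed registry order
(Cu, Cr, Zn, Cd, Pb, As) and a tie flag raised.

All concentrations entering the package are mg/kg dry weight; no unit
conversion happens inside the pipeline.

## Pollution and ecological risk indices

The single-metal pollution index `PI = C/S` needs a screening standard `S`.
Which standard applies depends on land use and soil pH band, so **no default
is assumed**: the screening set is explicit configuration, every result
echoes its provenance, and two GB 15618-2018 tables (paddy and other
farmland, four pH bands) are packaged as constructors. A third packaged set,
`screening_backcalc()`, is a synthetic reconstruction chosen so the packaged
contaminated-soil means reproduce a reference PI profile (As 5.92 > Pb 4.66
> Cd 3.35 > Zn 1.96 > Cu 0.65 > Cr 0.32); its Cr entry matches no
regulatory band, which is why it is labelled synthetic and used only for
end-to-end demonstrations.

The Nemerow composite `NIPI = sqrt((mean(PI)² + max(PI)²)/2)` satisfies
`PI_max/√2 ≤ NIPI ≤ PI_max`; the property suite asserts these bounds on
random vectors. The Hakanson index `EI = T·PI` uses toxic response factors
defaulting to Cd 30, As 10, Pb 5, Cu 5, Cr 2, Zn 1, and `RI = ΣEI`.

Class labels come from band tables (`default_index_bands()`). Published
band tables rarely say which class owns a boundary value, so every band
here is half-open `[lower, upper)` — a value equal to a cut falls in the
class above it — applied uniformly and overridable via configuration.
Values are kept at full precision internally; two-decimal rounding happens
only in printing.

## Health risk model

Average daily intake (mg per kg body weight per day) is computed for four
pathways: rice consumption (`ADI_food = C_rice·IR·EF·ED/(BW·AT)`), and soil
ingestion, inhalation and dermal contact, which carry an extra `10⁻⁶` factor
converting mg of soil to kg (the factor applies to the three soil pathways
only). Hazard quotients `HQ = ADI/RfD` and carcinogenic risks `CR = ADI·SF`
aggregate to `HI` and `TCR` per population.

Three choices here are standard practice but worth stating:

* **Two averaging times.** Non-carcinogenic doses average over the exposure
  duration (`AT_nc = ED × 365` days) while carcinogenic doses average over a
  70-year lifetime (`AT_ca = 25 550` days). A single ambiguous `AT` symbol
  cannot reproduce typical HQ and CR magnitudes simultaneously; both values
  sit in the exposure configuration.
* **Absent slope factors are absences.** Cu and Zn have no slope factor on
  any pathway and Pb none for dermal contact; those CR cells do not exist
  and are excluded from `TCR`, never counted as zero. A metal with no CR
  cell at all carries an absent total.
* **Strict thresholds.** `HQ/HI > 1` and `CR/TCR > 10⁻⁴` flag risk; the
  boundary values themselves are assigned to the non-risk side.

Default exposure parameters (adult: 0.3 kg rice/day, 100 mg soil/day,
14.5 m³ air/day, EF 350 d/y, ED 24 y, BW 60 kg, SA 5700 cm², AF 0.07,
ABS 0.001, PEF 1.36×10⁹ m³/kg; child correspondingly 0.2 kg, 200 mg,
7.5 m³, ED 6 y, BW 15 kg, SA 2800 cm², AF 0.2) and the RfD/SF tables follow
widely used US EPA IRIS/RAIS values; all are overridable and every report
echoes the configuration in force. Because HQ and CR depend multiplicatively
on these configurable values, per-cell risks are configuration-dependent;
what is configuration-independent — and what the tests pin down — is the
aggregation structure (HI and TCR as exact sums, linear scaling in
concentration, metal-then-pathway summation equal to pathway-then-metal).

Summation order inside the aggregation is fixed (registry metal order,
pathways food/ing/inh/der) using R's extended-precision accumulators, so
totals are bit-reproducible regardless of input row order and the
degenerate Monte Carlo run below matches the deterministic pipeline exactly.

## Monte Carlo uncertainty propagation

`simulate_risk()` replaces any subset of model inputs — concentrations per
metal, intake rates, body weight, exposure duration — by distributions
(point, normal, lognormal, uniform, triangular), samples them independently
(no correlation structure is modelled), and pushes each of the n iterations
through the *same* intake/HQ/CR operations as the deterministic pipeline.
Outputs are exceedance probabilities (`HQ/HI > 1`, `CR/TCR > 10⁻⁴`), means
and the 5th/50th/95th percentiles per endpoint and population.

Numerical choices: truncation is by rejection, so draws follow the exact
conditional distribution inside the bounds, with an error raised if the
acceptance rate shows the bounds exclude essentially all mass (< 10⁻⁴);
the triangular family uses inverse-CDF sampling; the seed is a mandatory
argument — there is no silent nondeterminism — and identical
(configuration, n, seed) gives bit-identical results. The default n of
10,000 iterations makes the binomial standard error of an exceedance
probability at most 0.5 percentage points. An exceedance of 1.0 means every
iteration exceeded; it is a sample statement, not a certainty claim.

Three analytic anchors validate the machinery: all-point distributions
reproduce the deterministic pipeline bit-for-bit; a lognormal concentration
with a linear risk chain has a closed-form exceedance probability that the
simulated fraction must match within binomial error; and shifting a
concentration distribution upward can never lower an exceedance
probability at fixed seed.

## Phytotoxicity endpoints

Growth traits (plant height, root length, dry weights, tiller number,
panicle emergence), oxidative-stress markers (MDA, SOD, POD, CAT) and
rhizosphere amino acids are summarised as percent change of the
contaminated-group mean against the control mean: negative is inhibition,
positive stimulation. The report carries replicate-level SDs (the SD of
per-replicate percent changes against the control mean) so external tools
can run significance tests; the package itself performs none — ANOVA/Tukey
machinery is routine and orthogonal to the descriptive percent change the
assessment headlines.

## The synthetic-data generator

`generate_dataset()` samples from an explicit forward model calibrated to a
pot study on paddy soil near a long-exploited Pb–Zn mining area:

* soil concentrations are lognormal around the configured contaminated and
  control means (defaults: Cu 65.18, Cr 69.75, Zn 490.87, Cd 2.01,
  Pb 652.34, As 148.11 mg/kg contaminated; Cu 23.98, Cr 38.46, Zn 123.94,
  Cd 0.27, Pb 31.92, As 13.08 control) with coefficient of variation 0.05,
  the order of the replicate scatter those measurements show;
* tissue concentrations chain the true transfer factors — root from soil,
  stem from root, leaf and grain from stem — with independent multiplicative
  lognormal noise (σ = 0.1) at each step, and no grain at tillering;
* endpoints are control mean × (1 + effect/100) × lognormal noise
  (σ = 0.05), with effect defaults such as −31.4 % plant height at
  tillering and +116.6 % stem MDA at heading; control means are
  field-plausible magnitudes chosen once (the emulated study reports only
  percent changes);
* four replicates per group, matching the emulated design, and a seed that
  makes the dataset a pure function of the configuration.

Lognormality is the standard choice for non-negative, right-skewed
environmental concentration data. The generator deliberately omits features
of real data — spatial structure, inter-metal correlation, censoring at
detection limits, stage-dependent soil dynamics — so passing tests show the
estimators and index chain are correct under the stated statistical
structure, not that field data will satisfy that structure.

With noise set to zero the forward model inverts exactly: the accumulation
module recovers every generating factor, and the factor chain equals
`C_leaf/C_soil` identically, which the tests assert.

## Problem sizes and runtime choices

The test suite uses four replicates per generated dataset (the emulated
design), 200 seeded datasets for the transfer-factor recovery study, 1,000
random vectors for the Nemerow bound property, and 10⁴ Monte Carlo
iterations for the exceedance-probability comparison — sizes at which the
Monte Carlo error bounds in the tests are meaningful while the full suite
runs in well under two minutes. The packaged demo configuration runs 2,000
Monte Carlo iterations; production runs default to 10,000.

## Known limitations

* Factors are descriptive ratios; no mechanistic uptake, speciation or
  pH-dependent sorption modelling.
* Health risk covers two populations (adult, child) with deterministic
  exposure defaults; no age-stratified dose–response, no bioaccessibility
  correction.
* Monte Carlo sampling is independent across parameters; correlated inputs
  (e.g. co-contamination) are not modelled.
* Classification bands and toxicological reference values are conventions
  shipped as defaults, not facts about any particular jurisdiction; results
  should always be read together with the echoed configuration.
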