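---
title: "Mechanistic and correlative range modelling for anadromous fish: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic and correlative range modelling for anadromous fish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shadrange)
```

`shadrange` simulates the distribution dynamics of an anadromous fish —
parameterized by default for allis shad (*Alosa alosa*) — over a network of
river basins under climate forcing, and confronts those mechanistic
projections with a correlative habitat-suitability model fitted to
presence/absence data. This vignette is the package's account of the
science: the models, their assumptions, the tunable parameters, the
numerical choices, and the limits of what the synthetic test bed can show.

## The mechanistic model

### State representation

The population is a collection of super-individuals: weighted cohorts of
identical fish characterized by age (quarter-year resolution), length,
natal basin, location (a river basin, or the sea adjacent to a basin) and
spawning history. Internally the engine stores weights and mean lengths in
arrays indexed by age class and basin, split by location and by first-time
vs repeat spawner status. Survival and post-spawning survival scale cohort
weights deterministically (the expected value); recruitment and growth
carry explicit log-normal noise; dispersal is sampled stochastically by
default. This keeps a seasonal step to a fixed set of vectorized array
operations, so century-scale runs over tens of basins complete in seconds.

### Seasonal cycle

Seasons are calendar quarters (winter = JFM, spring = AMJ, summer = JAS,
fall = OND); a seasonal step is 0.25 year. A simulation year starts in
summer — the season in which each basin is seeded with juveniles at the
first step — and ends with the spring reproduction. Within a step the
process order is fixed and test-pinned:

1. resolve water temperatures for every basin;
2. survival — at sea under the annual mortality coefficient `z_sea`
   (`exp(-z_sea/4)` per step), in river under the thermal window of river
   survival raised to the 1/4 power times `exp(-h_riv/4)`;
3. growth, at sea only (see below);
4. maturation — fish of length at least `l_mat` are mature;
5. season-gated migration: in the upstream season mature fish at sea run
   into rivers (homing or straying); in the reproduction season spawners
   present in a basin reproduce and post-spawning survival (`sp_sp`) is
   applied, first-time survivors becoming repeat spawners; in the
   downstream season river fish of age at least `down_mig_age` (new
   recruits and spent spawners alike) run to the sea adjacent to the basin;
6. ageing by a quarter year.

All temperature-dependent rates share one dome response: performance is 1
at the optimum, falls continuously to 0 at the window bounds, and is 0
outside. Growth, egg-to-recruit survival and river survival each carry
their own `(tmin, topt, tmax)` triplet.

### Recruitment

Recruits (juveniles of assumed age `dt_rec` = 0.33 yr) are produced by a
Beverton–Holt relation on the *effective* spawner stock. The Allee
(depensation) correction multiplies the stock `S` by a logistic term that
reaches 0.5 at `S50 = eta*wa/theta` and 0.95 at `S95 = eta*wa` — scaled by
the basin's drainage area `wa` (km²), so founding a population in a large
basin takes more colonists.

The Beverton–Holt coefficients themselves are a documented reconstruction,
isolated in one internal function so an alternative can be swapped in:

* the asymptotic recruitment (capacity) scales with drainage area,
  `alpha_j = lambda_rec * wa_j * 1e6`, i.e. `lambda_rec` is read as
  recruits per m² of drainage area. With the nominal
  `lambda_rec = 4e-4` this gives a ~2×10⁶-recruit capacity for a
  5000 km² basin, consistent with a fecundity of 135 000 eggs and optimal
  egg-to-recruit survival of order 10⁻³ (a km² reading would cap
  recruitment at a few fish and no basin could ever sustain a population);
* the half-saturation constant is `beta_j = alpha_j / (a * surv(T))` with
  `a` the fecundity and `surv(T) = surv_opt_rep * dome(T)`, so the
  low-density slope of the curve equals fecundity × temperature-dependent
  egg survival — the natural density-independent limit.

Realized recruitment multiplies the kernel by mean-corrected log-normal
noise `exp(eps - sigma_rep^2/2)`, `eps ~ N(0, sigma_rep)`, so its
expectation equals the kernel; the same correction applies to growth
increments (`sigma_dl`). The correction is a package choice: without it the
noise would inflate expectations by `exp(sigma^2/2)`.

### Growth and maturation

Growth follows a seasonal von Bertalanffy increment
`(l_inf - L) * (1 - exp(-k_opt_grow * dome(T)))`, applied at sea with the
temperature of the adjacent basin. `k_opt_grow` is treated as the
per-season von Bertalanffy rate at the thermal optimum; its catalogued
range (0.2–0.5 per season) makes fish approach `l_inf` quickly, so
simulated maiden spawners are younger than wild allis shad (whose mean
spawner age is about five years). This is a known tension in the
parameterization — the spawner-age summary statistic (`ss3`) exists
precisely to let calibration pull `k_opt_grow` toward values reproducing
the observed age pattern. Fish growing in unsuitable temperatures simply
do not grow; length never decreases and never exceeds `l_inf`.

### Dispersal

The upstream run is a three-stage process. Each mature fish first adopts
homing with probability `p_hom` (nominally 0.75) and then returns to its
natal basin; strays instead choose among all basins through a logit weight
combining accessibility (dispersal distance from the natal basin,
standardized by `dist_mean`/`dist_sd`, entering negatively so remote basins
are unreachable) and, when their coefficients are nonzero, fish length and
basin area. A virtual death basin with fixed weight `w_death_basin` absorbs
strays that fail to find any river. Weights are normalized to destination
probabilities and the choice is multinomial.

Two engine modes exist. The default stochastic mode allocates integer
strays by binomial/multinomial draws (a vectorized conditional-binomial
construction, one `rbinom` per destination rather than one `rmultinom` per
cohort), which preserves the discreteness that makes colonization — and
the Allee effect — meaningful. The `expected` mode allocates weight
deterministically by the probabilities; it is useful for theoretical runs
(e.g. the conservation check) but lets infinitesimal weight trickle into
every basin, so it is not the default. Fish fractions below one individual
stay with the homing pool rather than straying.

After spawning, surviving spawners are keyed to the basin in which they
spawned (spawning-site fidelity for repeat homing) and return to sea at the
next downstream season; whether spent spawners overwinter in river instead
is unresolved in the source literature, and the immediate-return choice is
test-pinned.

Distances default to great-circle (haversine, Earth radius 6371 km)
between basin outlets; whether along-coast or straight-line distances are
the better model input is an open question, so a user-supplied (e.g.
coastal-route) matrix passes through after symmetry/positivity validation.

### Climate forcing

Demography consumes water temperatures; air-medium input is converted on
load by a constant −2 °C offset. Three regimes resolve a temperature: the
constant reference regime (per-basin seasonal means over a reference
decade, used during spin-up), and observed/scenario series regimes that
look up `(basin, year, season)` and treat a missing value as an error,
never a silent fallback. The projection protocol — spin-up on the constant
reference, then a historical series, then a scenario — is expressed as a
(spin-up years, series start) schedule in the configuration; a 300-year
protocol is exactly 1200 seasonal steps.

## Calibration machinery

Three summary statistics confront a run with an observed distribution: the
Bernoulli log-likelihood of the presence/absence flags under the per-basin
persistence probabilities (with a 0.001 guard inside the logarithms); the
latitude of the northernmost populated basin, where "populated" means mean
terminal-decade recruitment strictly above 50 juveniles; and the summed
squared deviation of mean first-time-spawner ages from five years.
Persistence itself is the fraction of years with successful reproduction
over a terminal window (10 years for historical runs, 30 for projections).

The sensitivity analysis is a complete two-level factorial over the 11
uncertain parameters (2¹¹ = 2048 combinations, replicated to absorb
simulator stochasticity). Indices are factorial-ANOVA variance shares:
main effects, pairwise interactions, and a residual that includes pure
error; on the orthogonal ±1 design these equal squared contrast sums over
the total sum of squares, which is how the test oracle computes them.

Calibration of the two most influential parameters uses rejection ABC. The
package deliberately replaces the adaptive ABC algorithm used in the
original calibration work with standard rejection sampling (plus a
reusable reference table), because it is transparent, trivially
parallelizable and exactly reproducible; the sampler is isolated behind
`abc_calibrate()` so a sequential scheme can be slotted in. The three
objectives are collapsed into one scalar discrepancy — each component
deviation normalized by its spread (MAD) across the prior sample, equally
weighted by default since no trade-off is prescribed — and an undefined
northern limit (no populated basin) receives the maximal discrepancy of
its component. Non-calibrated uncertain parameters stay at the centre of
their ranges, which is also their default value.

## The correlative model

A binomial additive model relates presence/absence to at most three
predictors; each smooth term gets exactly two effective degrees of freedom
(`mgcv` spline bases with fixed df), enough to express increasing,
decreasing or dome-shaped responses without overfitting. The smoother
family behind the fixed-df basis is a package choice (thin-plate by
default through `mgcv`) and is pluggable in principle; nothing downstream
depends on the basis. All subsets of size 1–3 are fitted by maximum
likelihood and compared by AIC; non-converging candidates are excluded
with a warning. Surface area is log-transformed before fitting. The
calibration/validation split (75/25) is random but stratified by class —
stratification is a package choice, made so small validation sets keep
both classes. Evaluation uses explained deviance, rank-based AUC and
Cohen's kappa at the kappa-maximizing threshold, which is scanned over all
midpoints between consecutive distinct scores plus the endpoints, ties
broken toward the smaller threshold. Projection onto new climates is the
inverse-logit evaluation of the fitted terms; basins outside the fitted
predictor range are flagged as extrapolated rather than refused.

## Joint analysis

Comparisons are restricted to the basins common to both model families,
ordered by latitude. Probabilities are reported raw and in five classes
(0; (0, 0.25]; (0.25, 0.53]; (0.53, 0.75]; (0.75, 1]) — the 0.53 cut is
the kappa-maximizing threshold of the reference correlative model, so the
moderate/high boundary coincides with the binary presence call. The
package emits tidy wide and long tables (heat-map-ready) rather than maps,
since probabilities drawn on areas as heterogeneous as river basins invite
over-reading of large polygons. `joint_report()` turns the two
interpretation patterns — trend congruence between periods and range-limit
congruence between model families — into explicit verdicts computed from
mean-probability deltas and range-limit deltas under user-set tolerances;
the tolerances are reporting choices, not fitted quantities.

## The synthetic test bed

Every fixture is generated in code. The default network is a 20-basin
latitudinal chain from 37 to 59.8 °N (the size keeps the full suite,
including an ABC recovery run, within minutes on one CPU) with log-normal
drainage areas (median 5000 km², log-sd 1 — spanning small coastal basins
to Loire-scale systems). The climate declines linearly with latitude
(0.45 °C per degree from 16 °C spring water at 37 °N), carries a ±6 °C
summer/winter seasonal cycle, optional linear warming for scenario runs,
and small Gaussian noise; the first decade doubles as the reference
regime. The virtual species is present where the dome response of its
egg-survival window to reference spring temperature reaches 0.25, giving a
contiguous southern presence band with its edge mid-network — so both
model families see a range limit inside the study area. Optional seeded
contamination emulates false presences/absences.

What the fixture does *not* emulate: real coastlines and route distances,
inter-basin heterogeneity of the seasonal cycle, temporally autocorrelated
climate anomalies, observation bias correlated with basin size, and any
anthropogenic pressure. Passing tests therefore demonstrate that the
algorithms are implemented as specified and recover known structure from
data generated under their own assumptions — not that the parameterization
is faithful to any real fish population.

## Numerical choices and degenerate inputs

* Age is tracked in quarter-year classes offset by `dt_rec` (recruits are
  created at age 0.33 in spring and reach the sea the following summer);
  fish beyond `max_age` (default 20 years, configurable) leave the system.
* The thermal dome is clamped to exactly 0 at and outside its bounds; the
  removable singularity at the bounds is handled explicitly.
* Zero spawners, zero egg survival or a zero capacity give exactly zero
  recruits (no noise is drawn around a zero kernel).
* Empty cohort cells keep zero length; merges recompute mean length as a
  weight-weighted average, so phantom lengths cannot leak.
* An all-zero destination weight vector is an error (no basin reachable
  and no death weight); probabilities are validated to sum to one.
* Replicate seeds derive deterministically from the base seed
  (`(seed + 1000003 * k) mod (2^31 - 1)`), so any stage can be reproduced
  in isolation.
* In `sensitivity_indices()` a constant response returns all-zero shares
  rather than an error; in `fit_sdm()` a predictor without enough distinct
  values falls back to a linear term.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the 2048-row design
generation (without simulations), a single 300-year/20-basin projection, a
50-year conservation run, a 2000-draw ABC reference table on the 20-basin
fixture with ten recovery repetitions at 5 % acceptance, and a 150-basin
correlative recovery. The ABC reference table is simulated once and
re-used across the ten repetitions (each repetition has its own observed
dataset and accepted set) — the standard fixed-reference-table practice
for rejection ABC.

## Known limitations

* Basins are atomic: no within-basin spawning reaches, dams or
  longitudinal structure.
* The sea is represented as a box adjacent to each basin; marine movement
  and marine thermal habitat are not modelled.
* No evolutionary processes (e.g. local thermal adaptation) and no
  anthropogenic pressures; a persistent mismatch at a modelled northern
  range edge is exactly the signature such missing processes would leave.
* The Beverton–Holt coefficient reconstruction above is one defensible
  reading of the catalogued parameters; alternative stock–recruitment
  parameterizations can replace it behind `recruitment()`.
* Rejection ABC is inefficient for sharply concentrated posteriors;
  the acceptance fraction and reference-table size trade accuracy against
  cost and both are exposed.
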