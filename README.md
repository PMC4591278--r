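# shadrange

Mechanistic and correlative range modelling for anadromous fish.

`shadrange` is for ecologists and conservation modellers who want to ask,
for a migratory fish such as allis shad (*Alosa alosa*), two complementary
questions about climate change: *where will conditions be suitable?* (a
correlative species distribution model fitted to presence/absence data)
and *where can populations actually persist and which basins can be
colonized?* (a mechanistic, process-explicit simulator of the full
anadromous life cycle over a network of river basins). The package
implements both model families, the machinery to calibrate the mechanistic
one against an observed distribution, and the tools to analyse the two
sets of projections jointly.

## The models in brief

**Mechanistic simulator.** Time advances in seasons (quarter years) over a
set of river basins with outlet coordinates, drainage areas `wa_j` (km²)
and seasonal water temperatures. Reproduction in basin *j* follows a
Beverton–Holt stock–recruitment relation with an Allee correction:

    R_j = alpha_j * S'_j / (beta_j + S'_j),
    S'_j = S_j / (1 + exp(-ln(19) * (S_j - S50_j) / (S95_j - S50_j)))

with `S95_j = eta * wa_j`, `S50_j = eta * wa_j / theta`, capacity
`alpha_j` proportional to drainage area and `beta_j` set so the
low-density slope equals fecundity × temperature-dependent egg survival.
Every temperature-dependent rate (egg survival, growth, river survival)
shares the dome response

    k(T) = (T - Tmin)(T - Tmax) / [(T - Tmin)(T - Tmax) - (T - Topt)^2]

which is 1 at `Topt` and 0 at and beyond the window bounds. Growth is
seasonal von Bertalanffy at sea; mortality is `exp(-Z_sea/4)` per season
at sea and thermally modulated in river; maturity is a length threshold.
On the upstream run each mature fish homes to its natal basin with
probability `p_hom` or strays, choosing a destination by a multinomial
draw over logit accessibility/attractiveness weights that include a
virtual "death basin" absorbing failed transfers — straying is what lets
the range shift. Per-basin persistence probability `p_sust` is the
fraction of terminal-window years with successful reproduction.

**Calibration.** Three summary statistics (distribution log-likelihood,
northernmost populated latitude under a 50-juvenile rule, spawner-age
deviation from five years) feed a complete 2^11 two-level factorial
sensitivity analysis with ANOVA variance-share indices, and rejection-ABC
posterior estimation for the two most influential parameters.

**Correlative model.** A binomial additive model with at most three
predictors and two effective degrees of freedom per smooth, selected by
exhaustive AIC search, evaluated by explained deviance, Cohen's kappa at
the kappa-maximizing threshold, and rank-based AUC, on a stratified 75/25
calibration/validation split.

A synthetic-data module generates basin networks, latitude-structured
seasonal climates with optional warming, and virtual-species
distributions, so the entire tool chain runs without any external data.
See the vignette in `vignettes/range-modelling-methods.Rmd` for the full
model description and design rationale.

## Worked example

Simulate sixty years on a 20-basin synthetic coastline, fit the
correlative model to a noisy virtual distribution, and compare the two:

```r
library(shadrange)

fx  <- make_fixture(n_basins = 20, years = 60, seed = 1)
obs <- make_virtual_distribution(fx$network, fx$climate,
                                 thermal_rep(fx$params),
                                 false_presence = 0.15,
                                 false_absence = 0.15, seed = 3)

res <- run_simulation(fx$network, fx$climate, fx$params,
                      simulation_config(years = 60, seed = 1))
res
#> <simulation result: 60 years (240 seasonal steps), 20 basins>
#>   final-year spawners: 13136484, recruits: 31311970

summary_statistics(res, obs)
#> $ss1            $ss2      $ss3
#> [1] -41.43      [1] 49    [1] 115.9

dat <- data.frame(presence     = as.integer(obs),
                  temperature  = fx$climate$reference[fx$network$basins$id,
                                                      "summer"],
                  surface_area = fx$network$basins$surface_area,
                  lat          = fx$network$basins$lat)
fit <- fit_sdm(dat, c("temperature", "surface_area", "lat"), seed = 1)
fit
#> <correlative SDM fit>
#>   predictors: temperature, surface_area
#>   AIC 18.60, explained deviance 55.0%
#>   kappa 0.842 / 1.000, AUC 0.960 / 1.000 (calibration/validation)
#>   kappa-maximizing threshold 0.680

p_suit <- setNames(project_sdm(fit, dat)$p_suit, fx$network$basins$id)
cmp <- comparison_table(p_suit, persistence_probability(res, 10),
                        fx$network)
cmp
#> <joint comparison: 20 basins; mean p_suit 0.370, mean p_sust 0.550>
#>   probability-class agreement: 4 / 20 basins
```

Reading the numbers: the simulator sustains reproduction every year in the
eleven southern basins (populated up to 49 °N, the `ss2` value), while the
correlative model — fitted to the contaminated virtual distribution —
recovers summer temperature as the dominant predictor and explains 55 % of
the deviance. The joint table shows the mechanistic range reaching
slightly farther north than the correlative suitability band, the kind of
discrepancy whose interpretation `joint_report()` structures (congruent
trends vs divergent range limits).

Calibration runs look like:

```r
sim <- make_summary_simulator(fx$network, fx$climate, fx$params,
                              simulation_config(years = 30, seed = 1,
                                                max_age = 10), obs)
post <- abc_calibrate(priors  = list(tmin_rep = c(9, 12),
                                     k_opt_grow = c(0.2, 0.5)),
                      targets = c(ss1 = 0, ss2 = 53.55, ss3 = 0),
                      simulator = sim, n_draws = 500, accept_rate = 0.05,
                      seed = 1)
```

A thin command-line interface covers data generation and simulation
(`Rscript -e 'quit(status = shadrange::main())' synth --seed 1 --out fx`,
then `simulate --basins fx/basins.csv ...`); see `?main`.

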