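# redtidesim

A desk-scale spatiotemporal food-web simulator for studying episodic
harmful-algal-bloom (red tide) impacts on coastal marine ecosystems.

Gulf-of-Mexico-style red tides — blooms of the toxic dinoflagellate
*Karenia brevis* — kill fish directly, depress feeding and growth below
lethal concentrations, and push mobile animals out of affected areas.
Quantifying what a bloom year costs an ecosystem (and a fished stock)
requires a model that couples food-web dynamics, space, and episodic
mortality forcing. `redtidesim` provides that machinery in a compact,
fully synthetic form for methodologists and ecosystem modellers: every
input — the balanced food web, monthly environmental rasters, bloom
concentration maps, and survey observations — is generated by seeded
code, so every result in the package is reproducible from a single
integer.

## The model

**Static snapshot.** An Ecopath-style mass balance: for each group *i*
with biomass *B*, production/biomass *PB*, consumption/biomass *QB*,
diet fractions *DC*, catch *Y* and accumulation *BA*,

    B_i PB_i EE_i = sum_j B_j QB_j DC_ji + Y_i + BA_i,

and the unconsumed remainder defines baseline "other mortality"
`M0base_i = PB_i (1 − EE_i)`.

**Dynamics.** Foraging-arena consumption
`Q = a' v B_prey B_pred / (2v + a' B_pred)` with the search rate scaled
by habitat capacity (`a' = a·capacity`), vulnerability multipliers per
predator, and a semi-implicit monthly integrator for which the balanced
snapshot is an exact fixed point. On the grid, habitat capacity is the
product of environmental response functions; biomass moves toward
better habitat at trait-based dispersal rates (the "300-30-3" rule) with
exact mass conservation, and fishing effort follows a gravity model of
cell profitability.

**Red-tide forcing** (the core of the package). The proportion of
biomass killed per cell and month is a logistic in bloom concentration
*x*:

    A = 1 / (1 + (x/c)^(−b)),   Â = −ln(1 − A)·12,   M0mult = Â / M0base,

with 5 inflection concentrations × 4 slopes = 20 lethal curves, and 15
sublethal (foraging) curves at 25/50/75% of each lethal inflection that
shrink habitat capacity — reduced feeding plus avoidance. Crossing 20
mortality-only with 60 mortality+foraging configurations and two target
sets (all consumers vs. one focal group) yields the 160-scenario
ensemble. Annual indicators (total biomass `B_T`, harvested biomass
`B_har`, bloom-caused loss `B_loss`, catch `C_T`), a per-group annual
red-tide mortality rate, ensemble screening against an assessment loss
rate (0.77 ± 0.12 band plus an RMSE filter), and before/after–in/out
abundance contrasts summarise the impacts. A one-at-a-time,
percent-bias-minimising iterative routine calibrates vulnerability and
dispersal parameters against a reference trajectory.

## Worked example

```r
library(redtidesim)

web   <- gen_foodweb(n_groups = 10, n_fleets = 2, seed = 1)
glance(web)
#>   n_groups n_consumers total_biomass total_production total_catch max_ee
#> 1       10           8          67.7            6255.        13.3  0.480

model <- calibrate_model(web)
grid  <- make_grid(15, 15, cell_km = 10)
drivers <- gen_drivers(grid, n_months = 60, seed = 2)
blooms  <- gen_blooms(grid, n_years = 5, severe_years = 3, seed = 3)

scenarios <- build_scenario_grid(target_group = "grouper")
scen <- scenarios[17, ]     # a mortality-only curve applied to all consumers
run <- run_simulation(model, grid, drivers, blooms, scenario = scen,
                      n_months = 60,
                      env_responses = default_env_responses(web))

ecosystem_indicators(run)
#>   scenario      year   B_T B_har B_loss   C_T
#> 1 S017_M17_all     1  69.5  6.91  0.118  13.9
#> 2 S017_M17_all     2  69.5  7.00  0.201  14.0
#> 3 S017_M17_all     3  69.5  6.41 10.6    12.7
#> 4 S017_M17_all     4  69.2  6.93  0.276  14.0
#> 5 S017_M17_all     5  69.4  6.99  0.217  14.0

mortality_index(run, "grouper")
#>   year   loss mean_biomass    rate
#> 1    1 0.0524         6.01 0.00871
#> 2    2 0.0881         5.87 0.0150
#> 3    3 2.73           4.72 0.579
#> 4    4 0.0357         2.87 0.0124
#> 5    5 0.0320         3.03 0.0106
```

Year 3 is the configured severe bloom year: ecosystem-wide biomass loss
jumps from ~0.2 to 10.6 t km⁻², and the focal group's annual red-tide
mortality rate spikes to 0.58 yr⁻¹ before the stock rebuilds. Units are
t km⁻² for biomass quantities and yr⁻¹ for rates.

The full ensemble, screening, validation contrast and calibration
demonstration run from one configuration:

```r
p <- run_pipeline(default_config(seed = 1), out_dir = "runs/demo")
```

which writes `indicators.csv`, `scenarios.csv`, `screening.csv`,
`validation.csv`, `calibration_log.csv`, `status.csv`, the generated
inputs, and a manifest. `autoplot()` methods cover indicator tables and
calibration logs; `plot_response_library()` and `plot_blooms()` draw the
forcing.

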