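---
title: "Modelling red-tide impacts on a synthetic shelf food web"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling red-tide impacts on a synthetic shelf food web}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redtidesim)
```

`redtidesim` couples three layers — a mass-balanced food web, per-cell
trophic dynamics, and a gridded spatial engine — and forces them with
episodic harmful-algal-bloom (red tide) mortality. This vignette is the
package's account of the science: the model and its assumptions, the
parameters that matter, what the synthetic generators do and do not
emulate, and the numerical and design choices made where the problem
was genuinely open.

## 1. The static snapshot

The food web is a set of biomass pools (one producer, a ladder of
consumers, one detritus pool) satisfying, for every living group, the
mass-balance identity

$$B_i\,PB_i\,EE_i \;=\; \sum_j B_j\,QB_j\,DC_{ji} + Y_i + BA_i,$$

production equals predation plus catch plus accumulation. `solve_balance()`
treats the identity as a linear system with exactly one unknown per
group (biomass or ecotrophic efficiency $EE$) and refuses to balance a
web whose solved $EE$ leaves $[0,1]$ — reported per group, never
clipped. The remainder $M0_{base,i} = PB_i (1-EE_i)$ is baseline "other
mortality": disease, senescence, environment. It is the term the
red-tide forcing acts on, which is why the snapshot must be balanced
before anything dynamic happens.

Detritus is a non-living pool that receives every group's other
mortality plus a fixed unassimilated fraction of all consumption
(default 0.2, the conventional assimilation complement); detritivory
and a burial/export closure balance it at baseline.

## 2. Trophic dynamics

Consumption follows foraging-arena theory: prey shuttle between an
invulnerable reserve and an arena where predators hunt,

$$Q_{ji} = \frac{a' v B_i B_j}{2v + a' B_j},\qquad a' = a\cdot capacity_j .$$

Two conventions matter here:

* **Vulnerability scaling.** The per-link exchange rate is
  $v = m_j\,Q^0_{ji}/B_i^0$, with $m_j > 1$ a unitless per-predator
  multiplier (default 2, mixed trophic control; the calibration loop
  searches $[1.01, 10^4]$). Scaling by the baseline flow is what makes
  any realistic baseline feasible — a consumer's annual ration routinely
  exceeds its prey's standing biomass, so an unscaled exchange rate of
  order 1 could never supply it. The multiplier bounds how far predation
  mortality can rise above baseline, which is exactly its role in
  foraging-arena theory.
* **Search-rate calibration.** $a$ is chosen per link so that at
  baseline biomasses and capacity 1 the flow equals the snapshot flow
  $B_j QB_j DC_{ji}$ exactly. The balanced state is therefore an exact
  equilibrium of the dynamics, and the package's fixed-point tests hold
  to floating-point noise rather than to a loose tolerance.

Growth efficiency is $PB/QB$ at baseline, held constant. Producers grow
at $PB \cdot B \cdot f(\mathrm{chl}) \cdot capacity$ with $f$ the relative
chlorophyll anomaly clipped to $[0.1, 10]$; the kernel supplies a
density-dependent $PB(B) = PB_0\,2/(1+B/B_0)$ (production saturates at
twice the baseline flow, equal to $PB_0$ at baseline). Without that
standard closure, any scenario that suppresses grazers sends the
producer into unbounded exponential growth; the system the package
emulates avoids this because its production is anchored to observed
chlorophyll fields, an anchor a self-contained simulator does not have.

**Integration.** Months are integrated in 4 sub-steps with a
semi-implicit (Patankar-type) update: gains explicit, losses implicit
through their rates,
$B' = (B + \Delta t\,G)/(1 + \Delta t\,L/B)$. The detritus pool and the
producer turn over at 100–200 yr⁻¹, far beyond the explicit-Euler
stability limit at $\Delta t = 1/48$ yr — an explicit scheme with loss
capping was tried first and oscillated explosively at exactly those
pools. The semi-implicit form is positivity-preserving, needs no
capping, keeps the balanced state an exact fixed point at any step
size, and is shared verbatim between the single-cell and spatial
engines, so the one-cell equivalence check is exact. Realized losses
are the implicit rates times updated biomass, so each group's budget
(growth − predation − fishing − other mortality) closes identically at
every sub-step.

## 3. Space

Cells are square (default 10 km, 15 × 15 with a western coastline).
Habitat capacity is the product of a group's environmental response
functions times the sublethal bloom multiplier, floored at $10^{-4}$.
Responses are logistic preferences (bottom temperature for demersal,
reef-associated and benthic groups; surface temperature for pelagic
groups) evaluated **relative to their value at the baseline driver
value** and capped at 1, so capacity is exactly 1 under baseline
conditions — the same normalisation applied to the sublethal curve
(§4). Movement is donor-controlled on the rook lattice with reflecting
boundaries: a cell sheds biomass at a rate scaling with
$\min(0.95,\,D\,\Delta t/\ell)\,(1-capacity)$, and the flux over each
edge is weighted by the receiving neighbour's capacity and normalised
by the full stencil size. That normalisation makes a uniform field
under uniform capacity exactly neutral and conserves every group's
domain total to machine precision. Dispersal rates $D$ follow the
"300-30-3" rule from the habitat traits: 300 km yr⁻¹ pelagic, 30
demersal/reef-associated, 3 benthic and planktonic. How strongly
reduced capacity should accelerate emigration is not settled; the
linear $(1-capacity)$ factor is this package's choice.

Fishing effort is reallocated monthly by a gravity model: each fleet's
fixed total is spread over cells in proportion to price-weighted target
biomass minus a spatial cost (default zero, so the baseline allocation
is uniform and the fixed point survives on the grid), with a uniform
fallback when nothing is profitable. Catchabilities are calibrated so
baseline effort reproduces the snapshot catches.

Runs open with a spin-up (default 24 months) during which blooms are
off and each group's domain total is relaxed toward baseline with a
6-month time constant; recording starts afterwards. A stability screen
aborts any run whose biomass goes non-finite or whose domain total
leaves $[10^{-4}, 100]\times$ baseline — the persistence criterion an
accepted simulation must meet — and aborted runs are recorded and
excluded from aggregation, never silently dropped.

The fixed per-month order of operations is: (1) capacity update,
(2) red-tide kill, (3) trophic sub-steps, (4) movement, (5) effort
reallocation for the next month.

## 4. Red-tide forcing

The proportion of a group's biomass killed in a cell over a month is a
logistic in *K. brevis* concentration $x$ (cells L⁻¹):

$$A = \frac{1}{1 + (x/c)^{-b}},\qquad
\hat A = -\ln(1-A)\cdot 12,\qquad
M0_{mult} = \hat A / M0_{base}.$$

The curve library crosses 5 inflections, log-spaced over
$10^{4.5}$–$10^{6.5}$ cells L⁻¹ (the range over which blooms harm
marine fauna; config-overridable) with 4 slopes (1, 2, 4, 8). Sublethal
foraging curves sit at 25/50/75% of each lethal inflection with a
constant linear-$x$ rate of $5\times10^{-5}$ L cells⁻¹, so every curve
is an x-translation of one shape. Together: 20 lethal curves, 15
foraging curves, 20 + 60 = 80 configurations, × 2 target sets = 160
scenarios.

Three design points deserve emphasis:

* **Discrete kill, not a doubled rate.** $\hat A$ over one month
  removes exactly the proportion $A$ by construction, so applying the
  multiplier in the derivative *and* removing $A\,B$ at the start of
  the month would kill everything twice. The engine removes the kill
  $loss = A \cdot B$ discretely at step 2 (routed to detritus for mass
  closure) and records it — making the loss tensor exact bookkeeping —
  while `m0_multiplier()` reports $M0_{mult}$ diagnostically. Where a
  caller does drive the dynamics through the multiplier,
  the contract is **additive**: effective other mortality is
  $M0_{base}(1 + mult)$, so zero forcing recovers the baseline (a
  replacement convention would make a bloom-free month lethal for any
  group with $mult < 1$). Groups with $EE = 1$ have $M0_{base} = 0$;
  for them the annualized rate is applied as an absolute rate and
  flagged.
* **Sublethal normalisation.** A linear-$x$ logistic has $f(0) < 1$
  (materially so for the smallest inflections), which would let a
  zero-concentration bloom change a run. The engine therefore applies
  $f(x)/f(0)$ — the same baseline-relative convention as the
  environmental responses — so zero concentration is exactly neutral
  while the curve itself keeps its midpoint at the inflection.
* **Slope interpretation.** A rate proportional to the inflection
  would change the curve's shape on a linear axis; shape-preserving
  translation requires a constant rate, which is how the
  $-5\times10^{-5}$ multiplier is implemented.

## 5. Calibration

The fitting loop mirrors ecosystem-model practice: one-at-a-time
sensitivity over per-predator vulnerability multipliers and per-group
dispersal multipliers (perturbation factors ×2 and ×0.5), ranking by
induced change in the score, then iterative coordinate descent where
each parameter is tried at 20 log-spaced candidates
($v \in [1.01, 10^4]$, dispersal multiplier $\in [0.1, 10]$) and the
value minimising the **total absolute percent bias**

$$pbias_i = 100\,\frac{\sum_t (sim_{t,i} - ref_{t,i})}{\sum_t ref_{t,i}},
\qquad score = \sum_i |pbias_i|$$

is retained (ties broken toward the incumbent in log space). The loop
stops at the first pass with no improvement, so the score trajectory is
non-increasing by construction. A lognormal log-likelihood
($\sigma = 0.3$) is recorded for every candidate as a diagnostic but
never optimised — the acceptance rule is percent bias alone. Unstable
candidate runs score worst and are flagged. The calibration target is a
reference *simulated* trajectory rather than noisy observations, which
is what makes twin experiments (generate the reference at known
parameters, refit from defaults, check recovery) a meaningful test of
the machinery; the package's twin tests perturb three vulnerability and
two dispersal parameters on a 6-group, 5 × 5 model and require recovery
within one candidate-grid step. Identifiability is real: a benthic
group's dispersal, for instance, can be observationally nil, and a twin
design that perturbs it cannot be expected to recover it — the
acceptance script pre-ranks sensitivity against the model's own
unperturbed run and perturbs only identifiable parameters.

## 6. Impact metrics and screening

Annual indicators: $B_T$ (mean over months of domain-mean biomass
summed over non-juvenile living groups), $B_{har}$ (harvested groups),
$B_{loss}$ (kills summed over months and cells, spatially averaged),
$C_T$ (catch summed over fleets and months). The per-group annual
red-tide mortality rate divides the year's summed loss by the mean
annual domain biomass — in the analytic case of a uniform field with a
single month's 10% kill it is exactly 0.1. Community aggregates sum
trait or taxon classes, excluding juveniles. Ensemble screening accepts
scenarios whose focal-year loss rate falls within 2 SD of an
assessment estimate (defaults 0.77 ± 0.12) *and* whose RMSE against an
observed index is within 10% of the ensemble minimum; RMSE is computed
on mean-centred log indices because survey indices are relative and no
scaling convention is inherited from data. The before/after–inside/
outside contrast compares cell means (with standard errors) of summed
group biomass between two strata, with the reference stratum as the
denominator of the percent change.

## 7. What the generators emulate — and what they do not

* `gen_foodweb()` draws a producer–consumer ladder with biomass
  declining roughly an order of magnitude per trophic level, producer
  $P/B$ of order $10^2$ yr⁻¹ down to top-predator $P/B$ below 1 yr⁻¹,
  growth efficiencies 0.12–0.25, and exploitation $F = (0.05$–$0.2)\,PB$
  on targeted groups; draws that cannot balance (EE > 0.95) are
  rejected and redrawn, bounded. Trait tags are assigned by trophic
  level with a pelagic/demersal coin flip; the highest-trophic-level
  harvested consumer is the focal group ("grouper"). Juvenile/adult
  stanza pairs are supported only as a flag honoured by the metrics
  (the generator never emits them); stanza transfer dynamics are out of
  scope.
* `gen_drivers()` builds seasonal sinusoids plus smooth spatial
  gradients plus seeded smooth noise. The chlorophyll cycle is ±15% on
  the log scale with coastal enrichment — mild but realistic for a
  subtropical shelf, and deliberately within what the food web can
  absorb given that forced production is the system's stiffest lever.
* `gen_blooms()` superposes Gaussian patches anchored on coastal cells,
  active July–November and peaking in September–October, with log-scale
  amplitudes ($10^4$–$10^{5.3}$ cells L⁻¹ ordinary years,
  $10^{5.8}$–$10^7$ severe years) over a $10^3$ cells L⁻¹ background
  (the background is a parameter, not an asserted value). Severe years
  have more and wider patches, hence larger footprints and higher
  90th-percentile concentrations.
* `gen_surveys()` samples station observations as local biomass times
  mean-corrected lognormal error ($e^{-\sigma^2/2}$ correction), so
  survey means are unbiased for model biomass and the validation
  contrast has the right expectation.

None of this reproduces real bathymetry, hydrodynamics, satellite
radiometry or kriged bloom maps, and the default problem sizes — a
15 × 15 grid, 10 groups, 60 recorded months, the full 160-scenario
ensemble — are chosen so the whole pipeline exercises every code path
in minutes on one core. Passing tests therefore demonstrate the
*machinery* (balance, equilibrium, conservation, equivalence,
combinatorics, recovery, and the qualitative impact patterns: loss
peaking in the severe year, avoidance mitigating cumulative loss,
single-target forcing leaving non-targets near baseline), not fidelity
to any real shelf's dynamics or to magnitudes estimated from data.

## 8. Numerical conventions and degenerate inputs

* Kill proportions are clipped to $1 - 10^{-12}$ before annualization
  ($A = 1$ would be an infinite rate); $A(0)$ is defined as the limit 0.
* Capacity is floored at $10^{-4}$; vulnerability multipliers are
  clamped to ≥ 1.01 inside the calibration runner (the search domain's
  lower edge).
* Monthly dispersal fractions are capped at 0.95 of a cell's biomass.
* An all-zero reference series is an error for percent bias;
  non-positive series are errors for the log-likelihood; empty strata
  and empty run sets are errors for the comparison and screening
  functions. Zero-biomass years report a missing mortality index.
* Candidate ties in the fit are broken toward the value closest to the
  incumbent in log space, making the records deterministic.
* Every generator is a pure function of its arguments; the pipeline
  derives per-stage child seeds from the master seed (all below
  $2^{31}$).

## 9. Known limitations

Single-cell homogeneity within 10-km cells; no stanza dynamics,
mediation, nutrient cycling or hypoxia co-forcing; bloom fields are
statistical patches, not simulated blooms (forecasting blooms is
explicitly not the goal); the gravity model has no port geography by
default; and calibration is a local coordinate search — adequate for
twin recovery on identifiable parameters, not a global optimiser.
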