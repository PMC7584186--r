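---
title: "Modelling pollination and yield in a dioecious orchard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pollination and yield in a dioecious orchard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollidyn)
```

## The system being modelled

Kiwifruit is functionally dioecious: male and female flowers grow on
separate vines, female flowers offer no nectar and produce only inviable
pollen, and every fruit requires an insect — in managed orchards almost
always a honey bee — to carry viable pollen from a male flower to a
female flower. `pollidyn` couples a bloom-phenology model to a
pollinator-behaviour model so that plant-side levers (bud numbers, sex
ratio, bloom timing) and bee-side levers (density, movement preference,
handling speed) can be compared within one framework.

Two standing assumptions shape everything below:

* **Mean-field homogeneity.** Flowers and bees are well mixed across the
  orchard (the default parameterisation describes 1 ha). There is no
  spatial structure, so every open female flower receives the same
  expected share of visits.
* **Male pollen is never limiting.** A single male-flower visit fully
  reloads a bee. Foraging is restricted to a few hours a day in the
  field; this is folded into the visitation-rate parameters rather than
  modelled explicitly.

## Bloom phenology

Each sex has a fixed bud stock $B$ whose opening rate follows a Gaussian
curve with peak day $t_0$ and spread $\sigma$. With nothing open before
day 0, the cumulative openings have the closed form

$$M(t) = B\left[\Phi\!\left(\tfrac{t - t_0}{\sigma}\right) -
\Phi\!\left(\tfrac{-t_0}{\sigma}\right)\right],$$

and, because each flower stays open for a fixed sex-specific lifespan
$\tau$, the open count is $m(t) = M(t) - M(t-\tau)$. The left-truncation
at day 0 means a small Gaussian tail of buds (about 0.8% at the default
male settings) never opens; yield proportions still divide by the full
bud stock.

`flower_params()` holds the six phenology parameters per sex. Defaults
(per hectare): 600,000 buds per sex, peaks $t_m = t_f = 6$ d, spreads
$\sigma_m = 2.5$ d and $\sigma_f = 2$ d, lifespans $\tau_m = 4$ d and
$\tau_f = 5$ d. These are the base values of the orchard data the model
was calibrated against; the plausible ranges used for sensitivity
analysis are in `parameter_ranges()`.

## Pollinator movement and pollen loads

Bees are tracked in four pollen-load compartments — high, medium, low,
empty. The total per-bee visitation rate is Holling type II in the open
flower count $x = m + f$:

$$V(x) = \frac{\alpha x}{1 + \alpha\beta x},$$

with search rate $\alpha = 480\,(\text{day·flower})^{-1}$ and handling
time $\beta = 0.0011$ d, capping visits at $1/\beta \approx 909$ per
day. Both parameters are expressed per *active foraging day* of four
hours: $\alpha = 480$ is two flower encounters per minute over four
hours, and $\beta = 0.0011$ d is 16 s of that window. For the same
reason `handling_seconds_to_days()` converts at 14,400 s per day, not
86,400 — the conversion that keeps the quoted seconds and the quoted
day-values consistent.

Movement between the sexes follows a preference power law: a bee on a
male flower next visits a male flower with probability $(m/(m+f))^\delta$,
and symmetrically with exponent $\varepsilon$ on female flowers. The
exponents are calibrated by inverting this law at a 1:1 flower ratio
against observed stay probabilities (0.957 on males, 0.951 on females):
`preference_from_stay()` gives $\delta = \ln(0.957)/\ln(0.5) = 0.0634$
and $\varepsilon = 0.0725$. Exponent 1 is indifference; exponent 0 means
never switching.

Any male visit resets a bee to the high class. Each female visit steps
the bee down one class and deposits pollen — a *type-n* visit for a
class-$n$ bee, with per-visit fruit-set chances $p_1 = 0.66$,
$p_2 = 0.55$, $p_3 = 0.22$. Empty bees deposit nothing. The compartment
derivatives (`state_derivative()`) conserve the bee population exactly;
the three depositing fluxes are exposed by `deposit_visit_rates()`.

The absolute bee count comes from the density $\rho$ (default 6 bees per
1000 female buds). The per-female-bud basis follows the initial-condition
convention of the study design; `scenario(rho_basis = "per_all")` is
available for per-total-bud stocking arithmetic.

## From visits to yield

The solver state is augmented with three cumulative per-flower accrual
integrals $A_n(t) = \int_0^t r_n(s)/f(s)\,ds$, where $r_n$ is the
field-level type-$n$ visit rate. Under mean-field homogeneity, a flower
closing at time $t$ (having opened at $t - \tau_f$) has expected
exposures $v_n(t) = A_n(t) - A_n(t - \tau_f)$, and sets fruit with
probability

$$P(t) = 1 - (1-p_1)^{v_1}(1-p_2)^{v_2}(1-p_3)^{v_3}.$$

Exposures are real-valued expectations — the deterministic model has no
per-flower stochasticity — so the exponents are not integers. Daily
yield is the closing count times $P$, and total predicted yield sums
over days.

**Daily aggregation.** How the continuous exposure curve $v_n(t)$ is
collapsed into one value per closing day is a genuine free choice, and
it moves the headline yield by well under 1%. Three conventions are
implemented (`scenario(close_time = ...)`):

* `"weighted"` (default): within each day, $v_n(t)$ is averaged with the
  closing-density weight. By Fubini's theorem this makes total visits
  received by cohorts equal total visits delivered by bees exactly (up
  to quadrature), which is why it is the default;
* `"midpoint"` / `"end"`: $v_n$ evaluated at a single time in the day.
  The midpoint variant is what the fixed-step and delay-formulation
  cross-check oracles in the test suite use.

The distinction matters mainly at the bloom edges, where $f \to 0$ while
loaded bees persist and the *per-flower* accrual rate spikes; the
affected cohorts carry negligible closing mass, but single-time
evaluation there leaves a visible (~3%) hole in the visit bookkeeping
that the weighted rule closes.

## Numerical choices

* **Closed-form forcing instead of literal delays.** Because $M$ and $F$
  are closed-form, $m(t)$ and $f(t)$ enter the bee system as known
  forcing functions and the delayed-lifespan model is integrated as a
  non-autonomous ODE. This is mathematically identical to the delay
  formulation (substituting the phenology into the compartment system);
  the test suite keeps a literal method-of-steps delay integration as a
  regression oracle and the two agree to well under 0.1% in yield.
* **Solver.** Backward-differentiation (`deSolve`, method `"bdf"`),
  relative tolerance $10^{-8}$, absolute tolerance $10^{-6}$ per bee
  compartment and $10^{-8}$ per accrual integral. The system is mildly
  stiff: at bloom the compartment relaxation rates approach
  $1/\beta \approx 900\,\text{d}^{-1}$, and there is a fast loading-up
  transient at the first flower openings. (A classical fixed-step RK4
  cross-check needs steps of about $10^{-3}$ d to remain stable.)
* **Division guards.** When no flowers are open the visitation rate is
  zero and stay-probabilities are defined as 1, removing the 0/0 without
  touching the dynamics. Per-flower accrual is zeroed when fewer than
  $10^{-6}$ female flowers are open.
* **Horizon rule.** Default horizon
  $\max(t_m,t_f) + 4\max(\sigma_m,\sigma_f) + \max(\tau_m,\tau_f) + 1$
  days, after which >99.99% of the opening mass has opened and closed;
  a run whose horizon leaves flowers open fails loudly. Output grid step
  0.01 d.
* **Degenerate inputs.** Zero spreads are rejected rather than treated
  as instantaneous bloom pulses; zero bud counts and zero bee densities
  are valid and give zero yield.

## The experiment layer

Each sweep point is an independent full simulation; the forward model is
deterministic, so sweeps are reproducible bitwise. One design decision
deserves emphasis: in the female-fraction sweep
(`sweep_female_fraction()`), the *absolute* bee population is held at
the base scenario's count while the sex ratio varies (option
`bees = "base"`, the default). Re-deriving bees from $\rho$ and each
point's female bud count (`bees = "per_female"`) instead couples the
pollinator supply to the thing being varied and produces a qualitatively
different curve — fruit set collapsing at low female fractions rather
than approaching 100%. The fixed-count rule isolates the sex-ratio
effect and reproduces the study-scale behaviour (optimum near two-thirds
female); the per-female rule is used by the fraction × density surface,
whose second axis is explicitly bees per 1000 female buds.

## Sensitivity analysis

`lhs_sample()` draws a Latin hypercube (exactly one draw per
equiprobable stratum per parameter, uniform marginals — the one place
randomness enters, always behind an explicit seed) over the ranges in
`parameter_ranges()`; `run_batch()` simulates each row; `prcc()`
computes partial rank correlations with the regression-residual
construction, with a $t$-referenced significance test on
$\mathrm{prcc}\sqrt{(n-2-k)/(1-\mathrm{prcc}^2)}$ (a normal-referenced
p-value is emitted alongside). The test suite checks the implementation
against the textbook rank-correlation-matrix inversion to $10^{-10}$.

The bud parameters are sampled in the *composition* basis by default:
total buds (0.6–1.8 million) and female fraction (5–96%), matching the
quantities the analysis reports on. Sampling raw male and female counts
independently (the `"raw"` basis, available by flag) confines the female
fraction to 25–75% and cannot probe female-dominated orchards at all,
which is why composition is the default.

PRCC assumes monotone parameter–response relationships.
`monotonicity_check()` screens each parameter by binning it into
deciles, smoothing the bin-mean yields with a 3-point moving average,
and flagging the parameter nonmonotone when both the upward and the
downward movement of the smoothed means exceed 10% of their range — a
rule chosen so that a noisy monotone trend passes while a hump does
not. For flagged parameters it proposes a split at the edge of the
extremum bin, and `truncated_prcc()` reruns the whole pipeline inside a
window. The female fraction is the canonical case: strongly positive
below its optimum (around three-quarters female), negative above it.

## What the fixtures emulate — and what they do not

`scenario_fixture()` encodes the standard experiments (baseline,
sex-ratio, bloom-peak, bee-density, preference, handling-time sweeps and
the fraction × density surface) with grids that bracket the plausible
ranges: fractions 0.05–0.95 with 0.01 refinement near the optimum,
densities 1–20, male peak days 3–9, preference exponents 0–1, handling
times 5–120 s. These are synthetic study conditions, not field data.
Passing tests therefore demonstrate internal consistency and agreement
with the study-scale behaviour of this model family — not that a real
orchard will hit the predicted numbers. In particular the model omits
weather-driven phenology, spatial structure, multiple pollinator taxa,
pollen-carryover decay, and any fruit-quality outcome beyond set/not-set.

Test problem sizes are deliberately modest: the bulk property checks run
200 randomised scenarios on a coarsened grid, and the sensitivity
structure is asserted at design size $n = 200$ (larger designs sharpen
the PRCC estimates but do not change the sign/significance structure
asserted).

## Known limitations

* The per-flower accrual spike at the bloom tail is a mean-field
  artifact (thousands of bees, a handful of flowers); it is guarded and
  carries negligible yield mass, but per-cohort exposures for the very
  last closing days should not be over-interpreted.
* The 1:1 calibration of the preference exponents extrapolates by a
  power law to all flower ratios; there is no empirical constraint far
  from 1:1.
* $\rho$ scales bees with female buds; comparisons across scenarios with
  different bud stocks implicitly change the absolute bee population
  unless the fixed-count sweep rule is used.
* Visitation saturates in total flowers only; there is no interference
  between bees and no resource depletion within a day.
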