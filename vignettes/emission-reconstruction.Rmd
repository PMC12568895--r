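---
title: "Reconstructing historical MSWI dioxin emissions: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing historical MSWI dioxin emissions: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dioxinrecon)
```

This vignette documents the science implemented by `dioxinrecon`, its
assumptions, and the choices made where the design was genuinely open. It
states no empirical result beyond what the package's tests and acceptance
script themselves compute.

## The reconstruction problem

Municipal solid waste incinerators (MSWIs) that operated from the 1950s
through the 1990s rarely had PCDD/F stack monitoring, yet their cumulative
emissions dominate the dioxin burden of many urban soils. A reconstruction
therefore combines (i) archive-derived inputs — annual waste throughput,
waste composition, device history, operating temperatures — with (ii)
empirical congener-profile data from closely similar reference plants and
(iii) a kinetic model of furnace-side formation. `dioxinrecon` implements
the computational side of this workflow; the archival side enters as data.

All vectors use one canonical congener order (`congener_registry()`):
the 7 toxic dioxins followed by the 10 toxic furans, each by increasing
chlorination. A single unambiguous indexing avoids an entire class of
join errors between profiles, TEFs, half-lives and kinetic constants.

## Profile propagation

A *phase-resolved profile* is a 34-entry relative mass-fraction vector
(17 congeners x gas/particle). A device with per-entry concentration-based
removal efficiencies `eta` transforms it as

$$R^{out}_{i,j} = \frac{R^{in}_{i,j}\,(1-\eta_{i,j})}
{\sum_k (1-\eta_k)\,R^{in}_k},$$

the sum running over all 34 entries for phase-resolved input (17 for
collapsed profiles). Working through the mass bookkeeping: assign any inlet
concentration, scale each entry by its survival factor `1 - eta`, and
renormalize — the denominator is then exactly the device's total
concentration pass-through ratio, and equals `1 - eta_aggregate`. The
package exposes that denominator on every propagation
(`attr(_, "pass_through")`) because the emission-quantity track consumes it
directly. Negative efficiencies are deliberately unbounded below: an
electrostatic precipitator (ESP) sitting in the 200–400 °C de novo
synthesis window is a net *source*, and the bundled worked example
(`esp_example()`) shows an aggregate efficiency near −161%. `eta = 1`
(complete removal) zeroes an entry; `eta > 1` is rejected as unphysical
under nonnegative concentrations.

Efficiencies are stored as dimensionless fractions everywhere; percent
appears only at CSV boundaries (declared by a `units` column or argument).
This removes double-scaling bugs at the cost of one explicit conversion.

### Temperature repartitioning

Reference-plant profiles are often measured at a different device inlet
temperature than the target plant's. Since gas/particle partitioning of
these semivolatiles tracks vapor pressure, `repartition_by_temperature()`
moves mass between the two phases of each congener — never between
congeners — assuming the gas:particle odds scale with a per-congener
log-linear (Clausius–Clapeyron) vapor pressure,
$\log_{10} p_i = a_i - b_i/T$. Only the slopes $b_i$ matter for a
temperature *ratio* correction; defaults derive from typical PCDD/F
vaporization enthalpies (90–110 kJ/mol, increasing with chlorination,
`default_vp_slopes()`). The operator is a clearly-flagged stand-in for
plant-specific adjustment procedures: the contract (per-congener totals
preserved; gaseous share nondecreasing in temperature; identity at equal
temperatures) is stable, and the slope vector is user-replaceable.

## Furnace kinetics

Formation and decomposition are first order with congener-specific
formation constants:

$$[\mathrm{PCDD/F}]_i = \frac{k_{1,i} E_{Cl} E_{metal}}{k_2}
\left(1 - e^{-k_2 \lambda_{oxygen} t}\right).$$

The expression is implemented exactly as written — the oxygen ratio
$\lambda$ appears only in the exponential, not in the prefactor. It is the
unique solution of $dP/dt = \lambda (k_1 E_{Cl} E_{metal} - k_2 P)$,
$P(0)=0$, and the test suite verifies the closed form against a numerical
integration of that ODE to $10^{-8}$ relative over a 100-point grid,
plus the $t \to 0$ and $t \to \infty$ limits and monotonicity/concavity in
every driver.

Three congeners have published calibrations (2,3,7,8-TeCDF, OCDF,
1,2,3,6,7,8-HxCDD). The reconstruction selects whichever of these has the
largest share of the pre-treatment profile (`select_reference_congener()`,
ties to the earlier canonical index) — a large share minimizes
profile-estimation leverage on the scale-up `total = amount / share`.
With the bundled pre-ESP profile that is OCDF at 20.7%.

Constants ship in an editable CSV rather than code, because they originate
from external fits that users may legitimately replace; the bundled file is
a synthetic order-of-magnitude placeholder (named accordingly) chosen so
that a 10^5 t/yr plant produces tens of grams of PCDD/Fs per year in the
furnace — the right scale for a mid-century urban MSWI, but not a fitted
value. Influence-factor mappings from raw waste fractions to
$E_{Cl}, E_{metal}, \lambda$ are likewise configuration
(`influence_config()`): identity (the equation's literal reading, the
default), linear normalized to reference conditions, or tabulated lookup.

## Emission timelines

`build_timeline()` turns period-level archive values into annual series;
piecewise-constant (step) interpolation is the default because archival
estimates are themselves period averages, with midpoint-linear as an
option. The quantity track applies *scalar* per-stage aggregate
efficiencies per scenario period (`apcd_scenario()`), while profile shape
uses the full 34-entry propagation — a deliberate two-track treatment:
aggregate scalars are what the archive record constrains for quantity,
whereas profile shape needs congener resolution. Stack/furnace ratios obey
`prod(1 - eta)` exactly, so scenario arithmetic is auditable by hand.
Year granularity is the modelling floor; start-up/shutdown transients are
out of scope. The default scenario set — ESP alone 1958–1982, ESP plus wet
scrubber (WS) 1982–2005, with WS efficiency 0 or 40% — encodes the bounds
of a reasonable WS band, not a validated estimate; real plants may have
seen higher or even negative WS efficiencies, and the band is plain
configuration.

## Soil fate

All emitted mass is assumed to deposit within the study area
(`deposition_fraction = 1`), a deliberate overestimate appropriate for
bounding comparisons with soil surveys; a per-congener sorption/retention
factor (default 1) supports sorption-adjusted variants. Decay is first
order in elapsed years with congener-specific half-lives; residuals
compose as a semigroup (decaying 9 then 6 years equals 15 years), which the
tests assert to 10^-12. Half-lives transfer poorly between soils, so
`residual_profile_uncertainty()` perturbs them per congener by independent
multiplicative factors drawn uniformly on a −50%/+100% band — uniform
because only the support, not a distribution, is defensible from field
data; the draw is pluggable by editing the band. Default 10^5 Monte-Carlo
draws keeps bands stable at the percent level while running in seconds;
10^6 is available by argument for survey-grade figures.

## Sensitivity analysis

Inputs are sampled by Latin hypercube from truncated normals (default
truncation mean ± 2 sd, clipped to physical bounds). Stratum placement
defaults to the probability midpoint of each stratum — a fully reproducible
design — with uniform-within-stratum sampling (via `lhs::randomLHS`) as an
option. Attribution uses normalized squared Spearman rank correlations
$k_i = \rho_i^2 / \sum \rho^2$ with average ranks on ties (the standard
Spearman convention). Rank-basedness buys invariance to monotone output
transforms and affine input rescalings, both property-tested. The factors
are relative influences within the declared parameter space; they are not
variance decompositions in the Sobol sense, and correlated inputs are out
of scope.

## What the synthetic generator does and does not emulate

`synthetic_waste_timeline()` produces a plant-like 1958–2005 history:
throughput rising steeply to ~1970, declining to 1990, recovering to
closure; chlorine content stepping 0.3 → 0.7 wt% with the plastics share
(the bundled period table); metal content declining then recovering. It
reproduces the *shape and scale* of a mid-century urban incinerator's
record — enough to exercise every pipeline stage, and to recover a planted
importance ordering (chlorine > temperature > waste flow) in the
sensitivity tests when the surrogate model's coefficients are set that
way. It does not emulate measurement error structure in
archives, sub-annual operations, or correlated year-to-year shocks; tests
passing on it demonstrate correct model arithmetic, not calibration to any
real plant.

## Numerical choices and degenerate inputs

- Profile normalization tolerance 10^-9 internally; CSV readers accept 1%
  slack (rounded published tables) and renormalize.
- `-expm1(-x)` instead of `1 - exp(-x)` for the kinetic saturation term,
  exact at small exposure.
- Propagation refuses a nonpositive denominator (total annihilation or
  inconsistent inputs) rather than returning NaN; inlet concentration must
  be strictly positive for an efficiency to exist.
- Aggregate efficiencies over an empty or massless subset error out.
- Seeds: every stochastic function takes an explicit integer seed; the CLI
  threads a single `--seed` through all of them.

## Problem sizes in the shipped tests

The test suite runs at deliberately small scale — LHS moment checks at
n = 50,000, attribution symmetry at n = 10,000, soil quantile bands against
a 200 x 200 quadrature grid at n = 20,000 draws — sizes at which the
Monte-Carlo error bounds asserted are comfortably valid while the whole
suite completes in seconds. These are the package's documented reference
checks; users reproducing survey-grade band estimates should raise
`n_samples` to 10^6.

## Known limitations

Device efficiencies beyond temperature-driven repartitioning (residence
time, dust load, ESP field strength) are not modelled; atmospheric
dispersion is out of scope (deposition is local by assumption); PCBs are
excluded; the bundled WHO-2022 TEF column, kinetic constants and half-life
file are editable data whose bundled values are defaults, not site
calibrations.
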