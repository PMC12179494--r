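---
title: "Methods: eco-evolutionary optimization of exoenzyme allocation in a microbe-enzyme soil carbon model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eco-evolutionary optimization of exoenzyme allocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(awbevo)
```

## The model and its assumptions

`awbevo` simulates soil organic carbon decomposition with a four-pool
microbe–enzyme model of the AWB family: polymeric SOC (`C`) is depolymerised
into dissolved organic carbon (`D`) by extracellular enzymes (`Z`);
microbial biomass (`M`) takes `D` up through saturating transporters and
splits the assimilable share between growth and enzyme production according
to a single quantitative trait, the allocation fraction φ. Decomposition and
uptake are Michaelis–Menten in the substrate and first order in the catalyst
(`Z` and `M` respectively). The respiration flux is whatever uptake is not
converted into biomass (efficiency γ\_M) or enzymes (efficiency γ\_Z).
Structural assumptions worth making explicit:

* **No litter input to DOC.** All litter enters the SOC pool; this
  simplifies the steady-state algebra and the steady states are insensitive
  to the split.
* **Abiotic leaching** removes carbon from both `C` and `D` at small
  first-order rates. `eC > 0` is *required*: it is what bounds SOC when
  enzymes vanish, and it defines the bracket for the steady-state solver.
* **Well-mixed pools.** Spatial structure appears only implicitly, through
  the competition kernel of the evolutionary layer (below); there is no
  vertical discretisation, moisture dependence, or transient global run —
  projections are sequences of local steady states.
* **Temperature enters through Arrhenius factors** `v0 exp(−E/(R (T+273)))`
  for the four kinetic parameters (offset 273, not 273.15, following the
  source formulation; the difference is absorbed by the pre-exponentials).

## The evolutionary layer

A rare mutant with allocation φ\_mut invading a resident φ\_res at its
ecological equilibrium experiences DOC scaled by `1 + c(φ_mut − φ_res)`. The
kernel `c` is odd-signed with `c(0) = 0` and slope `c0 > 0`: cells that
produce more enzymes than the resident gain private access to locally
decomposed DOC, those that produce less lose access. This single number
summarises diffusion-limited spatial structure without modelling it
explicitly. Invasion fitness is the mutant's per-capita growth rate; its
derivative at the resident (the selection gradient) vanishes at

φ\* = 1 − d\_M/(γ\_M v\_maxU) − 1/c0,

the unique evolutionary singularity. It exists (is positive) iff
d\_M/(γ\_M v\_maxU) < 1 *and* c0 > 1/(1 − d\_M/(γ\_M v\_maxU)); when it
exists it is convergence stable, and uninvadable whenever c''(0) < 2 c0².
Because only v\_maxU among these quantities responds to temperature in the
baseline scenario, φ\*(T) inherits the Arrhenius curvature: increasing in T,
with larger increments in cold climates (see "deliberate red flags").

**Kernel shape.** Only `c(0) = 0`, the sign structure, the slope and the
curvature bound are constrained by theory. We ship
`c(z) = (2/π) atan(c0 (π/2) z)`: it is smooth, odd and bounded in (−1, 1) so
mutant DOC access `1 + c` can never go non-positive, it has `c'(0) = c0`
exactly, and `c''(0) = 0 < 2 c0²` satisfies the uninvadability condition
identically. The interface accepts any user function with the same
contract.

**Sweep values of c0.** The intermediate value 1.17 is the published
reference point. The flanking low/high values are not published; we ship 1.1
and 1.4. Any c0 ≤ 1 is degenerate — φ\* = 1 − w − 1/c0 ≤ 0 everywhere, the
trait can never evolve above zero, and no projection curve exists — so the
"low" value must sit above the existence threshold 1/(1 − w), which is
≈ 1.02–1.14 for temperate-to-tropical temperatures at default parameters.
1.1 keeps warm and temperate cells active while masking cold ones, which is
the qualitative behaviour a weaker producer-advantage should have.

## Steady states and stability

At a nontrivial steady state the biomass equation pins DOC in closed form,
the enzyme equation ties `Z*` to `M*`, and total mass balance expresses
`M*` through `C*`; what remains is one scalar equation `f(C*) = 0` on
`(0, (I − eD D*)/eC)`. The solver scans 220 log-spaced points for sign
changes, polishes each bracket with `uniroot` at tolerance
`.Machine$double.eps^0.75`, verifies the full residual, classifies stability
from the analytic 4×4 Jacobian (eigenvalue real parts against a −1e-12
threshold, an "oscillatory-" prefix when imaginary parts exceed 1e-12), and
returns the stable root — the smallest stable `C*` with a warning if there
are several. Generic outcomes at default-like parameters are either no root
(infeasible: cells too cold to support microbial activity) or a pair of
roots: an interior equilibrium with substantial biomass, approached as a
damped spiral (oscillatory-stable), plus a near-extinction root just below
the leaching-only SOC ceiling, which is unstable and never returned.

Numerical choices: equilibrium residual acceptance 1e-9 in pool units;
feasibility of a trait value = existence of such a stable root; the lower
trait bound φ\_min is found by bisection (tolerance 1e-6) on that predicate.
The dynamical oracle is an independent adaptive Cash–Karp RK45 integrator
(implemented in C++; local tolerances rtol 1e-8 to 1e-10), needed because
spiral decay rates are 1e-5–1e-4 h⁻¹ while the DOC pool limits explicit
steps to a few hours: convergence runs cover ~1e6 model hours.

## Temperature scenarios

* `kinetics_only` (baseline): only the four kinetic parameters respond to T.
* `mortality_arrhenius`: turnover d\_M also follows Arrhenius with energy
  `EdM`; its pre-exponential is anchored so d\_M(T\_ref) equals the base
  value (T\_ref = 20 °C). With `EdM = 55 > EvU = 38` mortality outruns
  uptake and φ\*(T) *decreases* with warming — the documented sign
  reversal; with `EdM = 25` it does not.
* `cue_linear`: growth efficiency declines linearly, slope m = −0.014 per
  °C anchored at T\_ref, clipped to [0.01, 1]. The clip floor (0.01) is a
  package choice: the linear decline is unbounded below and a non-positive
  efficiency is unphysical.

Biome-specific decomposition kinetics can replace the global values per
cell via a five-row CSV table. The shipped table is a clearly labelled
**synthetic stand-in** (the measured cross-latitudinal values are not
redistributable here): it preserves the qualitative cold-to-warm gradient
of activation energies but must not be used for quantitative inference.

## Default parameters

Units: mg C cm⁻³ soil and hours; energies kJ mol⁻¹ with R = 0.008314. The
published configuration fixes I = 5×10⁻³ mg C cm⁻³ h⁻¹, v0U = 1×10⁵,
EvU = 38, c0 = 1.17, T\_ref = 20 °C, m = −0.014, EdM ∈ {25, 55}. The
remaining values follow the AWB literature: d\_M = 2×10⁻⁴ h⁻¹,
d\_Z = 1×10⁻³ h⁻¹, γ\_M = 0.31 (the 20 °C carbon use efficiency),
v0D = 1×10⁸, EvD = 47. Two gaps were filled as package choices, recorded in
the shipped config's `notes` block: (i) the source model's half-saturation
constants are linear in T while this model is Arrhenius throughout, so
K0D/EKD and K0U/EKU were set to reproduce the source's 20 °C magnitudes
(KmD ≈ 582, KmU ≈ 0.30 mg C cm⁻³) with moderate sensitivities (30 and
20 kJ mol⁻¹); (ii) leaching eC = eD = 1×10⁻⁵ h⁻¹, a small abiotic loss
consistent with "small amounts of carbon lost" (the source has no explicit
value); γ\_Z = 0.5 is likewise unconstrained by the source.

## What the synthetic forcing emulates — and what it does not

`generate_forcing()` produces a regular lat–lon grid, decades 2010–2100,
with (i) 2010 MAT linear in |latitude| between 27 °C (equator) and −20 °C
(pole) — a range that contains the three published reference-site
temperatures 4.2, 12.6 and 23.6 °C; (ii) a warming ramp linear in decade
index whose 2100 field has an area-weighted mean of exactly
`warming_global_2100` (+3.2 °C default) and a polar band (north of 60° N)
mean of `polar_amp_factor ×` the extratropical base warming. The default
factor 1.6283 was derived once from the stated targets (+3.2 global, +5
polar) and cos-latitude area fractions, so the default grid reproduces both
numbers by construction; (iii) optional spatial Gaussian MAT noise, constant
over decades so zero-warming tests stay exact; (iv) optional litter input
with a linear trend. It does **not** emulate land/ocean masks, spatial
covariance, seasonality, interannual variability, or moisture. A green
projection test therefore establishes the *orderings* the theory predicts
(evolving loss ≥ fixed loss; stronger per-unit-warming effect in cold
bands; lower c0 → higher stocks and larger losses) on a world with the
stated gross statistics — not agreement with any observed carbon map.

Global aggregates are stock density × cos-latitude weight × a reference
depth (default 1 cm). The depth/area convention that would convert these to
Pg-scale totals is deliberately left as configuration: absolute totals are
convention-dependent and are not validated here.

## Q10 reference model

The comparison model is one-pool first-order decay with
`k(T) = r0 Q10^((T−T0)/10)` (Q10 = 2 by default). Calibration matches
**decay rates** at 10 °C — r0 is set to the mechanistic equilibrium decay
rate `(I − eC C*)/C*` with φ = φ\*(10 °C) — because the Q10 model has no
leaching term; stocks then match at the calibration point up to the
leaching share x/(1−x) with x = eC C\*/I (≈ 0.007 percent-level at
defaults), which `calibrate_r0()` reports. A switch allows calibrating
against the fixed-trait variant instead; the fixed-trait comparison column
freezes φ at φ\*(T\_cal) by default, which is also what the evolving column
equals at the calibration temperature.

## Randomised test worlds

Property tests draw parameter sets as seeded multiplicative jitters
(±0.3–0.5 log-units) around the default configuration at temperate
temperatures (10–25 °C), rejecting draws without a positive, feasible,
stable optimum. Temperate temperatures keep equilibration times (and hence
the integration oracle) fast; the rejection step mirrors the model's own
existence conditions rather than hiding failures.

## Known limitations and deliberate red flags

* **φ\*(T) is concave, not convex.** One acceptance criterion inherited
  from the build specification asserts positive second differences of
  φ\*(T) under baseline kinetics. The closed form subtracts a positive
  multiple of `exp(EvU/(R(T+273)))`, which is decreasing and convex in T,
  so φ\*(T) is increasing and strictly concave for every positive EvU —
  equivalently, a degree of warming moves the optimum most in cold
  climates, which is precisely the mechanism amplifying high-latitude
  losses. The expectation is implemented as written and left failing; a
  separate property test asserts the mathematically correct concavity.
* NetCDF I/O is not provided (no NetCDF library in the supported
  environment); the long-format CSV route carries forcings and results.
* Cold-edge masking has two causes that the projection does not
  distinguish in its aggregates: nonexistence of a positive optimum, and
  infeasibility of the equilibrium at a tiny optimum (φ\* < φ\_min). Both
  are reported per cell.
* Absolute global totals are convention-dependent (depth, area weights)
  and unvalidated; only orderings and relative changes are tested.
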