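---
title: "Methods: rate estimation, ATP-maximizing FBA and energetics for CHO fed-batch cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rate estimation, ATP-maximizing FBA and energetics for CHO fed-batch cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chofba)
```

## Scope

`chofba` implements the computational path from raw fed-batch
timecourses of a CHO antibody production process to cellular
energetics: shape-constrained smoothing and cell-specific rate
estimation, ATP-maximizing flux balance analysis (FBA) on a reduced
central-carbon network, Monte Carlo sampling of the constrained flux
polytope for flux errors, and ATP accounting (production ledger,
yield per c-mol, adenylate energy charge). A synthetic fed-batch
generator with known ground truth supplies data for three process
phenotypes, so every stage can be validated end to end without
external measurements.

## The core metabolic network

The model spans glycolysis at near-reaction resolution (hexokinase
through pyruvate kinase, with aldolase/triose-phosphate isomerase and
GAPDH/phosphoglycerate kinase lumped), a two-step lumped pentose
phosphate pathway, lactate dehydrogenase as the single internal
lactate reaction, the full TCA cycle with a GTP-yielding succinyl-CoA
synthetase and a FADH2-yielding succinate dehydrogenase, anaplerosis
and cataplerosis (pyruvate carboxylase, malic enzyme, PEP
carboxykinase), glutaminolysis, and one lumped catabolic entry per
proteinogenic amino acid into its standard entry point. A single
intracellular compartment is used; since mitochondrial shuttles are
not resolved, NADH and FADH2 are pooled before two oxidative
phosphorylation reactions with P/O ratios of 2.5 (NADH) and 1.5
(FADH2) by default. An ATP hydrolysis drain closes the energy
balance and serves as the FBA objective.

Two pseudo-reactions connect the network to the culture: a biomass
reaction whose flux is the growth rate in 1/day (precursor
coefficients are mmol/g dry weight times a configurable cell dry
weight, default 250 pg/cell), and an antibody-synthesis reaction
consuming amino acids according to a generic IgG1 residue table plus
4 ATP per peptide bond, with flux in fmol antibody/cell/day
(150 kDa molar mass by default, so 1 pg/cell/day = 1/150
fmol/cell/day). The biomass composition is a configurable,
literature-typical CHO table; neither table claims cell-line
accuracy, and both are exported/imported with the SBML document.

Carbon bookkeeping is explicit: every metabolite carries a carbon
count, and model validation asserts a zero carbon residual for every
internal reaction. Exchange, biomass and antibody pseudo-reactions
are exempt (they cross the system boundary). Acetyl-CoA counts only
its acetyl carbons, so the CoA moiety does not need balancing.

Two design points deserve emphasis:

* **PEP carboxykinase is required.** With malic enzyme as the only
  cataplerotic exit, every mole of four- or five-carbon amino-acid
  carbon entering the TCA must leave via malic enzyme — but malic
  enzyme produces NADPH, whose only sink is biosynthesis. Realistic
  measured-rate constraint sets then make the feasible set empty.
  PEPCK decouples cataplerosis from the NADPH balance and is standard
  in CHO central-carbon models.
* **The ATP-maximization objective is the drain flux.** "Maximizing
  ATP-yielding reactions" is implemented as maximal flux through the
  single ATP hydrolysis drain, i.e. maximal net ATP production at
  steady state. Maximizing the sum of producing fluxes instead would
  reward futile cycles.

## Rate estimation from fed-batch balances

Measured concentrations are smoothed with piecewise cubic
polynomials, at most four segments, joined with a continuous first
derivative; fitted concentrations are constrained non-negative. The
basis is a truncated-power basis on scaled time with equally spaced
interior knots, so the fit is linear least squares; when the
unconstrained fit dips below zero it is re-solved as a quadratic
program with non-negativity imposed on a dense grid (401 points).

Three estimator refinements matter in practice:

* **Viable cell density is fitted on the log scale.** The density
  spans 0.7 to 15 million cells/mL; absolute least squares would
  ignore the relative error of the small early values and destabilize
  every per-cell rate in the early growth phase.
* **Heteroscedastic weighting.** With replicate cultivations, the
  per-time-point standard deviation across replicates (unbiased for
  small samples via the c4 factor) weights the fit. Under
  multiplicative measurement noise the early, near-zero titer values
  are almost exact and anchor the early derivative.
* **Segment-count selection.** The default rule picks the smallest
  segment count whose residual RMS is within 10% of the maximal
  (4-segment) fit. When the noise level is known — from replicate
  scatter — a discrepancy-principle rule takes precedence: the
  smallest count whose weighted residual RMS reaches ~1.2 times the
  noise level. Without it, the 4-segment fit spends its flexibility
  on measurement noise and the derivative (hence every rate) inherits
  spurious wiggles.

Cell-specific rates come from the standard per-volume fed-batch
balance with dilution rate `D = F/V`:

$$q(t) = \frac{dC/dt + D(t)\,(C(t) - C_\mathrm{feed})}{X(t)},
\qquad \mu(t) = \frac{dX/dt}{X(t)} + D(t),$$

production positive, uptake negative; metabolite rates in
fmol/cell/day, antibody in pg/cell/day, growth in 1/day. Sampling
drains are treated as concentration-neutral (the feed program is
assumed reduced to compensate the drawn volume). Analytes that
receive boluses (glucose) are not smoothed directly: the recorded
step increments are subtracted first and the continuous cumulative
consumption signal is fitted (without the non-negativity constraint,
which does not apply to the transformed signal). `detect_boluses()`
flags unrecorded refills as upward jumps between consecutive samples;
detecting every refill requires sampling finer than the refill
spacing, so recorded events are preferred when available.

Replicate rate tables combine as mean ± sample standard deviation;
this SD is the "rate error" that becomes the FBA bounds. The default
analysis time points are 33, 82, 154 and 238 h (early growth, middle
growth, early stationary, early decline); FBA is run at the last
three only, because per-cell rates at the first point divide by very
small cell densities and are dominated by their noise.

## FBA under measured-rate constraints

For each measured rate `r` with error `e` the matching exchange (or
biomass/antibody pseudo-flux) is bounded to `[r − e, r + e]`; other
reactions keep defaults. Measured intervals are truncated to the
reaction's structural range, so a negative net growth rate in the
decline phase clamps the irreversible biomass flux to zero rather
than making the problem infeasible. The LP maximizes the ATP drain
subject to `S v = 0` and the bounds.

The pipeline floors the rate error at 2% of the rate (plus small
absolute floors: 0.005 1/day for growth, 0.05 pg/cell/day for the
antibody, 2 fmol/cell/day for metabolites). Replicate scatter with
two or three replicates underestimates the true uncertainty —
identical replicates would even give zero-width bounds — while the
smoothing approximation alone contributes errors of this order; the
floor keeps the measured-rate polytope from collapsing to an
inconsistent point.

Infeasibility is diagnosed, not hidden: an elastic-relaxation LP
reports the minimal widening of each measured bound that restores
feasibility. Interactive use (`solve_max_atp()`) raises an error
carrying that diagnosis. The pipeline applies the minimal relaxation
(times 1.5), emits a warning naming the bounds and amounts, and
records them in the phase report — under multiplicative noise a
small-rate analyte occasionally lands on a bound the network cannot
realize (e.g. apparent net secretion of an amino acid without an
internal source), and aborting the whole run for a few
fmol/cell/day would be less informative than reporting the conflict.

The LP itself is solved by a bounded-variable revised simplex
implemented in the package (column-equilibrated, two-phase, with
bound flips in the ratio test). Flux problems here mix zero-width
measured bounds with wide defaults and coefficients spanning four
orders of magnitude; the simplex was validated against hand
stoichiometric oracles (32 ATP per glucose fully oxidized, 2 per
glucose fermented to lactate) and on randomized instances during
development.

## Sampling the flux polytope

Flux errors are Monte Carlo estimates over the polytope
`{v : S v = 0, lb ≤ v ≤ ub}` (sampled, by default, without an
optimality cut). The sampler parameterizes the polytope in the null
space of `S`, with bound-fixed and polytope-constant coordinates
pinned first: a sum-of-capped-margins LP identifies coordinates that
are constant on the feasible set (for example, the oxidative PPP
flux when the biomass flux is fixed at zero pins the NADPH
balance), and the walk then operates on the genuinely free face.
Coordinates are rescaled by their bound widths (default bounds
capped at the largest measured width) because growth in 1/day and a
fraction-of-a-fmol antibody flux next to exchanges of thousands of
fmol/cell/day make the polytope a thin slab that would cripple
mixing.

The walk is artificial-centering hit-and-run: a pure random-direction
warm-up walk builds a fixed pool of points; sampling chains start
from pool points and alternate directions drawn through the pool
(relative to the pool center) with isotropic random directions. The
pool is frozen after warm-up so the direction distribution is
independent of the chain state, which keeps the uniform distribution
exactly stationary; the random-direction share guarantees
irreducibility. Chord endpoints are exact (closed-form line search
against the box).

Defaults are a scaled-down test configuration: 2,500 points from 25
chains, 1,000 warm-up steps per chain, thinning 10. At this scale
the sampler's means and spreads on the full network are approximate
(validated against a long plain hit-and-run run during development:
means within about one marginal SD, SDs of the right magnitude);
its exactness is asserted against a rejection-sampling oracle on
low-dimensional polytopes, where both agree within Monte Carlo
error. The study-scale configuration (2.5 million points from 2,500
chains) is expressible through the same arguments and mixes
correspondingly better; it is not exercised by the test suite.

## Energetics

The ATP ledger splits gross ATP production of a flux solution into
oxidative phosphorylation of NADH (P/O times the NADH-oxphos flux),
oxidative phosphorylation of FADH2, net glycolytic substrate-level
phosphorylation (phosphoglycerate kinase + pyruvate kinase −
hexokinase − phosphofructokinase), and succinyl-CoA synthetase. The
glycolytic share counts glycolysis-tagged reactions only; ATP
re-entering via the PPP is not attributed to glycolysis.
Contributions sum to the total by construction.

`Y_ATP,C` divides total ATP production by the summed carbon uptake
of net-consumed substrates only — glucose, amino acids with negative
rates, and lactate when (and only when) it is consumed. The
adenylate energy charge is Atkinson's `(ATP + ADP/2)/(AMP + ADP +
ATP)`, computed from the measured per-phase pools, not from fluxes.

## The synthetic generator

Each preset defines smooth ground-truth trajectories (natural cubic
splines through anchor points) for cell density, specific
productivity, glucose, lactate, glutamine and alanine rates; the
other amino-acid uptakes are 1.4 times the biosynthetic demand of
growth plus antibody synthesis, so uptake always covers demand with
a surplus that is catabolized. Concentrations are integrated from
exactly the balances the estimator assumes (deSolve, with the
glucose bolus rule: below 2 g/L refill to 4 g/L, detected by root
finding), so noise-free round-trip recovery is limited only by the
spline approximation. Process parameters follow the emulated study
design: 1.0 L start volume, 0.7e6 cells/mL inoculum, continuous feed
from 24 h, ~264 h duration, sampling twice daily, intracellular AMP/
ADP/ATP (and pyruvate) pools at 33/82/154/238 h. Measurement noise
is multiplicative lognormal, mean-preserving, with a CV of 3% for
cell density and titer and 5% for metabolite concentrations by
default. pH, pCO2 and osmolality are emitted as descriptive channels
only; they feed no computation.

The three presets emulate the study phenotypes. REF peaks at 15e6
cells/mL with productivity reaching 18 pg/cell/day near 120 h and
steady lactate accumulation. COP starts at 23 pg/cell/day under
early CO2 stress and declines, with elevated lactate and a low peak
density of 9e6 cells/mL, and declining ATP pools. NOB switches from
lactate production to consumption between 144 and 240 h, holds
lactate near 25 mmol/L, rises to 20 pg/cell/day near 240 h, reaches
the highest titer, and keeps stable ATP pools with a final adenylate
energy charge of 0.90 (against 0.80 and 0.76 for the CO2-stressed
and reference processes).

The metabolic scale of the presets is a deliberate compromise. The
emulated study's printed numbers are mutually inconsistent under P/O
2.5/1.5: a growth-phase lactate flux of ~500 fmol/cell/day cannot
coexist with a 65% oxidative share of ATP production and a q_ATP of
~25,000 fmol/cell/day (stoichiometric bookkeeping forces glucose
uptake near 400 fmol/cell/day and q_ATP near 3,000 under those
fractions). The presets use field-realistic CHO rates — middle
growth phase glucose uptake 1,800 and lactate production 3,100
fmol/cell/day (lactate yield ~1.7), glutamine uptake 120 — chosen so
that the ATP decomposition lands near the reported 65% oxidative /
25% glycolytic split; the resulting q_ATP (~12-17 pmol/cell/day)
and Y_ATP,C (~1) are consequently below the study's printed scale.
The fixed LDH/ALT flux checks are separate desk problems that use
the printed values (1,200, 500, 200 fmol/cell/day) directly as
constraints, where node conservation makes the internal flux equal
the fixed exchange regardless of the rest of the solution.

## What passing tests do and do not show

The generator shares its balance equations with the estimator; round
trips therefore validate the implementation, not the model of real
measurement processes. Real cultures add sampling artifacts,
analyte-specific biases, viability/lysis effects, and measurement
error that is neither lognormal nor independent; none of these are
emulated. FBA results inherit every limitation of the reduced
network (lumped amino-acid catabolism, pooled redox cofactors, no
compartments, no maintenance partitioning) and of the max-ATP
objective, which under wide noisy bounds systematically prefers the
energy-richest corner of the polytope.

## Problem sizes and numerical choices

The shipped network has 74 metabolites and 96 reactions. Test-scale
runs use 2,500 sample points over 25 chains per phase and the
12-h/3%-noise/triplicate generator configuration; a full three-phase
pipeline run takes well under a minute on one core. Feasibility
tolerances: 1e-6 (relative) on steady state, 1e-9 for the simplex;
profile non-negativity is enforced on a 401-point grid; the bolus
threshold default is 1 g/L. Ties in segment selection resolve toward
fewer segments. Degenerate inputs (fewer than five points,
non-monotone times, all-zero adenylate pools, zero consumed carbon)
raise errors rather than returning silently wrong values.
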