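---
title: "Modelling switches, pulses and oscillations in the Ring1B/Bmi1 ubiquitination system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling switches, pulses and oscillations in the Ring1B/Bmi1 ubiquitination system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prc1dyn)
```

## The biological system and the model

Ring1B is the catalytic E3 ligase of Polycomb repressive complex 1
(PRC1): in a self-ubiquitinated, Bmi1-associated state it
monoubiquitinates histone H2A, a repressive chromatin mark. The same
lysines of Ring1B can instead receive canonical K48-linked chains from
the external ligase E6-AP, which target Ring1B for proteasomal
degradation, and Bmi1 is analogously ubiquitinated by its own external
ligase (SPOP/Cul-3). Deubiquitinases, chiefly USP7, reverse all of these
modifications. Because a self-ubiquitinated Ring1B molecule can
ubiquitinate other Ring1B molecules (intermolecular autocatalysis), and
because the three ubiquitination routes compete for the same residues,
the network contains positive feedback, competition, and opposing
enzyme cycles -- the classic ingredients of switch-like dynamics.

`prc1dyn` implements this network as a 13-reaction kinetic scheme over
ten species: free Bmi1 (`B`) and its degradation-targeted form (`Bd`),
free Ring1B (`R`) and its degradation-targeted form (`Rd`), the
Bmi1-Ring1B complex (`Z`), the self-ubiquitinated complex (`Zub`, the
strongest H2A ligase), the active free self-ubiquitinated form (`Ra`,
produced when `Zub` dissociates), the weakly active free
self-ubiquitinated form (`Ru`), and histone H2A (`H`) with its
monoubiquitinated form (`Hu`). Two formulations are provided:

* the **Michaelis-Menten (MM) reduction** (default), in which
  deubiquitination of `Zub` (reaction 7) is a saturable lumped reaction
  `k7 * USP7_tot * Zub / (KM7 + Zub)` and the remaining DUB reactions
  are apparent first order with maximal rates proportional to total
  USP7; and
* the **mass-action (MA) formulation**, in which USP7 and its complex
  with `Zub` are explicit species and reactions 4, 10 and 11 are second
  order in free USP7.

On the short timescale (under an hour) protein synthesis and
degradation are neglected, so total Ring1B, total Bmi1 and total H2A
are conserved; the long-timescale variant adds zero-order synthesis of
the free proteins and first-order proteasomal degradation of the
K48-tagged pools `Bd` and `Rd` (complex-bound protein is structurally
protected, which is how complex formation extends the proteins'
half-lives). Concentrations are handled internally in units of the
reference Ring1B abundance (100 nM); nanomolar input is converted once
at the interface.

```{r scheme}
cfg <- model_config()
p <- default_parameters()
round(unclass(p), 5)
```

## Parameter provenance: a calibrated default set

The numeric supplementary tables of the study this model family comes
from are not available alongside the article text; only the values
printed in figure captions are. The package therefore ships a
**calibrated** default set (`default_parameters()`), fitted in-package
so that the printed anchor behaviors hold, and clearly marked as such:

* with `USP7_tot = 1` (100 nM), the steady-state count along the Bmi1
  axis is 1 (stable) at `Bmi1_tot = 1`, 3 (two stable, one unstable)
  at 2.5, and 1 (stable) at 4;
* the Bmi1 scan is bistable over an interval wider than 100 nM with the
  upper saddle-node near 300 nM;
* at `(USP7_tot = 2, Bmi1_tot = 3)` the system is excitable (one stable
  rest state plus two unstable states, the upper one an unstable
  focus), with an all-or-none threshold for `Zub` increments between
  0.01 and 0.02.

Two calibration targets could **not** be met simultaneously with the
rest and are reported openly as not reproduced by the default set: the
lower saddle-node sits at 156 nM rather than about 200 nM (the onset of
the *stable* upper branch, a subcritical Hopf point, is at about
190 nM), and the elevated-USP7 points `(2, 3.25)` and
`(k1 = 0.0016, 3, 5)` are excitable rather than self-oscillatory. The
structural reason is a tight coupling in this model family: the
ignition fold of the switch is set by the balance between the
autocatalytic gain and the saturable-DUB removal slope, which scales
linearly with USP7. Keeping that fold near 300 nM of Bmi1 at *both*
100 and 200 nM USP7 requires the USP7-releasable parked material
(`Bd`, `Rd`, `Ru` pools) to supply a two-fold increase in ignition
drive; the achievable release is smaller, so parameter sets that
oscillate at 200 nM USP7 invariably lose the 100 nM bistable window,
and vice versa. We chose the set that preserves the bistability and
hysteresis block, which is the headline switch behavior.

Design decisions taken during calibration (all exposed as parameters or
configuration switches):

* **Autocatalytic activity.** The activity driving reactions 6 and 9 is
  `A = wZ*Zub + wRa*Ra + wRu*Ru` with default weights `(1, 0, 0)`: only
  the self-ubiquitinated *complex* acts as the intermolecular
  self-ubiquitinating enzyme. With equal weights every slowly
  discharging pool feeds back positively and the system admits no
  excitable structure at all.
* **Saturable external ligases.** The external-ligase reactions may be
  run saturably (`KM1`, `KM3`; `Inf` recovers first order). The default
  makes E6-AP saturable (`KM3 = 0.1`), so the degradation-targeted
  Ring1B pool at the off state is an approximately zero-order parking
  reservoir whose size scales as 1/USP7 -- the main carrier of the
  USP7-dependent release described above.
* **The Bmi1-directed DUB** (reaction 2) is *not* scaled with USP7 by
  default (`bmi1_dub_usp7_scaled = FALSE`); the enzyme is not
  identified experimentally, and USP7-scaled Bd recycling
  over-stabilizes the active branch at high USP7.

## Steady states, stability and the regime taxonomy

`find_steady_states()` eliminates the conservation laws (reduced
coordinates `Bd, Rd, Z, Zub, Ra, Ru, Hu`), runs a multi-start damped
least-squares root search (corner-biased deterministic starts plus
seeded random starts on the conservation simplex), deduplicates roots
at a relative distance of `1e-5`, and classifies stability from the
reduced Jacobian spectrum with margin `eps_eig = 1e-9` (eigenvalues
within the margin flag the root as marginal). Roots are accepted only
if the right-hand-side norm is below `1e-8`.

```{r steady}
ss <- find_steady_states(p, cfg, n_starts = 30, seed = 1)
length(ss)
sapply(ss, function(s) c(Zub = s$state[["Zub"]], Rd = s$state[["Rd"]]))
sapply(ss, function(s) s$stability)
```

Regimes follow the eigenvalue-count taxonomy used for the
(Bmi1, USP7) map: one stable state is `monostable`; two stable states
separated by one unstable is `bistable`; a single unstable state is
`oscillatory`; one stable plus two unstable is `excitable`; three or
more stable states is `multistable`.

```{r regime}
classify_regime(ss)
```

The two quasi-steady-state nullclines on the (`Rd`, `Zub`) plane are
computed by `qss_curves()`. The partition (an open choice) is: the
`Zub` curve solves the Ring1B ubiquitination cycle to steady state at
clamped *free Bmi1* -- by construction it is exactly invariant under
changes of total Bmi1 -- while the `Rd` curve clamps `Zub` and solves
the complementary subsystem (Bmi1 cycle, complex formation, the free-
Ring1B reactions) under both conservation laws, so it shifts with total
Bmi1. The second curve folds in `Zub`; it is computed by analytic
elimination to a scalar equation in free Bmi1 whose roots are located
by sign-scanning, and grid points where no branch exists are flagged
rather than interpolated. Intersections of the two curves reproduce the
enumerated steady states (this is tested).

## Bifurcation scans, hysteresis and the regime map

`scan_1d()` tracks all steady states over a parameter grid and refines
each fold (a change of the steady-state count by two) by bisection to a
relative precision of `1e-3`. `hysteresis_sweep()` implements the
quasi-static protocol: relax to the occupied steady state, step the
parameter, carry the state forward (material entering through a swept
*total* is injected into the corresponding free pool), and report the
parameter value at which the occupied branch disappears and the state
jumps. Inside the bistable window the up-switch occurs at the upper
fold and the down-switch at the lower fold, the experimental signature
of hysteresis and cellular memory.

```{r scan, eval = FALSE}
br <- scan_1d(p, cfg, "Bmi1_tot", range = c(0.5, 4.5), n_points = 17)
br$folds          # P1, P2 (normalized units; multiply by 100 for nM)
up <- hysteresis_sweep(p, cfg, "Bmi1_tot", c(1, 4), "up", step = 0.1)
down <- hysteresis_sweep(p, cfg, "Bmi1_tot", c(1, 4), "down", step = 0.1)
c(up = up$threshold, down = down$threshold)
```

`regime_map()` evaluates the classification over a rectangular
(Bmi1, USP7) grid (default window 0--6 by 0--4 in normalized units,
covering all anchor points). Near regime boundaries initial conditions
can select between coexisting attractors; the map reports the
eigenvalue-based label.

## Time courses, excitability and oscillation detection

Integration uses `deSolve::lsoda` with tight tolerances
(`rtol = 1e-8`, `atol = 1e-10`); the fast ignition / slow recovery
structure of the switch makes a stiff-capable integrator mandatory.
Along every short-timescale trajectory the three conserved totals drift
by less than `1e-6` relative (audited by
`trajectory_conservation()`).

The bistable memory is visible directly from the two printed initial
conditions of the bistable anchor: starting with Bmi1 parked in its
degradation-targeted form the system relaxes to the low-`Zub` /
high-`Rd` state, while starting with free Bmi1 it reaches the
high-`Zub` / low-`Rd` state:

```{r timecourse}
init_off <- make_state(cfg, Bd = 2.45, Rd = 0.05, R = 0.9, Zub = 0.05,
                       H = 1)
init_on <- make_state(cfg, Bd = 1.08, B = 1.1, Rd = 0.12, R = 0.1,
                      Z = 0.2, Zub = 0.12, Ra = 0.44, Ru = 0.02, H = 1)
tr_off <- simulate_timecourse(p, cfg, init_off, t_end = 3600)
tr_on <- simulate_timecourse(p, cfg, init_on, t_end = 3600)
c(off = tail(tr_off$Zub, 1), on = tail(tr_on$Zub, 1))
```

`excitability_threshold()` locates the all-or-none threshold of an
excitable rest state by bisection (relative precision `1e-3`). A
response counts as a large excursion when the peak deviation of the
readout exceeds 10 times the applied increment (state increments) or 10
times a known sub-threshold response (parameter pulses); the factor 10
is this package's operational definition of "no intermediate
responses" and is exposed as an argument. Parameter pulses are
rectangular: the parameter is restored exactly at pulse end. Note that
a state increment changes the conserved totals, so the post-excursion
state is the rest state of the *perturbed* totals. At the excitable
anchor the threshold separates responses differing by a factor of more
than 30 in peak `Zub` deviation, and monoubiquitinated H2A shows the
same dichotomy. A sustained 40 percent increase of the autocatalytic
constant `k6a` does not abolish the rest state of the calibrated set
(the fold in that direction lies at about 2.5-fold), so no pulse
duration of that amplitude can trigger the excursion -- the
corresponding printed bracket is not reproduced, as discussed above.

`detect_oscillations()` discards a configurable transient (default
30 percent), finds peaks, and requires regular inter-peak intervals
(coefficient of variation below 0.05) and non-decaying amplitude
(last/first cycle ratio above 0.95) before declaring a sustained
oscillation; the period is the mean inter-peak interval and phase lags
come from circular cross-correlation at the period.

## Synthetic data and parameter recovery

The synthetic-data module emulates quantified immunoblot readouts of
ubiquitination assays: `noisy_timecourse()` samples composite
observables (total ubiquitinated Ring1B `Rd + Ru + Ra + Zub`, total
active ubiquitinated Ring1B `Zub + Ra + Ru`, and single species) at
given times and applies independent multiplicative log-normal noise
(default coefficient of variation 0.1, reflecting densitometry of
band intensities: positive-valued and heteroscedastic) with a
detection floor. What these pseudo-data do *not* emulate: saturation of
the detection chemistry, correlated lane-to-lane errors, and loading
normalization artifacts -- so passing recovery tests demonstrate
identifiability under idealized noise, not performance on real blots.

`sample_parameters()` draws seed-reproducible log-uniform perturbations
of the rate constants, and `recover_parameters()` refits selected
constants by bounded multi-start Levenberg-Marquardt in log-parameter
space. With 10 percent noise and 15 sampling times over an hour, the
median relative errors for (`k7`, `k6a`) are a few percent.

## Numerical choices and problem sizes

* Root searches: `minpack.lm::nls.lm` with `ftol = ptol = 1e-15`,
  up to 200 iterations; soft penalties keep eliminated species
  non-negative. Badly scaled sets (for example the no-feedback control
  with `k6 = k9 = 20`) fall back to integration-seeded starts.
* Fold refinement: bisection on the steady-state count, not
  pseudo-arclength continuation -- robust and directly checkable
  against the hysteresis protocol at this system size.
* Default test/analysis problem sizes are kept modest (scan grids of
  13-17 points, 20-30 root-search starts, 20 recovery replicates);
  they reproduce the anchor quantities to well within their tolerances.
* The MM and MA variants agree species-by-species to better than
  5 percent where the reduction's premise holds (ubiquitinated
  substrate well below `KM7`). At the saturated high branch the
  explicit USP7-substrate complex sequesters most of the free enzyme,
  so the elementary-step model genuinely departs from the reduction
  there -- a shared-DUB competition effect that the first-order
  treatment of reactions 4, 10 and 11 cannot represent.

## Known limitations

* The default parameter set is a calibration product, not a transcribed
  table; every quantitative statement above is tied to it, and the two
  unreproduced anchors (lower fold position; self-sustained
  oscillations at the elevated-USP7 points) are flagged both here and
  in the test suite.
* Stochastic switching, spatial propagation of the H2A mark, and
  downstream gene-expression consequences are out of scope.
* The regime map reports eigenvalue-based labels; limit-cycle
  continuation and Hopf-point tracking are not implemented.
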