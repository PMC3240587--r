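# prc1dyn

Kinetic modelling of the Ring1B/Bmi1 histone H2A ubiquitination switch.

Ring1B, the catalytic E3 ligase of Polycomb repressive complex 1,
monoubiquitinates histone H2A when it is self-ubiquitinated and bound to
Bmi1; the same lysines can instead carry K48 chains placed by the
external ligase E6-AP, which send Ring1B to the proteasome, and the
deubiquitinase USP7 reverses both modifications. Intermolecular
autocatalysis (self-ubiquitinated Ring1B ubiquitinates other Ring1B
molecules) plus a saturable deubiquitination step make this cycle a
dynamical switch. `prc1dyn` implements the 13-reaction network in both
its Michaelis-Menten and elementary-step (mass-action) forms:

```
dx/dt = N v(x; k),   with e.g.
v6  = (k6 + k6a * A(x)) * [Z],        A = wZ*[Zub] + wRa*[Ra] + wRu*[Ru]
v7  = k7 * USP7_tot * [Zub] / (KM7 + [Zub])
v12 = (cZ*[Zub] + cRa*[Ra] + cRu*[Ru]) * [H2A]
```

and provides: steady-state enumeration with linear stability analysis,
one-parameter scans with saddle-node (fold) detection, quasi-static
hysteresis protocols, two-parameter regime maps over (Bmi1, USP7)
abundance, relaxation-oscillation detection, excitability-threshold
bisection, a synthetic-data module (noisy pseudo-immunoblot time
courses, randomized parameter sets, parameter recovery), YAML model
configurations, and SBML Level 3 export.

Because the source study's numeric parameter tables are not publicly
available, the shipped default parameter set is *calibrated in-package*
against the printed anchor behaviors (see the methods vignette,
`vignettes/ring1b-bmi1-dynamics.Rmd`, for the calibration account and
its two openly reported limitations).

## Worked example

```r
library(prc1dyn)

cfg <- model_config()           # Michaelis-Menten, short timescale
p   <- default_parameters()     # calibrated set, normalized units
                                # (1 unit = 100 nM; Ring1B total = 1)

## three steady states at 250 nM Bmi1, two of them stable
ss <- find_steady_states(p, cfg, n_starts = 30, seed = 1)
sapply(ss, function(s) round(c(Zub = s$state[["Zub"]],
                               Rd = s$state[["Rd"]]), 4))
#>        [,1]   [,2]   [,3]
#> Zub  0.0022 0.0063 0.0747
#> Rd   0.1542 0.1459 0.0335
sapply(ss, `[[`, "stability")
#> [1] "stable"   "unstable" "stable"
classify_regime(ss)
#> [1] "bistable"

## the switch has memory: saddle-node folds and hysteresis
br <- scan_1d(p, cfg, "Bmi1_tot", range = c(0.5, 4.5), n_points = 17)
round(br$folds * 100)    # nM
#>  P1  P2
#> 156 303
```

The low-`Zub` state is the "off" configuration (Ring1B mostly parked in
its degradation-targeted form, H2A unmodified); the high-`Zub` state is
the "on" configuration with active H2A monoubiquitination. Between the
two folds the state reached depends on history: sweeping total Bmi1
upward the system switches on only at the upper fold (~303 nM), sweeping
back down it switches off only at the lower fold -- a bistable window
of ~147 nM.

At doubled USP7 the system becomes excitable:

```r
pe <- set_parameters(p, USP7_tot = 2, Bmi1_tot = 3)
thr <- excitability_threshold(
  pe, cfg, perturbation_spec("state_increment", "Zub", NA),
  bracket = c(0.01, 0.02))
round(thr$threshold, 4)
#> [1] 0.0198
round(thr$over_response / thr$sub_response, 1)
#> [1] 31.6
```

A `Zub` increment below ~0.02 decays quietly; anything above it
triggers a stereotyped excursion more than 30-fold larger before the
system returns to rest -- an all-or-none pulse of H2A-directed ligase
activity.

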