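---
title: "The canonical microcircuit model: dynamics, classification, and bifurcation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The canonical microcircuit model: dynamics, classification, and bifurcation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmcircuit)
```

## The model

`cmcircuit` simulates a neural mass model of a local cortical circuit with
three populations: pyramidal cells (Py), excitatory interneurons (EIN), and
inhibitory interneurons (IIN).  Each population is described by its mean
membrane potential and mean firing rate.  Afferent firing rates are turned
into membrane potentials by convolution with an alpha-function synaptic
kernel `h(t) = (H/tau) t exp(-t/tau)`, which is equivalent to the
critically damped second-order operator

    V'' = (H/tau) u - (2/tau) V' - V / tau^2,

with `u` the summed afferent firing rate of that synaptic channel.
Membrane potentials are turned back into firing rates by the logistic
activation function `S(V) = 2 e0 / (1 + exp(r (v0 - V)))`.  The circuit has
five synaptic channels (two excitatory and one inhibitory onto Py, one
excitatory onto IIN, one inhibitory IIN self-feedback), hence a
10-dimensional state `(V1..V5, W1..W5)`.  The observable output is the Py
potential `V_Py = V2 - V3`.

Two architectural parameters interpolate between circuit layouts.  `b1`
blends *indirect* excitatory feedback through the EIN (`b1 = 1`; external
input arrives at the EIN) with *direct* Py self-feedback (`b1 = 0`; input
arrives at the Py, with self-gain `N_PP`).  `b2` switches the IIN
self-feedback loop: `b2 = 1` removes it, `b2 = 0` enables it with gain
`N_II` (disinhibition).  The default parameterization is the classic one
for this model family (`He = 3.25` mV, `Hi = 22` mV, `tau_e = 10` ms,
`tau_i = 20` ms, `N_EP = 135` and proportional gains, `e0 = 2.5` s⁻¹,
`r = 0.56` mV⁻¹, `v0 = 6` mV).  `N_PP = 113.4` and `N_II = 33.25` are taken
as given constants of the two-population mapping; the mapping derivation
itself is out of scope here.  All internal computation uses mV, s, and s⁻¹;
millisecond time constants are converted at construction.

```{r}
model_params()
```

## Simulation and response classification

`integrate_heun()` integrates the circuit with the explicit two-stage Heun
scheme at a default step of 1 ms, from a zero initial state.  Drives are
piecewise constant, evaluated once per step and frozen through both stages;
pulse boundaries follow the half-open convention `[onset, onset + dur)`.
When noise is requested (only the network module's contextual channel uses
it), it is Gaussian, resampled once per step and held through both stages —
a frozen-noise stochastic Heun variant, chosen because the model is studied
as an ODE with piecewise-constant inputs rather than as an SDE with a
prescribed scheme.  The integrator is written in C++ because the mapping
experiments below run thousands of 5 s simulations.

The standard stimulation protocol is a 5 s run: 1 s settling, then one
rectangular afferent pulse.  `classify_response()` compares the maximum
`V_Py` with the 4 mV firing threshold (about a quarter of the maximal
firing rate is reached there) in three windows — prestimulus (0.5–1 s),
immediate (1.1–3.5 s), asymptotic (4–5 s) — and maps the activation triple
to a label:

* **MEMORY** — active in the asymptotic window after starting inactive:
  the stimulus switched the circuit into a lasting high state;
* **TRANSFER** — active only during the immediate window: the stimulus was
  forwarded, then the circuit relaxed back;
* **NONRESPONSIVE** — uniformly inactive (or uniformly active).

An activity that oscillates about the threshold counts as active, since the
population then drives its targets at least part of the time; the maximum
criterion implements exactly that.  Triples `(1,1,0)` and `(1,0,*)` cannot
arise under the standard protocol and are mapped to NONRESPONSIVE with a
warning.  An optional oscillation flag (asymptotic peak-to-peak above
0.5 mV) marks oscillatory variants; the full sub-color taxonomy of mapped
figures is deliberately not reproduced because its thresholds are not
specified anywhere.

```{r}
classify_response(run_protocol(100, 1.0, model_params()))
classify_response(run_protocol(60, 1.0, model_params()))
```

`fingerprint()` runs the protocol over an intensity × duration grid
(defaults 50–250 s⁻¹ × 0.5–1.5 s, 41×41 when unspecified; the analyses in
the tests use 21×21 or smaller, which resolves every region of the map at a
fraction of the cost).  `dynamic_function_map()` summarizes fingerprints
over an `He × Hi` grid by the set of behaviors present — the package's
proxy for the color classes of mapped figures.

## Why the behaviors arise: bifurcation structure

At steady state each channel obeys `V = H tau u(V)`.  The equilibrium curve
along the drive admits a *global closed-form parameterization by*
`y = V_Py`: given `y`, the IIN channels follow directly (for `b2 = 0` after
one scalar Newton solve of the self-feedback fixed point), and the drive
`p_ext(y)` that supports the equilibrium is recovered by inverting the Py
channel (for intermediate `b1`, by a monotone scalar root).  Continuation
therefore reduces to a dense sweep in `y` — no pseudo-arclength predictor
or corrector is needed, there are no step-size failures, and folds are
*exactly* the turning points of `p_ext(y)`.  This is the package's central
numerical design choice; the 5-D damped-Newton solver `find_equilibria()`
is kept as an independent route and is cross-checked against a dense scan
oracle in the tests.

Stability comes from the eigenvalues of the analytic 10×10 Jacobian.
Event detection in `continue_branch()`:

* **folds** — turning points of `p_ext(y)`, refined by golden-section
  optimization; typed at the fold itself by discarding the eigenvalue
  closest to zero: saddle-node (SN) if all remaining eigenvalues are
  stable, saddle-saddle (SS) otherwise;
* **Hopf points** — zero crossings of the largest real part among complex
  eigenvalue pairs, refined by root bracketing (localization far below
  0.01 s⁻¹); crossings coinciding with a fold (where a complex pair merely
  forms) are excluded;
* **criticality** — decided by simulation probing on the unstable side:
  a trajectory started 0.05 mV along the branch with a 0.01 mV kick either
  settles into a small-amplitude cycle (supercritical) or escapes to a
  distant attractor (subcritical).  Normal-form coefficients of a 10-D
  system are avoided deliberately; only the qualitative label is needed.

At the default parameterization the branch is S-shaped: a saddle-node fold
at `p_ext ≈ 78.2` s⁻¹ (the gating threshold), a saddle-saddle fold at
`≈ -29.9` s⁻¹, and a subcritical Hopf at `≈ -5.31` s⁻¹ whose unstable
cycle acts as the separatrix that produces the offset-phase stripes of the
fingerprint.

```{r}
continue_branch(model_params(), classify_hopf = TRUE)$events
```

`trace_codim2()` traces fold loci through the `(He, Hi)` plane at zero
drive: for each `Hi` it finds the `He` at which the named fold sits exactly
at `p_ext = 0` (scan plus root refinement) and classifies the fold there.
Along the two-population upper-fold locus the at-fold test places the
SN→SS split (the point from which a Hopf branch emanates) at
`Hi ≈ 4.4` mV; with disinhibition the upper fold remains saddle-node over
the whole tested `Hi` range, which is what preserves the wide
working-memory region of that architecture.

A note on numbers: quantities that depend only on the geometry of the
equilibrium curve (fold positions, resting potential, equilibrium counts)
agree with the published descriptions of this model family to all printed
digits.  Two eigenvalue-derived locations — the subcritical Hopf (computed
here at −5.31 s⁻¹) and the two-population fold-split (computed at
`Hi ≈ 4.4` mV) — differ somewhat from figure-read values reported
elsewhere (−5.9 s⁻¹ and ≈6 mV).  Both computations are verified internally
by two independent routes (analytic vs. finite-difference Jacobians, and
eigenvalues vs. direct simulation of the linearized decay), so the package
reports its own faithfully computed values.

## The sentence-parsing network

`simulate_network()` couples circuits through their pyramidal firing
rates: excitatory edges feed the target's afferent route, inhibitory edges
drive the target's IIN — the same route by which a brief impulse resets an
active circuit (`deactivation_map()`).  Contextual information is a noisy
inhibitory offset subtracted from the target's afferent drive (floored at
zero, Gaussian with SD = 10 % of the offset, resampled per step; the
routing and the noise law are package choices, since only the qualitative
role of context is specified by the underlying theory).

The shipped six-node demo parses *"I hit the thief with the club"*: word
circuits for `I`, `hit`, `the_thief`, two competing `with` circuits
(verb-modifier vs. object-modifier), and `the_club`.  Each word arrives as
a 60 s⁻¹, 1.2 s pulse — *subthreshold on its own* (the fold sits at 78 s⁻¹)
— so a word only ignites its circuit when the upstream context has
pre-activated it (≈ +50 s⁻¹ from an active neighbour through gain-20
edges).  That is the gating operation; the resulting lasting activations
are the working-memory operation.  The first word gets a stronger pulse
(120 s⁻¹) since nothing precedes it.  The modifiers inhibit each other
asymmetrically (30 vs. 5), so with low context the verb-modifier wins;
high context (offset 50 s⁻¹ on the verb-modifier) hands the competition to
the object-modifier.  All connection gains are calibration artifacts tuned
by `scripts/calibrate_network.R` (34 of 36 combinations in its sweep
reproduce the qualitative outcomes, so the demo is not fragile); none is a
measured quantity.

```{r}
demo <- sentence_demo("high")
simulate_network(demo$spec, demo$schedule, seed = 1)
```

Raising `Hi` from 22 to 23–24 mV on all nodes destroys the circuits'
bistability at rest, so no word can hold its activation: the parse
degrades to a defective trace or to complete memory loss.  This is the
network-level signature of a local excitation–inhibition imbalance.

## Degenerate inputs, tolerances, limitations

* Sigmoid exponents are clamped at ±500; the clamp is unreachable for
  physiological potentials and affects no reported quantity.
* Equilibrium residuals are accepted below 1e−9 (Newton) / 1e−11 (scalar
  roots); fold positions are refined to ~1e−10 in `y`; duplicate Newton
  solutions are merged at 1e−5 mV.
* Divergent integrations (e.g. a time constant far below the step) abort
  with a diagnostic rather than returning garbage.
* The default sweep resolution (4001 points over `V_Py ∈ [−60, 40]` mV)
  resolves every event of the studied parameterizations; the stated event
  accuracies degrade gracefully at coarser settings.
* Not covered by design: limit-cycle continuation (stable cycles are
  detected only by the simulation probe in `bistability_check()`),
  conduction delays, neural-field extensions, plasticity, and any
  morphosyntactic elaboration of the parsing demo.  The synthetic word
  schedule idealizes word recognition as clean rectangular pulses; passing
  tests therefore demonstrate the network mechanism, not performance on
  real speech input.
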