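---
title: "Modelling firing-rate effects of perineuronal-net degradation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling firing-rate effects of perineuronal-net degradation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Perineuronal nets (PNNs) are lattices of negatively charged extracellular
matrix wrapping the soma and proximal dendrites of fast-spiking
parvalbumin-positive (PV) interneurons.  Degrading them experimentally
increases the specific membrane capacitance `c_m` of the wrapped membrane
(the net acts like extra dielectric thickness) by 25-50 % and lowers the
sustained firing rate by roughly 38 % at strong drive.  Since
`tau_m = R_m C_m`, a larger `c_m` slows membrane dynamics, but spiking is a
nonlinear interplay of many currents, so the sign and size of the effect on
the f-I curve is a quantitative question.  `pnnsim` implements the
machinery to answer it in conductance-based models and to explore which
*additional* parameters -- channel conductances and ionic reversal
potentials -- could be co-responsible for the observed rate drop.

## Model and solver

Cells are trees of cylindrical compartments.  Compartment `j` obeys

$$ c_{m,j} \frac{dV_j}{dt} = -\bar g_L (V_j - E_L)
   - \sum_X \bar g_X m^{\alpha} h^{\beta} (V_j - E_X)
   + \frac{I_{stim,j}}{A_j} + \frac{\sum_k g_{jk}(V_k - V_j)}{A_j} $$

with membrane areas `A_j = pi d l` (cylinder side only; end caps are not
part of cable bookkeeping) and axial coupling
`g_jk = 1/(r_j/2 + r_k/2)`, `r = 4 R_a l/(pi d^2)`.

Kinetics are **data, not code**: mechanism-definition JSON files express
every rate curve in a small set of canonical forms (`exp_linear`,
`exponential`, `sigmoid`, `constant`, `bell`), plus Markov transition
schemes and Hill-type calcium activation for SK channels.  The solver only
ever sees tabulated `inf/tau` (or transition-rate) curves on a 0.05 mV grid
over [-120, 60] mV; interpolation error at that spacing is negligible
relative to the time-discretization error.

One step of the integrator, at the protocol step `dt = 0.0078125` ms:

1. calcium channel currents are evaluated at the current voltage and gates;
2. gates and Markov occupancies advance by exact-exponential updates at
   frozen voltage (`x <- inf + (x - inf) exp(-dt/tau)`;
   `p <- expm(Q dt) p`), and calcium pools by the exact solution of their
   linear ODE;
3. `E_Ca` is recomputed from the Nernst relation;
4. the voltage advances by one backward-Euler step with channel
   conductances frozen: a tree-structured linear system solved exactly by
   Hines elimination (no iteration; residual at machine precision).

Backward Euler is first-order but unconditionally stable, which is the
binding constraint on stiff spike upstrokes at a fixed `dt`.  The compiled
core (Rcpp/Armadillo) and a plain-R reference stepper implement the same
algorithm independently and agree to ~1e-13 mV; accuracy against the true
solution is established by comparison with an adaptive Runge-Kutta oracle
in the test suite, not by assumption.

Simulations settle for 600 ms before the stimulus window is recorded
(initialization: `V = V_init`, gates at steady state for `V_init`, Markov
schemes at their stationary distribution, calcium at rest).  Somatic
voltage is recorded at every step of the stimulus window.

## Protocols

* **Spike detection**: a sample strictly greater than both neighbours and
  above -20 mV.  Flat-topped (exactly tied) peaks are not spikes; on
  floating-point traces ties are measure-zero.
* **Sustained firing**: spikes count only if at least one falls in the
  latter half of the stimulus; the rate is the count in the rate window
  divided by its length (HH models: 1000 ms stimulus, full-window rate;
  Allen-style models: 2000 ms stimulus, rate over the last 1000 ms --
  these models show late-onset spiking near threshold).
* **f-I curve**: current sweeps from 0 in 0.01 nA increments until the
  sustained rate returns to zero after having been positive
  (depolarization block, confirmed at one extra grid point) or a 1.0 nA
  cap (comfortably above all currents of interest, which stay <= 0.8 nA).
* **Threshold**: smallest sustained-firing current on a 0.001 nA grid,
  located by coarse sweep plus bisection; the bracket property
  `f(thr) > 0, f(thr - 0.001) = 0` is guaranteed and checked against an
  exhaustive fine sweep in the tests.
* **Spike width** at -40 mV by linear interpolation of the level crossings
  around each apex.  The mean width per trace is reported (the aggregation
  is not pinned down by the source design; the first-spike width is also
  exposed).

## Perturbations

`pnn_perturbation()` captures one experimental hypothesis:

* `cm_factor` on `cm_region = "all"` or `"sprx"` -- the sprx mask is the
  soma plus every dendritic segment whose *midpoint* lies within 3.5 soma
  lengths path distance of the cell body.  Midpoints were chosen (over
  proximal edges) to match the segment-center evaluation convention of
  compartmental simulators; the axon is never part of the mask, since PNNs
  are described as covering soma and proximal dendrites.
* conductance factors per mechanism, validated to [0.3, 10];
* reversal shifts per ion (+-20 mV), applied to *every* mechanism carrying
  that ion (reversals are per-ion, not per-channel).  Calcium is special:
  its reversal is dynamic, so a shift is expressed through the fixed
  extracellular concentration, `[Ca]_out <- [Ca]_out exp(z F dE / RT)`,
  which moves `E_Ca(t = 0)` by exactly `dE` and leaves the dynamics intact.
  The bundled combinatorial config uses `[Ca]_out x 10` (`dE = 30.47 mV` at
  34 C), which lands on the printed altered reversal 161.53 mV exactly;
  a nominal `+30 mV` shift would give 161.06 mV.
* `[Ca]_in` is never perturbed directly, and a floor of 1e-10 mM keeps the
  Nernst argument defined (far below physiological resolution).

`scan_parameter()` and `run_scenarios()` evaluate one axis or a list of
combined scenarios against baseline, recording per curve the threshold,
rates and spike widths at probe currents (0.2 and 0.4 nA), termination
reason, and the relative f difference at the largest current with
sustained firing in both curves -- the statistic whose experimental
benchmark is a 38 % drop.

## The synthetic-data module

`generate_synthetic_cell(seed)` emits a reproducible random cell in the
same bundle schema as a database model: a binary dendritic tree (section
lengths 20-200 um, diameters 0.5-2 um, soma 10-20 um -- typical PV-cell
scales), plus channel densities drawn uniformly from 0.5-1.5x the defaults
of the bundled `toy_allen` mechanism set.  The set covers the full
eleven-mechanism perisomatic inventory (Ih, NaV, Kd, Kv2like, K_T, Kv3_1,
Im_v2, SK, Ca_HVA, Ca_LVA, leak).  Its NaV/Kv3_1 kinetics are the canonical
fast-spiking-interneuron formulation (Type I excitability, instantaneous
Na activation gate); Ca_HVA uses standard high-voltage-activated calcium
kinetics; Kd is a two-state Markov scheme exercising the Markov engine in
real dynamics; the remaining channels are schematic sigmoid/constant-tau
stand-ins with small conductances.  The calcium pool uses the standard
shell parameters (gamma 0.05, depth 0.1 um, decay 80 ms, rest 1e-4 mM,
[Ca]_out 2 mM).

What a green test on the fixture establishes: the *pipeline* (SWC ->
perisomatic assembly with axon replacement -> solver -> protocols ->
scans) and the *qualitative physiology* (Type I onset; SK-mediated sign of
calcium-conductance effects when the SK draw is substantial).  What it does
not establish: quantitative agreement with any real database cell -- the
fixture's kinetics are stand-ins, and the sign of the Ca_HVA effect
legitimately flips when the drawn SK conductance is small (the
depolarizing calcium current then wins), a composition dependence the
source analysis itself discusses.  The reference fixture used throughout
tests and the acceptance report is seed 42 with two primary dendrites.

## Numerical choices and degenerate inputs

* Temperatures: HH models at 6.3 C with q10 = 3 (rates in the modern
  -65 mV resting convention); Allen-style models at 34 C with the q10
  folded into the toy kinetics.
* `V_init = -65 mV` for HH models; per-bundle for Allen-style models.  The
  600 ms settle erases initialization transients; this is relied upon
  rather than proven per-model.
* The backward-Euler phase error at the production `dt` is visible as
  spike-time drift (~1e-2 ms per spike on the one-compartment model); rate
  and threshold measurements are insensitive to it, and trace-level
  equivalence with the adaptive oracle is demonstrated at `dt/64`
  (max deviation ~0.6 mV over 200 ms of repetitive firing).
* Soma sections are kept as a single segment (the source design segments
  only dendrites); SWC somata are merged into one cylinder whose length is
  the path span of the soma samples (single sample: length = diameter).
* Scan points that fail (e.g. no firing at an extreme factor) are recorded
  as gaps, not errors; depolarization block at extreme parameters is
  expected behaviour.
* Flat-topped spikes, truncated spikes at trace edges, and disjoint firing
  ranges in the comparison statistic all degrade to explicit `NA`s or
  typed errors rather than silent numbers.

## Known limitations

* The axon initial segment is excluded from the sprx mask; whether real
  PNN coverage includes it is unresolved.
* Active-kinetics (activation-curve) perturbations are out of scope by
  design -- only conductances and reversals are varied.
* A genuine database parameter bundle is an optional external input; no
  downloading is performed.  All quantitative claims about database cells
  would require supplying such bundles to `build_allen_style()`.
* The ball-and-stick rheobase *does* move with `c_m` at 0.001 nA
  resolution (0.103 -> 0.108 nA under a 1.5x sprx change): the onset of a
  Type II soma loaded by a capacitive cable is genuinely
  capacitance-dependent.  The no-shift statement holds at the 0.01 nA
  resolution of the f-I protocol, which is how the acceptance suite tests
  it; the fine-grid literalization is kept as a deliberately failing test.
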