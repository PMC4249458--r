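---
title: "The MLI-Purkinje network model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The MLI-Purkinje network model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette explains the model implemented by **purkinet**, the choices
that were genuinely open when writing it, and what the package's tests do
and do not establish. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## The scientific question

Purkinje cells (PKJs) and molecular layer interneurons (MLIs) fire
spontaneously: their activity does not require excitatory input. In
slices, with GABAergic transmission blocked, both fire fast and almost
clockwork-regularly; in control conditions they fire slower and much more
irregularly. The model asks whether that transformation needs nothing more
than (1) an endogenous depolarizing current in every cell and (2) the
known inhibitory wiring of a parasagittal strip — MLI→PKJ feedforward
inhibition, MLI→MLI mutual inhibition, and PKJ→MLI recurrent collaterals
onto the lower-molecular-layer interneurons.

## Neuron model

Conductance-based leaky integrate-and-fire, in a fixed unit system
(mV, ms, nS, pF, hence pA for currents):

$$C\,\dot V = -g_{leak}(V-E_{leak}) - g_{ahp}(t)(V-E_{ahp})
 - g_{GABA}(t)(V-E_{GABA}) + I_{spont}(t)$$

* The GABA conductance is a peak value times the synaptic weight,
  deposited at each presynaptic spike and decaying as
  $\exp(-t/\tau_{GABA})$; simultaneous inputs add linearly. The peak
  ($\bar g_{GABA}$) is a property of the *target* class: 1 nS onto PKJs,
  4 nS onto MLIs.
* The after-hyperpolarization conductance restarts at its peak at each
  spike — most recent spike only, no summation across spikes — and decays
  with $\tau_{ahp} = 2.5$ ms. With peaks of 100 nS (PKJ) and 50 nS (MLI),
  20–40× the leak, it repolarizes the cell within a few steps. **There is
  no hard voltage reset**; the AHP is the entire reset mechanism.
* $I_{spont} \sim \Gamma(\kappa,\beta)$ (shape, scale; nA), drawn afresh
  every time step for every neuron. The gamma law has non-negative
  support, so the endogenous drive is purely depolarizing.

There are no excitatory synaptic conductances anywhere in the model, and
no parallel-fibre input: the network's spontaneous state is the object of
study.

### Parameters

Defaults per class (all overridable via `neuronParams()`):

| parameter | PKJ | MLI | units | meaning |
|---|---|---|---|---|
| V_threshold | −55 | −53 | mV | spike threshold |
| C | 107 | 14.6 | pF | membrane capacitance |
| g_leak | 2.32 | 1.6 | nS | leak conductance |
| E_leak | −68 | −68 | mV | resting potential |
| ḡ_GABA | 1.0 | 4.0 | nS | peak IPSC conductance onto this class |
| E_GABA | −75 | −82 | mV | GABA reversal |
| τ_GABA | 10 | 4.6 | ms | IPSC decay |
| ḡ_AHP | 100 | 50 | nS | AHP peak |
| E_AHP | −70 | −82 | mV | AHP reversal |
| τ_AHP | 2.5 | 2.5 | ms | AHP decay |
| κ | 0.430303 | 3.966333 | – | drive shape |
| β | 0.195962 | 0.006653 | nA | drive scale |

κ and β were found by grid search (`calibrateSpont()`) against in-vitro
exemplar statistics under GABA block (PKJ: 40 Hz, ISI CV 0.18; MLI:
30 Hz, CV 0.14). The mean drive κβ is ≈ 84 pA for PKJs (asymptotic
potential well above threshold: strongly mean-driven) and ≈ 26 pA for
MLIs (asymptotic potential barely above threshold: closer to
fluctuation-driven) — which is why the two classes respond differently to
added inhibition.

`kappa = 0` is admitted as the degenerate "no drive" case (a point mass
at zero current); it is the natural way to silence a cell in control
experiments, and drawing from it consumes no random numbers, which keeps
paired comparisons stream-identical.

## Integration conventions

Forward Euler with `dt = 0.25 ms`. Because the drive is redrawn each
step, dt is part of the *model*, not merely of the integrator: halving dt
whitens the effective noise. The engine therefore treats dt as a fixed
constant of the published conditions, and no convergence-in-dt claim is
made.

The sub-step ordering, which the governing equations leave open, is fixed
as follows (identically in the compiled engine and in the scalar R
reference used to test it):

1. membrane update using the conductance traces valid at the step start;
2. threshold test after the update; a crossing at step *k* is recorded at
   time *k·dt* and restarts the AHP at its peak;
3. both traces decay by one step (values below 1e−30 nS flush to zero —
   dynamically irrelevant, and subnormal arithmetic is pathologically
   slow);
4. all spikes of the step deposit their conductance increments, so a
   spike first influences its targets on step *k+1* (zero transmission
   delay, one-step causality). Same-step spikes are order-independent for
   the dynamics; deposits are summed in a fixed (source, target) order so
   results do not depend on internal vectorisation.

A neuron is never reset below threshold, so consecutive-step spikes are
possible in principle; with the default AHP strengths a single step
suffices to pull the membrane below threshold, and the test suite's
strictly-increasing-spike-time invariant covers the realised behaviour.

Initial conditions are V = E_leak, zero traces, never spiked. No burn-in
is discarded: the membrane time constants (≈ 46 ms for PKJs, ≈ 9 ms for
MLIs) are negligible against the 60–300 s analysis windows.

RNG discipline: one R stream seeded by the wiring seed generates the
network; an independent stream seeded by the dynamics seed drives the
simulation, with per-step gamma draws made in ascending neuron id. Runs
are bit-reproducible from the two seeds. Clamped neurons (used by
`forceSpike()` for triggered-IPSC experiments) draw nothing, so a trial
with and without a forced spike shares its entire random stream — a
paired design that isolates the synaptic effect.

## The wiring generator

The strip holds `nPkj = 16` territories at 64 µm spacing, each with 10
MLIs, the first 3 flagged lower-molecular-layer (the subset eligible for
PKJ recurrent collaterals). Each MLI axon runs left or right (equal
probability) across 8 territories; each PKJ collateral across 2. Within
the span every candidate is equally likely (no distance decay), one
Bernoulli draw per ordered pair, so autapses and duplicate synapses are
impossible, and PKJ→PKJ contacts are excluded outright (adult tissue).
Weights are `Unif(0, 1)` for MLI→MLI and PKJ→MLI, `Unif(0, 1.25)` for
MLI→PKJ.

**Boundary handling** was the one genuinely open design decision. The
anatomical constraints are stated as population averages — 20 MLI inputs
per PKJ, 4 per MLI, 3 collateral targets per PKJ, 1 PKJ input per
eligible MLI. On an idealised (infinite or wrapped) strip the
per-candidate probabilities follow as target/candidates: 2/8 = 0.25,
4/80 = 0.05, 3/6 = 0.5. But the modelled strip is finite and axons
truncate at its ends; with the idealised probabilities the *realised*
average MLI→PKJ convergence on 16 territories is only ≈ 14.4, and the
network is visibly under-inhibited. `deriveProbabilities()` therefore
offers two conventions: `boundary = "interior"` (the idealised
arithmetic, exact for neurons whose span is uncut) and
`boundary = "average"` (candidate counts averaged over the actual strip,
so the population-average convergence meets the targets exactly —
p ≈ 0.348, 0.0696, 0.552 for the default geometry). The default
`networkConfig()` uses the averaged form, because the circuit is
specified by its average connectivity; the truncated geometry itself is
kept, since a wrapped strip has no anatomical meaning. Heterogeneous
in-degree — including near-zero for edge neurons pointing outward — is a
real feature of the model and produces the wide per-neuron rate
distributions the network experiment reports.

## What the generator emulates, and what it does not

This package is a simulator: its "data" are the spike trains of the model
itself under the published conditions (300 s recordings at dt = 0.25 ms;
60 s for the pruning protocol). Those conditions are what the tests
exercise. Passing tests therefore show that the *model* reproduces the
target statistics under its stated assumptions — single-compartment
cells, one idealised MLI type, no gap junctions, no synaptic or
propagation delays, no parallel-fibre drive, a 1-D strip. They do not
show that real MLI-PKJ tissue satisfies those assumptions, nor do they
probe 2-D (medio-lateral) structure, synchrony phenomena that depend on
transmission delays, or plasticity.

## Experiments and their problem sizes

* `expIsolated()` — one neuron, 300 s: rate, ISI CV, ISI histogram (1 ms
  bins), autocorrelogram (1 ms bins, ±100 ms window — bin width and
  window chosen to resolve the 25–35 ms baseline periodicity),
  Shapiro–Wilk normality of the ISIs.
* `expNetwork()` — 176 neurons, 300 s: per-neuron rates and CVs,
  per-class summaries, rate–CV Spearman correlations, rate histograms.
* `expFeedforward()` — PKJ + clamped MLI, 500 paired trials per peak
  conductance {0, 1, 2, 4, 8} nS, MLI triggered 12 ms after the PKJ's
  first spike; the first-to-second-spike interval is compared with its
  paired no-IPSC control (Mann–Whitney), and mean interval is regressed
  on peak conductance. The peak is specified directly in nS (it
  deliberately exceeds ḡ_GABA·w_max to probe the linear range).
* `expPruning()` — 60 s per condition, fractions {0, .25, .5, .75, 1} of
  MLI→MLI or PKJ→MLI synapses removed from one wiring (independent prune
  draws per fraction, one shared dynamics seed so conditions are
  matched); medians, quartiles and means per class, Mann–Whitney between
  intact and fully pruned.
* `calibrateSpont()` — exhaustive (κ, β) grid, by default 5×5 log-spaced
  points bracketing the shipped values by ×/÷4, 60 s per point, one
  shared dynamics seed (paired evaluations). Loss = sum of relative
  errors in rate and CV; ties break toward smaller κ, then smaller β.
  The loss and tie-break are artifact choices; only the existence of the
  grid search is inherited.
* `expRobustness()` — (a) independent re-instantiations (default 5×60 s)
  of the wiring and dynamics, reporting the spread of population
  statistics; (b) every cell parameter and weight bound scaled by an
  independent Unif(0.9, 1.1) factor, re-run, reporting the same
  statistics and whether all cells stayed spontaneously active. ±10%
  keeps every reversal-potential/threshold ordering valid for the default
  values.

Statistical conventions: ISI CV uses the N−1 sample standard deviation
("assuming a normal distribution", for comparability with slice
literature); neurons with fewer than 3 spikes have no defined CV and are
excluded from CV aggregates but kept in rate aggregates (at 60 s some
MLIs fire < 0.5 Hz, so this matters); Shapiro–Wilk is capped at n = 5000
by a fixed-seed subsample (the statistic is undefined above that in the
reference implementation); Spearman p-values use the large-sample
approximation (ties get average ranks).

## Numerical and degenerate-input choices

* Trace flush at 1e−30 nS (≈ 280 decay constants below any physiological
  scale) in both engine and reference; without it, silent neurons' traces
  decay into subnormal range and slow the integrator by orders of
  magnitude.
* The compiled engine is built with floating-point contraction disabled
  so it rounds operation-for-operation like R; the engine-vs-reference
  test asserts bit-identical spike times, not approximate agreement.
* Degenerate inputs: `duration = dt` runs one step; empty spike trains
  give rate 0 and undefined CV; `fraction = 0/1` pruning are exact
  identity/removal; a one-point calibration grid returns that point.
* The command line refuses recording durations under 1 s: every
  experiment it exposes reports interval statistics, which are
  meaningless below that scale.

## Known limitations

Single-compartment cells without channel dynamics; one homogeneous MLI
class standing in for stellate and basket cells; chemical synapses only
(no gap junctions); no transmission delays (hence no delay-driven
synchrony); no excitatory input pathway; a single parasagittal strip. The
per-step current redraw ties the drive spectrum to dt, so the model
should be compared across conditions only at the fixed 0.25 ms step.
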