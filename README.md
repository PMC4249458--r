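# purkinet

A spiking network model of the cerebellar molecular layer: spontaneously
active Purkinje cells (PKJs) and molecular layer interneurons (MLIs —
stellate and basket cells, modelled as one class) coupled exclusively by
inhibitory synapses along a one-dimensional parasagittal strip.

The package is for computational neuroscientists who want a small,
fully reproducible substrate for studying how feedforward and feedback
inhibition shape the *irregularity* of spontaneous firing in the
MLI–Purkinje circuit — the shift from the regular, clock-like firing both
cell types show in isolation (as in slices under GABA blockers) to the
slow, irregular firing they show inside the intact network.

## Model

Each neuron is a conductance-based leaky integrate-and-fire unit,

```
C dV/dt = − g_leak (V − E_leak) − g_ahp(t) (V − E_ahp)
          − g_GABA(t) (V − E_GABA) + I_spont(t)
```

with three non-standard ingredients:

* **Stochastic endogenous drive.** `I_spont ~ Gamma(κ, β)` (nA) is redrawn
  at every integration step. The gamma law keeps the current non-negative
  and its shape/scale were calibrated (grid search, `calibrateSpont()`) so
  isolated cells match in-vitro exemplars: ~40 Hz at ISI CV 0.18 (PKJ),
  ~30 Hz at CV 0.14 (MLI).
* **AHP as the only reset.** A spike triggers an after-hyperpolarization
  conductance `g_ahp(t) = ḡ_ahp exp(−(t − t_spike)/τ_ahp)` that restarts
  from the most recent spike; there is no hard voltage reset.
* **Anatomically constrained wiring.** 16 PKJ territories × 10 MLIs
  (3 per territory eligible for PKJ recurrent collaterals). Every axon
  runs one randomly chosen direction; synapses form per candidate with
  probabilities chosen so the population-average convergence matches the
  anatomy: 20 MLI inputs per PKJ, 4 MLI inputs per MLI, 3 MLI targets per
  PKJ collateral. Weights are uniform, `w ~ Unif(0, w_max)` per type.

Integration is forward Euler at `dt = 0.25 ms` (a model constant — the
per-step current redraw ties the noise statistics to the step), with
zero-delay, one-step-causal synaptic transmission. The engine is compiled
(Rcpp) and bit-reproducible from two seeds (wiring, dynamics); a scalar R
reference implementation in the test suite checks it spike-for-spike.

## Worked example

```r
library(purkinet)

net <- buildNetwork(networkConfig(seed = 7))
net
#> CellNetwork: 176 neurons (16 PKJ, 160 MLI), 1093 synapses
#>    MLI_MLI: 694  MLI_PKJ: 356  PKJ_MLI: 43

res <- runSimulation(net, simSettings(60e3, simSeed = 8))  # 60 s
ps  <- populationStats(res)
subset(ps$summary, measure == "rate")
#>   class measure   n mean   sd median    q1   q3
#> 1   PKJ    rate  16 24.6 5.25   23.6 21.18 28.6
#> 3   MLI    rate 160 13.4 8.22   13.1  7.01 20.5
subset(ps$summary, measure == "cv")
#>   class measure   n  mean     sd median    q1    q3
#> 2   PKJ      cv  16 0.302 0.0771  0.284 0.241 0.347
#> 4   MLI      cv 160 0.601 0.2543  0.605 0.385 0.780
```

Inside the network both classes fire slower and far more irregularly than
in isolation (`expIsolated("PKJ")` gives 38.5 Hz at CV 0.168 over 300 s),
and rate and irregularity are almost perfectly anticorrelated across
neurons — the most inhibited cells are both the slowest and the most
irregular:

```r
rateCvCorrelation(subset(ps$perNeuron, class == "MLI"))
#> $rho  -0.988      $p  1.7e-131
```

The scripted experiments reproduce the model's headline analyses:
`expIsolated()` (regular firing, ISI histogram, autocorrelogram,
normality test), `expNetwork()` (population statistics and rate–CV
correlations), `expFeedforward()` (a triggered MLI IPSC prolongs the PKJ
inter-spike interval in proportion to the peak conductance),
`expPruning()` (removing MLI→MLI synapses reshapes network activity;
removing PKJ→MLI synapses barely moves it), `calibrateSpont()` and
`expRobustness()`. A thin command-line wrapper is available via
`cliMain()` / `inst/cli/purkinet.R`.

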