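## model core: cell-class parameter profiles and the single-neuron dynamics.
## These scalar operations define the model semantics; the network engine in
## src/engine.cpp implements the identical update rule for speed.

## Default parameter tables, one column per cell class.
.PARAM_DEFAULTS <- list(
  PKJ = list(vThreshold = -55.0, capacitance = 107.0, gLeak = 2.32,
             eLeak = -68.0, gGabaPeak = 1.0, eGaba = -75.0, tauGaba = 10.0,
             gAhpPeak = 100.0, eAhp = -70.0, tauAhp = 2.5,
             kappa = 0.430303, beta = 0.195962),
  MLI = list(vThreshold = -53.0, capacitance = 14.6, gLeak = 1.6,
             eLeak = -68.0, gGabaPeak = 4.0, eGaba = -82.0, tauGaba = 4.6,
             gAhpPeak = 50.0, eAhp = -82.0, tauAhp = 2.5,
             kappa = 3.966333, beta = 0.006653)
)

#' Cell-class parameters
#'
#' Construct a \linkS4class{NeuronParams} object. With no overrides this
#' returns the default profile for the requested class: a Purkinje cell
#' ("PKJ") or a molecular layer interneuron ("MLI"). The defaults were
#' calibrated (see [calibrateSpont()]) so that the isolated neuron
#' reproduces in-vitro exemplar firing under GABA block: about 40 Hz at ISI
#' CV 0.18 for the PKJ, 30 Hz at CV 0.14 for the MLI.
#'
#' @param cellClass "PKJ" or "MLI".
#' @param ... named overrides of individual slots (e.g. \code{kappa = 0}).
#' @return a validated \linkS4class{NeuronParams}.
#' @examples
#' neuronParams("PKJ")
#' neuronParams("MLI", kappa = 0)  # silenced: no spontaneous drive
#' @export
neuronParams <- function(cellClass = c("PKJ", "MLI"), ...) {
  cellClass <- match.arg(cellClass)
  vals <- .PARAM_DEFAULTS[[cellClass]]
  ovr <- list(...)
  bad <- setdiff(names(ovr), names(vals))
  if (length(bad))
    stop("unknown NeuronParams field(s): ", paste(bad, collapse = ", "))
  vals[names(ovr)] <- ovr
  do.call(new, c(list("NeuronParams", cellClass = cellClass), vals))
}

#' Fresh neuron state
#'
#' Initial conditions: membrane potential at the leak reversal, zero
#' synaptic conductance, never spiked. No burn-in is discarded anywhere in
#' the package; the initial transient is far shorter than the analysis
#' windows (60-300 s).
#'
#' @param params a \linkS4class{NeuronParams}.
#' @return a \linkS4class{NeuronState}.
#' @export
neuronState <- function(params) {
  new("NeuronState", v = params@eLeak, gGaba = 0,
      tLastSpike = NA_real_, spiked = FALSE)
}

#' Draw the spontaneous depolarizing current
#'
#' One (or \code{n}) i.i.d. sample(s) from Gamma(shape = kappa,
#' scale = beta), in nA. A fresh draw is made every integration step, so the
#' effective noise spectrum is tied to dt. \code{kappa = 0} is the
#' degenerate no-drive case and returns 0 without consuming random numbers.
#'
#' @param params a \linkS4class{NeuronParams}.
#' @param n number of draws.
#' @return numeric vector of currents, nA (always >= 0).
#' @export
drawSpontCurrent <- function(params, n = 1L) {
  if (params@kappa < 0 || params@beta <= 0)
    stop("gamma parameters must satisfy kappa >= 0, beta > 0")
  if (params@kappa == 0) return(rep(0, n))
  rgamma(n, shape = params@kappa, scale = params@beta)
}

#' One forward-Euler membrane update
#'
#' Advances the membrane potential by one step of
#' \deqn{C\,dV/dt = -g_{leak}(V-E_{leak}) - g_{AHP}(t)(V-E_{AHP})
#'   - g_{GABA}(t)(V-E_{GABA}) + I_{spont},}
#' where \eqn{g_{AHP}(t) = \bar g_{AHP}\exp(-(t-t_{spike})/\tau_{AHP})}
#' restarts from the most recent spike only (0 if the neuron has never
#' spiked). The threshold test follows the update: if the new potential
#' reaches \code{vThreshold} the neuron spikes, \code{tLastSpike} is set to
#' \code{now}, and the AHP restarts. There is no hard voltage reset; the
#' AHP conductance (20-40x the leak) carries repolarization.
#'
#' @param state a \linkS4class{NeuronState}.
#' @param params a \linkS4class{NeuronParams}.
#' @param iSpont spontaneous current for this step, nA.
#' @param dt step, ms.
#' @param now time at the start of the step, ms.
#' @return the updated \linkS4class{NeuronState}.
#' @export
stepNeuron <- function(state, params, iSpont, dt, now) {
  if (dt <= 0) stop("dt must be > 0")
  gAhp <- if (is.na(state@tLastSpike)) 0 else
    params@gAhpPeak * exp(-(now - state@tLastSpike) / params@tauAhp)
  v <- state@v
  v <- v + (dt / params@capacitance) *
    (-params@gLeak * (v - params@eLeak) -
       gAhp * (v - params@eAhp) -
       state@gGaba * (v - params@eGaba) +
       iSpont * 1000)  # nA -> pA
  if (!is.finite(v))
    stop(sprintf("membrane potential diverged at t = %g ms", now))
  spiked <- v >= params@vThreshold
  new("NeuronState", v = v, gGaba = state@gGaba,
      tLastSpike = if (spiked) now else state@tLastSpike, spiked = spiked)
}

#' Decay the synaptic conductance trace
#'
#' Multiplies the summed GABA conductance by \eqn{\exp(-dt/\tau_{GABA})};
#' exact for any step size (exponential semigroup), so k small steps equal
#' one k-times-larger step up to floating-point rounding.
#'
#' @inheritParams stepNeuron
#' @return the updated \linkS4class{NeuronState}.
#' @export
decayGabaTrace <- function(state, params, dt) {
  if (dt <= 0) stop("dt must be > 0")
  new("NeuronState", v = state@v,
      gGaba = state@gGaba * exp(-dt / params@tauGaba),
      tLastSpike = state@tLastSpike, spiked = state@spiked)
}

#' Register a presynaptic spike
#'
#' Increments the conductance trace by \code{gGabaPeak * weight} (the peak
#' conductance is a property of the *target* cell class). Simultaneous
#' presynaptic spikes sum linearly.
#'
#' @inheritParams stepNeuron
#' @param weight synaptic weight (dimensionless, >= 0).
#' @return the updated \linkS4class{NeuronState}.
#' @export
receiveSpike <- function(state, params, weight) {
  if (length(weight) != 1L || !is.finite(weight) || weight < 0)
    stop("weight must be a single number >= 0")
  new("NeuronState", v = state@v,
      gGaba = state@gGaba + params@gGabaPeak * weight,
      tLastSpike = state@tLastSpike, spiked = state@spiked)
}
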