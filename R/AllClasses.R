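## S4 containers. All dynamic quantities use a fixed unit system in which
## conductance x voltage yields current directly: mV, ms, nS, pF, pA.
## The spontaneous current is specified in nA (the natural scale of the
## gamma parameters) and converted to pA inside the integrator.

#' Cell-class parameters
#'
#' Electrical constants and stochastic-drive parameters for one cell class.
#' The spontaneous depolarizing current is redrawn every time step from
#' Gamma(shape = \code{kappa}, scale = \code{beta}), in nA. \code{gGabaPeak}
#' is the peak inhibitory conductance a unit-weight synapse deposits onto a
#' neuron of this class; \code{gAhpPeak} scales the spike-triggered
#' after-hyperpolarization conductance, which decays exponentially with
#' \code{tauAhp} from the most recent spike only.
#'
#' @slot cellClass "PKJ" or "MLI".
#' @slot vThreshold spike threshold, mV.
#' @slot capacitance membrane capacitance, pF.
#' @slot gLeak leak conductance, nS.
#' @slot eLeak leak reversal potential, mV.
#' @slot gGabaPeak peak GABA conductance per unit synaptic weight, nS.
#' @slot eGaba GABA reversal potential, mV.
#' @slot tauGaba GABA conductance decay time constant, ms.
#' @slot gAhpPeak peak AHP conductance, nS.
#' @slot eAhp AHP reversal potential, mV.
#' @slot tauAhp AHP decay time constant, ms.
#' @slot kappa gamma shape of the spontaneous current (dimensionless;
#'   0 is the degenerate "no drive" case).
#' @slot beta gamma scale of the spontaneous current, nA.
#' @export
setClass("NeuronParams",
  representation(
    cellClass   = "character",
    vThreshold  = "numeric",
    capacitance = "numeric",
    gLeak       = "numeric",
    eLeak       = "numeric",
    gGabaPeak   = "numeric",
    eGaba       = "numeric",
    tauGaba     = "numeric",
    gAhpPeak    = "numeric",
    eAhp        = "numeric",
    tauAhp      = "numeric",
    kappa       = "numeric",
    beta        = "numeric"
  )
)

setValidity("NeuronParams", function(object) {
  msg <- character(0)
  num1 <- function(x) length(x) == 1L && is.finite(x)
  for (s in slotNames(object)[-1L])
    if (!num1(slot(object, s))) msg <- c(msg, paste0(s, " must be a finite scalar"))
  if (length(msg)) return(msg)
  if (!(object@cellClass %in% c("PKJ", "MLI")))
    msg <- c(msg, "cellClass must be 'PKJ' or 'MLI'")
  if (object@capacitance <= 0) msg <- c(msg, "capacitance must be > 0")
  if (object@gLeak < 0 || object@gGabaPeak < 0 || object@gAhpPeak < 0)
    msg <- c(msg, "conductance peaks must be >= 0")
  if (object@tauGaba <= 0 || object@tauAhp <= 0)
    msg <- c(msg, "time constants must be > 0")
  if (object@eGaba >= object@vThreshold)
    msg <- c(msg, "eGaba must lie below vThreshold")
  if (object@eAhp >= object@vThreshold)
    msg <- c(msg, "eAhp must lie below vThreshold")
  if (object@kappa < 0) msg <- c(msg, "kappa must be >= 0")
  if (object@beta <= 0) msg <- c(msg, "beta must be > 0")
  if (length(msg)) msg else TRUE
})

#' Per-neuron dynamic state
#'
#' The minimal state evolved by the single-neuron operations: membrane
#' potential, the summed decaying GABA conductance trace, and the time of the
#' most recent spike (\code{NA} = has never spiked).
#'
#' @slot v membrane potential, mV.
#' @slot gGaba summed synaptic conductance trace, nS (never negative).
#' @slot tLastSpike time of the most recent spike, ms, or \code{NA}.
#' @slot spiked did the neuron emit a spike on the last update?
#' @export
setClass("NeuronState",
  representation(v = "numeric", gGaba = "numeric",
                 tLastSpike = "numeric", spiked = "logical")
)

setValidity("NeuronState", function(object) {
  msg <- character(0)
  if (length(object@v) != 1L || !is.finite(object@v))
    msg <- c(msg, "v must be a finite scalar")
  if (length(object@gGaba) != 1L || !is.finite(object@gGaba) || object@gGaba < 0)
    msg <- c(msg, "gGaba must be a finite scalar >= 0")
  if (length(object@tLastSpike) != 1L)
    msg <- c(msg, "tLastSpike must be scalar (NA = never)")
  if (length(object@spiked) != 1L || is.na(object@spiked))
    msg <- c(msg, "spiked must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Network wiring recipe
#'
#' Geometry and probabilistic-connectivity parameters of the one-dimensional
#' parasagittal strip. The strip holds \code{nPkj} Purkinje-cell territories,
#' each with \code{mliPerPkj} interneurons of which the first
#' \code{lowerMliPerPkj} are flagged lower-molecular-layer (eligible for
#' Purkinje recurrent collaterals). Each MLI axon runs one way (left/right,
#' equal probability) across \code{mliAxonSpanPkjs} territories; each PKJ
#' collateral runs one way across \code{pkjCollateralSpanPkjs} territories.
#' Synapses form independently per eligible (source, target) pair with the
#' per-type probabilities; weights are uniform on (0, \code{wMax[type]}).
#'
#' @slot nPkj number of Purkinje cells (territories).
#' @slot mliPerPkj interneurons per territory.
#' @slot lowerMliPerPkj lower-molecular-layer interneurons per territory.
#' @slot pkjSpacingUm centre-to-centre territory spacing, micrometres
#'   (bookkeeping only; connectivity is territory-based).
#' @slot mliAxonSpanPkjs MLI axon span, in territories to one side.
#' @slot pkjCollateralSpanPkjs PKJ recurrent-collateral span, territories.
#' @slot pMliToPkj,pMliToMli,pPkjToMli per-candidate synapse probabilities.
#' @slot wMax named numeric: upper weight bound per connection type
#'   (\code{MLI_MLI}, \code{MLI_PKJ}, \code{PKJ_MLI}).
#' @slot seed wiring RNG seed.
#' @export
setClass("NetworkConfig",
  representation(
    nPkj = "integer", mliPerPkj = "integer", lowerMliPerPkj = "integer",
    pkjSpacingUm = "numeric", mliAxonSpanPkjs = "integer",
    pkjCollateralSpanPkjs = "integer",
    pMliToPkj = "numeric", pMliToMli = "numeric", pPkjToMli = "numeric",
    wMax = "numeric", seed = "integer"
  )
)

setValidity("NetworkConfig", function(object) {
  msg <- character(0)
  if (object@nPkj < 1L || object@mliPerPkj < 1L)
    msg <- c(msg, "counts must be >= 1")
  if (object@lowerMliPerPkj < 0L || object@lowerMliPerPkj > object@mliPerPkj)
    msg <- c(msg, "lowerMliPerPkj must lie in [0, mliPerPkj]")
  for (p in c(object@pMliToPkj, object@pMliToMli, object@pPkjToMli))
    if (!is.finite(p) || p < 0 || p > 1)
      msg <- c(msg, "probabilities must lie in [0, 1]")
  if (object@mliAxonSpanPkjs < 1L || object@mliAxonSpanPkjs >= object@nPkj)
    msg <- c(msg, "mliAxonSpanPkjs must be >= 1 and smaller than nPkj")
  if (object@pkjCollateralSpanPkjs < 1L ||
      object@pkjCollateralSpanPkjs >= object@nPkj)
    msg <- c(msg, "pkjCollateralSpanPkjs must be >= 1 and smaller than nPkj")
  need <- c("MLI_MLI", "MLI_PKJ", "PKJ_MLI")
  if (!identical(sort(names(object@wMax)), sort(need)) ||
      any(!is.finite(object@wMax)) || any(object@wMax <= 0))
    msg <- c(msg, "wMax must be positive and named MLI_MLI, MLI_PKJ, PKJ_MLI")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' A realised microcircuit
#'
#' Neurons, directed weighted synapses, the wiring recipe that generated
#' them, and the cell-class parameter sets. Neuron ids are 1..nPkj for
#' Purkinje cells followed by the interneurons in territory order.
#'
#' @slot neurons data.frame: id, class ("PKJ"/"MLI"), territory,
#'   within (index inside the territory; 0 for the PKJ), lowerMl (logical),
#'   posUm (soma position, micrometres), axonDir (+1 right / -1 left).
#' @slot synapses data.frame: source, target, type
#'   ("MLI_PKJ"/"MLI_MLI"/"PKJ_MLI"), weight.
#' @slot config the \linkS4class{NetworkConfig} used.
#' @slot params named list of \linkS4class{NeuronParams} ("PKJ", "MLI").
#' @export
setClass("CellNetwork",
  representation(neurons = "data.frame", synapses = "data.frame",
                 config = "NetworkConfig", params = "list")
)

setValidity("CellNetwork", function(object) {
  msg <- character(0)
  nr <- object@neurons
  sy <- object@synapses
  needN <- c("id", "class", "territory", "within", "lowerMl", "posUm", "axonDir")
  needS <- c("source", "target", "type", "weight")
  if (!all(needN %in% names(nr))) return("neurons is missing required columns")
  if (!all(needS %in% names(sy))) return("synapses is missing required columns")
  if (anyDuplicated(nr$id)) msg <- c(msg, "duplicate neuron ids")
  if (!all(nr$class %in% c("PKJ", "MLI"))) msg <- c(msg, "unknown cell class")
  if (!all(c("PKJ", "MLI") %in% names(object@params)) ||
      !all(vapply(object@params[c("PKJ", "MLI")], is, TRUE, "NeuronParams")))
    msg <- c(msg, "params must hold NeuronParams for PKJ and MLI")
  if (nrow(sy)) {
    if (!all(sy$source %in% nr$id) || !all(sy$target %in% nr$id))
      msg <- c(msg, "synapse endpoints must be neuron ids")
    if (any(sy$source == sy$target)) msg <- c(msg, "self-synapses are not allowed")
    if (anyDuplicated(sy[, c("source", "target")]))
      msg <- c(msg, "at most one synapse per ordered (source, target) pair")
    cls <- setNames(nr$class, nr$id)
    scl <- cls[as.character(sy$source)]
    tcl <- cls[as.character(sy$target)]
    if (any(scl == "PKJ" & tcl == "PKJ"))
      msg <- c(msg, "PKJ->PKJ synapses are not allowed")
    expect <- paste0(scl, "_", tcl)
    if (!all(sy$type == expect))
      msg <- c(msg, "synapse type must match endpoint classes")
    lower <- setNames(nr$lowerMl, nr$id)
    if (any(sy$type == "PKJ_MLI" & !lower[as.character(sy$target)]))
      msg <- c(msg, "PKJ->MLI targets must be lower-molecular-layer MLIs")
    wmax <- object@config@wMax[sy$type]
    if (any(sy$weight < 0 | sy$weight > wmax))
      msg <- c(msg, "synapse weights outside configured bounds")
    ## axon-direction/span consistency
    ter <- setNames(nr$territory, nr$id)
    dir <- setNames(nr$axonDir, nr$id)
    off <- ter[as.character(sy$target)] - ter[as.character(sy$source)]
    span <- ifelse(sy$type == "PKJ_MLI",
                   object@config@pkjCollateralSpanPkjs,
                   object@config@mliAxonSpanPkjs)
    ok <- sign(off) == dir[as.character(sy$source)] & abs(off) >= 1 &
      abs(off) <= span
    if (!all(ok))
      msg <- c(msg, "synapse offsets must respect axon direction and span")
  }
  if (length(msg)) msg else TRUE
})

#' Simulation settings
#'
#' @slot duration total simulated time, ms.
#' @slot dt integration step, ms. The per-step redraw of the spontaneous
#'   current makes the noise statistics dt-dependent, so dt is a model
#'   constant (0.25 ms), not a numerical knob.
#' @slot simSeed RNG seed for the dynamics (independent of the wiring seed).
#' @slot recordIds neuron ids whose membrane potential is recorded.
#' @slot recordStride record every this-many steps.
#' @export
setClass("SimSettings",
  representation(duration = "numeric", dt = "numeric", simSeed = "integer",
                 recordIds = "integer", recordStride = "integer")
)

setValidity("SimSettings", function(object) {
  msg <- character(0)
  if (!is.finite(object@dt) || object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (!is.finite(object@duration) || object@duration < object@dt)
    msg <- c(msg, "duration must be >= dt")
  if (length(object@simSeed) != 1L || is.na(object@simSeed))
    msg <- c(msg, "simSeed must be a single integer")
  if (object@recordStride < 1L) msg <- c(msg, "recordStride must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Simulation result
#'
#' Spike trains (and optional voltage traces) plus everything needed to
#' re-run the simulation exactly: the network (which embeds its wiring
#' config and seed) and the settings.
#'
#' @slot spikes data.frame (id, time) sorted by time then id; times are
#'   integer multiples of dt in [0, duration).
#' @slot vTime sample times of the voltage traces, ms (may be empty).
#' @slot v matrix of membrane potentials, one column per recorded neuron
#'   (column names are neuron ids).
#' @slot network the simulated \linkS4class{CellNetwork}.
#' @slot settings the \linkS4class{SimSettings} used.
#' @export
setClass("SimResult",
  representation(spikes = "data.frame", vTime = "numeric", v = "matrix",
                 network = "CellNetwork", settings = "SimSettings")
)

setValidity("SimResult", function(object) {
  msg <- character(0)
  sp <- object@spikes
  if (!all(c("id", "time") %in% names(sp)))
    return("spikes must have columns id, time")
  if (nrow(sp)) {
    dt <- object@settings@dt
    if (any(sp$time < 0) || any(sp$time > object@settings@duration))
      msg <- c(msg, "spike times must lie in [0, duration]")
    if (max(abs(sp$time / dt - round(sp$time / dt))) > 1e-9)
      msg <- c(msg, "spike times must be integer multiples of dt")
    if (is.unsorted(sp$time)) msg <- c(msg, "spikes must be sorted by time")
    if (any(vapply(split(sp$time, sp$id), is.unsorted, TRUE)))
      msg <- c(msg, "per-neuron spike times must be increasing")
  }
  if (length(msg)) msg else TRUE
})
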