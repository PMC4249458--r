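#' @rdname CellNetwork-accessors
#' @export
setGeneric("neurons", function(x) standardGeneric("neurons"))

#' @rdname CellNetwork-accessors
#' @export
setGeneric("synapses", function(x) standardGeneric("synapses"))

#' @rdname CellNetwork-accessors
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))

#' @rdname CellNetwork-accessors
#' @export
setGeneric("nSynapses", function(x) standardGeneric("nSynapses"))

#' @rdname SimResult-accessors
#' @export
setGeneric("spikeTrains", function(x, ...) standardGeneric("spikeTrains"))

#' @rdname SimResult-accessors
#' @export
setGeneric("spikeTimes", function(x, id) standardGeneric("spikeTimes"))

#' Accessors for CellNetwork objects
#'
#' \code{neurons()} and \code{synapses()} return the underlying data.frames;
#' \code{nNeurons()} and \code{nSynapses()} their row counts.
#'
#' @param x a \linkS4class{CellNetwork}.
#' @return data.frames / integer counts.
#' @name CellNetwork-accessors
#' @aliases neurons,CellNetwork-method synapses,CellNetwork-method
#'   nNeurons,CellNetwork-method nSynapses,CellNetwork-method
NULL

setMethod("neurons", "CellNetwork", function(x) x@neurons)
setMethod("synapses", "CellNetwork", function(x) x@synapses)
setMethod("nNeurons", "CellNetwork", function(x) nrow(x@neurons))
setMethod("nSynapses", "CellNetwork", function(x) nrow(x@synapses))

#' Accessors for SimResult objects
#'
#' \code{spikeTrains()} returns a named list with one sorted numeric vector
#' of spike times (ms) per neuron (including silent neurons, as length-0
#' vectors); \code{spikeTimes()} the train of a single neuron.
#'
#' @param x a \linkS4class{SimResult}.
#' @param id a neuron id.
#' @param ... unused.
#' @return list of numeric vectors, or one numeric vector.
#' @name SimResult-accessors
#' @aliases spikeTrains,SimResult-method spikeTimes,SimResult-method
NULL

setMethod("spikeTrains", "SimResult", function(x, ...) {
  ids <- x@network@neurons$id
  split(x@spikes$time, factor(x@spikes$id, levels = ids))
})

setMethod("spikeTimes", "SimResult", function(x, id) {
  x@spikes$time[x@spikes$id == id]
})

setMethod("show", "NeuronParams", function(object) {
  cat(sprintf("NeuronParams <%s>\n", object@cellClass))
  cat(sprintf("  V_th %g mV | C %g pF | g_leak %g nS -> E %g mV\n",
              object@vThreshold, object@capacitance, object@gLeak, object@eLeak))
  cat(sprintf("  GABA: peak %g nS, E %g mV, tau %g ms\n",
              object@gGabaPeak, object@eGaba, object@tauGaba))
  cat(sprintf("  AHP:  peak %g nS, E %g mV, tau %g ms\n",
              object@gAhpPeak, object@eAhp, object@tauAhp))
  cat(sprintf("  I_spont ~ Gamma(shape %g, scale %g nA); mean %.4g nA\n",
              object@kappa, object@beta, object@kappa * object@beta))
})

setMethod("show", "NetworkConfig", function(object) {
  cat(sprintf("NetworkConfig: %d PKJ x %d MLI (lower %d), span %d/%d, seed %d\n",
              object@nPkj, object@mliPerPkj, object@lowerMliPerPkj,
              object@mliAxonSpanPkjs, object@pkjCollateralSpanPkjs, object@seed))
  cat(sprintf("  p(MLI->PKJ) %.4g  p(MLI->MLI) %.4g  p(PKJ->MLI) %.4g\n",
              object@pMliToPkj, object@pMliToMli, object@pPkjToMli))
})

setMethod("show", "CellNetwork", function(object) {
  tab <- table(object@synapses$type)
  cat(sprintf("CellNetwork: %d neurons (%d PKJ, %d MLI), %d synapses\n",
              nrow(object@neurons), sum(object@neurons$class == "PKJ"),
              sum(object@neurons$class == "MLI"), nrow(object@synapses)))
  if (length(tab))
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = "  "), "\n")
})

setMethod("show", "SimSettings", function(object) {
  cat(sprintf("SimSettings: %g ms at dt %g ms (seed %d)\n",
              object@duration, object@dt, object@simSeed))
})

setMethod("show", "SimResult", function(object) {
  cat(sprintf("SimResult: %d spikes from %d neurons over %g s\n",
              nrow(object@spikes), nrow(object@network@neurons),
              object@settings@duration / 1000))
  if (length(object@vTime))
    cat(sprintf("  voltage traces: %d neurons x %d samples\n",
                ncol(object@v), length(object@vTime)))
})
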