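## simulation engine front end: packs a CellNetwork for the compiled core,
## runs it under a seeded RNG stream, and wraps the result.

#' Simulation settings
#'
#' @param duration total simulated time, ms.
#' @param dt integration step, ms. 0.25 ms is a model constant: the
#'   spontaneous current is redrawn every step, so changing dt changes the
#'   effective noise, not just the integration error.
#' @param simSeed dynamics RNG seed, independent of the wiring seed.
#' @param recordIds neuron ids whose membrane potential to record.
#' @param recordStride keep every \code{recordStride}-th sample.
#' @return a validated \linkS4class{SimSettings}.
#' @export
simSettings <- function(duration, dt = 0.25, simSeed = 1L,
                        recordIds = integer(0), recordStride = 1L) {
  new("SimSettings", duration = duration, dt = dt,
      simSeed = as.integer(simSeed), recordIds = as.integer(recordIds),
      recordStride = as.integer(recordStride))
}

## Per-neuron parameter vectors + CSR synapse arrays for the compiled core.
## Synapses are sorted by (source, target) so that same-step conductance
## deposits always sum in the same order.
.packNetwork <- function(net, dt) {
  nr <- net@neurons
  n <- nrow(nr)
  pk <- net@params[["PKJ"]]; ml <- net@params[["MLI"]]
  pick <- function(s) ifelse(nr$class == "PKJ", slot(pk, s), slot(ml, s))
  sy <- net@synapses
  if (nrow(sy)) {
    sy <- sy[order(sy$source, sy$target), , drop = FALSE]
    ## the deposited conductance is the peak of the *target* class x weight
    gbar <- ifelse(nr$class[match(sy$target, nr$id)] == "PKJ",
                   pk@gGabaPeak, ml@gGabaPeak)
    inc <- gbar * sy$weight
  } else inc <- numeric(0)
  idx <- match(sy$source, nr$id)
  list(
    vth = pick("vThreshold"), cap = pick("capacitance"), gl = pick("gLeak"),
    el = pick("eLeak"), egaba = pick("eGaba"),
    dgaba = exp(-dt / pick("tauGaba")),
    gahpPeak = pick("gAhpPeak"), eahp = pick("eAhp"),
    dahp = exp(-dt / pick("tauAhp")),
    kappa = pick("kappa"), beta = pick("beta"),
    synPtr = c(0L, cumsum(tabulate(idx, n))),
    synTgt = match(sy$target, nr$id) - 1L,
    synInc = inc, n = n)
}

#' Run a network simulation
#'
#' Integrates the whole network with fixed-step forward Euler. Per step,
#' every neuron draws a fresh spontaneous current, the membrane is updated
#' using the conductance traces valid at the step start, threshold crossings
#' are detected after the update (spike time recorded as k*dt for step k,
#' counted from 0), and all spikes of the step are then delivered so their
#' conductance first acts on the next step (zero transmission delay,
#' one-step causality). Results are bit-reproducible from
#' \code{(net@config@seed, settings@simSeed)}.
#'
#' \code{clampIds} names neurons that are frozen at rest: they draw no
#' random numbers, never cross threshold, and only fire if listed in
#' \code{forcedSpikes} (data.frame id, time). Forced spikes are delivered to
#' the targets with the same one-step causality.
#'
#' @param net a \linkS4class{CellNetwork}.
#' @param settings a \linkS4class{SimSettings}.
#' @param clampIds neuron ids to clamp (see Details).
#' @param forcedSpikes data.frame (id, time) of imposed spikes, or NULL.
#' @return a \linkS4class{SimResult}.
#' @examples
#' net <- buildNetwork(networkConfig(seed = 1))
#' res <- runSimulation(net, simSettings(1000, simSeed = 2))
#' head(res@spikes)
#' @export
runSimulation <- function(net, settings, clampIds = integer(0),
                          forcedSpikes = NULL) {
  validObject(net); validObject(settings)
  dt <- settings@dt
  nSteps <- as.integer(round(settings@duration / dt))
  pk <- .packNetwork(net, dt)
  ids <- net@neurons$id
  clamped <- ids %in% clampIds
  if (is.null(forcedSpikes))
    forcedSpikes <- data.frame(id = integer(0), time = numeric(0))
  if (nrow(forcedSpikes)) {
    if (!all(forcedSpikes$id %in% ids)) stop("forced spike id not in network")
    if (any(forcedSpikes$time < 0 | forcedSpikes$time > settings@duration))
      stop("forced spike time outside the simulated window")
    forcedSpikes <- forcedSpikes[order(forcedSpikes$time), , drop = FALSE]
  }
  fIdx <- match(forcedSpikes$id, ids)
  fStep <- as.integer(round(forcedSpikes$time / dt))
  fStep <- pmin(fStep, nSteps - 1L)

  out <- .withSeed(settings@simSeed,
    .cppSimulate(pk$vth, pk$cap, pk$gl, pk$el, pk$egaba, pk$dgaba,
                 pk$gahpPeak, pk$eahp, pk$dahp, pk$kappa, pk$beta,
                 pk$synPtr, pk$synTgt, pk$synInc,
                 nSteps, dt, clamped,
                 fIdx, fStep,
                 match(settings@recordIds, ids), settings@recordStride))

  sp <- data.frame(id = ids[out$id], time = out$time)
  sp <- sp[order(sp$time, sp$id), , drop = FALSE]
  rownames(sp) <- NULL
  v <- t(out$v)
  colnames(v) <- as.character(settings@recordIds)
  new("SimResult", spikes = sp, vTime = out$vTime, v = v,
      network = net, settings = settings)
}

#' Impose a single spike on a clamped neuron
#'
#' Identical to [runSimulation()] except that the named neuron is clamped
#' (no spontaneous drive, no threshold spiking) and emits exactly one spike
#' at \code{tFire}. Because clamped neurons draw no random numbers, the rest
#' of the network sees the same random stream with or without the forced
#' spike, which yields paired trials that isolate the synaptic effect.
#'
#' @inheritParams runSimulation
#' @param neuronId the neuron to clamp and fire.
#' @param tFire spike time, ms (within the simulated window).
#' @return a \linkS4class{SimResult}.
#' @export
forceSpike <- function(net, settings, neuronId, tFire) {
  if (!neuronId %in% net@neurons$id) stop("neuronId not in network")
  runSimulation(net, settings, clampIds = neuronId,
                forcedSpikes = data.frame(id = neuronId, time = tFire))
}

#' Write / read spike trains as CSV
#'
#' \code{writeSpikes()} writes a two-column CSV (neuron_id, time_ms), sorted
#' by time then id, plus a JSON sidecar (\code{<path>.json}) recording the
#' seeds, duration and step. \code{readSpikes()} loads the CSV back and
#' checks per-neuron monotonicity.
#'
#' @param result a \linkS4class{SimResult}.
#' @param path CSV file path.
#' @return \code{writeSpikes()} the path, invisibly; \code{readSpikes()} a
#'   data.frame (id, time).
#' @export
writeSpikes <- function(result, path) {
  sp <- result@spikes
  write.csv(data.frame(neuron_id = sp$id,
                       time_ms = sprintf("%.17g", sp$time)),
            path, row.names = FALSE)
  st <- result@settings
  jsonlite::write_json(
    list(duration_ms = st@duration, dt_ms = st@dt, sim_seed = st@simSeed,
         wiring_seed = result@network@config@seed,
         n_neurons = nrow(result@network@neurons),
         package = as.character(packageVersion("purkinet"))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSpikes
#' @export
readSpikes <- function(path) {
  d <- read.csv(path, colClasses = c(time_ms = "character"))
  sp <- data.frame(id = d$neuron_id, time = as.numeric(d$time_ms))
  if (any(vapply(split(sp$time, sp$id), is.unsorted, TRUE)))
    stop("per-neuron spike times are not monotone in ", path)
  sp
}
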