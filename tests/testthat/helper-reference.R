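# Scalar reference engine: a deliberately plain, loop-per-neuron
# re-implementation of the update rule, written independently of the
# compiled engine. Same RNG discipline (one gamma draw per non-clamped
# neuron per step, ascending id), same conventions (threshold after update,
# spike time k*dt, decay-then-deliver, 1e-30 flush), so results must agree
# bit-for-bit.
refSimulate <- function(net, duration, dt, simSeed,
                        clampIds = integer(0), forced = NULL) {
  nr <- net@neurons
  n <- nrow(nr)
  P <- lapply(nr$class, function(cl) net@params[[cl]])
  sy <- net@synapses
  sy <- sy[order(sy$source, sy$target), , drop = FALSE]
  inc <- vapply(seq_len(nrow(sy)), function(e) {
    tgt <- which(nr$id == sy$target[e])
    P[[tgt]]@gGabaPeak * sy$weight[e]
  }, 1)
  outBySrc <- split(seq_len(nrow(sy)), factor(sy$source, levels = nr$id))
  clamped <- nr$id %in% clampIds
  if (is.null(forced)) forced <- data.frame(id = integer(0), time = numeric(0))
  fStep <- as.integer(round(forced$time / dt))

  V <- vapply(P, function(p) p@eLeak, 1)
  ggaba <- numeric(n)
  ahp <- numeric(n)
  nSteps <- as.integer(round(duration / dt))
  ids <- integer(0); times <- numeric(0)

  set.seed(simSeed)
  for (k in seq_len(nSteps) - 1L) {
    now <- k * dt
    spikers <- integer(0)
    for (i in seq_len(n)) {
      if (clamped[i]) next
      p <- P[[i]]
      I <- if (p@kappa > 0)
        rgamma(1, shape = p@kappa, scale = p@beta) * 1000 else 0
      v <- V[i]
      v <- v + (dt / p@capacitance) *
        (-p@gLeak * (v - p@eLeak) - ahp[i] * (v - p@eAhp) -
           ggaba[i] * (v - p@eGaba) + I)
      V[i] <- v
      if (v >= p@vThreshold) {
        spikers <- c(spikers, i)
        ids <- c(ids, nr$id[i]); times <- c(times, now)
      }
    }
    for (i in seq_len(n)) {
      ggaba[i] <- ggaba[i] * exp(-dt / P[[i]]@tauGaba)
      if (ggaba[i] < 1e-30) ggaba[i] <- 0
      ahp[i] <- ahp[i] * exp(-dt / P[[i]]@tauAhp)
      if (ahp[i] < 1e-30) ahp[i] <- 0
    }
    for (s in spikers) {
      for (e in outBySrc[[s]])
        ggaba[which(nr$id == sy$target[e])] <-
          ggaba[which(nr$id == sy$target[e])] + inc[e]
      ahp[s] <- P[[s]]@gAhpPeak
    }
    for (f in which(fStep == k)) {
      s <- which(nr$id == forced$id[f])
      ids <- c(ids, nr$id[s]); times <- c(times, now)
      for (e in outBySrc[[s]])
        ggaba[which(nr$id == sy$target[e])] <-
          ggaba[which(nr$id == sy$target[e])] + inc[e]
      ahp[s] <- P[[s]]@gAhpPeak
    }
  }
  out <- data.frame(id = ids, time = times)
  out[order(out$time, out$id), , drop = FALSE]
}

# Two spontaneously active neurons: MLI (id 2) inhibiting a PKJ (id 1).
activePairNetwork <- function(weight = 1) {
  cfg <- networkConfig(seed = 0L,
                       wMax = c(MLI_MLI = 1, MLI_PKJ = max(1.25, weight),
                                PKJ_MLI = 1))
  nr <- data.frame(id = 1:2, class = c("PKJ", "MLI"), territory = c(1L, 2L),
                   within = c(0L, 1L), lowerMl = FALSE,
                   posUm = c(0, 64), axonDir = c(1L, -1L))
  sy <- data.frame(source = 2L, target = 1L, type = "MLI_PKJ",
                   weight = weight)
  new("CellNetwork", neurons = nr, synapses = sy, config = cfg,
      params = list(PKJ = neuronParams("PKJ"), MLI = neuronParams("MLI")))
}

# Three neurons with a little convergence/divergence for engine checks:
# MLI 3 -> {PKJ 1, MLI 2}, PKJ 1 -> MLI 2 is not allowed (2 not lower),
# so use MLI 2 -> PKJ 1 as the second edge.
threeNeuronNetwork <- function() {
  cfg <- networkConfig(seed = 0L)
  nr <- data.frame(id = 1:3, class = c("PKJ", "MLI", "MLI"),
                   territory = c(1L, 2L, 3L), within = c(0L, 1L, 1L),
                   lowerMl = FALSE, posUm = c(0, 64, 128),
                   axonDir = c(1L, -1L, -1L))
  sy <- data.frame(source = c(2L, 3L, 3L), target = c(1L, 1L, 2L),
                   type = c("MLI_PKJ", "MLI_PKJ", "MLI_MLI"),
                   weight = c(0.8, 1.1, 0.5))
  new("CellNetwork", neurons = nr, synapses = sy, config = cfg,
      params = list(PKJ = neuronParams("PKJ"), MLI = neuronParams("MLI")))
}
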