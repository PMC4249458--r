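## network builder: the 1-D parasagittal strip, its eligibility rules and
## the seeded probabilistic synapse generator.

## Evaluate expr under a temporary RNG seed, restoring the caller's stream.
.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## Mean number of candidate territories to one (random) side of a source in
## territory 1..nPkj, for an axon of the given span, with truncation at the
## strip boundaries.
.meanSpanTerritories <- function(nPkj, span) {
  t <- seq_len(nPkj)
  mean((pmin(span, t - 1) + pmin(span, nPkj - t)) / 2)
}

#' Derive per-candidate synapse probabilities from convergence targets
#'
#' The anatomical targets are expressed as average out-degrees: each MLI
#' contacts \code{mliToPkj} Purkinje cells and \code{mliToMli} other MLIs on
#' average (equivalently, by symmetry, each PKJ receives 20 MLI inputs and
#' each MLI 4 MLI inputs with the default geometry), and each PKJ contacts
#' \code{pkjToMli} lower-molecular-layer MLIs. The probability for a type is
#' the target divided by the number of candidates the axon can reach.
#'
#' With \code{boundary = "interior"} the candidate count is the idealised
#' full-span count (e.g. 8 territories x 1 PKJ = 8 candidates, giving
#' p = 2/8 = 0.25), which realises the targets only for neurons whose span
#' is not cut by the strip ends. With \code{boundary = "average"} the
#' candidate count is averaged over the actual finite strip, so the
#' *population-average* convergence and divergence hit the targets exactly;
#' this is the default used by [networkConfig()], since the circuit is
#' specified by its average connectivity.
#'
#' @param nPkj,mliPerPkj,lowerMliPerPkj,mliAxonSpanPkjs,pkjCollateralSpanPkjs
#'   geometry, as in \linkS4class{NetworkConfig}.
#' @param mliToPkj,mliToMli,pkjToMli target average out-degrees per type.
#' @param boundary candidate-count convention, see Details.
#' @return named numeric: \code{pMliToPkj}, \code{pMliToMli}, \code{pPkjToMli}.
#' @examples
#' deriveProbabilities()                        # 0.25, 0.05, 0.5
#' deriveProbabilities(boundary = "average")    # finite-strip correction
#' @export
deriveProbabilities <- function(nPkj = 16L, mliPerPkj = 10L,
                                lowerMliPerPkj = 3L, mliAxonSpanPkjs = 8L,
                                pkjCollateralSpanPkjs = 2L,
                                mliToPkj = 2, mliToMli = 4, pkjToMli = 3,
                                boundary = c("interior", "average")) {
  boundary <- match.arg(boundary)
  terMli <- switch(boundary,
    interior = mliAxonSpanPkjs,
    average  = .meanSpanTerritories(nPkj, mliAxonSpanPkjs))
  terPkj <- switch(boundary,
    interior = pkjCollateralSpanPkjs,
    average  = .meanSpanTerritories(nPkj, pkjCollateralSpanPkjs))
  cand <- c(pMliToPkj = terMli,                      # one PKJ per territory
            pMliToMli = terMli * mliPerPkj,
            pPkjToMli = terPkj * lowerMliPerPkj)
  p <- c(mliToPkj, mliToMli, pkjToMli) / cand
  if (any(p > 1))
    stop("infeasible target: required probability exceeds 1 (",
         paste(names(cand)[p > 1], collapse = ", "), ")")
  names(p) <- names(cand)
  p
}

#' Network wiring recipe
#'
#' Constructs a \linkS4class{NetworkConfig}. Defaults model a 1 mm
#' parasagittal microzone: 16 Purkinje cells at 64 um spacing, 10 MLIs per
#' PKJ (3 of them lower-molecular-layer), MLI axons spanning 8 territories
#' to one randomly chosen side and PKJ recurrent collaterals spanning 2.
#' Default probabilities come from [deriveProbabilities()] with
#' \code{boundary = "average"}, so the realised population-average
#' convergence/divergence equals the anatomical targets
#' (20 MLI inputs per PKJ, 4 MLI inputs per MLI, 3 MLI targets per PKJ,
#' 1 PKJ input per eligible MLI) on the finite strip.
#'
#' @param nPkj,mliPerPkj,lowerMliPerPkj,pkjSpacingUm,mliAxonSpanPkjs,pkjCollateralSpanPkjs
#'   geometry; see \linkS4class{NetworkConfig}.
#' @param pMliToPkj,pMliToMli,pPkjToMli per-candidate probabilities; defaults
#'   derived from the anatomical targets.
#' @param wMax per-type upper weight bounds.
#' @param seed wiring RNG seed.
#' @return a validated \linkS4class{NetworkConfig}.
#' @export
networkConfig <- function(nPkj = 16L, mliPerPkj = 10L, lowerMliPerPkj = 3L,
                          pkjSpacingUm = 64, mliAxonSpanPkjs = 8L,
                          pkjCollateralSpanPkjs = 2L,
                          pMliToPkj = NULL, pMliToMli = NULL, pPkjToMli = NULL,
                          wMax = c(MLI_MLI = 1, MLI_PKJ = 1.25, PKJ_MLI = 1),
                          seed = 1L) {
  p <- deriveProbabilities(nPkj, mliPerPkj, lowerMliPerPkj, mliAxonSpanPkjs,
                           pkjCollateralSpanPkjs, boundary = "average")
  new("NetworkConfig",
      nPkj = as.integer(nPkj), mliPerPkj = as.integer(mliPerPkj),
      lowerMliPerPkj = as.integer(lowerMliPerPkj),
      pkjSpacingUm = pkjSpacingUm,
      mliAxonSpanPkjs = as.integer(mliAxonSpanPkjs),
      pkjCollateralSpanPkjs = as.integer(pkjCollateralSpanPkjs),
      pMliToPkj = if (is.null(pMliToPkj)) unname(p["pMliToPkj"]) else pMliToPkj,
      pMliToMli = if (is.null(pMliToMli)) unname(p["pMliToMli"]) else pMliToMli,
      pPkjToMli = if (is.null(pPkjToMli)) unname(p["pPkjToMli"]) else pPkjToMli,
      wMax = wMax[c("MLI_MLI", "MLI_PKJ", "PKJ_MLI")],
      seed = as.integer(seed))
}

## Neuron layout for a config: PKJs get ids 1..nPkj, then MLIs in territory
## order; the first lowerMliPerPkj MLIs of each territory are lower-ML.
.layoutNeurons <- function(config) {
  nP <- config@nPkj; mpp <- config@mliPerPkj
  pkj <- data.frame(id = seq_len(nP), class = "PKJ",
                    territory = seq_len(nP), within = 0L, lowerMl = FALSE,
                    posUm = (seq_len(nP) - 1) * config@pkjSpacingUm)
  ter <- rep(seq_len(nP), each = mpp)
  within <- rep(seq_len(mpp), times = nP)
  mli <- data.frame(id = nP + seq_len(nP * mpp), class = "MLI",
                    territory = ter, within = within,
                    lowerMl = within <= config@lowerMliPerPkj,
                    posUm = (ter - 1) * config@pkjSpacingUm +
                      (within - 1) * config@pkjSpacingUm / mpp)
  rbind(pkj, mli)
}

#' Generate a microcircuit
#'
#' Realises a \linkS4class{CellNetwork} from a wiring recipe, deterministically
#' for a given \code{config@seed}. The draw sequence is fixed and documented
#' so that a run can be replayed independently: (1) one uniform per MLI for
#' its axon direction (u < 0.5 means rightward); (2) for each MLI in id
#' order, one uniform per candidate PKJ (territories at offsets 1..span on
#' the drawn side, truncated at the strip ends, nearest first), forming a
#' synapse when u < pMliToPkj, with the weight drawn Unif(0, wMax) right
#' after each formed synapse; then one uniform per candidate MLI (same
#' territory order, within-territory index 1..mliPerPkj); (3) one uniform
#' per PKJ for its collateral direction; (4) for each PKJ in id order, one
#' uniform per lower-ML MLI of the territories at offsets
#' 1..pkjCollateralSpanPkjs on the drawn side, again with the weight drawn
#' immediately on formation. Autapses cannot arise (own territory is outside
#' every span) and each ordered pair is visited once.
#'
#' @param config a \linkS4class{NetworkConfig}.
#' @param pkjParams,mliParams \linkS4class{NeuronParams} used later by the
#'   simulator; stored with the network.
#' @return a validated \linkS4class{CellNetwork}.
#' @examples
#' net <- buildNetwork(networkConfig(seed = 7))
#' nSynapses(net)
#' @export
buildNetwork <- function(config, pkjParams = neuronParams("PKJ"),
                         mliParams = neuronParams("MLI")) {
  validObject(config)
  nr <- .layoutNeurons(config)
  nP <- config@nPkj; mpp <- config@mliPerPkj
  mliIds <- nr$id[nr$class == "MLI"]
  wmax <- config@wMax

  src <- integer(0); tgt <- integer(0); typ <- character(0); wt <- numeric(0)
  k <- 0L
  add <- function(s, t, ty) {
    k <<- k + 1L
    src[k] <<- s; tgt[k] <<- t; typ[k] <<- ty
    wt[k] <<- runif(1, 0, wmax[[ty]])
  }

  .withSeed(config@seed, {
    mliDir <- ifelse(runif(nP * mpp) < 0.5, 1L, -1L)
    for (m in seq_len(nP * mpp)) {
      t0 <- (m - 1L) %/% mpp + 1L
      ters <- t0 + mliDir[m] * seq_len(config@mliAxonSpanPkjs)
      ters <- ters[ters >= 1L & ters <= nP]
      for (tt in ters)
        if (runif(1) < config@pMliToPkj) add(mliIds[m], tt, "MLI_PKJ")
      for (tt in ters)
        for (j in seq_len(mpp))
          if (runif(1) < config@pMliToMli)
            add(mliIds[m], nP + (tt - 1L) * mpp + j, "MLI_MLI")
    }
    pkjDir <- ifelse(runif(nP) < 0.5, 1L, -1L)
    for (p in seq_len(nP)) {
      ters <- p + pkjDir[p] * seq_len(config@pkjCollateralSpanPkjs)
      ters <- ters[ters >= 1L & ters <= nP]
      for (tt in ters)
        for (j in seq_len(config@lowerMliPerPkj))
          if (runif(1) < config@pPkjToMli)
            add(p, nP + (tt - 1L) * mpp + j, "PKJ_MLI")
    }
    nr$axonDir <- c(pkjDir, mliDir)
  })

  sy <- data.frame(source = src, target = tgt, type = typ, weight = wt)
  new("CellNetwork", neurons = nr, synapses = sy, config = config,
      params = list(PKJ = pkjParams, MLI = mliParams))
}

#' Prune a random subset of synapses of one type
#'
#' Removes \code{round(fraction * N)} synapses of the given connection type,
#' chosen uniformly at random without replacement; all other synapses are
#' untouched.
#'
#' @param net a \linkS4class{CellNetwork}.
#' @param connType "MLI_MLI" or "PKJ_MLI" (any present type is accepted).
#' @param fraction proportion to remove, in [0, 1].
#' @param seed optional RNG seed for the prune draw; if \code{NULL}, the
#'   current RNG stream is used.
#' @return the pruned \linkS4class{CellNetwork}.
#' @export
pruneSynapses <- function(net, connType, fraction, seed = NULL) {
  if (!connType %in% c("MLI_MLI", "MLI_PKJ", "PKJ_MLI"))
    stop("unknown connection type: ", connType)
  if (!is.finite(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]")
  idx <- which(net@synapses$type == connType)
  k <- round(fraction * length(idx))
  if (k > 0) {
    drop <- if (is.null(seed)) sample(idx, k)
            else .withSeed(seed, sample(idx, k))
    net@synapses <- net@synapses[-drop, , drop = FALSE]
    rownames(net@synapses) <- NULL
  }
  net
}

## Single-neuron and two-neuron networks used by the isolated-cell and
## feedforward experiments (and handy in tests).
.soloNetwork <- function(params) {
  other <- if (params@cellClass == "PKJ") neuronParams("MLI")
           else neuronParams("PKJ")
  cfg <- networkConfig(seed = 0L)
  nr <- data.frame(id = 1L, class = params@cellClass, territory = 1L,
                   within = if (params@cellClass == "PKJ") 0L else 1L,
                   lowerMl = FALSE, posUm = 0, axonDir = 1L)
  pl <- list(params, other)
  names(pl) <- c(params@cellClass, other@cellClass)
  new("CellNetwork", neurons = nr,
      synapses = data.frame(source = integer(0), target = integer(0),
                            type = character(0), weight = numeric(0)),
      config = cfg, params = pl)
}

## PKJ (id 1) receiving one MLI (id 2) synapse whose *weight* is chosen so
## that gGabaPeak(PKJ) * weight equals the requested peak conductance in nS.
.pairNetwork <- function(peakNs, pkjParams = neuronParams("PKJ"),
                         mliParams = neuronParams("MLI")) {
  weight <- peakNs / pkjParams@gGabaPeak
  cfg <- networkConfig(seed = 0L,
                       wMax = c(MLI_MLI = 1, MLI_PKJ = max(1.25, weight, 1e-12),
                                PKJ_MLI = 1))
  nr <- data.frame(id = 1:2, class = c("PKJ", "MLI"), territory = c(1L, 2L),
                   within = c(0L, 1L), lowerMl = FALSE,
                   posUm = c(0, 64), axonDir = c(1L, -1L))
  sy <- data.frame(source = 2L, target = 1L, type = "MLI_PKJ", weight = weight)
  new("CellNetwork", neurons = nr, synapses = sy, config = cfg,
      params = list(PKJ = pkjParams, MLI = mliParams))
}

#' Export / import a network as plain text
#'
#' \code{writeNetwork()} writes three files next to \code{basePath}: an edge
#' list (\code{<basePath>.edges.csv} with columns source_id, target_id, type,
#' weight; weights printed with 17 significant digits so the round-trip is
#' bit-exact), the neuron table (\code{<basePath>.neurons.csv}) and a JSON
#' sidecar (\code{<basePath>.json}) with the wiring config, seed and neuron
#' parameters. \code{readNetwork()} reconstructs the
#' \linkS4class{CellNetwork} exactly.
#'
#' @param net a \linkS4class{CellNetwork}.
#' @param basePath path prefix for the three files.
#' @return \code{writeNetwork()} the basePath, invisibly;
#'   \code{readNetwork()} the reconstructed network.
#' @export
writeNetwork <- function(net, basePath) {
  sy <- net@synapses
  edges <- data.frame(source_id = sy$source, target_id = sy$target,
                      type = sy$type,
                      weight = sprintf("%.17g", sy$weight))
  write.csv(edges, paste0(basePath, ".edges.csv"), row.names = FALSE)
  write.csv(net@neurons, paste0(basePath, ".neurons.csv"), row.names = FALSE)
  cfg <- net@config
  cfgList <- setNames(lapply(slotNames(cfg), function(s) slot(cfg, s)),
                      slotNames(cfg))
  cfgList$wMax <- as.list(cfgList$wMax)  # keep names in JSON
  meta <- list(
    config = cfgList,
    params = lapply(net@params, function(p)
      setNames(lapply(slotNames(p), function(s) slot(p, s)), slotNames(p))),
    package = as.character(packageVersion("purkinet")))
  jsonlite::write_json(meta, paste0(basePath, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(basePath)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(basePath) {
  meta <- jsonlite::read_json(paste0(basePath, ".json"), simplifyVector = TRUE)
  cfgl <- meta$config
  cfg <- new("NetworkConfig",
             nPkj = as.integer(cfgl$nPkj), mliPerPkj = as.integer(cfgl$mliPerPkj),
             lowerMliPerPkj = as.integer(cfgl$lowerMliPerPkj),
             pkjSpacingUm = cfgl$pkjSpacingUm,
             mliAxonSpanPkjs = as.integer(cfgl$mliAxonSpanPkjs),
             pkjCollateralSpanPkjs = as.integer(cfgl$pkjCollateralSpanPkjs),
             pMliToPkj = cfgl$pMliToPkj, pMliToMli = cfgl$pMliToMli,
             pPkjToMli = cfgl$pPkjToMli,
             wMax = unlist(cfgl$wMax)[c("MLI_MLI", "MLI_PKJ", "PKJ_MLI")],
             seed = as.integer(cfgl$seed))
  params <- lapply(meta$params, function(pl)
    do.call(neuronParams, c(list(cellClass = pl$cellClass),
                            pl[setdiff(names(pl), "cellClass")])))
  nr <- read.csv(paste0(basePath, ".neurons.csv"),
                 colClasses = c(class = "character"))
  edges <- read.csv(paste0(basePath, ".edges.csv"),
                    colClasses = c(type = "character", weight = "character"))
  sy <- data.frame(source = edges$source_id, target = edges$target_id,
                   type = edges$type, weight = as.numeric(edges$weight))
  new("CellNetwork", neurons = nr, synapses = sy, config = cfg,
      params = params[c("PKJ", "MLI")])
}
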