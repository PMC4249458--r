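## scripted experiments: isolated firing, intact-network statistics,
## feedforward-inhibition interval prolongation, synapse pruning, calibration
## of the spontaneous drive, and robustness checks. Each returns an
## ExperimentReport: a plain list with the settings and seeds needed to
## reproduce every number it contains.

.report <- function(name, seeds, settings, tables = list(), tests = list(),
                    values = list()) {
  structure(list(name = name, seeds = seeds, settings = settings,
                 tables = tables, tests = tests, values = values),
            class = "ExperimentReport")
}

#' @export
print.ExperimentReport <- function(x, ...) {
  cat(sprintf("ExperimentReport <%s>\n", x$name))
  cat("  seeds:", paste(names(x$seeds), unlist(x$seeds), sep = "=",
                        collapse = ", "), "\n")
  for (nm in names(x$values))
    cat(sprintf("  %s: %s\n", nm, format(x$values[[nm]], digits = 4)))
  for (nm in names(x$tables))
    cat(sprintf("  table '%s': %d rows\n", nm, nrow(x$tables[[nm]])))
  invisible(x)
}

#' Write an experiment report to disk
#'
#' Writes \code{report.json} (settings, seeds, scalar values, test results)
#' and one CSV per table into \code{dir}.
#'
#' @param report an ExperimentReport.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(name = report$name, seeds = report$seeds,
         settings = report$settings, values = report$values,
         tests = report$tests,
         package = as.character(packageVersion("purkinet"))),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  for (nm in names(report$tables))
    write.csv(report$tables[[nm]], file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE)
  invisible(dir)
}

#' Isolated-neuron experiment
#'
#' Simulates a single neuron with no synaptic input, driven only by its
#' spontaneous gamma current, and reports the statistics that characterise
#' regular firing: mean rate, ISI CV, ISI histogram, spike autocorrelogram,
#' and a Shapiro-Wilk test of ISI normality.
#'
#' @param cellClass "PKJ" or "MLI".
#' @param duration recording length, ms (default 300 s).
#' @param seed dynamics seed.
#' @param params neuron parameters (defaults to the class profile).
#' @param dt integration step, ms.
#' @return an ExperimentReport with values rate (Hz), cv, nSpikes,
#'   shapiroW, shapiroP and tables isiHistogram, autocorrelogram.
#' @export
expIsolated <- function(cellClass = c("PKJ", "MLI"), duration = 300e3,
                        seed = 1L, params = NULL, dt = 0.25) {
  cellClass <- match.arg(cellClass)
  if (is.null(params)) params <- neuronParams(cellClass)
  net <- .soloNetwork(params)
  res <- runSimulation(net, simSettings(duration, dt = dt, simSeed = seed))
  train <- spikeTimes(res, 1L)
  isi <- isis(train)
  norm <- if (length(isi) >= 3) normalityTest(isi)
          else list(W = NA_real_, p = NA_real_, n = length(isi))
  .report(
    "isolated",
    seeds = list(simSeed = seed),
    settings = list(cellClass = cellClass, duration = duration, dt = dt),
    tables = list(isiHistogram = isiHistogram(train),
                  autocorrelogram = autocorrelogram(train)),
    tests = list(shapiro = norm),
    values = list(rate = meanRate(train, duration), cv = isiCv(train),
                  nSpikes = length(train)))
}

#' Intact-network experiment
#'
#' Builds the default microcircuit, simulates it, and reports the
#' population firing statistics: per-neuron rates and CVs, per-class
#' summaries, the rate-CV Spearman correlation per class, and per-class
#' firing-rate histograms.
#'
#' @param duration recording length, ms (default 300 s).
#' @param wiringSeed,simSeed seeds for connectivity and dynamics.
#' @param config wiring recipe (defaults to [networkConfig()] with
#'   \code{wiringSeed}).
#' @param pkjParams,mliParams cell parameters.
#' @param dt integration step, ms.
#' @param rateBinHz rate-histogram bin width, Hz.
#' @return an ExperimentReport with tables perNeuron, summary,
#'   rateHistogram and values rho/p per class.
#' @export
expNetwork <- function(duration = 300e3, wiringSeed = 1L, simSeed = 2L,
                       config = NULL, pkjParams = neuronParams("PKJ"),
                       mliParams = neuronParams("MLI"), dt = 0.25,
                       rateBinHz = 2) {
  if (is.null(config)) config <- networkConfig(seed = wiringSeed)
  net <- buildNetwork(config, pkjParams, mliParams)
  res <- runSimulation(net, simSettings(duration, dt = dt, simSeed = simSeed))
  ps <- populationStats(res)
  corByClass <- lapply(split(ps$perNeuron, ps$perNeuron$class),
                       rateCvCorrelation)
  rateHist <- do.call(rbind, lapply(split(ps$perNeuron, ps$perNeuron$class),
    function(sub) {
      bin <- floor(sub$rate / rateBinHz)
      counts <- tabulate(bin + 1L, nbins = max(bin) + 1L)
      data.frame(class = sub$class[1],
                 rateLow = (seq_along(counts) - 1L) * rateBinHz,
                 rateHigh = seq_along(counts) * rateBinHz, count = counts)
    }))
  rownames(rateHist) <- NULL
  .report(
    "network",
    seeds = list(wiringSeed = config@seed, simSeed = simSeed),
    settings = list(duration = duration, dt = dt,
                    nNeurons = nNeurons(net), nSynapses = nSynapses(net)),
    tables = list(perNeuron = ps$perNeuron, summary = ps$summary,
                  rateHistogram = rateHist),
    tests = list(),
    values = list(rhoMli = corByClass$MLI$rho, pMli = corByClass$MLI$p,
                  rhoPkj = corByClass$PKJ$rho, pPkj = corByClass$PKJ$p))
}

#' Feedforward-inhibition experiment
#'
#' A single Purkinje cell fires spontaneously; a clamped MLI is triggered to
#' fire once, \code{mliDelay} ms after the PKJ's first spike, through a
#' synapse whose peak conductance is set directly in nS. Per trial the
#' first-to-second-spike interval is measured with and without the imposed
#' IPSC; trials are paired (identical spontaneous-current stream) because
#' clamped neurons consume no random numbers. The control interval is
#' independent of the peak and is computed once.
#'
#' @param ipscPeaks peak conductances to test, nS.
#' @param nTrials trials per peak.
#' @param mliDelay MLI spike delay after the first PKJ spike, ms.
#' @param seed base seed; trial i uses simSeed = seed + i.
#' @param trialDuration per-trial window, ms (long enough for two spikes).
#' @param dt integration step, ms.
#' @return an ExperimentReport with the per-trial ISI table, per-peak mean
#'   ISIs with Mann-Whitney tests against control, and the fitted slope of
#'   mean ISI against peak conductance (ms/nS).
#' @export
expFeedforward <- function(ipscPeaks = c(0, 1, 2, 4, 8), nTrials = 500L,
                           mliDelay = 12, seed = 1L, trialDuration = 500,
                           dt = 0.25) {
  ctrlNet <- .pairNetwork(0)
  first2 <- function(train) if (length(train) >= 2) train[1:2] else c(NA, NA)
  ctrl <- matrix(NA_real_, nTrials, 2)
  for (i in seq_len(nTrials)) {
    res <- runSimulation(ctrlNet,
                         simSettings(trialDuration, dt = dt, simSeed = seed + i),
                         clampIds = 2L)
    ctrl[i, ] <- first2(spikeTimes(res, 1L))
  }
  isiControl <- ctrl[, 2] - ctrl[, 1]

  trials <- list(); k <- 0L
  perPeak <- list()
  for (peak in ipscPeaks) {
    net <- .pairNetwork(peak)
    isiFfi <- rep(NA_real_, nTrials)
    for (i in seq_len(nTrials)) {
      if (is.na(ctrl[i, 1])) next
      res <- forceSpike(net,
                        simSettings(trialDuration, dt = dt, simSeed = seed + i),
                        neuronId = 2L, tFire = ctrl[i, 1] + mliDelay)
      isiFfi[i] <- diff(first2(spikeTimes(res, 1L)))
    }
    k <- k + 1L
    trials[[k]] <- data.frame(peakNs = peak, trial = seq_len(nTrials),
                              isiControl = isiControl, isiFfi = isiFfi)
    ok <- !is.na(isiFfi) & !is.na(isiControl)
    mw <- compareDistributions(isiFfi[ok], isiControl[ok])
    perPeak[[k]] <- data.frame(peakNs = peak, nTrials = sum(ok),
                               meanIsiControl = mean(isiControl[ok]),
                               meanIsiFfi = mean(isiFfi[ok]),
                               U = mw$U, p = mw$p)
  }
  perPeak <- do.call(rbind, perPeak)
  slope <- unname(coef(lm(meanIsiFfi ~ peakNs, data = perPeak))[2])
  .report(
    "feedforward",
    seeds = list(seed = seed),
    settings = list(ipscPeaks = ipscPeaks, nTrials = nTrials,
                    mliDelay = mliDelay, trialDuration = trialDuration,
                    dt = dt),
    tables = list(trials = do.call(rbind, trials), perPeak = perPeak),
    tests = list(mannWhitney = perPeak[, c("peakNs", "U", "p")]),
    values = list(isiSlopeMsPerNs = slope))
}

#' Synapse-pruning experiment
#'
#' From one intact wiring, removes a random 0/25/50/75/100% of the synapses
#' of one connection type, simulates each condition, and summarises the
#' per-class firing-rate and CV distributions (median, quartiles, mean), as
#' well as Mann-Whitney tests between the intact (0%) and fully pruned
#' (100%) conditions per class.
#'
#' @param connTypes connection types to prune.
#' @param fractions pruning fractions.
#' @param duration per-condition recording, ms (default 60 s).
#' @param wiringSeed,simSeed,pruneSeed seeds (the same dynamics seed is used
#'   across conditions; prune draws are independent per condition).
#' @param config wiring recipe.
#' @param dt integration step, ms.
#' @return an ExperimentReport with the per-condition summary table and the
#'   0%-vs-100% tests.
#' @export
expPruning <- function(connTypes = c("MLI_MLI", "PKJ_MLI"),
                       fractions = c(0, 0.25, 0.5, 0.75, 1),
                       duration = 60e3, wiringSeed = 1L, simSeed = 2L,
                       pruneSeed = 3L, config = NULL, dt = 0.25) {
  if (is.null(config)) config <- networkConfig(seed = wiringSeed)
  net <- buildNetwork(config)
  rows <- list(); tests <- list(); perNeuronRates <- list()
  for (ct in connTypes) {
    for (f in fractions) {
      pruned <- pruneSynapses(net, ct, f,
                              seed = pruneSeed + round(1000 * f))
      res <- runSimulation(pruned,
                           simSettings(duration, dt = dt, simSeed = simSeed))
      ps <- populationStats(res)
      s <- ps$summary
      s$connType <- ct; s$fraction <- f
      rows[[length(rows) + 1L]] <- s
      perNeuronRates[[paste(ct, f)]] <- ps$perNeuron
    }
    for (cls in c("MLI", "PKJ")) {
      a <- perNeuronRates[[paste(ct, 0)]]
      b <- perNeuronRates[[paste(ct, 1)]]
      mw <- compareDistributions(a$rate[a$class == cls],
                                 b$rate[b$class == cls])
      tests[[paste0(ct, "_", cls, "_rate_0_vs_100")]] <- mw
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  .report(
    "pruning",
    seeds = list(wiringSeed = config@seed, simSeed = simSeed,
                 pruneSeed = pruneSeed),
    settings = list(connTypes = connTypes, fractions = fractions,
                    duration = duration, dt = dt),
    tables = list(summary = summary),
    tests = tests,
    values = list())
}

#' Calibrate the spontaneous-drive parameters
#'
#' Exhaustive grid search over the gamma shape and scale of the spontaneous
#' current for an isolated neuron, targeting a mean firing rate and ISI CV
#' (e.g. an in-vitro exemplar under GABA block). The loss is the sum of
#' relative errors, |rate - target|/target + |cv - targetCv|/targetCv; ties
#' are broken toward the smaller shape, then the smaller scale. All grid
#' points share one dynamics seed so the comparison is paired.
#'
#' @param cellClass "PKJ" or "MLI".
#' @param targetRate target mean rate, Hz.
#' @param targetCv target ISI CV.
#' @param kappaGrid,betaGrid candidate values; default brackets the class
#'   default by factors of 4 (5 log-spaced points each).
#' @param duration per-point recording, ms.
#' @param seed dynamics seed.
#' @param dt integration step, ms.
#' @return list: kappa, beta, rate, cv, loss and the full \code{grid}
#'   data.frame of evaluated points.
#' @export
calibrateSpont <- function(cellClass = c("PKJ", "MLI"), targetRate, targetCv,
                           kappaGrid = NULL, betaGrid = NULL,
                           duration = 60e3, seed = 1L, dt = 0.25) {
  cellClass <- match.arg(cellClass)
  base <- neuronParams(cellClass)
  if (is.null(kappaGrid)) kappaGrid <- base@kappa * 4^seq(-1, 1, length.out = 5)
  if (is.null(betaGrid)) betaGrid <- base@beta * 4^seq(-1, 1, length.out = 5)
  grid <- expand.grid(kappa = kappaGrid, beta = betaGrid,
                      KEEP.OUT.ATTRS = FALSE)
  eval1 <- function(kappa, beta) {
    rep <- expIsolated(cellClass, duration = duration, seed = seed,
                       params = neuronParams(cellClass, kappa = kappa,
                                             beta = beta), dt = dt)
    c(rate = rep$values$rate, cv = rep$values$cv)
  }
  ev <- t(mapply(eval1, grid$kappa, grid$beta))
  grid$rate <- ev[, "rate"]
  grid$cv <- ev[, "cv"]
  grid$loss <- abs(grid$rate - targetRate) / targetRate +
    ifelse(is.na(grid$cv), Inf, abs(grid$cv - targetCv) / targetCv)
  ord <- order(grid$loss, grid$kappa, grid$beta)
  best <- grid[ord[1], ]
  list(kappa = best$kappa, beta = best$beta, rate = best$rate, cv = best$cv,
       loss = best$loss, grid = grid)
}

#' Robustness of the network statistics
#'
#' Two analyses: (a) re-instantiation - the intact-network experiment is
#' repeated across independent wiring and dynamics seeds and the spread of
#' the per-class population statistics is reported; (b) parameter
#' perturbation - every cell parameter and weight bound is scaled by an
#' independent Uniform(1-f, 1+f) factor and the network re-run, reporting
#' the same statistics and whether every neuron stayed spontaneously
#' active.
#'
#' @param nInstantiations number of independent re-instantiations.
#' @param perturbFraction maximum relative perturbation f (default 0.10).
#' @param duration per-run recording, ms (default 60 s).
#' @param seed base seed.
#' @param dt integration step, ms.
#' @return an ExperimentReport with tables instantiations (per-seed class
#'   summaries) and perturbed (baseline vs perturbed summaries), and values
#'   mliRateSpread (max - min across instantiations over their mean) and
#'   allActivePerturbed.
#' @export
expRobustness <- function(nInstantiations = 5L, perturbFraction = 0.10,
                          duration = 60e3, seed = 1L, dt = 0.25) {
  inst <- list()
  for (k in seq_len(nInstantiations)) {
    rep <- expNetwork(duration = duration, wiringSeed = seed + k,
                      simSeed = seed + 1000L + k, dt = dt)
    s <- rep$tables$summary
    s$instantiation <- k
    inst[[k]] <- s
  }
  inst <- do.call(rbind, inst)
  mliMeans <- inst$mean[inst$class == "MLI" & inst$measure == "rate"]
  spread <- (max(mliMeans) - min(mliMeans)) / mean(mliMeans)

  perturb <- function(params, factors) {
    fields <- setdiff(slotNames(params), "cellClass")
    vals <- lapply(seq_along(fields), function(i)
      slot(params, fields[i]) * factors[i])
    names(vals) <- fields
    do.call(neuronParams, c(list(cellClass = params@cellClass), vals))
  }
  nField <- length(slotNames(neuronParams("PKJ"))) - 1L
  prt <- .withSeed(seed + 2000L, {
    fPkj <- runif(nField, 1 - perturbFraction, 1 + perturbFraction)
    fMli <- runif(nField, 1 - perturbFraction, 1 + perturbFraction)
    fW <- runif(3, 1 - perturbFraction, 1 + perturbFraction)
    list(fPkj = fPkj, fMli = fMli, fW = fW)
  })
  cfg <- networkConfig(seed = seed,
                       wMax = c(MLI_MLI = 1, MLI_PKJ = 1.25, PKJ_MLI = 1) *
                         prt$fW[c(1, 2, 3)])
  base <- expNetwork(duration = duration, wiringSeed = seed,
                     simSeed = seed + 1L, dt = dt)
  pert <- expNetwork(duration = duration, wiringSeed = seed,
                     simSeed = seed + 1L, config = cfg,
                     pkjParams = perturb(neuronParams("PKJ"), prt$fPkj),
                     mliParams = perturb(neuronParams("MLI"), prt$fMli),
                     dt = dt)
  baseS <- base$tables$summary; baseS$condition <- "baseline"
  pertS <- pert$tables$summary; pertS$condition <- "perturbed"
  pkjRates <- pert$tables$perNeuron
  allActive <- all(pkjRates$rate[pkjRates$class == "PKJ"] > 0)
  .report(
    "robustness",
    seeds = list(seed = seed),
    settings = list(nInstantiations = nInstantiations,
                    perturbFraction = perturbFraction, duration = duration,
                    dt = dt),
    tables = list(instantiations = inst, perturbed = rbind(baseS, pertS)),
    tests = list(),
    values = list(mliRateSpread = spread, allActivePerturbed = allActive))
}
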