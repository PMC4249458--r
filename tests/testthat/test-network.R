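# wiring generator: probabilities, structure, convergence/divergence,
# pruning, export round-trip.

test_that("probabilities derive from the anatomical targets", {
  p <- deriveProbabilities()
  expect_equal(unname(p), c(0.25, 0.05, 0.5))
  # doubled span halves the MLI->PKJ probability
  p2 <- deriveProbabilities(nPkj = 33L, mliAxonSpanPkjs = 16L)
  expect_equal(unname(p2["pMliToPkj"]), 0.125)
  expect_equal(unname(deriveProbabilities(mliToMli = 0)["pMliToMli"]), 0)
  expect_error(deriveProbabilities(mliToPkj = 10), "infeasible")
  # finite-strip averaging raises the probabilities so the population
  # average convergence still meets the targets
  pa <- deriveProbabilities(boundary = "average")
  expect_true(all(pa > p))
  expect_equal(unname(pa["pMliToPkj"]), 2 / 5.75, tolerance = 1e-12)
})

test_that("zero probabilities give an empty synapse list, 176 neurons", {
  cfg <- networkConfig(pMliToPkj = 0, pMliToMli = 0, pPkjToMli = 0, seed = 3)
  net <- buildNetwork(cfg)
  expect_identical(nSynapses(net), 0L)
  expect_identical(nNeurons(net), 176L)
  expect_identical(sum(neurons(net)$lowerMl), 48L)
})

test_that("structural invariants hold for generated networks", {
  for (seed in c(2, 77)) {
    net <- buildNetwork(networkConfig(seed = seed))
    expect_true(validObject(net))  # no autapses, no PKJ->PKJ, span/direction
    sy <- synapses(net)
    nr <- neurons(net)
    expect_false(anyDuplicated(sy[, c("source", "target")]) > 0)
    # PKJ->MLI targets are all lower-molecular-layer
    lower <- setNames(nr$lowerMl, nr$id)
    expect_true(all(lower[as.character(sy$target[sy$type == "PKJ_MLI"])]))
    # weights within configured bounds
    expect_true(all(sy$weight >= 0 &
                      sy$weight <= net@config@wMax[sy$type]))
  }
})

test_that("a seeded build is reproduced by replaying the draw sequence", {
  # independent recount oracle: replay the documented RNG protocol with
  # plain loops and compare the full edge list, weights included
  cfg <- networkConfig(seed = 19)
  net <- buildNetwork(cfg)
  nP <- cfg@nPkj; mpp <- cfg@mliPerPkj
  edges <- list()
  set.seed(19)
  dirs <- ifelse(runif(nP * mpp) < 0.5, 1L, -1L)
  for (m in seq_len(nP * mpp)) {
    t0 <- (m - 1L) %/% mpp + 1L
    ters <- t0 + dirs[m] * seq_len(cfg@mliAxonSpanPkjs)
    ters <- ters[ters >= 1 & ters <= nP]
    for (tt in ters) if (runif(1) < cfg@pMliToPkj)
      edges[[length(edges) + 1]] <-
        list(nP + m, tt, "MLI_PKJ", runif(1, 0, cfg@wMax[["MLI_PKJ"]]))
    for (tt in ters) for (j in seq_len(mpp)) if (runif(1) < cfg@pMliToMli)
      edges[[length(edges) + 1]] <-
        list(nP + m, nP + (tt - 1L) * mpp + j, "MLI_MLI",
             runif(1, 0, cfg@wMax[["MLI_MLI"]]))
  }
  pdirs <- ifelse(runif(nP) < 0.5, 1L, -1L)
  for (p in seq_len(nP)) {
    ters <- p + pdirs[p] * seq_len(cfg@pkjCollateralSpanPkjs)
    ters <- ters[ters >= 1 & ters <= nP]
    for (tt in ters) for (j in seq_len(cfg@lowerMliPerPkj))
      if (runif(1) < cfg@pPkjToMli)
        edges[[length(edges) + 1]] <-
          list(p, nP + (tt - 1L) * mpp + j, "PKJ_MLI",
               runif(1, 0, cfg@wMax[["PKJ_MLI"]]))
  }
  oracle <- data.frame(source = vapply(edges, function(e) e[[1]], 1),
                       target = vapply(edges, function(e) e[[2]], 1),
                       type = vapply(edges, function(e) e[[3]], ""),
                       weight = vapply(edges, function(e) e[[4]], 1))
  got <- synapses(net)
  expect_equal(got$source, as.integer(oracle$source))
  expect_equal(got$target, as.integer(oracle$target))
  expect_equal(got$type, oracle$type)
  expect_equal(got$weight, oracle$weight, tolerance = 0)
})

test_that("population-average convergence and divergence meet the targets", {
  # default (finite-strip averaged) probabilities, 200 wiring seeds
  nSeeds <- 200
  conv <- matrix(NA_real_, nSeeds, 4)  # MLI->PKJ, MLI->MLI, PKJ div, elig conv
  wts <- list(MLI_PKJ = c(), MLI_MLI = c(), PKJ_MLI = c())
  for (s in seq_len(nSeeds)) {
    net <- buildNetwork(networkConfig(seed = 10000 + s))
    sy <- synapses(net)
    nr <- neurons(net)
    nElig <- sum(nr$lowerMl)
    conv[s, ] <- c(sum(sy$type == "MLI_PKJ") / 16,
                   sum(sy$type == "MLI_MLI") / 160,
                   sum(sy$type == "PKJ_MLI") / 16,
                   sum(sy$type == "PKJ_MLI") / nElig)
    if (s <= 40)
      for (ty in names(wts)) wts[[ty]] <- c(wts[[ty]], sy$weight[sy$type == ty])
  }
  means <- colMeans(conv)
  se <- apply(conv, 2, sd) / sqrt(nSeeds)
  targets <- c(20, 4, 3, 1)
  for (j in 1:4) expect_lt(abs(means[j] - targets[j]), 4 * se[j])

  # weight laws: Kolmogorov-Smirnov against the configured uniforms
  ub <- c(MLI_PKJ = 1.25, MLI_MLI = 1, PKJ_MLI = 1)
  for (ty in names(wts)) {
    x <- wts[[ty]]
    if (length(x) > 1e4) x <- x[1:1e4]
    expect_gt(stats::ks.test(x, "punif", 0, ub[[ty]])$p.value, 0.01)
  }
})

test_that("interior neurons realise the idealised targets; boundary less", {
  # wide strip + interior-formula probabilities: interior PKJs see the full
  # candidate pool, so their expected convergence is exactly 20
  p <- deriveProbabilities()
  nSeeds <- 60
  interior <- numeric(nSeeds)
  edge <- numeric(nSeeds)
  for (s in seq_len(nSeeds)) {
    cfg <- networkConfig(nPkj = 32L, pMliToPkj = p[["pMliToPkj"]],
                         pMliToMli = p[["pMliToMli"]],
                         pPkjToMli = p[["pPkjToMli"]], seed = 500 + s)
    net <- buildNetwork(cfg)
    sy <- synapses(net)
    nr <- neurons(net)
    ter <- setNames(nr$territory, nr$id)
    tt <- ter[as.character(sy$target[sy$type == "MLI_PKJ"])]
    interior[s] <- sum(tt >= 9 & tt <= 24) / 16
    edge[s] <- sum(tt == 1 | tt == 32) / 2
  }
  se <- sd(interior) / sqrt(nSeeds)
  expect_lt(abs(mean(interior) - 20), 4 * se)
  expect_lt(mean(edge), mean(interior))
})

test_that("pruning removes exactly the requested fraction of one type", {
  net <- buildNetwork(networkConfig(seed = 4))
  sy <- synapses(net)
  n0 <- table(sy$type)
  expect_identical(synapses(pruneSynapses(net, "MLI_MLI", 0)), sy)
  full <- pruneSynapses(net, "MLI_MLI", 1, seed = 9)
  expect_identical(sum(synapses(full)$type == "MLI_MLI"), 0L)
  expect_identical(table(synapses(full)$type)[["PKJ_MLI"]], n0[["PKJ_MLI"]])
  half <- pruneSynapses(net, "PKJ_MLI", 0.5, seed = 9)
  expect_identical(sum(synapses(half)$type == "PKJ_MLI"),
                   as.integer(n0[["PKJ_MLI"]] - round(0.5 * n0[["PKJ_MLI"]])))
  # untouched synapses keep their identity (weights included)
  keep <- synapses(half)
  other <- keep[keep$type != "PKJ_MLI", ]
  expect_true(all(paste(other$source, other$target, other$weight) %in%
                    paste(sy$source, sy$target, sy$weight)))
  expect_error(pruneSynapses(net, "PKJ_PKJ", 0.5), "unknown connection")
  expect_error(pruneSynapses(net, "MLI_MLI", 1.5), "fraction")
})

test_that("network export round-trips exactly", {
  net <- buildNetwork(networkConfig(seed = 12))
  base <- file.path(tempdir(), "net-roundtrip")
  writeNetwork(net, base)
  back <- readNetwork(base)
  expect_equal(synapses(back), synapses(net), tolerance = 0)
  expect_equal(neurons(back), neurons(net))
  expect_equal(back@config, net@config)
  expect_equal(back@params$PKJ, net@params$PKJ)
})
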