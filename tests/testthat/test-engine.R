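# simulation engine: determinism, causality, equivalence with the scalar
# reference implementation, forced spikes.

test_that("identical seeds give bit-identical results", {
  net <- buildNetwork(networkConfig(seed = 5))
  a <- runSimulation(net, simSettings(2000, simSeed = 8))
  b <- runSimulation(net, simSettings(2000, simSeed = 8))
  expect_identical(a@spikes, b@spikes)
  c <- runSimulation(net, simSettings(2000, simSeed = 9))
  expect_false(identical(a@spikes, c@spikes))
})

test_that("spike times are step-aligned and per-neuron increasing", {
  net <- buildNetwork(networkConfig(seed = 5))
  res <- runSimulation(net, simSettings(1500, simSeed = 2))
  sp <- res@spikes
  expect_true(all(abs(sp$time / 0.25 - round(sp$time / 0.25)) < 1e-9))
  expect_true(all(sp$time >= 0 & sp$time < 1500))
  expect_true(all(vapply(split(sp$time, sp$id),
                         function(x) !is.unsorted(x, strictly = TRUE), TRUE)))
})

test_that("a one-step simulation emits at most one spike per neuron", {
  net <- buildNetwork(networkConfig(seed = 5))
  res <- runSimulation(net, simSettings(0.25, simSeed = 2))
  expect_true(all(table(res@spikes$id) <= 1))
})

test_that("engine agrees bit-for-bit with the scalar reference", {
  for (mk in list(function() activePairNetwork(1.0), threeNeuronNetwork)) {
    net <- mk()
    got <- runSimulation(net, simSettings(100, simSeed = 31))@spikes
    ref <- refSimulate(net, 100, 0.25, 31)
    rownames(got) <- rownames(ref) <- NULL
    expect_identical(got$id, ref$id)
    expect_identical(got$time, ref$time)
  }
  # longer two-neuron run so synaptic deliveries accumulate
  net <- activePairNetwork(1.2)
  got <- runSimulation(net, simSettings(2000, simSeed = 7))@spikes
  ref <- refSimulate(net, 2000, 0.25, 7)
  expect_identical(got$time, ref$time)
})

test_that("clamped neurons and forced spikes match the reference", {
  net <- activePairNetwork(1.0)
  got <- forceSpike(net, simSettings(200, simSeed = 13), 2L, 50)@spikes
  ref <- refSimulate(net, 200, 0.25, 13, clampIds = 2L,
                     forced = data.frame(id = 2L, time = 50))
  expect_identical(got$id, ref$id)
  expect_identical(got$time, ref$time)
})

test_that("a clamped partner leaves the other neuron's stream untouched", {
  # the clamped MLI consumes no random numbers, so the PKJ replays its
  # isolated trajectory exactly under the same dynamics seed
  pair <- activePairNetwork(1.0)
  solo <- purkinet:::.soloNetwork(neuronParams("PKJ"))
  a <- runSimulation(pair, simSettings(3000, simSeed = 4), clampIds = 2L)
  b <- runSimulation(solo, simSettings(3000, simSeed = 4))
  expect_identical(spikeTimes(a, 1L), spikeTimes(b, 1L))
})

test_that("forced spikes with zero weight leave the target unchanged", {
  net0 <- activePairNetwork(0)
  ctrl <- runSimulation(net0, simSettings(500, simSeed = 21), clampIds = 2L)
  frc <- forceSpike(net0, simSettings(500, simSeed = 21), 2L, 30)
  expect_identical(spikeTimes(ctrl, 1L), spikeTimes(frc, 1L))
})

test_that("a forced spike cannot act before it happens", {
  net <- activePairNetwork(1.5)
  ctrl <- runSimulation(net, simSettings(800, simSeed = 6), clampIds = 2L)
  t12 <- spikeTimes(ctrl, 1L)[1:2]
  # force the MLI after the PKJ's second spike: first two ISIs identical
  frc <- forceSpike(net, simSettings(800, simSeed = 6), 2L, t12[2] + 5)
  expect_identical(spikeTimes(frc, 1L)[1:2], t12)
})

test_that("perturbing a synapse changes nothing before its first use", {
  netA <- activePairNetwork(0.3)
  netB <- activePairNetwork(1.2)
  a <- runSimulation(netA, simSettings(1000, simSeed = 17))@spikes
  b <- runSimulation(netB, simSettings(1000, simSeed = 17))@spikes
  tMli <- min(a$time[a$id == 2])
  expect_identical(min(b$time[b$id == 2]), tMli)  # MLI receives nothing
  expect_identical(a$time[a$id == 1 & a$time <= tMli],
                   b$time[b$id == 1 & b$time <= tMli])
})

test_that("inhibitory input never raises the target's rate", {
  for (seed in 1:20) {
    withInh <- runSimulation(activePairNetwork(1.0),
                             simSettings(10e3, simSeed = 100 + seed))
    without <- runSimulation(activePairNetwork(0),
                             simSettings(10e3, simSeed = 100 + seed))
    expect_lte(length(spikeTimes(withInh, 1L)),
               length(spikeTimes(without, 1L)))
  }
})

test_that("zero-weight network reduces to per-neuron isolated statistics", {
  net <- buildNetwork(networkConfig(seed = 30))
  net@synapses$weight <- 0
  res <- runSimulation(net, simSettings(60e3, simSeed = 31))
  ps <- populationStats(res)$summary
  pkjRate <- ps$mean[ps$class == "PKJ" & ps$measure == "rate"]
  mliRate <- ps$mean[ps$class == "MLI" & ps$measure == "rate"]
  expect_lt(abs(pkjRate - 38.9), 1.5)
  expect_lt(abs(mliRate - 29.1), 1.5)
  pkjCv <- ps$mean[ps$class == "PKJ" & ps$measure == "cv"]
  expect_lt(abs(pkjCv - 0.17), 0.03)
})

test_that("voltage recording honours ids and stride", {
  net <- activePairNetwork(1.0)
  res <- runSimulation(net, simSettings(100, simSeed = 3),
                       clampIds = integer(0))
  expect_identical(length(res@vTime), 0L)
  res2 <- runSimulation(net,
                        simSettings(100, simSeed = 3, recordIds = 1L,
                                    recordStride = 4L))
  expect_identical(length(res2@vTime), 100L)  # 400 steps / 4
  expect_identical(colnames(res2@v), "1")
  expect_true(all(is.finite(res2@v)))
  # spike trains are unaffected by recording
  expect_identical(res@spikes, res2@spikes)
})
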