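# single-neuron model: parameter profiles, gamma drive, membrane update,
# conductance bookkeeping.

test_that("parameter profiles carry the published constants and validate", {
  pkj <- neuronParams("PKJ")
  mli <- neuronParams("MLI")
  expect_equal(pkj@kappa, 0.430303)
  expect_equal(pkj@beta, 0.195962)
  expect_equal(mli@gGabaPeak, 4.0)
  expect_equal(mli@capacitance, 14.6)
  expect_error(neuronParams("PKJ", capacitance = -1), "capacitance")
  expect_error(neuronParams("PKJ", eGaba = -10), "eGaba")
  expect_error(neuronParams("PKJ", kappa = -0.1), "kappa")
  expect_error(neuronParams("PKJ", nosuch = 1), "unknown")
})

test_that("spontaneous current is gamma with the requested moments", {
  pkj <- neuronParams("PKJ")
  mli <- neuronParams("MLI")
  set.seed(11)
  x <- drawSpontCurrent(pkj, 1e6)
  expect_true(all(x >= 0))
  m <- pkj@kappa * pkj@beta
  se <- sqrt(pkj@kappa * pkj@beta^2 / 1e6)
  expect_lt(abs(mean(x) - m), 3 * se)
  y <- drawSpontCurrent(mli, 1e6)
  vtarget <- mli@kappa * mli@beta^2
  # SE of the sample variance of a gamma: sqrt((mu4 - var^2)/n)
  mu4 <- (3 + 6 / mli@kappa) * vtarget^2
  expect_lt(abs(var(y) - vtarget), 3 * sqrt((mu4 - vtarget^2) / 1e6))
  expect_identical(drawSpontCurrent(neuronParams("MLI", kappa = 0), 5),
                   rep(0, 5))
})

test_that("membrane update matches the hand-computed Euler step", {
  pkj <- neuronParams("PKJ")
  st <- neuronState(pkj)
  # all driving terms vanish at the leak reversal
  st2 <- stepNeuron(st, pkj, iSpont = 0, dt = 0.25, now = 0)
  expect_identical(st2@v, pkj@eLeak)
  expect_false(st2@spiked)
  # leak term zero at E_leak: dV = (dt/C) * I[pA]
  st3 <- stepNeuron(st, pkj, iSpont = 0.0843, dt = 0.25, now = 0)
  expect_equal(st3@v, -68 + (0.25 / 107) * 84.3, tolerance = 1e-12)
  # general hand-computed value away from rest, with a conductance trace
  st4 <- new("NeuronState", v = -60, gGaba = 2.5, tLastSpike = NA_real_,
             spiked = FALSE)
  byHand <- -60 + (0.25 / 107) *
    (-2.32 * (-60 + 68) - 2.5 * (-60 + 75) + 50)
  expect_equal(stepNeuron(st4, pkj, 0.05, 0.25, 10)@v, byHand,
               tolerance = 1e-12)
})

test_that("threshold crossing sets the spike flag and restarts the AHP", {
  pkj <- neuronParams("PKJ")
  st <- new("NeuronState", v = -55.5, gGaba = 0, tLastSpike = NA_real_,
            spiked = FALSE)
  st2 <- stepNeuron(st, pkj, iSpont = 1.0, dt = 0.25, now = 42)
  expect_true(st2@spiked)
  expect_gte(st2@v, pkj@vThreshold)
  expect_identical(st2@tLastSpike, 42)
  # AHP at the spike time itself is the full peak, and it pulls V down hard
  st3 <- stepNeuron(st2, pkj, iSpont = 0, dt = 0.25, now = 42.25)
  expect_lt(st3@v, st2@v)
})

test_that("conductance trace decays exponentially and sums linearly", {
  mli <- neuronParams("MLI")
  st <- neuronState(mli)
  expect_identical(decayGabaTrace(st, mli, 4.6)@gGaba, 0)
  st <- receiveSpike(st, mli, 1.0)
  expect_equal(st@gGaba, 4.0)  # peak of the target class
  expect_equal(decayGabaTrace(st, mli, 4.6)@gGaba, 4 * exp(-1),
               tolerance = 1e-12)
  # semigroup: 40 steps of 0.25 ms == one step of 10 ms
  fine <- st
  for (i in 1:40) fine <- decayGabaTrace(fine, mli, 0.25)
  expect_equal(fine@gGaba, decayGabaTrace(st, mli, 10)@gGaba,
               tolerance = 1e-12)
  # linear superposition of simultaneous inputs
  a <- receiveSpike(receiveSpike(neuronState(mli), mli, 0.3), mli, 0.7)
  b <- receiveSpike(neuronState(mli), mli, 1.0)
  expect_equal(a@gGaba, b@gGaba, tolerance = 1e-12)
  expect_identical(receiveSpike(st, mli, 0)@gGaba, st@gGaba)
  expect_error(receiveSpike(st, mli, -0.1), "weight")
})

test_that("trace after arbitrary event sequences equals the explicit sum", {
  # oracle: g(T) = sum_i gPeak * w_i * exp(-(T - t_i)/tau) over past spikes
  mli <- neuronParams("MLI")
  set.seed(21)
  for (rep in 1:10) {
    nEv <- sample(1:20, 1)
    tEv <- sort(runif(nEv, 0, 50))
    wEv <- runif(nEv, 0, 1)
    dt <- 0.25
    steps <- seq(0, 60, by = dt)
    st <- neuronState(mli)
    done <- 0L
    for (k in seq_along(steps)[-1]) {
      st <- decayGabaTrace(st, mli, dt)
      while (done < nEv && tEv[done + 1] <= steps[k]) {
        done <- done + 1L
        st <- receiveSpike(st, mli, wEv[done])
      }
    }
    # each event decays from the step boundary at which it was deposited
    tDep <- dt * ceiling(tEv / dt)
    oracle <- sum(mli@gGabaPeak * wEv * exp(-(60 - tDep) / mli@tauGaba))
    expect_equal(st@gGaba, oracle, tolerance = 1e-9)
  }
})

test_that("with no drive the membrane relaxes monotonically to rest", {
  # AHP disabled: the premise is zero AHP, GABA and spontaneous drive
  pkj <- neuronParams("PKJ", gAhpPeak = 0)
  for (v0 in c(-20, -90)) {
    st <- new("NeuronState", v = v0, gGaba = 0, tLastSpike = NA_real_,
              spiked = FALSE)
    path <- numeric(200)
    for (k in 1:200) {
      st <- stepNeuron(st, pkj, 0, 0.25, (k - 1) * 0.25)
      path[k] <- st@v
    }
    gaps <- abs(path - pkj@eLeak)
    expect_true(all(diff(gaps) <= 0))
    expect_lt(gaps[200], abs(v0 - pkj@eLeak))
  }
})

test_that("isolated firing rate is monotone in the mean spontaneous drive", {
  base <- neuronParams("PKJ")
  rates <- vapply(c(0.5, 1, 2), function(scale) {
    rep <- expIsolated("PKJ", duration = 60e3, seed = 5,
                       params = neuronParams("PKJ",
                                             kappa = base@kappa * scale))
    rep$values$rate
  }, 1)
  expect_true(all(diff(rates) > 0))
})
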