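#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Fixed-step forward-Euler integration of the whole network.
//
// Update rule, per step k (time now = k*dt), for every non-clamped neuron in
// ascending id order:
//   1. draw I ~ Gamma(kappa, beta) [nA] (skipped, consuming no RNG state,
//      when kappa == 0 or the neuron is clamped),
//   2. V += (dt/C) * ( -g_leak (V-E_leak) - g_ahp (V-E_ahp)
//                      - g_gaba (V-E_gaba) + 1000 I ),
//      using the conductance traces valid at the start of the step,
//   3. threshold test after the update; a spike is recorded at k*dt and the
//      AHP trace restarts at its peak (most recent spike only, no summation,
//      no hard voltage reset).
// Then both traces decay by one step (values below 1e-30 nS are flushed to
// zero: they are dynamically irrelevant and subnormal arithmetic is slow)
// and all spikes of the step -- threshold crossings first, then forced
// events -- deposit their increments into the targets' GABA traces, so a
// spike at step k first affects the membrane update of step k+1
// (zero-delay, one-step causality).
//
// RNG: uses R's stream (caller seeds with set.seed), draws in fixed neuron
// order, so results are reproducible and independent of vectorisation.

static const double FLUSH = 1e-30;

// [[Rcpp::export(name = ".cppSimulate")]]
List cppSimulate(NumericVector vth, NumericVector cap, NumericVector gl,
                 NumericVector el, NumericVector egaba, NumericVector dgaba,
                 NumericVector gahpPeak, NumericVector eahp, NumericVector dahp,
                 NumericVector kappa, NumericVector beta,
                 IntegerVector synPtr, IntegerVector synTgt,
                 NumericVector synInc,
                 int nSteps, double dt,
                 LogicalVector clamped,
                 IntegerVector forcedId, IntegerVector forcedStep,
                 IntegerVector recordIds, int recordStride) {
  const int n = vth.size();
  std::vector<double> V(n), ggaba(n, 0.0), ahp(n, 0.0);
  for (int i = 0; i < n; ++i) V[i] = el[i];

  std::vector<int> spikeId;
  std::vector<double> spikeTime;
  std::vector<int> sp;
  sp.reserve(32);

  const int nRec = recordIds.size();
  std::vector<double> vSamples;
  std::vector<double> vTimes;

  // forced events sorted by step on the R side; walk a cursor through them
  int fcur = 0;
  const int nForced = forcedId.size();

  RNGScope scope;
  for (int k = 0; k < nSteps; ++k) {
    const double now = k * dt;
    sp.clear();
    for (int i = 0; i < n; ++i) {
      if (clamped[i]) continue;
      const double I = (kappa[i] > 0.0)
        ? R::rgamma(kappa[i], beta[i]) * 1000.0 : 0.0;  // nA -> pA
      double v = V[i];
      v += (dt / cap[i]) * (-gl[i] * (v - el[i]) - ahp[i] * (v - eahp[i])
                            - ggaba[i] * (v - egaba[i]) + I);
      if (!std::isfinite(v))
        stop("membrane potential diverged: neuron %d at step %d", i + 1, k);
      V[i] = v;
      if (v >= vth[i]) {
        sp.push_back(i);
        spikeId.push_back(i + 1);
        spikeTime.push_back(now);
      }
    }
    for (int i = 0; i < n; ++i) {
      ggaba[i] *= dgaba[i];
      if (ggaba[i] < FLUSH) ggaba[i] = 0.0;
      ahp[i] *= dahp[i];
      if (ahp[i] < FLUSH) ahp[i] = 0.0;
    }
    for (size_t j = 0; j < sp.size(); ++j) {
      const int s = sp[j];
      for (int e = synPtr[s]; e < synPtr[s + 1]; ++e)
        ggaba[synTgt[e]] += synInc[e];
      ahp[s] = gahpPeak[s];
    }
    while (fcur < nForced && forcedStep[fcur] == k) {
      const int s = forcedId[fcur] - 1;
      spikeId.push_back(s + 1);
      spikeTime.push_back(now);
      for (int e = synPtr[s]; e < synPtr[s + 1]; ++e)
        ggaba[synTgt[e]] += synInc[e];
      ahp[s] = gahpPeak[s];
      ++fcur;
    }
    if (nRec > 0 && k % recordStride == 0) {
      vTimes.push_back(now);
      for (int r = 0; r < nRec; ++r) vSamples.push_back(V[recordIds[r] - 1]);
    }
  }

  NumericMatrix vm(nRec, (int)vTimes.size());
  if (nRec > 0)
    std::copy(vSamples.begin(), vSamples.end(), vm.begin());
  return List::create(_["id"] = wrap(spikeId), _["time"] = wrap(spikeTime),
                      _["vTime"] = wrap(vTimes), _["v"] = vm);
}
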