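#ifndef DEMEFLOW_PRUNE_H
#define DEMEFLOW_PRUNE_H

#include <R.h>
#include <Rmath.h>
#include <algorithm>
#include <vector>
#include <cmath>
#ifdef __SSE2__
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif

// Subnormal partial-likelihood values cause a large arithmetic slowdown on
// x86; the kernels run with flush-to-zero / denormals-are-zero enabled and
// restore the FP environment on exit.
struct FlushDenormals {
#ifdef __SSE2__
  unsigned int ftz, daz;
  FlushDenormals() {
    ftz = _MM_GET_FLUSH_ZERO_MODE();
    daz = _MM_GET_DENORMALS_ZERO_MODE();
    _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
    _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
  }
  ~FlushDenormals() {
    _MM_SET_FLUSH_ZERO_MODE(ftz);
    _MM_SET_DENORMALS_ZERO_MODE(daz);
  }
#endif
};

// Scratch buffers reused across pruning calls.
struct PruneScratch {
  std::vector<double> part, scal, contrib, catLL;
  std::vector<int> ord;
  std::vector<int> kidHead, kidNext; // intrusive child lists
  void ensure(int nnode, int npat, int ncat) {
    part.resize((size_t)nnode * 4 * npat);
    scal.resize(npat);
    contrib.resize(4 * (size_t)npat);
    catLL.resize((size_t)ncat * npat);
    ord.resize(nnode);
    kidHead.resize(nnode);
    kidNext.resize(nnode);
  }
};

inline void pruneTransition(const double* right, const double* vals,
                            const double* left, double t, double* P) {
  double ev[4];
  for (int e = 0; e < 4; ++e) ev[e] = std::exp(vals[e] * t);
  for (int i = 0; i < 4; ++i) {
    double rowsum = 0.0;
    for (int j = 0; j < 4; ++j) {
      double s = 0.0;
      for (int e = 0; e < 4; ++e)
        s += right[i + 4 * e] * ev[e] * left[e + 4 * j];
      if (s < 0.0) s = 0.0;
      P[i + 4 * j] = s;
      rowsum += s;
    }
    for (int j = 0; j < 4; ++j) P[i + 4 * j] /= rowsum;
  }
}

// Felsenstein pruning over an ultrametric clock tree, mixed over site-rate
// classes; parent[] is 1-based with 0 marking the root, tips are nodes
// 0..ntip-1, patterns is ntip x npat column-major with entries 1..4
// (0 = fully ambiguous).
inline double pruneLoglik(const int* parent, const double* time, int nnode,
                          const int* patterns, int ntip, int npat,
                          const double* weights, const double* right,
                          const double* vals, const double* left,
                          const double* freqs, const double* rates,
                          const double* probs, int ncat, double rateScale,
                          PruneScratch& sc) {
  FlushDenormals fd;
  sc.ensure(nnode, npat, ncat);
  int* ord = sc.ord.data();
  for (int v = 0; v < nnode; ++v) ord[v] = v;
  std::sort(ord, ord + nnode,
            [&](int a, int b) { return time[a] < time[b]; });
  int* kidHead = sc.kidHead.data();
  int* kidNext = sc.kidNext.data();
  std::fill(kidHead, kidHead + nnode, -1);
  int root = -1;
  for (int v = 0; v < nnode; ++v) {
    int p = parent[v];
    if (p == 0) root = v;
    else { kidNext[v] = kidHead[p - 1]; kidHead[p - 1] = v; }
  }
  double* part = sc.part.data();
  double* scal = sc.scal.data();
  double* contrib = sc.contrib.data();
  double* catLL = sc.catLL.data();
  double P[16];
  for (int k = 0; k < ncat; ++k) {
    double rk = rates[k] * rateScale;
    std::fill(scal, scal + npat, 0.0);
    for (int oi = 0; oi < nnode; ++oi) {
      int v = ord[oi];
      if (v < ntip) continue;
      double* pv = part + (size_t)v * 4 * npat;
      bool first = true;
      for (int c = kidHead[v]; c != -1; c = kidNext[c]) {
        pruneTransition(right, vals, left, (time[v] - time[c]) * rk, P);
        if (c < ntip) {
          for (int s = 0; s < npat; ++s) {
            int b = patterns[c + ntip * s];
            for (int i = 0; i < 4; ++i)
              contrib[4 * s + i] = (b == 0) ? 1.0 : P[i + 4 * (b - 1)];
          }
        } else {
          const double* pc = part + (size_t)c * 4 * npat;
          for (int s = 0; s < npat; ++s)
            for (int i = 0; i < 4; ++i) {
              double acc = 0.0;
              for (int j = 0; j < 4; ++j)
                acc += P[i + 4 * j] * pc[4 * s + j];
              contrib[4 * s + i] = acc;
            }
        }
        if (first) {
          std::copy(contrib, contrib + 4 * (size_t)npat, pv);
          first = false;
        } else {
          for (int x = 0; x < 4 * npat; ++x) pv[x] *= contrib[x];
        }
      }
      for (int s = 0; s < npat; ++s) {
        double mx = pv[4 * s];
        for (int i = 1; i < 4; ++i) mx = std::max(mx, pv[4 * s + i]);
        if (mx <= 0.0) mx = 1.0;
        else {
          for (int i = 0; i < 4; ++i) {
            pv[4 * s + i] /= mx;
            // flush to zero before subnormals accumulate (huge slowdown)
            if (pv[4 * s + i] < 1e-280) pv[4 * s + i] = 0.0;
          }
          scal[s] += std::log(mx);
        }
      }
    }
    const double* pr = part + (size_t)root * 4 * npat;
    for (int s = 0; s < npat; ++s) {
      double lik = 0.0;
      for (int i = 0; i < 4; ++i) lik += freqs[i] * pr[4 * s + i];
      catLL[(size_t)k * npat + s] =
        (lik > 0.0 ? std::log(lik) : R_NegInf) + std::log(probs[k]) + scal[s];
    }
  }
  double total = 0.0;
  for (int s = 0; s < npat; ++s) {
    double mx = R_NegInf;
    for (int k = 0; k < ncat; ++k)
      mx = std::max(mx, catLL[(size_t)k * npat + s]);
    if (!std::isfinite(mx)) return R_NegInf;
    double acc = 0.0;
    for (int k = 0; k < ncat; ++k)
      acc += std::exp(catLL[(size_t)k * npat + s] - mx);
    total += weights[s] * (mx + std::log(acc));
  }
  return total;
}

#endif
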