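#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
#include "prune.h"
using namespace Rcpp;

// Metropolis-Hastings chain over structured-coalescent genealogies with
// migration histories (single-lineage re-simulation kernel), run entirely
// in compiled code. Mirrors the R reference implementation in R/mh.R: the
// proposal re-grows one detached lineage from the conditional structured
// coalescent at the driving parameters, so the acceptance ratio is the
// (power-tempered) data-likelihood ratio.

namespace {

struct Path { std::vector<double> t; std::vector<int> d; };

struct GState {
  int n, nd;
  std::vector<int> parent, nodeDeme;
  std::vector<double> time;
  std::vector<Path> paths;
};

struct Seg { int node; double t0, t1; int deme; };

int sampleDest(const double* Mrow, int nd, double outRate) {
  double u = unif_rand() * outRate;
  double acc = 0.0;
  for (int j = 0; j < nd; ++j) {
    acc += Mrow[j];
    if (u <= acc) return j;
  }
  return nd - 1;
}

// One re-simulation proposal at driving (theta, M row-major). Returns false
// when the re-growth deadlocks or overruns the time cap.
bool proposeResim(const GState& st, const std::vector<double>& theta,
                  const std::vector<double>& M,
                  const std::vector<double>& outRate, double cap,
                  GState& out) {
  int nnode = st.parent.size();
  int nd = st.nd;
  int root = -1;
  for (int v = 0; v < nnode; ++v) if (st.parent[v] == 0) { root = v; break; }
  int c0 = (int)std::floor(unif_rand() * (nnode - 1));
  if (c0 >= root) ++c0; // uniform over non-root nodes
  out = st;
  int p = st.parent[c0] - 1;
  int sib = -1;
  for (int v = 0; v < nnode; ++v)
    if (v != c0 && st.parent[v] - 1 == p) { sib = v; break; }
  int g = st.parent[p]; // 1-based, 0 when p is the root
  out.parent[sib] = g;
  // sib inherits p's lineage
  out.paths[sib].t.insert(out.paths[sib].t.end(), st.paths[p].t.begin(),
                          st.paths[p].t.end());
  out.paths[sib].d.insert(out.paths[sib].d.end(), st.paths[p].d.begin(),
                          st.paths[p].d.end());
  out.paths[p].t.clear(); out.paths[p].d.clear();
  out.parent[p] = -1;

  int rootNode = (g == 0) ? sib : root;
  // lineage segments of everything except c0 and p
  std::vector<Seg> segs;
  segs.reserve(2 * nnode);
  std::vector<double> bps;
  for (int v = 0; v < nnode; ++v) {
    if (v == c0 || v == p) continue;
    int par = out.parent[v];
    double top = (par == 0) ? R_PosInf : out.time[par - 1];
    const Path& pth = out.paths[v];
    double t0 = out.time[v];
    int dm = out.nodeDeme[v];
    for (size_t e = 0; e <= pth.t.size(); ++e) {
      double t1 = (e < pth.t.size()) ? pth.t[e] : top;
      Seg s; s.node = v; s.t0 = t0; s.t1 = t1; s.deme = dm;
      segs.push_back(s);
      if (std::isfinite(t1)) bps.push_back(t1);
      if (e < pth.t.size()) { t0 = pth.t[e]; dm = pth.d[e]; }
    }
  }
  std::sort(bps.begin(), bps.end());
  double t = st.time[c0];
  int a = st.nodeDeme[c0];
  std::vector<double> npT; std::vector<int> npD; // new path of c0
  std::vector<double> reT; std::vector<int> reD; // root-lineage extension
  double maxTheta = *std::max_element(theta.begin(), theta.end());
  double tmax = out.time[rootNode];
  for (int v = 0; v < nnode; ++v)
    if (v != p) tmax = std::max(tmax, st.time[v]);
  double maxT = tmax + cap * maxTheta;
  int target = -1;
  size_t bi = std::lower_bound(bps.begin(), bps.end(), t) - bps.begin();
  while (bi < bps.size() && bps[bi] <= t) ++bi;
  long guard = 0;
  while (true) {
    if (++guard > 1000000) return false;
    int nAlive = 0, nPart = 0, lastAliveIdx = -1;
    for (size_t si = 0; si < segs.size(); ++si) {
      if (segs[si].t0 <= t && segs[si].t1 > t) {
        ++nAlive; lastAliveIdx = (int)si;
        if (segs[si].deme == a) ++nPart;
      }
    }
    bool joint = (nAlive == 1) && !std::isfinite(segs[lastAliveIdx].t1);
    if (joint) { // only the extended root lineage remains: evolve jointly
      int rdeme = segs[lastAliveIdx].deme;
      double rateMigA = outRate[a];
      double rateMigR = outRate[rdeme];
      double rateCoal = (a == rdeme) ? 2.0 / theta[a] : 0.0;
      double tot = rateMigA + rateMigR + rateCoal;
      if (tot <= 0.0) return false;
      t += exp_rand() / tot;
      if (t > maxT) return false;
      double u = unif_rand() * tot;
      if (u < rateCoal) { target = segs[lastAliveIdx].node; break; }
      if (u < rateCoal + rateMigA) {
        a = sampleDest(&M[(size_t)a * nd], nd, outRate[a]);
        npT.push_back(t); npD.push_back(a);
      } else {
        int j = sampleDest(&M[(size_t)rdeme * nd], nd, outRate[rdeme]);
        reT.push_back(t); reD.push_back(j);
        segs[lastAliveIdx].deme = j;
      }
      continue;
    }
    double rate = outRate[a] + 2.0 / theta[a] * nPart;
    double nxt = (bi < bps.size()) ? bps[bi] : R_PosInf;
    if (rate <= 0.0) {
      if (!std::isfinite(nxt)) return false;
      t = nxt; ++bi;
      continue;
    }
    double dt = exp_rand() / rate;
    if (t + dt > nxt) { t = nxt; ++bi; continue; }
    t += dt;
    if (t > maxT) return false;
    if (unif_rand() * rate < outRate[a]) {
      a = sampleDest(&M[(size_t)a * nd], nd, outRate[a]);
      npT.push_back(t); npD.push_back(a);
    } else {
      int pick = (int)std::floor(unif_rand() * nPart);
      for (size_t si = 0; si < segs.size(); ++si) {
        if (segs[si].t0 <= t && segs[si].t1 > t && segs[si].deme == a) {
          if (pick-- == 0) { target = segs[si].node; break; }
        }
      }
      break;
    }
  }
  // re-insert p as the coalescence of c0 with target at (t, a)
  int x = target;
  out.time[p] = t;
  out.nodeDeme[p] = a;
  for (size_t e = 0; e < reT.size(); ++e) {
    if (reT[e] <= t) {
      out.paths[rootNode].t.push_back(reT[e]);
      out.paths[rootNode].d.push_back(reD[e]);
    }
  }
  if (x == rootNode && out.parent[x] == 0) {
    out.parent[p] = 0;
    // lineage above the new root no longer exists
    Path& px = out.paths[x];
    size_t keep = 0;
    while (keep < px.t.size() && px.t[keep] <= t) ++keep;
    px.t.resize(keep); px.d.resize(keep);
  } else {
    int xp = out.parent[x];
    out.parent[p] = xp;
    Path& px = out.paths[x];
    size_t keep = 0;
    while (keep < px.t.size() && px.t[keep] <= t) ++keep;
    out.paths[p].t.assign(px.t.begin() + keep, px.t.end());
    out.paths[p].d.assign(px.d.begin() + keep, px.d.end());
    px.t.resize(keep); px.d.resize(keep);
  }
  out.parent[x] = p + 1;
  out.parent[c0] = p + 1;
  out.paths[c0].t = npT;
  out.paths[c0].d = npD;
  return true;
}

// Deme-path refresh proposal: pick a random non-root lineage and redraw
// its migration path from the CTMC at the driving rates, conditioned on
// its fixed start and end demes (by retrying). Tree and all other paths
// unchanged. Returns false when no endpoint-matching path is found.
bool proposePath(const GState& st, const std::vector<double>& M,
                 const std::vector<double>& outRate, GState& out) {
  int nnode = st.parent.size();
  int nd = st.nd;
  int root = -1;
  for (int v = 0; v < nnode; ++v) if (st.parent[v] == 0) { root = v; break; }
  int v = (int)std::floor(unif_rand() * (nnode - 1));
  if (v >= root) ++v;
  int p = st.parent[v] - 1;
  double t0 = st.time[v], t1 = st.time[p];
  int d0 = st.nodeDeme[v], d1 = st.nodeDeme[p];
  std::vector<double> npT; std::vector<int> npD;
  bool ok = false;
  for (int retry = 0; retry < 30 && !ok; ++retry) {
    npT.clear(); npD.clear();
    double t = t0;
    int a = d0;
    while (true) {
      if (outRate[a] <= 0.0) break;
      t += exp_rand() / outRate[a];
      if (t >= t1) break;
      a = sampleDest(&M[(size_t)a * nd], nd, outRate[a]);
      npT.push_back(t); npD.push_back(a);
    }
    ok = (a == d1);
  }
  if (!ok) return false;
  out = st;
  out.paths[v].t = npT;
  out.paths[v].d = npD;
  return true;
}

// Transition probability P(X(dt) = b | X(0) = a) of the migration CTMC
// (generator: off-diagonal M[i][j], diagonal -outRate[i]) by uniformization.
double ctmcTransProb(const std::vector<double>& M,
                     const std::vector<double>& outRate, int nd,
                     int a, int b, double dt) {
  double lam = 0.0;
  for (int i = 0; i < nd; ++i) lam = std::max(lam, outRate[i]);
  if (lam <= 0.0) return (a == b) ? 1.0 : 0.0;
  lam *= 1.0001;
  // DTMC kernel K = I + Q/lam
  std::vector<double> K((size_t)nd * nd);
  for (int i = 0; i < nd; ++i)
    for (int j = 0; j < nd; ++j)
      K[(size_t)i * nd + j] =
        (i == j ? 1.0 - outRate[i] / lam : M[(size_t)i * nd + j] / lam);
  double x = lam * dt;
  // row a of exp(Q dt) = sum_k Pois(k; x) (K^k)[a, ]
  std::vector<double> v(nd, 0.0), w(nd);
  v[a] = 1.0;
  double pk = std::exp(-x); // Poisson(0)
  double acc = pk * v[b];
  int kmax = (int)(x + 12.0 * std::sqrt(x + 1.0) + 20.0);
  for (int k = 1; k <= kmax; ++k) {
    for (int j = 0; j < nd; ++j) {
      double s = 0.0;
      for (int i = 0; i < nd; ++i) s += v[i] * K[(size_t)i * nd + j];
      w[j] = s;
    }
    std::swap(v, w);
    pk *= x / k;
    acc += pk * v[b];
    if (pk < 1e-14 && k > x) break;
  }
  return std::min(std::max(acc, 0.0), 1.0);
}

// CTMC bridge by rejection: path from deme a at t0 to deme b at t1 under
// the driving rates. Returns false when no match is found within `tries`.
bool ctmcBridge(const std::vector<double>& M,
                const std::vector<double>& outRate, int nd,
                int a, int b, double t0, double t1, int tries,
                std::vector<double>& outT, std::vector<int>& outD) {
  for (int r = 0; r < tries; ++r) {
    outT.clear(); outD.clear();
    double t = t0;
    int cur = a;
    while (true) {
      if (outRate[cur] <= 0.0) break;
      t += exp_rand() / outRate[cur];
      if (t >= t1) break;
      cur = sampleDest(&M[(size_t)cur * nd], nd, outRate[cur]);
      outT.push_back(t); outD.push_back(cur);
    }
    if (cur == b) return true;
  }
  return false;
}

// Node-deme flip: pick an internal node, propose a new deme for it and
// redraw the three adjacent path segments as endpoint-conditioned CTMC
// bridges. The tree (and hence the data likelihood) is unchanged; the
// Hastings ratio carries the coalescence-rate factor, the pair-time
// interaction terms (computed by the caller) and the bridge endpoint
// normalisers returned in logqCorr.
bool proposeDemeFlip(const GState& st, const std::vector<double>& theta,
                     const std::vector<double>& M,
                     const std::vector<double>& outRate, GState& out,
                     double& logAccBase) {
  int nnode = st.parent.size();
  int nd = st.nd;
  if (nd < 2 || nnode <= st.n) return false;
  int p = st.n + (int)std::floor(unif_rand() * (nnode - st.n));
  int dOld = st.nodeDeme[p];
  int dNew = (int)std::floor(unif_rand() * (nd - 1));
  if (dNew >= dOld) ++dNew;
  int kids[2]; int nk = 0;
  for (int v = 0; v < nnode; ++v)
    if (st.parent[v] - 1 == p && nk < 2) kids[nk++] = v;
  if (nk != 2) return false;
  out = st;
  out.nodeDeme[p] = dNew;
  double tP = st.time[p];
  logAccBase = std::log(theta[dOld]) - std::log(theta[dNew]); // 2/theta ratio
  std::vector<double> bt; std::vector<int> bd;
  for (int s = 0; s < 3; ++s) {
    int v, a, b; double t0, t1;
    if (s < 2) {          // child segment: from child's deme up to p
      v = kids[s]; a = st.nodeDeme[v]; b = dNew; t0 = st.time[v]; t1 = tP;
    } else {              // p's own segment up to its parent
      if (st.parent[p] == 0) continue;
      v = p; a = dNew; b = st.nodeDeme[st.parent[p] - 1];
      t0 = tP; t1 = st.time[st.parent[p] - 1];
    }
    if (!ctmcBridge(M, outRate, nd, a, b, t0, t1, 30, bt, bd)) return false;
    out.paths[v].t = bt;
    out.paths[v].d = bd;
    // endpoint normalisers: q uses Z(a -> b); reverse move uses the old demes
    int aOld = (s < 2) ? st.nodeDeme[v] : dOld;
    int bOld = (s < 2) ? dOld : b;
    double zNew = ctmcTransProb(M, outRate, nd, a, b, t1 - t0);
    double zOld = ctmcTransProb(M, outRate, nd, aOld, bOld, t1 - t0);
    if (zOld <= 0.0 || zNew <= 0.0) return false;
    logAccBase += std::log(zNew) - std::log(zOld);
  }
  return true;
}

// Structured-coalescent sufficient statistics of a state:
// coal[nd], pairTime[nd], lineageTime[nd], migrations[nd*nd] row-major.
void stateStats(const GState& st, std::vector<double>& out) {
  int nd = st.nd, n = st.n;
  int nnode = st.parent.size();
  struct Ev { double t; int type, i, j; };
  std::vector<Ev> ev;
  for (int v = n; v < nnode; ++v)
    ev.push_back({st.time[v], 1, st.nodeDeme[v], 0});
  for (int v = 0; v < nnode; ++v) {
    int from = st.nodeDeme[v];
    for (size_t e = 0; e < st.paths[v].t.size(); ++e) {
      ev.push_back({st.paths[v].t[e], 2, from, st.paths[v].d[e]});
      from = st.paths[v].d[e];
    }
  }
  std::sort(ev.begin(), ev.end(),
            [](const Ev& a, const Ev& b) { return a.t < b.t; });
  std::vector<int> k(nd, 0);
  for (int v = 0; v < n; ++v) ++k[st.nodeDeme[v]];
  out.assign(3 * nd + nd * nd, 0.0);
  double t0 = 0.0;
  for (size_t r = 0; r < ev.size(); ++r) {
    double dt = ev[r].t - t0;
    for (int i = 0; i < nd; ++i) {
      out[nd + i] += k[i] * (k[i] - 1) / 2.0 * dt;   // pairTime
      out[2 * nd + i] += k[i] * dt;                  // lineageTime
    }
    t0 = ev[r].t;
    if (ev[r].type == 1) {
      out[ev[r].i] += 1.0;                           // coal
      --k[ev[r].i];
    } else {
      out[3 * nd + ev[r].i * nd + ev[r].j] += 1.0;   // migrations
      --k[ev[r].i]; ++k[ev[r].j];
    }
  }
}

GState stateFromR(const List& stR) {
  GState st;
  st.n = as<int>(stR["n"]);
  st.nd = as<int>(stR["nd"]);
  IntegerVector pa = stR["parent"], ndm = stR["nodeDeme"];
  NumericVector tm = stR["time"];
  st.parent.assign(pa.begin(), pa.end());
  st.nodeDeme.assign(ndm.begin(), ndm.end());
  for (size_t i = 0; i < st.nodeDeme.size(); ++i) --st.nodeDeme[i]; // 0-based
  st.time.assign(tm.begin(), tm.end());
  List paths = stR["paths"];
  st.paths.resize(st.parent.size());
  for (int v = 0; v < (int)st.parent.size(); ++v) {
    NumericMatrix m = paths[v];
    for (int r = 0; r < m.nrow(); ++r) {
      st.paths[v].t.push_back(m(r, 0));
      st.paths[v].d.push_back((int)m(r, 1) - 1);
    }
  }
  return st;
}

List stateToR(const GState& st) {
  int nnode = st.parent.size();
  IntegerVector pa(nnode), ndm(nnode);
  NumericVector tm(nnode);
  List paths(nnode);
  for (int v = 0; v < nnode; ++v) {
    pa[v] = st.parent[v];
    ndm[v] = st.nodeDeme[v] + 1;
    tm[v] = st.time[v];
    int k = st.paths[v].t.size();
    NumericMatrix m(k, 2);
    for (int r = 0; r < k; ++r) {
      m(r, 0) = st.paths[v].t[r];
      m(r, 1) = st.paths[v].d[r] + 1;
    }
    colnames(m) = CharacterVector::create("time", "deme");
    paths[v] = m;
  }
  return List::create(_["n"] = st.n, _["nd"] = st.nd, _["parent"] = pa,
                      _["time"] = tm, _["nodeDeme"] = ndm, _["paths"] = paths);
}

} // namespace

// [[Rcpp::export(name = ".mhChainCpp")]]
List mhChainCpp(List initState, NumericVector theta, NumericMatrix M,
                IntegerMatrix patterns, NumericVector weights,
                NumericMatrix right, NumericVector vals, NumericMatrix left,
                NumericVector freqs, NumericVector rates, NumericVector probs,
                int nIter, int burnin, int thin, double power, double cap,
                int nRefresh = 10) {
  GState st = stateFromR(initState);
  int nd = st.nd;
  std::vector<double> th(theta.begin(), theta.end());
  std::vector<double> Mr((size_t)nd * nd);
  std::vector<double> outRate(nd, 0.0);
  for (int i = 0; i < nd; ++i)
    for (int j = 0; j < nd; ++j) {
      Mr[(size_t)i * nd + j] = M(i, j);
      if (i != j) outRate[i] += M(i, j);
    }
  PruneScratch sc;
  int nnode = st.parent.size();
  int ntip = patterns.nrow(), npat = patterns.ncol(), ncat = rates.size();
  double ll = pruneLoglik(st.parent.data(), st.time.data(), nnode,
                          patterns.begin(), ntip, npat, weights.begin(),
                          right.begin(), vals.begin(), left.begin(),
                          freqs.begin(), rates.begin(), probs.begin(),
                          ncat, 1.0, sc);
  int nkeep = (nIter > burnin) ? (nIter - burnin) / thin : 0;
  NumericMatrix stats(nkeep, 3 * nd + nd * nd);
  NumericVector llTrace(nkeep);
  std::vector<double> sbuf, sbufOld, sbufNew;
  GState prop;
  int acc = 0, row = 0;
  for (int it = 1; it <= nIter; ++it) {
    // one tree move (re-simulation; requires a pruning pass) ...
    if (proposeResim(st, th, Mr, outRate, cap, prop)) {
      double ll2 = pruneLoglik(prop.parent.data(), prop.time.data(), nnode,
                               patterns.begin(), ntip, npat, weights.begin(),
                               right.begin(), vals.begin(), left.begin(),
                               freqs.begin(), rates.begin(), probs.begin(),
                               ncat, 1.0, sc);
      if (std::isfinite(ll2) &&
          std::log(unif_rand()) < power * (ll2 - ll)) {
        std::swap(st, prop); ll = ll2; ++acc;
      }
    }
    // ... plus a batch of cheap migration-history refreshes (tree and
    // likelihood unchanged): deme-path redraws and node-deme flips
    for (int r = 0; r < nRefresh; ++r) {
      bool flip = unif_rand() < 0.5 && st.parent.size() > (size_t)st.n;
      double base = 0.0;
      bool ok = flip ? proposeDemeFlip(st, th, Mr, outRate, prop, base)
                     : (st.parent.size() > 1 &&
                        proposePath(st, Mr, outRate, prop));
      if (!ok) continue;
      stateStats(st, sbufOld);
      stateStats(prop, sbufNew);
      double dlp = base;
      for (int i = 0; i < nd; ++i)
        dlp -= 2.0 / th[i] * (sbufNew[nd + i] - sbufOld[nd + i]);
      if (std::log(unif_rand()) < dlp) std::swap(st, prop);
    }
    if (it > burnin && (it - burnin) % thin == 0 && row < nkeep) {
      stateStats(st, sbuf);
      for (size_t q = 0; q < sbuf.size(); ++q) stats(row, q) = sbuf[q];
      llTrace[row] = ll;
      ++row;
    }
  }
  return List::create(_["stats"] = stats, _["loglik"] = llTrace,
                      _["acceptance"] = (double)acc / nIter,
                      _["state"] = stateToR(st));
}
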