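// MC3 sampler core: single-edge Metropolis-Hastings moves over layered DAGs
// scored by the BGe marginal likelihood, with an energy-based structure
// prior and an optional inverse-temperature chain. Called in chunks from R
// so that checkpointing stays on the R side.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

struct Engine {
  int d, nGE, N;
  std::vector<int> layer;               // 0 GE, 1 CNV, 2 METH
  std::vector<int> gePos;               // node -> GE index or -1
  std::vector<int> candRow;             // d*d -> candidate row (1-based), 0
  std::vector<int> candU, candV;        // candidate edge endpoints (0-based)
  std::vector<char> adj;                // d*d
  std::vector<uint64_t> geAdj;          // GE adjacency bitsets (row = parent)
  std::vector<int> indegGE, indegCNV, indegMETH;
  std::vector<std::vector<int> > parents;
  std::vector<double> bEdge;            // prior belief per candidate row
  std::vector<double> bMat;             // d*d
  double tdiag, alphaMu, alphaW;
  const double* Rm;                     // posterior parametric matrix d*d
  std::vector<double> localSc;
  double total, E;
  int fanIn[3];
  std::unordered_map<uint64_t, double> cache;
};

inline int at(const Engine& e, int u, int v) { return u + e.d * v; }

// log det of the principal submatrix of M (d x d, column-major) over idx,
// by an in-place Cholesky on a small buffer; one jitter retry
double logdetSub(const double* M, int d, const std::vector<int>& idx) {
  const int l = (int)idx.size();
  std::vector<double> A(l * l);
  for (int j = 0; j < l; ++j)
    for (int i = 0; i < l; ++i)
      A[i + l * j] = M[idx[i] + d * idx[j]];
  for (int attempt = 0; attempt < 2; ++attempt) {
    std::vector<double> L(A);
    if (attempt == 1)
      for (int k = 0; k < l; ++k) L[k + l * k] += 1e-8;
    double logdet = 0.0;
    bool ok = true;
    for (int k = 0; k < l && ok; ++k) {
      double s = L[k + l * k];
      for (int m = 0; m < k; ++m) s -= L[k + l * m] * L[k + l * m];
      if (s <= 0.0) { ok = false; break; }
      double lkk = std::sqrt(s);
      L[k + l * k] = lkk;
      logdet += std::log(lkk);
      for (int i = k + 1; i < l; ++i) {
        double v = L[i + l * k];
        for (int m = 0; m < k; ++m) v -= L[i + l * m] * L[k + l * m];
        L[i + l * k] = v / lkk;
      }
    }
    if (ok) return 2.0 * logdet;
  }
  stop("numerically degenerate posterior matrix in BGe score");
  return 0.0; // unreachable
}

// log marginal likelihood of the data restricted to the node subset idx;
// the subset model inherits Wishart dof alphaW - d + |idx|
double logmlSubset(const Engine& e, const std::vector<int>& idx) {
  const int l = (int)idx.size();
  if (l == 0) return 0.0;
  const double aw = e.alphaW - e.d + l;
  const double N = e.N;
  double lgr = 0.0;
  for (int j = 1; j <= l; ++j)
    lgr += R::lgammafn((N + aw + 1 - j) / 2.0) -
           R::lgammafn((aw + 1 - j) / 2.0);
  return -(l * N / 2.0) * std::log(M_PI) +
         (l / 2.0) * (std::log(e.alphaMu) - std::log(e.alphaMu + N)) +
         lgr + (aw / 2.0) * (l * std::log(e.tdiag)) -
         ((N + aw) / 2.0) * logdetSub(e.Rm, e.d, idx);
}

double localScore(Engine& e, int v, std::vector<int> pars) {
  std::sort(pars.begin(), pars.end());
  uint64_t key = 0;
  bool cacheable = e.d <= 250 && pars.size() <= 7;
  if (cacheable) {
    key = (uint64_t)(v + 1);
    for (size_t i = 0; i < pars.size(); ++i)
      key = (key << 8) | (uint64_t)(pars[i] + 1);
    std::unordered_map<uint64_t, double>::iterator it = e.cache.find(key);
    if (it != e.cache.end()) return it->second;
  }
  std::vector<int> joint(pars);
  joint.push_back(v);
  double val = logmlSubset(e, joint) - logmlSubset(e, pars);
  if (cacheable) e.cache[key] = val;
  return val;
}

void applyEdge(Engine& e, int u, int v, bool add) {
  e.adj[at(e, u, v)] = add ? 1 : 0;
  std::vector<int>& p = e.parents[v];
  if (add) p.push_back(u);
  else p.erase(std::find(p.begin(), p.end(), u));
  int step = add ? 1 : -1;
  if (e.layer[u] == 0) {
    e.indegGE[v] += step;
    uint64_t bit = 1ULL << e.gePos[v];
    if (add) e.geAdj[e.gePos[u]] |= bit;
    else e.geAdj[e.gePos[u]] &= ~bit;
  } else if (e.layer[u] == 1) e.indegCNV[v] += step;
  else e.indegMETH[v] += step;
}

void geReach(const Engine& e, std::vector<uint64_t>& reach) {
  reach = e.geAdj;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int i = 0; i < e.nGE; ++i) {
      uint64_t r = reach[i], nr = r;
      uint64_t bits = r;
      while (bits) {
        int j = __builtin_ctzll(bits);
        bits &= bits - 1;
        nr |= reach[j];
      }
      if (nr != r) { reach[i] = nr; changed = true; }
    }
  }
}

// enumerate legal moves; type 1 = add, 2 = delete, 3 = reverse
void enumMoves(const Engine& e, std::vector<int>& mu, std::vector<int>& mv,
               std::vector<int>& mt) {
  mu.clear(); mv.clear(); mt.clear();
  std::vector<uint64_t> reach;
  geReach(e, reach);
  const size_t nc = e.candU.size();
  for (size_t r = 0; r < nc; ++r) {
    const int u = e.candU[r], v = e.candV[r];
    if (e.adj[at(e, u, v)]) {
      mu.push_back(u); mv.push_back(v); mt.push_back(2);   // delete
      if (e.layer[u] == 0 && e.candRow[at(e, v, u)] &&
          e.indegGE[u] < e.fanIn[0]) {
        // reversal legal iff no other directed path u ~> v (length >= 2;
        // in a DAG such a path cannot use the edge u->v itself)
        const int gu = e.gePos[u], gv = e.gePos[v];
        uint64_t mids = e.geAdj[gu] & ~(1ULL << gv);
        bool path2 = false;
        while (mids) {
          int w = __builtin_ctzll(mids);
          mids &= mids - 1;
          if (reach[w] & (1ULL << gv)) { path2 = true; break; }
        }
        if (!path2) { mu.push_back(u); mv.push_back(v); mt.push_back(3); }
      }
    } else {
      bool ok;
      if (e.layer[u] == 0)
        ok = e.indegGE[v] < e.fanIn[0] &&
             !(reach[e.gePos[v]] & (1ULL << e.gePos[u]));
      else if (e.layer[u] == 1) ok = e.indegCNV[v] < e.fanIn[1];
      else ok = e.indegMETH[v] < e.fanIn[2];
      if (ok) { mu.push_back(u); mv.push_back(v); mt.push_back(1); }
    }
  }
}

int countMoves(const Engine& e) {
  static std::vector<int> mu, mv, mt;
  enumMoves(e, mu, mv, mt);
  return (int)mu.size();
}

double logPseudoZ(const Engine& e, double beta) {
  double s = 0.0;
  for (size_t r = 0; r < e.bEdge.size(); ++r)
    s += std::log(std::exp(-beta * e.bEdge[r]) +
                  std::exp(-beta * (1.0 - e.bEdge[r])));
  return s;
}

Engine buildEngine(const IntegerMatrix& adj, const IntegerMatrix& candRow,
                   const IntegerVector& layerCode,
                   const IntegerVector& fanIn, const NumericVector& bEdge,
                   const NumericMatrix& Rmat, double tdiag, double alphaMu,
                   double alphaW, int N) {
  Engine e;
  e.d = adj.nrow();
  e.N = N;
  e.tdiag = tdiag; e.alphaMu = alphaMu; e.alphaW = alphaW;
  e.Rm = REAL(Rmat);
  e.layer.assign(layerCode.begin(), layerCode.end());
  e.gePos.assign(e.d, -1);
  e.nGE = 0;
  for (int i = 0; i < e.d; ++i)
    if (e.layer[i] == 0) e.gePos[i] = e.nGE++;
  if (e.nGE > 64) stop("at most 64 GE nodes are supported");
  for (int k = 0; k < 3; ++k) e.fanIn[k] = fanIn[k];
  e.candRow.assign(candRow.begin(), candRow.end());
  int nc = (int)bEdge.size();
  e.candU.assign(nc, 0); e.candV.assign(nc, 0);
  for (int v = 0; v < e.d; ++v)
    for (int u = 0; u < e.d; ++u) {
      int r = candRow(u, v);
      if (r > 0) { e.candU[r - 1] = u; e.candV[r - 1] = v; }
    }
  e.bEdge.assign(bEdge.begin(), bEdge.end());
  e.bMat.assign(e.d * e.d, 0.0);
  for (int r = 0; r < nc; ++r)
    e.bMat[at(e, e.candU[r], e.candV[r])] = e.bEdge[r];
  e.adj.assign(e.d * e.d, 0);
  e.geAdj.assign(e.nGE > 0 ? e.nGE : 1, 0ULL);
  e.indegGE.assign(e.d, 0); e.indegCNV.assign(e.d, 0);
  e.indegMETH.assign(e.d, 0);
  e.parents.assign(e.d, std::vector<int>());
  for (int v = 0; v < e.d; ++v)
    for (int u = 0; u < e.d; ++u)
      if (adj(u, v)) applyEdge(e, u, v, true);
  return e;
}

} // namespace

// [[Rcpp::export(name = ".cppLocalScores")]]
NumericVector cppLocalScores(IntegerMatrix adj, IntegerMatrix candRow,
                             IntegerVector layerCode, IntegerVector fanIn,
                             NumericVector bEdge, NumericMatrix Rmat,
                             double tdiag, double alphaMu, double alphaW,
                             int N) {
  Engine e = buildEngine(adj, candRow, layerCode, fanIn, bEdge, Rmat, tdiag,
                         alphaMu, alphaW, N);
  NumericVector out(e.d);
  for (int v = 0; v < e.d; ++v) out[v] = localScore(e, v, e.parents[v]);
  return out;
}

// [[Rcpp::export(name = ".cppEnumMoves")]]
List cppEnumMoves(IntegerMatrix adj, IntegerMatrix candRow,
                  IntegerVector layerCode, IntegerVector fanIn) {
  NumericVector dummyB(max(candRow));
  NumericMatrix dummyR(adj.nrow(), adj.nrow());
  Engine e = buildEngine(adj, candRow, layerCode, fanIn, dummyB, dummyR,
                         1.0, 1.0, adj.nrow() + 2.0, 2);
  std::vector<int> mu, mv, mt;
  enumMoves(e, mu, mv, mt);
  return List::create(_["u"] = wrap(mu), _["v"] = wrap(mv),
                      _["type"] = wrap(mt));
}

// [[Rcpp::export(name = ".cppSampleChunk")]]
List cppSampleChunk(IntegerMatrix adj, IntegerMatrix candRow,
                    IntegerVector layerCode, IntegerVector fanIn,
                    NumericVector bEdge, NumericMatrix Rmat, double tdiag,
                    double alphaMu, double alphaW, int N,
                    NumericVector localSc, double total, double E,
                    double beta, int nIter, int iterOffset, int burnIn,
                    int thin, bool sampleBeta, double betaMax,
                    double betaHalfWidth) {
  Engine e = buildEngine(adj, candRow, layerCode, fanIn, bEdge, Rmat, tdiag,
                         alphaMu, alphaW, N);
  e.localSc.assign(localSc.begin(), localSc.end());
  e.total = total; e.E = E;

  NumericVector serScore(nIter), serPrior(nIter), serBeta(nIter);
  IntegerVector accepted(4), proposed(4); // add, delete, reverse, beta
  std::vector<std::vector<int> > snaps;
  std::vector<int> snapIter;
  std::vector<int> mu, mv, mt;
  double logZ = logPseudoZ(e, beta);

  for (int t = 1; t <= nIter; ++t) {
    const int it = iterOffset + t;
    enumMoves(e, mu, mv, mt);
    const int K = (int)mu.size();
    if (K == 0) stop("sampler stuck: empty move neighborhood");
    int k = (int)(unif_rand() * K);
    if (k >= K) k = K - 1;
    const int u = mu[k], v = mv[k], type = mt[k];
    double dScore, dE, newV = 0.0, newU = 0.0;
    std::vector<int> pv = e.parents[v];
    if (type == 1) {
      pv.push_back(u);
      newV = localScore(e, v, pv);
      dScore = newV - e.localSc[v];
      dE = 1.0 - 2.0 * e.bMat[at(e, u, v)];
      applyEdge(e, u, v, true);
    } else if (type == 2) {
      pv.erase(std::find(pv.begin(), pv.end(), u));
      newV = localScore(e, v, pv);
      dScore = newV - e.localSc[v];
      dE = 2.0 * e.bMat[at(e, u, v)] - 1.0;
      applyEdge(e, u, v, false);
    } else {
      pv.erase(std::find(pv.begin(), pv.end(), u));
      newV = localScore(e, v, pv);
      std::vector<int> pu = e.parents[u];
      pu.push_back(v);
      newU = localScore(e, u, pu);
      dScore = (newV - e.localSc[v]) + (newU - e.localSc[u]);
      dE = 2.0 * (e.bMat[at(e, u, v)] - e.bMat[at(e, v, u)]);
      applyEdge(e, u, v, false);
      applyEdge(e, v, u, true);
    }
    const int K2 = countMoves(e);
    const double logA = dScore - beta * dE + std::log((double)K) -
                        std::log((double)K2);
    proposed[type - 1]++;
    if (std::log(unif_rand()) < logA) {
      accepted[type - 1]++;
      e.localSc[v] = newV;
      if (type == 3) e.localSc[u] = newU;
      e.total += dScore;
      e.E += dE;
    } else {
      if (type == 1) applyEdge(e, u, v, false);
      else if (type == 2) applyEdge(e, u, v, true);
      else { applyEdge(e, v, u, false); applyEdge(e, u, v, true); }
    }
    if (sampleBeta && it % e.d == 0) {
      proposed[3]++;
      double prop = beta + unif_rand() * 2.0 * betaHalfWidth -
                    betaHalfWidth;
      while (prop < 0.0 || prop > betaMax) {
        if (prop < 0.0) prop = -prop;
        if (prop > betaMax) prop = 2.0 * betaMax - prop;
      }
      const double lZp = logPseudoZ(e, prop);
      const double lA = -(prop - beta) * e.E + logZ - lZp;
      if (std::log(unif_rand()) < lA) {
        accepted[3]++;
        beta = prop;
        logZ = lZp;
      }
    }
    serScore[t - 1] = e.total;
    serPrior[t - 1] = -beta * e.E - logZ;
    serBeta[t - 1] = beta;
    if (it > burnIn && (it - burnIn) % thin == 0) {
      std::vector<int> s;
      for (size_t r = 0; r < e.candU.size(); ++r)
        if (e.adj[at(e, e.candU[r], e.candV[r])]) s.push_back((int)r + 1);
      snaps.push_back(s);
      snapIter.push_back(it);
    }
  }

  IntegerMatrix adjOut(e.d, e.d);
  for (int v = 0; v < e.d; ++v)
    for (int u = 0; u < e.d; ++u) adjOut(u, v) = e.adj[at(e, u, v)];
  List snapList(snaps.size());
  for (size_t i = 0; i < snaps.size(); ++i) snapList[i] = wrap(snaps[i]);
  return List::create(
    _["adj"] = adjOut, _["localSc"] = wrap(e.localSc),
    _["total"] = e.total, _["E"] = e.E, _["beta"] = beta,
    _["logScore"] = serScore, _["logPrior"] = serPrior,
    _["betaSeries"] = serBeta, _["snapshots"] = snapList,
    _["snapshotIter"] = wrap(snapIter), _["accepted"] = accepted,
    _["proposed"] = proposed);
}
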