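// Exact branch-and-bound solvers for the constrained minimum hitting-set
// problems behind individual (ITS) and fair cohort (CTS) target selection.
//
// Cells are bitsets; per gene we hold the mask of tumor cells it can kill
// and the mask of non-tumor cells it would kill. Search is iterative
// deepening on solution cardinality with two prunes:
//   * coverage is submodular, so (current coverage) + (sum of the t largest
//     residual single-gene gains) bounds what t more genes can add;
//   * non-tumor kills are monotone under set union, so a branch whose
//     cumulative kills already exceed the budget is dead.
// Both solvers prove optimality by exhausting all smaller cardinalities.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

typedef std::vector<uint64_t> BitVec;

inline int popcnt(const BitVec &v) {
  int s = 0;
  for (uint64_t w : v) s += __builtin_popcountll(w);
  return s;
}

inline void orin(BitVec &a, const BitVec &b) {
  for (size_t i = 0; i < a.size(); ++i) a[i] |= b[i];
}

// |g \ cur|
inline int gain(const BitVec &g, const BitVec &cur) {
  int s = 0;
  for (size_t i = 0; i < g.size(); ++i) s += __builtin_popcountll(g[i] & ~cur[i]);
  return s;
}

// rows = genes, cols = cells -> per-gene bitset over cells
std::vector<BitVec> masks_from_matrix(const LogicalMatrix &m) {
  int ng = m.nrow(), nc = m.ncol();
  int words = nc > 0 ? (nc + 63) / 64 : 1;
  std::vector<BitVec> out(ng, BitVec(words, 0));
  for (int c = 0; c < nc; ++c)
    for (int g = 0; g < ng; ++g)
      if (m(g, c)) out[g][c / 64] |= (uint64_t(1) << (c % 64));
  return out;
}

struct SearchLimits {
  long long nodes = 0;
  long long node_limit;
  bool timed_out = false;
  bool tick() {
    if (++nodes > node_limit) { timed_out = true; return true; }
    return false;
  }
};

// ---------------------------------------------------------------- ITS ----

struct ItsSearch {
  const std::vector<BitVec> *tum, *nt;
  int T, B, k;
  bool stop_first;
  int max_sols;
  SearchLimits *lim;
  std::vector<int> cur;
  std::vector<std::vector<int> > sols;

  // cand: gene indices still admissible, any order. Returns true to abort.
  bool dfs(const std::vector<int> &cand, const BitVec &cov, const BitVec &kill,
           int ncov, int nkill) {
    if (lim->tick()) return true;
    if (ncov >= T) {
      sols.push_back(cur);
      return stop_first || (int)sols.size() >= max_sols;
    }
    int depth = (int)cur.size();
    if (depth == k) return false;
    int rem = k - depth;

    // residual gains; drop zero-gain genes (valid at minimal cardinality:
    // a solution containing a gene with no marginal tumor coverage would
    // yield a smaller feasible solution, contradicting minimality) and
    // genes that blow the kill budget (kills only grow deeper).
    std::vector<std::pair<int, int> > scored; // (gain, gene)
    scored.reserve(cand.size());
    for (int g : cand) {
      int gn = gain((*tum)[g], cov);
      if (gn <= 0) continue;
      if (nkill + gain((*nt)[g], kill) > B) continue;
      scored.push_back(std::make_pair(gn, g));
    }
    std::stable_sort(scored.begin(), scored.end(),
                     [](const std::pair<int, int> &a, const std::pair<int, int> &b) {
                       return a.first > b.first;
                     });
    long bound = ncov;
    for (int i = 0; i < rem && i < (int)scored.size(); ++i) bound += scored[i].first;
    if (bound < T) return false;

    std::vector<int> next;
    next.reserve(scored.size());
    for (size_t i = 0; i < scored.size(); ++i) next.push_back(scored[i].second);
    for (size_t i = 0; i < next.size(); ++i) {
      int g = next[i];
      BitVec cov2 = cov, kill2 = kill;
      orin(cov2, (*tum)[g]);
      orin(kill2, (*nt)[g]);
      int nk = popcnt(kill2);
      if (nk > B) continue;
      cur.push_back(g);
      std::vector<int> rest(next.begin() + i + 1, next.end());
      bool abort = dfs(rest, cov2, kill2, popcnt(cov2), nk);
      cur.pop_back();
      if (abort) return true;
    }
    return false;
  }
};

// Minimum-size subset of `genes` covering >= T tumor cells with <= B kills.
// Searches cardinalities lo..cap. Returns size or -1 (infeasible within cap),
// -2 on node-limit. Fills `sol` with one optimal solution.
int its_min(const std::vector<BitVec> &tum, const std::vector<BitVec> &nt,
            const std::vector<int> &genes, int T, int B, int cap,
            SearchLimits &lim, std::vector<int> &sol) {
  sol.clear();
  if (T <= 0) return 0;
  // usable genes: single-gene kills within budget
  std::vector<int> usable;
  BitVec unionCov;
  std::vector<std::pair<int, int> > covs;
  for (int g : genes) {
    if (popcnt(nt[g]) > B) continue;
    usable.push_back(g);
    if (unionCov.empty()) unionCov = tum[g]; else orin(unionCov, tum[g]);
    covs.push_back(std::make_pair(popcnt(tum[g]), g));
  }
  if (usable.empty() || popcnt(unionCov) < T) return -1;
  std::stable_sort(covs.begin(), covs.end(),
                   [](const std::pair<int, int> &a, const std::pair<int, int> &b) {
                     return a.first > b.first;
                   });
  // cardinality lower bound from sorted single-gene coverages
  int lo = 0;
  long acc = 0;
  for (size_t i = 0; i < covs.size() && acc < T; ++i) { acc += covs[i].first; ++lo; }
  if (acc < T) return -1;
  std::vector<int> order;
  for (size_t i = 0; i < covs.size(); ++i) order.push_back(covs[i].second);

  int maxk = std::min<int>(cap, (int)usable.size());
  int words = tum.empty() ? 1 : (int)tum[0].size();
  int wordsN = nt.empty() ? 1 : (int)nt[0].size();
  for (int k = std::max(lo, 1); k <= maxk; ++k) {
    ItsSearch s;
    s.tum = &tum; s.nt = &nt; s.T = T; s.B = B; s.k = k;
    s.stop_first = true; s.max_sols = 1; s.lim = &lim;
    BitVec cov(words, 0), kill(wordsN, 0);
    s.dfs(order, cov, kill, 0, 0);
    if (lim.timed_out) return -2;
    if (!s.sols.empty()) { sol = s.sols[0]; return k; }
  }
  return -1;
}

// ---------------------------------------------------------------- CTS ----

struct CtsProblem {
  int npat;
  std::vector<std::vector<BitVec> > tum, nt; // [pat][gene]
  std::vector<int> T, B, cap;
  std::vector<std::vector<char> > usable;    // [pat][gene]
  int ngene;
};

struct CtsSearch {
  const CtsProblem *P;
  int k;
  bool stop_first;
  int max_sols;
  SearchLimits *lim;
  std::vector<int> cur;
  std::vector<std::vector<int> > sols;

  bool leaf_ok() {
    for (int i = 0; i < P->npat; ++i) {
      std::vector<int> sub;
      for (int g : cur) if (P->usable[i][g]) sub.push_back(g);
      std::vector<int> dummy;
      int m = its_min(P->tum[i], P->nt[i], sub, P->T[i], P->B[i], P->cap[i],
                      *lim, dummy);
      if (m == -2) return false; // timeout propagates via lim
      if (m < 0) return false;
    }
    return true;
  }

  bool dfs(const std::vector<int> &cand, std::vector<BitVec> &cov,
           std::vector<int> &ncov) {
    if (lim->tick()) return true;
    int depth = (int)cur.size();
    if (depth == k) {
      if (leaf_ok()) {
        sols.push_back(cur);
        if (stop_first || (int)sols.size() >= max_sols) return true;
      }
      return lim->timed_out;
    }
    int rem = k - depth;
    // per-patient submodular coverage bound (no zero-gain skip here: with
    // per-patient cardinality caps a gene redundant for coverage of the
    // prefix can still be required by some patient's small assignment)
    std::vector<std::vector<int> > gains(P->npat, std::vector<int>(cand.size(), 0));
    for (int i = 0; i < P->npat; ++i) {
      std::vector<int> top;
      for (size_t j = 0; j < cand.size(); ++j) {
        int g = cand[j];
        int gn = P->usable[i][g] ? gain(P->tum[i][g], cov[i]) : 0;
        gains[i][j] = gn;
        top.push_back(gn);
      }
      std::sort(top.begin(), top.end(), std::greater<int>());
      long bound = ncov[i];
      for (int t = 0; t < rem && t < (int)top.size(); ++t) bound += top[t];
      if (bound < P->T[i]) return false;
    }
    // order branches by total gain across patients (descending)
    std::vector<std::pair<long, size_t> > scored;
    for (size_t j = 0; j < cand.size(); ++j) {
      long s = 0;
      for (int i = 0; i < P->npat; ++i) s += gains[i][j];
      scored.push_back(std::make_pair(s, j));
    }
    std::stable_sort(scored.begin(), scored.end(),
                     [](const std::pair<long, size_t> &a, const std::pair<long, size_t> &b) {
                       return a.first > b.first;
                     });
    std::vector<int> next;
    for (size_t i = 0; i < scored.size(); ++i) next.push_back(cand[scored[i].second]);
    for (size_t i = 0; i < next.size(); ++i) {
      int g = next[i];
      std::vector<BitVec> cov2 = cov;
      std::vector<int> ncov2 = ncov;
      for (int p = 0; p < P->npat; ++p)
        if (P->usable[p][g]) {
          orin(cov2[p], P->tum[p][g]);
          ncov2[p] = popcnt(cov2[p]);
        }
      cur.push_back(g);
      std::vector<int> rest(next.begin() + i + 1, next.end());
      bool abort = dfs(rest, cov2, ncov2);
      cur.pop_back();
      if (abort) return true;
    }
    return false;
  }
};

CtsProblem build_cts(const List &tumor_list, const List &nontumor_list,
                     const IntegerVector &minKill, const IntegerVector &maxSide,
                     const IntegerVector &caps) {
  CtsProblem P;
  P.npat = tumor_list.size();
  P.ngene = 0;
  for (int i = 0; i < P.npat; ++i) {
    LogicalMatrix tm = tumor_list[i];
    LogicalMatrix nm = nontumor_list[i];
    if (i == 0) P.ngene = tm.nrow();
    P.tum.push_back(masks_from_matrix(tm));
    P.nt.push_back(masks_from_matrix(nm));
    P.T.push_back(minKill[i]);
    P.B.push_back(maxSide[i]);
    P.cap.push_back(caps[i]);
  }
  P.usable.assign(P.npat, std::vector<char>(P.ngene, 0));
  for (int i = 0; i < P.npat; ++i)
    for (int g = 0; g < P.ngene; ++g)
      P.usable[i][g] = popcnt(P.nt[i][g]) <= P.B[i] ? 1 : 0;
  return P;
}

// candidate genes usable by at least one patient, ordered by total coverage
std::vector<int> cts_candidates(const CtsProblem &P) {
  std::vector<std::pair<long, int> > sc;
  for (int g = 0; g < P.ngene; ++g) {
    long s = 0;
    bool any = false;
    for (int i = 0; i < P.npat; ++i)
      if (P.usable[i][g]) { any = true; s += popcnt(P.tum[i][g]); }
    if (any && s > 0) sc.push_back(std::make_pair(s, g));
  }
  std::stable_sort(sc.begin(), sc.end(),
                   [](const std::pair<long, int> &a, const std::pair<long, int> &b) {
                     return a.first > b.first;
                   });
  std::vector<int> out;
  for (size_t i = 0; i < sc.size(); ++i) out.push_back(sc[i].second);
  return out;
}

int cts_lower_bound(const CtsProblem &P, const std::vector<int> &cand) {
  int lo = 1;
  for (int i = 0; i < P.npat; ++i) {
    std::vector<int> covs;
    for (int g : cand) if (P.usable[i][g]) covs.push_back(popcnt(P.tum[i][g]));
    std::sort(covs.begin(), covs.end(), std::greater<int>());
    long acc = 0;
    int need = 0;
    for (size_t j = 0; j < covs.size() && acc < P.T[i]; ++j) { acc += covs[j]; ++need; }
    if (acc < P.T[i]) return -1; // that patient cannot reach coverage at all
    lo = std::max(lo, need);
  }
  return lo;
}

} // namespace

// [[Rcpp::export]]
List cpp_solve_its(LogicalMatrix tumor_hits, LogicalMatrix nontumor_hits,
                   int min_kill, int max_side_kill, double node_limit) {
  std::vector<BitVec> tum = masks_from_matrix(tumor_hits);
  std::vector<BitVec> nt = masks_from_matrix(nontumor_hits);
  std::vector<int> genes;
  for (int g = 0; g < tumor_hits.nrow(); ++g) genes.push_back(g);
  SearchLimits lim;
  lim.node_limit = (long long)node_limit;
  std::vector<int> sol;
  int res = its_min(tum, nt, genes, min_kill, max_side_kill,
                    tumor_hits.nrow(), lim, sol);
  std::string status = res >= 0 ? "optimal" : (res == -2 ? "timeout" : "infeasible");
  IntegerVector sel(sol.size());
  for (size_t i = 0; i < sol.size(); ++i) sel[i] = sol[i] + 1;
  std::sort(sel.begin(), sel.end());
  return List::create(_["status"] = status, _["selected"] = sel,
                      _["size"] = res >= 0 ? res : NA_INTEGER,
                      _["nodes"] = (double)lim.nodes);
}

// [[Rcpp::export]]
List cpp_enumerate_its(LogicalMatrix tumor_hits, LogicalMatrix nontumor_hits,
                       int min_kill, int max_side_kill, int size,
                       int max_sols, double node_limit) {
  std::vector<BitVec> tum = masks_from_matrix(tumor_hits);
  std::vector<BitVec> nt = masks_from_matrix(nontumor_hits);
  SearchLimits lim;
  lim.node_limit = (long long)node_limit;
  ItsSearch s;
  s.tum = &tum; s.nt = &nt;
  s.T = min_kill; s.B = max_side_kill; s.k = size;
  s.stop_first = false; s.max_sols = max_sols; s.lim = &lim;
  std::vector<int> order;
  std::vector<std::pair<int, int> > covs;
  for (int g = 0; g < tumor_hits.nrow(); ++g) {
    if (popcnt(nt[g]) > max_side_kill) continue;
    covs.push_back(std::make_pair(popcnt(tum[g]), g));
  }
  std::stable_sort(covs.begin(), covs.end(),
                   [](const std::pair<int, int> &a, const std::pair<int, int> &b) {
                     return a.first > b.first;
                   });
  for (size_t i = 0; i < covs.size(); ++i) order.push_back(covs[i].second);
  int words = tum.empty() ? 1 : (int)tum[0].size();
  int wordsN = nt.empty() ? 1 : (int)nt[0].size();
  if (min_kill <= 0) {
    return List::create(_["solutions"] = List::create(IntegerVector(0)),
                        _["truncated"] = false);
  }
  BitVec cov(words, 0), kill(wordsN, 0);
  s.dfs(order, cov, kill, 0, 0);
  List out(s.sols.size());
  for (size_t i = 0; i < s.sols.size(); ++i) {
    IntegerVector v(s.sols[i].size());
    for (size_t j = 0; j < s.sols[i].size(); ++j) v[j] = s.sols[i][j] + 1;
    std::sort(v.begin(), v.end());
    out[i] = v;
  }
  return List::create(_["solutions"] = out,
                      _["truncated"] = (int)s.sols.size() >= max_sols || lim.timed_out);
}

// [[Rcpp::export]]
List cpp_solve_cts(List tumor_list, List nontumor_list, IntegerVector min_kill,
                   IntegerVector max_side_kill, IntegerVector caps,
                   double node_limit) {
  CtsProblem P = build_cts(tumor_list, nontumor_list, min_kill, max_side_kill, caps);
  std::vector<int> cand = cts_candidates(P);
  SearchLimits lim;
  lim.node_limit = (long long)node_limit;
  bool allzero = true;
  for (int i = 0; i < P.npat; ++i) if (P.T[i] > 0) allzero = false;
  if (allzero) {
    return List::create(_["status"] = "optimal", _["selected"] = IntegerVector(0),
                        _["size"] = 0, _["nodes"] = 0.0);
  }
  int lo = cts_lower_bound(P, cand);
  if (lo < 0) {
    return List::create(_["status"] = "infeasible", _["selected"] = IntegerVector(0),
                        _["size"] = NA_INTEGER, _["nodes"] = (double)lim.nodes);
  }
  int words;
  for (int k = lo; k <= (int)cand.size(); ++k) {
    CtsSearch s;
    s.P = &P; s.k = k; s.stop_first = true; s.max_sols = 1; s.lim = &lim;
    std::vector<BitVec> cov;
    std::vector<int> ncov(P.npat, 0);
    for (int i = 0; i < P.npat; ++i) {
      words = P.tum[i].empty() ? 1 : (int)P.tum[i][0].size();
      cov.push_back(BitVec(words, 0));
    }
    s.dfs(cand, cov, ncov);
    if (lim.timed_out)
      return List::create(_["status"] = "timeout", _["selected"] = IntegerVector(0),
                          _["size"] = NA_INTEGER, _["nodes"] = (double)lim.nodes);
    if (!s.sols.empty()) {
      IntegerVector sel(s.sols[0].size());
      for (size_t i = 0; i < s.sols[0].size(); ++i) sel[i] = s.sols[0][i] + 1;
      std::sort(sel.begin(), sel.end());
      return List::create(_["status"] = "optimal", _["selected"] = sel,
                          _["size"] = k, _["nodes"] = (double)lim.nodes);
    }
  }
  return List::create(_["status"] = "infeasible", _["selected"] = IntegerVector(0),
                      _["size"] = NA_INTEGER, _["nodes"] = (double)lim.nodes);
}

// [[Rcpp::export]]
List cpp_enumerate_cts(List tumor_list, List nontumor_list, IntegerVector min_kill,
                       IntegerVector max_side_kill, IntegerVector caps, int size,
                       int max_sols, double node_limit) {
  CtsProblem P = build_cts(tumor_list, nontumor_list, min_kill, max_side_kill, caps);
  std::vector<int> cand = cts_candidates(P);
  SearchLimits lim;
  lim.node_limit = (long long)node_limit;
  CtsSearch s;
  s.P = &P; s.k = size; s.stop_first = false; s.max_sols = max_sols; s.lim = &lim;
  std::vector<BitVec> cov;
  std::vector<int> ncov(P.npat, 0);
  for (int i = 0; i < P.npat; ++i) {
    int words = P.tum[i].empty() ? 1 : (int)P.tum[i][0].size();
    cov.push_back(BitVec(words, 0));
  }
  if (size > 0) s.dfs(cand, cov, ncov);
  List out(s.sols.size());
  for (size_t i = 0; i < s.sols.size(); ++i) {
    IntegerVector v(s.sols[i].size());
    for (size_t j = 0; j < s.sols[i].size(); ++j) v[j] = s.sols[i][j] + 1;
    std::sort(v.begin(), v.end());
    out[i] = v;
  }
  return List::create(_["solutions"] = out,
                      _["truncated"] = (int)s.sols.size() >= max_sols || lim.timed_out);
}
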