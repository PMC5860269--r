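// Random-walk sampling of proxy communities and their functional-homogeneity
// scoring. Walks use R's RNG (unif_rand), so set.seed() in R governs every
// draw. Pairwise similarities are cached per call, keyed on the unordered
// node pair, because consecutive walks revisit the same local neighbourhood.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

namespace {

// similarity of two sorted term-index vectors
double setSim(const std::vector<int>& a, const std::vector<int>& b,
              const std::vector<double>& ic, int measure) {
  size_t i = 0, j = 0;
  int ninter = 0;
  double icInter = 0.0, icUnion = 0.0;
  while (i < a.size() && j < b.size()) {
    if (a[i] == b[j]) {
      ++ninter;
      icInter += ic[a[i]];
      icUnion += ic[a[i]];
      ++i; ++j;
    } else if (a[i] < b[j]) {
      icUnion += ic[a[i]]; ++i;
    } else {
      icUnion += ic[b[j]]; ++j;
    }
  }
  for (; i < a.size(); ++i) icUnion += ic[a[i]];
  for (; j < b.size(); ++j) icUnion += ic[b[j]];
  int nunion = (int)a.size() + (int)b.size() - ninter;
  if (measure == 1) return nunion > 0 ? (double)ninter / nunion : 0.0;
  if (measure == 2) return icUnion > 0 ? icInter / icUnion : 0.0;
  return icInter;  // pandey: IC sum over the intersection
}

// simple random walk until n_distinct distinct nodes are visited; returns
// false when max_steps is exhausted or the walk gets stuck on a degree-0
// node. 'mark' is a reusable scratch vector, reset before returning.
bool doWalk(const std::vector<std::vector<int> >& adj, int start,
            int nDistinct, double maxSteps, double restartProb,
            std::vector<int>& visited, std::vector<char>& mark) {
  visited.clear();
  visited.push_back(start);
  mark[start] = 1;
  int cur = start;
  double steps = 0;
  bool ok = true;
  while ((int)visited.size() < nDistinct) {
    if (steps >= maxSteps) { ok = false; break; }
    steps += 1;
    if (restartProb > 0 && unif_rand() < restartProb) {
      cur = start;
      continue;
    }
    const std::vector<int>& nb = adj[cur];
    if (nb.empty()) { ok = false; break; }
    cur = nb[(int)(unif_rand() * nb.size())];
    if (!mark[cur]) {
      mark[cur] = 1;
      visited.push_back(cur);
    }
  }
  for (size_t k = 0; k < visited.size(); ++k) mark[visited[k]] = 0;
  return ok;
}

std::vector<std::vector<int> > asAdjacency(const List& adj_) {
  int n = adj_.size();
  std::vector<std::vector<int> > adj(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adj_[i];
    adj[i].assign(nb.begin(), nb.end());
  }
  return adj;
}

}  // namespace

// Sample walks_per_start walks from every start node; returns an integer
// matrix (rows = walks) of visited node indices, NA-filled rows for walks
// that failed to terminate. All indices 0-based.
// [[Rcpp::export]]
IntegerMatrix cpp_sample_walks(List adj_, IntegerVector starts,
                               int walksPerStart, int nDistinct,
                               double maxSteps, double restartProb) {
  std::vector<std::vector<int> > adj = asAdjacency(adj_);
  int nw = starts.size() * walksPerStart;
  IntegerMatrix out(nw, nDistinct);
  std::vector<char> mark(adj.size(), 0);
  std::vector<int> visited;
  visited.reserve(nDistinct);
  int w = 0;
  for (int s = 0; s < starts.size(); ++s) {
    for (int k = 0; k < walksPerStart; ++k, ++w) {
      bool ok = doWalk(adj, starts[s], nDistinct, maxSteps, restartProb,
                       visited, mark);
      for (int d = 0; d < nDistinct; ++d)
        out(w, d) = ok ? visited[d] : NA_INTEGER;
    }
  }
  return out;
}

// Walk + score: for every walk report the proxy module's functional
// homogeneity (NA when fewer than two visited nodes are annotated) and its
// research focus (fraction of visited nodes annotated beyond the root).
// closed_: per node a sorted 0-based vector of term indices (empty =
// unannotated); measure: 1 = simUI, 2 = simGIC, 3 = pandey.
// [[Rcpp::export]]
List cpp_walk_profiles(List adj_, IntegerVector starts, int walksPerStart,
                       int nDistinct, List closed_, NumericVector ic_,
                       int measure, LogicalVector beyondRoot,
                       double maxSteps, double restartProb) {
  std::vector<std::vector<int> > adj = asAdjacency(adj_);
  int n = adj.size();
  std::vector<std::vector<int> > closed(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector cl = closed_[i];
    closed[i].assign(cl.begin(), cl.end());
  }
  std::vector<double> ic(ic_.begin(), ic_.end());

  int nw = starts.size() * walksPerStart;
  IntegerVector outStart(nw);
  NumericVector outFh(nw), outFocus(nw);
  LogicalVector outOk(nw);

  std::unordered_map<long long, double> cache;
  std::vector<char> mark(n, 0);
  std::vector<int> visited, annotated;
  visited.reserve(nDistinct);
  annotated.reserve(nDistinct);

  int w = 0;
  for (int s = 0; s < starts.size(); ++s) {
    int start = starts[s];
    for (int k = 0; k < walksPerStart; ++k, ++w) {
      outStart[w] = start;
      bool ok = doWalk(adj, start, nDistinct, maxSteps, restartProb,
                       visited, mark);
      if (!ok) {
        outOk[w] = false;
        outFh[w] = NA_REAL;
        outFocus[w] = NA_REAL;
        continue;
      }
      outOk[w] = true;
      int nBeyond = 0;
      annotated.clear();
      for (size_t v = 0; v < visited.size(); ++v) {
        if (beyondRoot[visited[v]]) ++nBeyond;
        if (!closed[visited[v]].empty()) annotated.push_back(visited[v]);
      }
      outFocus[w] = (double)nBeyond / (double)visited.size();
      int ka = (int)annotated.size();
      if (ka < 2) {
        outFh[w] = NA_REAL;
        continue;
      }
      double total = 0.0;
      for (int i = 0; i < ka - 1; ++i) {
        for (int j = i + 1; j < ka; ++j) {
          int u = annotated[i], v = annotated[j];
          if (u > v) std::swap(u, v);
          long long key = (long long)u * n + v;
          std::unordered_map<long long, double>::iterator hit =
              cache.find(key);
          double sim;
          if (hit != cache.end()) {
            sim = hit->second;
          } else {
            sim = setSim(closed[u], closed[v], ic, measure);
            cache[key] = sim;
          }
          total += sim;
        }
      }
      outFh[w] = total / (ka * (ka - 1) / 2.0);
    }
  }
  return List::create(_["start"] = outStart, _["fh"] = outFh,
                      _["focus"] = outFocus, _["ok"] = outOk);
}
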