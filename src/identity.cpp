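// Exact generalized identity-by-descent functionals on a pedigree.
//
// A state is a collection of groups of gene draws; each draw is an
// independent uniform pick among the two genes of an individual (with
// replacement when an individual is repeated).  The value of a state is
// the probability that, at one locus, all draws within every group are
// identical by descent (identity across groups unconstrained).
//
// Recursion on the latest-generation individual `a` in the state: each of
// its k draws resolves to gene copy 1 (one fresh draw from parent1) or
// copy 2 (from parent2) with probability 1/2.  Draws resolving to the same
// copy are the same physical gene, so groups sharing it merge.  Founder
// genes are IBD only to themselves.  States are memoized in a cache that
// persists across calls on one pedigree.

#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

typedef std::unordered_map<std::string, double> Memo;

typedef std::vector<std::vector<int> > State; // 0-based individual indices

static std::string state_key(const State& gs) {
  std::string key;
  key.reserve(gs.size() * 12);
  for (size_t g = 0; g < gs.size(); ++g) {
    if (g) key.push_back(';');
    const std::vector<int>& v = gs[g];
    for (size_t i = 0; i < v.size(); ++i) {
      if (i) key.push_back(',');
      key += std::to_string(v[i]);
    }
  }
  return key;
}

static void canonicalize(State& gs) {
  State kept;
  for (size_t g = 0; g < gs.size(); ++g) {
    if (gs[g].size() > 1) {
      std::sort(gs[g].begin(), gs[g].end());
      kept.push_back(gs[g]);
    }
  }
  std::sort(kept.begin(), kept.end());
  gs.swap(kept);
}

static double phi_rec(State groups, const IntegerVector& gen,
                      const IntegerVector& p1, const IntegerVector& p2,
                      Memo& memo) {
  canonicalize(groups);
  if (groups.empty()) return 1.0;
  std::string key = state_key(groups);
  Memo::const_iterator hit = memo.find(key);
  if (hit != memo.end()) return hit->second;

  // latest individual (max generation, ties by index)
  int a = -1;
  for (size_t g = 0; g < groups.size(); ++g)
    for (size_t i = 0; i < groups[g].size(); ++i) {
      int id = groups[g][i];
      if (a < 0 || gen[id] > gen[a] || (gen[id] == gen[a] && id > a))
        a = id;
    }

  double val = 0.0;
  if (p1[a] == NA_INTEGER) {
    // all individuals in the state are founders
    val = 1.0;
    for (size_t g = 0; g < groups.size(); ++g) {
      const std::vector<int>& v = groups[g];
      bool same = true;
      for (size_t i = 1; i < v.size(); ++i)
        if (v[i] != v[0]) { same = false; break; }
      if (!same) { val = 0.0; break; }
      val *= std::pow(2.0, 1.0 - (double)v.size());
    }
  } else {
    int f = p1[a], m = p2[a];
    // count draws of a per group
    std::vector<int> ka(groups.size(), 0);
    int k = 0;
    for (size_t g = 0; g < groups.size(); ++g)
      for (size_t i = 0; i < groups[g].size(); ++i)
        if (groups[g][i] == a) { ++ka[g]; ++k; }
    int nmask = 1 << k;
    for (int mask = 0; mask < nmask; ++mask) {
      // per group: does it receive the copy-1 token / copy-2 token?
      std::vector<bool> hasF(groups.size(), false), hasM(groups.size(), false);
      int bit = 0;
      for (size_t g = 0; g < groups.size(); ++g)
        for (int d = 0; d < ka[g]; ++d, ++bit) {
          if (mask & (1 << bit)) hasF[g] = true; else hasM[g] = true;
        }
      // merge groups sharing a token (simple component labelling)
      std::vector<int> comp(groups.size());
      for (size_t g = 0; g < groups.size(); ++g) comp[g] = (int)g;
      int firstF = -1, firstM = -1;
      for (size_t g = 0; g < groups.size(); ++g) {
        if (hasF[g]) { if (firstF < 0) firstF = comp[g];
          else { int from = comp[g], to = firstF;
            for (size_t h = 0; h < groups.size(); ++h)
              if (comp[h] == from) comp[h] = to; } }
      }
      for (size_t g = 0; g < groups.size(); ++g) {
        if (hasM[g]) { if (firstM < 0) firstM = comp[g];
          else { int from = comp[g], to = firstM;
            for (size_t h = 0; h < groups.size(); ++h)
              if (comp[h] == from) comp[h] = to; } }
      }
      // rebuild groups per component
      State next;
      std::vector<int> labels;
      for (size_t g = 0; g < groups.size(); ++g) {
        int c = comp[g];
        int pos = -1;
        for (size_t l = 0; l < labels.size(); ++l)
          if (labels[l] == c) { pos = (int)l; break; }
        if (pos < 0) { labels.push_back(c); next.push_back(std::vector<int>());
          pos = (int)next.size() - 1; }
        for (size_t i = 0; i < groups[g].size(); ++i)
          if (groups[g][i] != a) next[pos].push_back(groups[g][i]);
      }
      // add one parental draw per token per component
      std::vector<bool> doneF(next.size(), false), doneM(next.size(), false);
      for (size_t g = 0; g < groups.size(); ++g) {
        int c = comp[g];
        int pos = -1;
        for (size_t l = 0; l < labels.size(); ++l)
          if (labels[l] == c) { pos = (int)l; break; }
        if (hasF[g] && !doneF[pos]) { next[pos].push_back(f); doneF[pos] = true; }
        if (hasM[g] && !doneM[pos]) { next[pos].push_back(m); doneM[pos] = true; }
      }
      val += phi_rec(next, gen, p1, p2, memo);
    }
    val /= (double)nmask;
  }
  memo[key] = val;
  return val;
}

// [[Rcpp::export]]
SEXP ibd_cache_cpp() {
  XPtr<Memo> p(new Memo, true);
  return p;
}

// [[Rcpp::export]]
double phi_groups_cpp(List groups, IntegerVector gen, IntegerVector p1,
                      IntegerVector p2, SEXP cache) {
  XPtr<Memo> memo(cache);
  State gs;
  for (int g = 0; g < groups.size(); ++g) {
    IntegerVector v = groups[g];
    std::vector<int> grp(v.size());
    for (int i = 0; i < v.size(); ++i) grp[i] = v[i] - 1; // to 0-based
    gs.push_back(grp);
  }
  return phi_rec(gs, gen, p1, p2, *memo);
}
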