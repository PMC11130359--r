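#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Semi-global (glocal) edit-distance DP: all of `query` against an arbitrary
// substring of `ref`, unit costs.  Returns false if the row minimum exceeds
// max_edits (early abandon); otherwise fills cost and the 1-based ref
// interval covered by the best alignment.
static bool dp_semi_global(const std::string& query, const std::string& ref,
                           int max_edits, int& cost, int& rstart, int& rend) {
  const int m = query.size(), n = ref.size();
  if (m == 0) { cost = 0; rstart = 1; rend = 0; return true; }
  std::vector<int> prev(n + 1), cur(n + 1), pstart(n + 1), cstart(n + 1);
  for (int j = 0; j <= n; ++j) { prev[j] = 0; pstart[j] = j + 1; }
  for (int i = 1; i <= m; ++i) {
    cur[0] = i; cstart[0] = 1;
    int rowmin = cur[0];
    const char qc = query[i - 1];
    const char* rp = ref.data();
    for (int j = 1; j <= n; ++j) {
      int best = prev[j - 1] + (qc == rp[j - 1] ? 0 : 1);
      int bs = pstart[j - 1];
      const int up = prev[j] + 1, left = cur[j - 1] + 1;
      if (up < best)   { best = up;   bs = pstart[j]; }
      if (left < best) { best = left; bs = cstart[j - 1]; }
      cur[j] = best; cstart[j] = bs;
      if (best < rowmin) rowmin = best;
    }
    if (max_edits >= 0 && rowmin > max_edits) return false;
    std::swap(prev, cur); std::swap(pstart, cstart);
  }
  int best = prev[0], bj = 0;
  for (int j = 1; j <= n; ++j) if (prev[j] < best) { best = prev[j]; bj = j; }
  cost = best; rstart = pstart[bj]; rend = bj;
  return true;
}

// [[Rcpp::export(name = ".semi_global_edit")]]
IntegerVector semi_global_edit(std::string query, std::string ref,
                               int max_edits = -1) {
  int cost, rs, re;
  if (!dp_semi_global(query, ref, max_edits, cost, rs, re))
    return IntegerVector::create(NA_INTEGER, NA_INTEGER, NA_INTEGER);
  return IntegerVector::create(cost, rs, re);
}

// Classify reads against junction references.  For each read (given in both
// orientations) and junction, the minimum edit distance of a semi-global
// alignment whose covered junction interval contains [lo_k, hi_k]; exact
// substring containment is tried first, and junctions are pruned with the
// best cost found so far for the read.  Returns an n_reads x n_junc matrix
// of edit costs, NA where no qualifying alignment <= max_edits exists.
// [[Rcpp::export(name = ".classify_read_batch")]]
IntegerMatrix classify_read_batch(CharacterVector reads,
                                  CharacterVector rc_reads,
                                  CharacterVector juncs,
                                  IntegerVector lo, IntegerVector hi,
                                  IntegerVector max_edits) {
  const int n = reads.size(), K = juncs.size();
  std::vector<std::string> J(K);
  for (int k = 0; k < K; ++k) J[k] = as<std::string>(juncs[k]);
  IntegerMatrix out(n, K);
  for (int r = 0; r < n; ++r) {
    const std::string rd = as<std::string>(reads[r]);
    const std::string rdrc = as<std::string>(rc_reads[r]);
    const int maxed = max_edits[r];
    std::vector<int> cost(K, INT_MAX);
    // exact pass (cannot be beaten): if any junction contains the read
    // exactly with the required interval covered, cost 0 there
    bool any_exact = false;
    for (int k = 0; k < K; ++k) {
      for (int s = 0; s < 2; ++s) {
        const std::string& q = s ? rdrc : rd;
        size_t pos = J[k].find(q);
        while (pos != std::string::npos) {
          int st = (int)pos + 1, en = (int)(pos + q.size());
          if (st <= lo[k] && en >= hi[k]) { cost[k] = 0; any_exact = true; break; }
          pos = J[k].find(q, pos + 1);
        }
        if (cost[k] == 0) break;
      }
    }
    if (!any_exact) {
      int bestSoFar = maxed;
      for (int k = 0; k < K; ++k) {
        for (int s = 0; s < 2; ++s) {
          const std::string& q = s ? rdrc : rd;
          int c, rs, re;
          if (dp_semi_global(q, J[k], bestSoFar, c, rs, re) &&
              c <= bestSoFar && rs <= lo[k] && re >= hi[k]) {
            if (c < cost[k]) cost[k] = c;
            if (c < bestSoFar) bestSoFar = c;
          }
        }
      }
    }
    for (int k = 0; k < K; ++k)
      out(r, k) = cost[k] == INT_MAX ? NA_INTEGER : cost[k];
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
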