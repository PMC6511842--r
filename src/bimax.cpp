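// BIMAX divide-and-conquer enumeration of inclusion-maximal all-1 submatrices
// of a binary matrix, with bitset column encoding.
//
// The recursion follows the classic scheme: pick a template row that is not
// all-1 over the current column set C, split C into CU (template 1s) and CV,
// and recurse on (rows touching CU, CU) and on (rows touching CV, C) with CV
// added to the set of mandatory column groups that any reported bicluster in
// that branch must intersect.  Mandatory groups prevent the second branch
// from re-reporting biclusters that live entirely inside CU.
//
// Every candidate leaf is additionally checked for *global* inclusion
// maximality against the full input matrix before being reported, so the
// output is guaranteed to contain only inclusion-maximal biclusters even in
// degenerate corner cases of the recursion.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

typedef std::vector<uint64_t> Bits;

inline int popcount_mask(const Bits& b) {
  long long s = 0;
  for (size_t i = 0; i < b.size(); ++i) {
#if defined(__GNUC__) || defined(__clang__)
    s += __builtin_popcountll(b[i]);
#else
    uint64_t x = b[i];
    while (x) { x &= x - 1; ++s; }
#endif
  }
  return (int)s;
}

struct BimaxSearch {
  int n, m, W;
  std::vector<Bits> rb;        // per-row column bitsets
  int minr, minc, cap, max_depth, tmpl_rule;
  long long budget, nodes;
  bool budget_hit;
  std::vector<std::vector<int> > out_rows, out_cols;

  BimaxSearch(const IntegerMatrix& M, int minr_, int minc_, int cap_,
              int max_depth_, int tmpl_rule_, long long budget_)
      : n(M.nrow()), m(M.ncol()), W((M.ncol() + 63) / 64),
        minr(minr_), minc(minc_), cap(cap_), max_depth(max_depth_),
        tmpl_rule(tmpl_rule_), budget(budget_), nodes(0), budget_hit(false) {
    rb.assign(n, Bits(W, 0));
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < m; ++j)
        if (M(i, j) != 0) rb[i][j >> 6] |= (uint64_t(1) << (j & 63));
  }

  bool row_full(int r, const Bits& C) const {
    for (int w = 0; w < W; ++w)
      if ((rb[r][w] & C[w]) != C[w]) return false;
    return true;
  }
  bool row_touches(int r, const Bits& C) const {
    for (int w = 0; w < W; ++w)
      if (rb[r][w] & C[w]) return true;
    return false;
  }

  // true iff (rows, C) cannot be grown by any full row or column
  bool globally_maximal(const std::vector<int>& rows, const Bits& C) const {
    std::vector<char> inrow(n, 0);
    for (size_t i = 0; i < rows.size(); ++i) inrow[rows[i]] = 1;
    for (int r = 0; r < n; ++r)
      if (!inrow[r] && row_full(r, C)) return false;
    // candidate extra columns: intersection of row bitsets outside C
    Bits inter(W, ~uint64_t(0));
    for (size_t i = 0; i < rows.size(); ++i)
      for (int w = 0; w < W; ++w) inter[w] &= rb[rows[i]][w];
    for (int w = 0; w < W; ++w)
      if (inter[w] & ~C[w] & word_mask(w)) return false;
    return true;
  }

  uint64_t word_mask(int w) const {
    int rem = m - (w << 6);
    if (rem >= 64) return ~uint64_t(0);
    if (rem <= 0) return 0;
    return (uint64_t(1) << rem) - 1;
  }

  void record(const std::vector<int>& rows, const Bits& C) {
    if (!globally_maximal(rows, C)) return;
    std::vector<int> cols;
    cols.reserve(popcount_mask(C));
    for (int j = 0; j < m; ++j)
      if (C[j >> 6] & (uint64_t(1) << (j & 63))) cols.push_back(j);
    // guard against duplicates (defensive; the mandatory sets should prevent them)
    for (size_t k = 0; k < out_rows.size(); ++k)
      if (out_rows[k] == rows && out_cols[k] == cols) return;
    out_rows.push_back(rows);
    out_cols.push_back(cols);
  }

  void search(std::vector<int> rows, Bits C, std::vector<Bits> mand,
              int depth) {
    if ((int)out_rows.size() >= cap || budget_hit) return;
    if (++nodes > budget) { budget_hit = true; return; }

    // prune: drop rows empty over C and columns not covered by any row
    for (;;) {
      std::vector<int> kept;
      kept.reserve(rows.size());
      Bits cover(W, 0);
      for (size_t i = 0; i < rows.size(); ++i) {
        int r = rows[i];
        bool touch = false;
        for (int w = 0; w < W; ++w) {
          uint64_t x = rb[r][w] & C[w];
          if (x) { touch = true; cover[w] |= x; }
        }
        if (touch) kept.push_back(r);
      }
      rows.swap(kept);
      if ((int)rows.size() < minr || popcount_mask(cover) < minc) return;
      bool shrunk = false;
      for (int w = 0; w < W; ++w)
        if (cover[w] != C[w]) { shrunk = true; break; }
      if (!shrunk) break;
      C = cover;
      for (size_t z = 0; z < mand.size(); ++z) {
        bool nonempty = false;
        for (int w = 0; w < W; ++w) {
          mand[z][w] &= C[w];
          if (mand[z][w]) nonempty = true;
        }
        if (!nonempty) return;
      }
    }

    // leaf test: all rows full over C; otherwise choose the template row
    // 0 = first non-full row, 1 = most balanced split, 2 = most ones,
    // 3 = fewest ones
    int tmpl = -1;
    int nc = popcount_mask(C);
    int best_score = -1;
    for (size_t i = 0; i < rows.size(); ++i) {
      Bits x(W);
      for (int w = 0; w < W; ++w) x[w] = rb[rows[i]][w] & C[w];
      int ones = popcount_mask(x);
      if (ones == nc) continue;  // full row
      int score;
      switch (tmpl_rule) {
        case 1: score = nc - std::abs(2 * ones - nc); break;
        case 2: score = ones; break;
        case 3: score = nc - ones; break;
        default: tmpl = (int)i; break;
      }
      if (tmpl_rule == 0) break;
      if (score > best_score) { best_score = score; tmpl = (int)i; }
    }
    if (tmpl < 0) {
      record(rows, C);
      return;
    }
    if (depth >= max_depth) return;  // division budget exhausted

    Bits CU(W), CV(W);
    for (int w = 0; w < W; ++w) {
      CU[w] = rb[rows[tmpl]][w] & C[w];
      CV[w] = C[w] & ~CU[w];
    }

    // branch 1: biclusters confined to CU
    if (popcount_mask(CU) >= minc) {
      std::vector<Bits> mand1(mand);
      bool ok = true;
      for (size_t z = 0; z < mand1.size(); ++z) {
        bool nonempty = false;
        for (int w = 0; w < W; ++w) {
          mand1[z][w] &= CU[w];
          if (mand1[z][w]) nonempty = true;
        }
        if (!nonempty) { ok = false; break; }
      }
      if (ok) {
        std::vector<int> r1;
        r1.reserve(rows.size());
        for (size_t i = 0; i < rows.size(); ++i)
          if (row_touches(rows[i], CU)) r1.push_back(rows[i]);
        search(r1, CU, mand1, depth + 1);
      }
    }
    if ((int)out_rows.size() >= cap || budget_hit) return;

    // branch 2: biclusters using at least one column of CV
    std::vector<int> r2;
    r2.reserve(rows.size());
    for (size_t i = 0; i < rows.size(); ++i)
      if (row_touches(rows[i], CV)) r2.push_back(rows[i]);
    mand.push_back(CV);
    search(r2, C, mand, depth + 1);
  }
};

}  // namespace

// [[Rcpp::export]]
List bimax_enumerate_cpp(IntegerMatrix M, int min_rows, int min_cols,
                         int max_seeds, int max_depth, int template_rule,
                         double node_budget) {
  BimaxSearch bs(M, min_rows, min_cols, max_seeds, max_depth, template_rule,
                 (long long)node_budget);
  std::vector<int> all_rows(bs.n);
  for (int i = 0; i < bs.n; ++i) all_rows[i] = i;
  Bits C(bs.W, 0);
  for (int w = 0; w < bs.W; ++w) C[w] = bs.word_mask(w);
  bs.search(all_rows, C, std::vector<Bits>(), 0);

  int k = (int)bs.out_rows.size();
  List rows(k), cols(k);
  for (int i = 0; i < k; ++i) {
    IntegerVector r(bs.out_rows[i].begin(), bs.out_rows[i].end());
    IntegerVector c(bs.out_cols[i].begin(), bs.out_cols[i].end());
    rows[i] = r + 1;  // 1-based for R
    cols[i] = c + 1;
  }
  return List::create(_["rows"] = rows, _["cols"] = cols,
                      _["budget_hit"] = bs.budget_hit,
                      _["nodes"] = (double)bs.nodes);
}
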