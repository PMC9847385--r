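#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Banded affine-gap local alignment (Smith-Waterman-Gotoh restricted to a
// diagonal band).  Diagonals are d = j - i with i indexing the query (rows)
// and j the reference (columns), both 1-based; only cells with
// d_lo <= j - i <= d_hi are computed.  Gap costs follow the convention that
// the first gapped base costs `gap_first` and each additional base
// `gap_extend` (both negative).
//
// Returns score 0 and empty coordinates when no positive-scoring local
// alignment exists inside the band.

static const int NEG = -1000000000;

struct BandMat {
  int n, d_lo, W;
  std::vector<int> v;
  BandMat(int n_, int d_lo_, int W_) : n(n_), d_lo(d_lo_), W(W_),
    v((size_t)(n_ + 1) * W_, NEG) {}
  inline bool inband(int i, int j) const {
    int c = j - i - d_lo;
    return c >= 0 && c < W;
  }
  inline int get(int i, int j) const {
    if (i < 0 || j < 0) return NEG;
    if (!inband(i, j)) return NEG;
    return v[(size_t)i * W + (j - i - d_lo)];
  }
  inline void set(int i, int j, int x) {
    v[(size_t)i * W + (j - i - d_lo)] = x;
  }
};

// H boundary: local alignment may start anywhere, so row/column 0 score 0
// (only meaningful where the band touches them).
static inline int getH0(const BandMat &H, int i, int j) {
  if (i < 0 || j < 0) return NEG;
  if (i == 0 || j == 0) return 0;
  return H.get(i, j);
}

// [[Rcpp::export]]
List banded_local_align(std::string q, std::string r,
                        int d_lo, int d_hi,
                        int match = 1, int mismatch = -1,
                        int gap_first = -2, int gap_extend = -1) {
  int n = (int)q.size(), m = (int)r.size();
  if (n == 0 || m == 0 || d_lo > d_hi)
    return List::create(_["score"] = 0);
  int W = d_hi - d_lo + 1;

  BandMat H(n, d_lo, W), E(n, d_lo, W), F(n, d_lo, W);

  int best = 0, bi = -1, bj = -1;
  for (int i = 1; i <= n; ++i) {
    int jmin = std::max(1, i + d_lo), jmax = std::min(m, i + d_hi);
    for (int j = jmin; j <= jmax; ++j) {
      // E: gap in query (consumes reference base j)
      int e = std::max(getH0(H, i, j - 1) + gap_first,
                       E.get(i, j - 1) + gap_extend);
      // F: gap in reference (consumes query base i)
      int f = std::max(getH0(H, i - 1, j) + gap_first,
                       F.get(i - 1, j) + gap_extend);
      int s = (q[i - 1] == r[j - 1]) ? match : mismatch;
      int h = getH0(H, i - 1, j - 1) + s;
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      E.set(i, j, e);
      F.set(i, j, f);
      H.set(i, j, h);
      // deterministic tie-break: first (smallest i, then j) best cell wins
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  if (best <= 0)
    return List::create(_["score"] = 0);

  // traceback: prefer diagonal moves, then E, then F (deterministic)
  int i = bi, j = bj;
  int matches = 0, columns = 0;
  int qe = bi, re = bj;
  char state = 'H';
  while (i > 0 && j > 0) {
    if (state == 'H') {
      int h = H.get(i, j);
      if (h <= 0) break;
      int s = (q[i - 1] == r[j - 1]) ? match : mismatch;
      if (getH0(H, i - 1, j - 1) + s == h) {
        ++columns;
        if (q[i - 1] == r[j - 1]) ++matches;
        --i; --j;
        if (getH0(H, i, j) == 0 && (i == 0 || j == 0 || H.get(i, j) == 0))
          break;
      } else if (E.get(i, j) == h) {
        state = 'E';
      } else {
        state = 'F';
      }
    } else if (state == 'E') {
      ++columns;  // gap column consuming reference
      int e = E.get(i, j);
      if (E.get(i, j - 1) + gap_extend == e) {
        --j;
      } else {
        --j;
        state = 'H';
      }
    } else {  // F
      ++columns;  // gap column consuming query
      int f = F.get(i, j);
      if (F.get(i - 1, j) + gap_extend == f) {
        --i;
      } else {
        --i;
        state = 'H';
      }
    }
  }

  return List::create(
    _["score"] = best,
    _["q_start"] = i + 1, _["q_end"] = qe,
    _["r_start"] = j + 1, _["r_end"] = re,
    _["matches"] = matches, _["columns"] = columns);
}
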