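#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Score-only semi-global (overlap) alignment with affine internal gaps.
//
// Three-state Gotoh recurrence over integer scores. End gaps are free on
// both ends of both sequences: leading gaps are encoded by zero-cost first
// row/column, trailing gaps by taking the maximum over the last row and
// last column. Alongside the score we carry, per cell and state, the
// maximum number of identical aligned pairs among all alignments achieving
// that cell's optimal score (lexicographic (score, identities) maximum),
// which gives a deterministic identity count for clustering.
//
// `a` and `b` are 0-based indices into `mat`. `gap_first` is the cost of
// the first residue of a gap, `gap_ext` of each subsequent residue, so the
// two affine conventions (open + (L-1)*ext vs open + L*ext) differ only in
// `gap_first`.

namespace {

const long NEG = LONG_MIN / 4;

struct Cell {
  long s;
  int id;
};

inline void take_max(Cell &dst, long s, int id) {
  if (s > dst.s || (s == dst.s && id > dst.id)) {
    dst.s = s;
    dst.id = id;
  }
}

} // namespace

// [[Rcpp::export]]
List gotoh_semiglobal(IntegerVector a, IntegerVector b, IntegerMatrix mat,
                      int gap_first, int gap_ext) {
  const int m = a.size(), n = b.size();
  if (m == 0 || n == 0)
    stop("sequences must be non-empty");

  // Row-sliding DP: keep one row of H, E, F (E = gap in `a`, consuming b).
  std::vector<Cell> H(n + 1), E(n + 1), F(n + 1), Hprev(n + 1);

  for (int j = 0; j <= n; ++j) {
    H[j] = {0, 0}; // free leading gap in `a`
    E[j] = {NEG, 0};
    F[j] = {NEG, 0};
  }

  Cell best = H[n]; // candidate: all of b in a leading/trailing gap

  for (int i = 1; i <= m; ++i) {
    std::swap(Hprev, H);
    H[0] = {0, 0}; // free leading gap in `b`
    E[0] = {NEG, 0};
    // F persists down columns; F[0] unused at j=0
    const int ai = a[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int bj = b[j - 1];

      Cell e = {NEG, 0};
      take_max(e, H[j - 1].s - gap_first, H[j - 1].id);
      take_max(e, E[j - 1].s - gap_ext, E[j - 1].id);
      E[j] = e;

      Cell f = {NEG, 0};
      take_max(f, Hprev[j].s - gap_first, Hprev[j].id);
      take_max(f, F[j].s - gap_ext, F[j].id);
      F[j] = f;

      Cell h = {NEG, 0};
      const int match = (ai == bj) ? 1 : 0;
      take_max(h, Hprev[j - 1].s + mat(ai, bj), Hprev[j - 1].id + match);
      take_max(h, e.s, e.id);
      take_max(h, f.s, f.id);
      H[j] = h;
    }
    // trailing gap in `b`: alignment may end having consumed all of b
    take_max(best, H[n].s, H[n].id);
  }
  // trailing gap in `a`: last row
  for (int j = 0; j <= n; ++j)
    take_max(best, H[j].s, H[j].id);

  return List::create(Named("score") = (double)best.s,
                      Named("identities") = best.id);
}
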