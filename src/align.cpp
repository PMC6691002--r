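#include <Rcpp.h>
using namespace Rcpp;

// Gotoh global alignment with affine gaps. A gap of length L costs
// open + L * ext (the Biostrings convention). Among all optimal-score
// alignments, the maximal number of identical aligned pairs is tracked,
// so the reported identity does not depend on traceback tie-breaking.
//
// Scores are sums of integers (integer substitution matrix, integer gap
// penalties), so exact double comparison is safe.

struct Cell {
  double score;
  int matches;
};

static const double NEG_INF = -1e18;

static inline Cell better(const Cell &a, const Cell &b) {
  if (a.score > b.score) return a;
  if (b.score > a.score) return b;
  return (a.matches >= b.matches) ? a : b;
}

static inline Cell step(const Cell &c, double add, int match_add) {
  Cell r;
  if (c.score <= NEG_INF / 2) { r.score = NEG_INF; r.matches = 0; return r; }
  r.score = c.score + add;
  r.matches = c.matches + match_add;
  return r;
}

// [[Rcpp::export(name = ".align_global_stats")]]
List align_global_stats(IntegerVector a, IntegerVector b,
                        NumericMatrix sub, double open, double ext) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");

  // rows: previous and current; three states M (a[i] aligned to b[j]),
  // X (gap in b, i.e. a[i] unaligned), Y (gap in a).
  std::vector<Cell> Mprev(m + 1), Xprev(m + 1), Yprev(m + 1);
  std::vector<Cell> Mcur(m + 1), Xcur(m + 1), Ycur(m + 1);

  Mprev[0] = {0.0, 0};
  Xprev[0] = {NEG_INF, 0};
  Yprev[0] = {NEG_INF, 0};
  for (int j = 1; j <= m; ++j) {
    Mprev[j] = {NEG_INF, 0};
    Xprev[j] = {NEG_INF, 0};
    Yprev[j] = {-(open + j * ext), 0};
  }

  for (int i = 1; i <= n; ++i) {
    Mcur[0] = {NEG_INF, 0};
    Ycur[0] = {NEG_INF, 0};
    Xcur[0] = {-(open + i * ext), 0};
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int bj = b[j - 1];
      const double s = sub(ai, bj);
      const int eq = (ai == bj) ? 1 : 0;
      Cell diag = better(better(Mprev[j - 1], Xprev[j - 1]), Yprev[j - 1]);
      Mcur[j] = step(diag, s, eq);
      // X: gap in b (consume a[i]); opening from M/Y costs open+ext.
      Xcur[j] = better(step(better(Mprev[j], Yprev[j]), -(open + ext), 0),
                       step(Xprev[j], -ext, 0));
      // Y: gap in a (consume b[j]).
      Ycur[j] = better(step(better(Mcur[j - 1], Xcur[j - 1]), -(open + ext), 0),
                       step(Ycur[j - 1], -ext, 0));
    }
    std::swap(Mprev, Mcur);
    std::swap(Xprev, Xcur);
    std::swap(Yprev, Ycur);
  }

  Cell fin = better(better(Mprev[m], Xprev[m]), Yprev[m]);
  return List::create(_["score"] = fin.score, _["matches"] = fin.matches);
}
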