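#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Weighted mismatch distance between two CDR3 amino-acid strings.
// Shorter sequence is aligned to the longer with a central gap block:
// the first ceil(m/2) residues align to the start, the last m - ceil(m/2)
// to the end.  Substitution cost min(cap, cap - S(x,y)) for x != y, 0 for
// x == y; each gapped position costs `gap`; the total is scaled by `w`.

static inline double pair_dist(const char *a, int la, const char *b, int lb,
                               const int *S, const int *lut, int nalpha,
                               int cap, int gap, int w) {
  if (la > lb) { const char *t = a; a = b; b = t; int tl = la; la = lb; lb = tl; }
  const int m = la, n = lb;
  const int front = (m + 1) / 2, back = m - front;
  double cost = 0.0;
  for (int i = 0; i < front; ++i) {
    const int x = lut[(unsigned char)a[i]], y = lut[(unsigned char)b[i]];
    if (x < 0 || y < 0) stop("non-amino-acid character in CDR3 sequence");
    if (x != y) {
      int c = cap - S[x + nalpha * y];
      if (c > cap) c = cap;
      cost += c;
    }
  }
  for (int i = 0; i < back; ++i) {
    const int x = lut[(unsigned char)a[m - 1 - i]], y = lut[(unsigned char)b[n - 1 - i]];
    if (x < 0 || y < 0) stop("non-amino-acid character in CDR3 sequence");
    if (x != y) {
      int c = cap - S[x + nalpha * y];
      if (c > cap) c = cap;
      cost += c;
    }
  }
  cost += (double)gap * (n - m);
  return (double)w * cost;
}

static void build_lut(const std::string &alphabet, int *lut) {
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  for (size_t i = 0; i < alphabet.size(); ++i)
    lut[(unsigned char)alphabet[i]] = (int)i;
}

// [[Rcpp::export]]
NumericVector cpp_cdr3_dist(CharacterVector a, CharacterVector b,
                            IntegerMatrix S, std::string alphabet,
                            int cap, int gap, int w) {
  if (a.size() != b.size()) stop("a and b must have equal length");
  int lut[256];
  build_lut(alphabet, lut);
  const int nalpha = S.nrow();
  NumericVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    const char *sa = CHAR(STRING_ELT(a, i));
    const char *sb = CHAR(STRING_ELT(b, i));
    out[i] = pair_dist(sa, (int)std::strlen(sa), sb, (int)std::strlen(sb),
                       S.begin(), lut, nalpha, cap, gap, w);
  }
  return out;
}

// Neighbor counts of each query against a pool.  When same_set is true the
// pool IS the query set and item i is excluded from its own count (identity,
// not sequence equality).  Length pre-filter: |dl| * gap * w > radius => skip.
// [[Rcpp::export]]
IntegerVector cpp_neighbor_counts(CharacterVector queries, CharacterVector pool,
                                  IntegerMatrix S, std::string alphabet,
                                  int cap, int gap, int w, double radius,
                                  bool same_set) {
  int lut[256];
  build_lut(alphabet, lut);
  const int nalpha = S.nrow();
  const R_xlen_t nq = queries.size(), np = pool.size();
  std::vector<const char *> ps(np);
  std::vector<int> pl(np);
  for (R_xlen_t j = 0; j < np; ++j) {
    ps[j] = CHAR(STRING_ELT(pool, j));
    pl[j] = (int)std::strlen(ps[j]);
  }
  IntegerVector out(nq);
  const double gapw = (double)gap * (double)w;
  for (R_xlen_t i = 0; i < nq; ++i) {
    const char *qa = CHAR(STRING_ELT(queries, i));
    const int ql = (int)std::strlen(qa);
    int k = 0;
    for (R_xlen_t j = 0; j < np; ++j) {
      if (same_set && j == i) continue;
      const int dl = ql > pl[j] ? ql - pl[j] : pl[j] - ql;
      if (gapw * dl > radius) continue;
      if (pair_dist(qa, ql, ps[j], pl[j], S.begin(), lut, nalpha, cap, gap, w) <= radius)
        ++k;
    }
    out[i] = k;
  }
  return out;
}
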