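#include <Rcpp.h>
using namespace Rcpp;

// Pairwise site-pattern counts over an encoded alignment.
//
// `m` is an L x N integer matrix with 1=A, 2=G, 3=C, 4=T and 0 for
// missing/ambiguous (pairwise deletion). For every unordered pair of
// columns we count usable sites, purine transitions (A<->G), pyrimidine
// transitions (C<->T), transversions, and pooled base occurrences from
// both sequences, which downstream distance formulas turn into P1, P2, Q
// and empirical base frequencies.
// [[Rcpp::export]]
List pair_site_stats(const IntegerMatrix& m) {
  const int L = m.nrow(), N = m.ncol();
  NumericMatrix used(N, N), ts1(N, N), ts2(N, N), tv(N, N);
  NumericMatrix cA(N, N), cG(N, N), cC(N, N), cT(N, N);
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double u = 0, t1 = 0, t2 = 0, v = 0;
      double bc[4] = {0, 0, 0, 0};
      for (int s = 0; s < L; ++s) {
        const int a = m(s, i), b = m(s, j);
        if (a == 0 || b == 0) continue;
        ++u;
        ++bc[a - 1];
        ++bc[b - 1];
        if (a != b) {
          const bool pa = a <= 2, pb = b <= 2;
          if (pa && pb) ++t1;
          else if (!pa && !pb) ++t2;
          else ++v;
        }
      }
      used(i, j) = used(j, i) = u;
      ts1(i, j) = ts1(j, i) = t1;
      ts2(i, j) = ts2(j, i) = t2;
      tv(i, j) = tv(j, i) = v;
      cA(i, j) = cA(j, i) = bc[0];
      cG(i, j) = cG(j, i) = bc[1];
      cC(i, j) = cC(j, i) = bc[2];
      cT(i, j) = cT(j, i) = bc[3];
    }
  }
  return List::create(_["used"] = used, _["ts_purine"] = ts1,
                      _["ts_pyrimidine"] = ts2, _["tv"] = tv,
                      _["cA"] = cA, _["cG"] = cG, _["cC"] = cC,
                      _["cT"] = cT);
}
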