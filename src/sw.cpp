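#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap Smith-Waterman with full traceback.
//
// q and s are 1-based indices into the substitution matrix; a gap of
// length k costs gap_open + k * gap_extend (BLAST convention). Ties among
// equal-scoring optima are broken deterministically: the best cell is the
// one with the smallest subject end coordinate, then the smallest query
// end coordinate, and traceback prefers diagonal > up (gap in subject) >
// left (gap in query).
//
// Returns score, 1-based aligned intervals and the aligned index vectors
// (0 marks a gap). Score 0 means the empty alignment is optimal.

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector s, NumericMatrix mat,
                  double gap_open, double gap_extend) {
  const int m = q.size(), n = s.size();
  const double NEG = -1e30;
  const double gfirst = gap_open + gap_extend;

  NumericMatrix H(m + 1, n + 1), E(m + 1, n + 1), F(m + 1, n + 1);
  for (int i = 0; i <= m; ++i) { E(i, 0) = NEG; F(i, 0) = NEG; }
  for (int j = 0; j <= n; ++j) { E(0, j) = NEG; F(0, j) = NEG; }

  double best = 0.0; int bi = 0, bj = 0;
  for (int j = 1; j <= n; ++j) {
    for (int i = 1; i <= m; ++i) {
      double e = std::max(H(i, j - 1) - gfirst, E(i, j - 1) - gap_extend);
      double f = std::max(H(i - 1, j) - gfirst, F(i - 1, j) - gap_extend);
      double diag = H(i - 1, j - 1) + mat(q[i - 1] - 1, s[j - 1] - 1);
      double h = std::max(0.0, std::max(diag, std::max(e, f)));
      E(i, j) = e; F(i, j) = f; H(i, j) = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0,
                        _["query_start"] = NA_INTEGER,
                        _["query_end"] = NA_INTEGER,
                        _["subject_start"] = NA_INTEGER,
                        _["subject_end"] = NA_INTEGER,
                        _["aligned_query"] = IntegerVector(0),
                        _["aligned_subject"] = IntegerVector(0));
  }

  std::vector<int> aq, as;
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = F (up), 2 = E (left)
  while (true) {
    if (state == 0) {
      if (H(i, j) <= 0.0) break;
      double diag = H(i - 1, j - 1) + mat(q[i - 1] - 1, s[j - 1] - 1);
      if (H(i, j) == diag) {
        aq.push_back(q[i - 1]); as.push_back(s[j - 1]);
        --i; --j;
      } else if (H(i, j) == F(i, j)) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {      // gap in subject, consume query residue
      aq.push_back(q[i - 1]); as.push_back(0);
      bool from_h = (F(i, j) == H(i - 1, j) - gfirst);
      --i;
      if (from_h) state = 0;
    } else {                      // gap in query, consume subject residue
      aq.push_back(0); as.push_back(s[j - 1]);
      bool from_h = (E(i, j) == H(i, j - 1) - gfirst);
      --j;
      if (from_h) state = 0;
    }
  }

  std::reverse(aq.begin(), aq.end());
  std::reverse(as.begin(), as.end());
  return List::create(_["score"] = best,
                      _["query_start"] = i + 1,
                      _["query_end"] = bi,
                      _["subject_start"] = j + 1,
                      _["subject_end"] = bj,
                      _["aligned_query"] = wrap(aq),
                      _["aligned_subject"] = wrap(as));
}
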