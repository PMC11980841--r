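#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap (Gotoh) Smith-Waterman score of a short query against each
// length-k window of a target sequence. Residues are 1-based integer codes
// into the 20-letter alphabet; `starts` are 1-based window offsets known to
// contain no ambiguity codes. A gap of length L costs gap_open + gap_extend*L.
// [[Rcpp::export]]
NumericVector sw_window_scores_cpp(IntegerVector query, IntegerVector target,
                                   int k, IntegerVector starts,
                                   NumericMatrix score_matrix,
                                   double gap_open, double gap_extend) {
  const int m = query.size();
  const int n = starts.size();
  const double gfirst = gap_open + gap_extend;
  NumericVector out(n);

  std::vector<double> H((m + 1) * (k + 1));
  std::vector<double> E((m + 1) * (k + 1));
  std::vector<double> F((m + 1) * (k + 1));
  const double neg = -1e30;

  for (int w = 0; w < n; ++w) {
    const int off = starts[w] - 1;  // 0-based start in target
    double best = 0.0;
    for (int j = 0; j <= k; ++j) { H[j] = 0.0; E[j] = neg; F[j] = neg; }
    for (int i = 1; i <= m; ++i) {
      const int row = i * (k + 1), prev = (i - 1) * (k + 1);
      H[row] = 0.0; E[row] = neg; F[row] = neg;
      const int qi = query[i - 1] - 1;
      for (int j = 1; j <= k; ++j) {
        const double e = std::max(H[row + j - 1] - gfirst,
                                  E[row + j - 1] - gap_extend);
        const double f = std::max(H[prev + j] - gfirst,
                                  F[prev + j] - gap_extend);
        const int tj = target[off + j - 1] - 1;
        double h = H[prev + j - 1] + score_matrix(qi, tj);
        if (e > h) h = e;
        if (f > h) h = f;
        if (h < 0.0) h = 0.0;
        E[row + j] = e;
        F[row + j] = f;
        H[row + j] = h;
        if (h > best) best = h;
      }
    }
    out[w] = best;
  }
  return out;
}
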