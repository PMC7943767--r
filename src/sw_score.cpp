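#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Batch Smith-Waterman local alignment scores with affine gaps (Gotoh,
// score-only). A gap of length L costs gap_open + L * gap_extend, matching
// the convention of the R-side alignment routines used for the final
// reported hits. Characters absent from the alphabet score 0 against
// everything (like the ambiguity code X).
//
// qseq/sseq: the two sequences of each pair (parallel vectors).
// submat: square substitution matrix ordered as `alphabet`.
// [[Rcpp::export]]
NumericVector sw_score_batch(CharacterVector qseq, CharacterVector sseq,
                             NumericMatrix submat, std::string alphabet,
                             double gap_open, double gap_extend) {
  int npair = qseq.size();
  NumericVector out(npair);
  int idx[256];
  for (int c = 0; c < 256; ++c) idx[c] = -1;
  for (size_t a = 0; a < alphabet.size(); ++a) {
    idx[(unsigned char)alphabet[a]] = (int)a;
  }
  double open_cost = gap_open + gap_extend;
  int nal = alphabet.size();

  std::vector<double> H, E;
  for (int p = 0; p < npair; ++p) {
    const char *q = CHAR(STRING_ELT(qseq, p));
    const char *s = CHAR(STRING_ELT(sseq, p));
    int n = strlen(q), m = strlen(s);
    H.assign(m + 1, 0.0);
    E.assign(m + 1, R_NegInf);
    double best = 0.0;
    for (int i = 1; i <= n; ++i) {
      int qi = idx[(unsigned char)q[i - 1]];
      const double *srow = (qi >= 0) ? &submat[(size_t)qi * nal] : NULL;
      double diag = 0.0;   // H[i-1][0]
      double F = R_NegInf;
      double Hprev = 0.0;  // H[i][0]
      for (int j = 1; j <= m; ++j) {
        int sj = idx[(unsigned char)s[j - 1]];
        double sub = (srow && sj >= 0) ? srow[sj] : 0.0;
        double e = E[j] - gap_extend;
        double eo = H[j] - open_cost;          // H[i-1][j] - open
        E[j] = (e > eo) ? e : eo;
        double f = F - gap_extend;
        double fo = Hprev - open_cost;
        F = (f > fo) ? f : fo;
        double h = diag + sub;
        if (E[j] > h) h = E[j];
        if (F > h) h = F;
        if (h < 0.0) h = 0.0;
        diag = H[j];
        H[j] = h;
        Hprev = h;
        if (h > best) best = h;
      }
    }
    out[p] = best;
  }
  return out;
}
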