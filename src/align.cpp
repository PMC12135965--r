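#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Position-specific local alignment (Gotoh affine-gap Smith-Waterman).
//
// `prof` is a width x 20 matrix of per-column residue scores (half-bit
// log-odds). Subject residues are coded 0..19; any negative code (unknown
// residue) scores 0 against every column. Opening a gap costs
// gap_open + gap_extend for its first position and gap_extend for each
// further position. E carries gaps that consume subject residues (profile
// column skipped in subject coordinates stays put), F carries gaps that
// consume profile columns.

static inline double cell_score(const NumericMatrix& prof, int i, int code) {
  return code < 0 ? 0.0 : prof(i, code);
}

// [[Rcpp::export(name = ".sw_align_profile")]]
List sw_align_profile(NumericMatrix prof, IntegerVector subj,
                      double gap_open, double gap_extend,
                      LogicalVector mask) {
  const int L = prof.nrow();
  const int n = subj.size();
  const double NEG = -1e30;
  if (L == 0 || n == 0)
    return List::create(_["score"] = 0.0);

  // full matrices: traceback needed. (L+1) x (n+1), row-major on i.
  std::vector<double> H((size_t)(L + 1) * (n + 1), 0.0);
  std::vector<double> E((size_t)(L + 1) * (n + 1), NEG);
  std::vector<double> F((size_t)(L + 1) * (n + 1), NEG);
  // tbH: 0 stop, 1 diagonal, 2 from E, 3 from F
  std::vector<unsigned char> tbH((size_t)(L + 1) * (n + 1), 0);
  // tbE/tbF: 1 if opened from H, 0 if extended
  std::vector<unsigned char> tbE((size_t)(L + 1) * (n + 1), 0);
  std::vector<unsigned char> tbF((size_t)(L + 1) * (n + 1), 0);

  const size_t W = (size_t)n + 1;
  double best = 0.0;
  int bi = 0, bj = 0;
  const int* sj = INTEGER(subj);
  const int* mk = LOGICAL(mask);
  double srow[21];

  for (int i = 1; i <= L; ++i) {
    for (int a = 0; a < 20; ++a) srow[a] = prof(i - 1, a);
    srow[20] = 0.0;
    for (int j = 1; j <= n; ++j) {
      const size_t c = (size_t)i * W + j;
      const size_t up = c - W, left = c - 1, diag = c - W - 1;

      double eo = H[left] - gap_open - gap_extend;
      double ee = E[left] - gap_extend;
      if (eo >= ee) { E[c] = eo; tbE[c] = 1; } else { E[c] = ee; tbE[c] = 0; }

      double fo = H[up] - gap_open - gap_extend;
      double fe = F[up] - gap_extend;
      if (fo >= fe) { F[c] = fo; tbF[c] = 1; } else { F[c] = fe; tbF[c] = 0; }

      int code = sj[j - 1];
      double s = mk[j - 1] ? NEG : srow[code < 0 ? 20 : code];
      double d = H[diag] + s;

      double h = 0.0; unsigned char t = 0;
      if (d > h) { h = d; t = 1; }
      if (E[c] > h) { h = E[c]; t = 2; }
      if (F[c] > h) { h = F[c]; t = 3; }
      H[c] = h; tbH[c] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  if (best <= 0.0)
    return List::create(_["score"] = 0.0);

  // traceback: collect matched (profile column, subject position) pairs
  std::vector<int> pc, sp;
  int i = bi, j = bj;
  int state = 0; // 0 = H, 2 = E, 3 = F
  while (i > 0 && j > 0) {
    const size_t c = (size_t)i * W + j;
    if (state == 0) {
      unsigned char t = tbH[c];
      if (t == 0) break;
      if (t == 1) { pc.push_back(i); sp.push_back(j); --i; --j; }
      else state = t;
    } else if (state == 2) {
      unsigned char t = tbE[c];
      --j;
      if (t == 1) state = 0;
    } else {
      unsigned char t = tbF[c];
      --i;
      if (t == 1) state = 0;
    }
  }
  std::reverse(pc.begin(), pc.end());
  std::reverse(sp.begin(), sp.end());

  return List::create(
    _["score"] = best,
    _["prof_start"] = pc.front(), _["prof_end"] = pc.back(),
    _["sub_start"] = sp.front(), _["sub_end"] = sp.back(),
    _["prof_cols"] = IntegerVector(pc.begin(), pc.end()),
    _["sub_pos"] = IntegerVector(sp.begin(), sp.end()));
}

// Score-only scan of many subjects; linear memory. Returns best local score
// per subject.
// [[Rcpp::export(name = ".sw_score_batch")]]
NumericVector sw_score_batch(NumericMatrix prof, List subjects,
                             double gap_open, double gap_extend) {
  const int L = prof.nrow();
  const int m = subjects.size();
  const double NEG = -1e30;
  NumericVector out(m);

  for (int k = 0; k < m; ++k) {
    IntegerVector subj = subjects[k];
    const int n = subj.size();
    if (n == 0 || L == 0) { out[k] = 0.0; continue; }
    std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
    std::vector<double> Eprev(n + 1, NEG); // E is per-row (depends on left)
    std::vector<double> Fcol(n + 1, NEG);
    double best = 0.0;
    const int* sj = INTEGER(subj);
    double srow[21];
    for (int i = 1; i <= L; ++i) {
      for (int a = 0; a < 20; ++a) srow[a] = prof(i - 1, a);
      srow[20] = 0.0;  // unknown residue
      Hcur[0] = 0.0;
      double Eleft = NEG;
      for (int j = 1; j <= n; ++j) {
        double e = std::max(Hcur[j - 1] - gap_open - gap_extend,
                            Eleft - gap_extend);
        double f = std::max(Hprev[j] - gap_open - gap_extend,
                            Fcol[j] - gap_extend);
        int code = sj[j - 1];
        double s = srow[code < 0 ? 20 : code];
        double h = Hprev[j - 1] + s;
        if (h < 0.0) h = 0.0;
        if (e > h) h = e;
        if (f > h) h = f;
        Hcur[j] = h; Eleft = e; Fcol[j] = f;
        if (h > best) best = h;
      }
      std::swap(Hprev, Hcur);
    }
    out[k] = best;
  }
  return out;
}
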