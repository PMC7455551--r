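#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman optimal local alignment score with affine gaps.  A gap of
// length L costs open + L * extend (Biostrings convention), so the first
// gapped position pays open + extend.  Alongside the score we track the
// aligned span on each sequence at the best cell, giving the coverage used
// for best-hit tie-breaking.

struct SWResult {
  double score;
  int len_a;   // aligned span on a
  int len_b;   // aligned span on b
};

static SWResult sw_one(const std::string &a, const std::string &b,
                       const std::vector<double> &submat,
                       const std::vector<int> &code, int nalpha,
                       double open, double extend) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<double> H(m + 1, 0.0), F(m + 1, R_NegInf);
  // start coordinates propagated through the DP for span reporting
  std::vector<int> Hi(m + 1, 0), Hj(m + 1, 1), Fi(m + 1, 0), Fj(m + 1, 0);
  for (int j = 0; j <= m; ++j) { Hi[j] = 1; Hj[j] = j + 1; }
  double best = 0.0;
  int best_i = 0, best_j = 0, bsi = 0, bsj = 0;
  for (int i = 1; i <= n; ++i) {
    double diagH = 0.0;           // H[i-1][j-1], starts at H[i-1][0] = 0
    int diag_si = i, diag_sj = 1; // a zero cell starts a fresh alignment
    double E = R_NegInf;          // gap state along the row
    int Esi = 0, Esj = 0;
    int ai = code[(unsigned char)a[i - 1]];
    if (ai < 0) stop("illegal residue '%c' in sequence", a[i - 1]);
    for (int j = 1; j <= m; ++j) {
      int bj = code[(unsigned char)b[j - 1]];
      if (bj < 0) stop("illegal residue '%c' in sequence", b[j - 1]);
      // E: gap in a (consume b), propagates along the row
      double e_open = H[j - 1] - open - extend;  // H[i][j-1], current row
      double e_ext = E - extend;
      if (e_open >= e_ext) { E = e_open; Esi = Hi[j - 1]; Esj = Hj[j - 1]; }
      else { E = e_ext; }
      // F: gap in b (consume a), propagates down the column
      double f_open = H[j] - open - extend;      // H[i-1][j], previous row
      double f_ext = F[j] - extend;
      if (f_open >= f_ext) { F[j] = f_open; Fi[j] = Hi[j]; Fj[j] = Hj[j]; }
      else { F[j] = f_ext; }
      double diag = diagH + submat[ai * nalpha + bj];
      int dsi = diag_si, dsj = diag_sj;
      // save H[i-1][j] for the next cell's diagonal
      diagH = H[j]; diag_si = Hi[j]; diag_sj = Hj[j];
      double h = diag; int hsi = dsi, hsj = dsj;
      if (E > h) { h = E; hsi = Esi; hsj = Esj; }
      if (F[j] > h) { h = F[j]; hsi = Fi[j]; hsj = Fj[j]; }
      if (h <= 0.0) { h = 0.0; hsi = i + 1; hsj = j + 1; }
      H[j] = h; Hi[j] = hsi; Hj[j] = hsj;
      if (h > best) {
        best = h; best_i = i; best_j = j; bsi = hsi; bsj = hsj;
      }
    }
  }
  SWResult r;
  r.score = best;
  r.len_a = best > 0 ? best_i - bsi + 1 : 0;
  r.len_b = best > 0 ? best_j - bsj + 1 : 0;
  return r;
}

static void build_code(const CharacterVector &alphabet,
                       std::vector<int> &code) {
  code.assign(256, -1);
  for (int k = 0; k < alphabet.size(); ++k) {
    const char *s = CHAR(STRING_ELT(alphabet, k));
    code[(unsigned char)s[0]] = k;
    code[(unsigned char)tolower(s[0])] = k;
  }
}

// [[Rcpp::export(name = ".sw_score_cpp")]]
List sw_score_cpp(std::string a, std::string b, NumericMatrix submat,
                  CharacterVector alphabet, double open, double extend) {
  std::vector<int> code;
  build_code(alphabet, code);
  int nalpha = alphabet.size();
  // NumericMatrix is column-major; copy into row-major ai*nalpha+bj
  std::vector<double> smr(nalpha * nalpha);
  for (int i = 0; i < nalpha; ++i)
    for (int j = 0; j < nalpha; ++j)
      smr[i * nalpha + j] = submat(i, j);
  SWResult r = sw_one(a, b, smr, code, nalpha, open, extend);
  return List::create(_["score"] = r.score, _["len_a"] = r.len_a,
                      _["len_b"] = r.len_b);
}

// All-vs-all scores between two protein sets; returns score and coverage
// (aligned span / query length) matrices.
// [[Rcpp::export(name = ".sw_all_pairs_cpp")]]
List sw_all_pairs_cpp(CharacterVector setA, CharacterVector setB,
                      NumericMatrix submat, CharacterVector alphabet,
                      double open, double extend) {
  std::vector<int> code;
  build_code(alphabet, code);
  int nalpha = alphabet.size();
  std::vector<double> smr(nalpha * nalpha);
  for (int i = 0; i < nalpha; ++i)
    for (int j = 0; j < nalpha; ++j)
      smr[i * nalpha + j] = submat(i, j);
  int na = setA.size(), nb = setB.size();
  NumericMatrix score(na, nb), cova(na, nb), covb(na, nb);
  for (int i = 0; i < na; ++i) {
    std::string a = as<std::string>(setA[i]);
    for (int j = 0; j < nb; ++j) {
      std::string b = as<std::string>(setB[j]);
      SWResult r = sw_one(a, b, smr, code, nalpha, open, extend);
      score(i, j) = r.score;
      cova(i, j) = a.size() ? (double)r.len_a / (double)a.size() : 0.0;
      covb(i, j) = b.size() ? (double)r.len_b / (double)b.size() : 0.0;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["score"] = score, _["coverage_a"] = cova,
                      _["coverage_b"] = covb);
}
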