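#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Base-vs-base score. Ambiguity codes (anything outside ACGT) score 0:
// neither match nor mismatch.
static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static inline double pair_score(char a, char b, double match, double mismatch) {
  if (!is_acgt(a) || !is_acgt(b)) return 0.0;
  return (a == b) ? match : mismatch;
}

static void count_columns(const std::string &qa, const std::string &ta,
                          int &matches, int &mismatches, int &columns) {
  matches = 0; mismatches = 0; columns = (int) qa.size();
  for (size_t k = 0; k < qa.size(); ++k) {
    char a = qa[k], b = ta[k];
    if (a == '-' || b == '-') continue;
    if (!is_acgt(a) || !is_acgt(b)) continue; // ambiguity: neither
    if (a == b) ++matches; else ++mismatches;
  }
}

// Global alignment, linear gap penalty, with traceback.
// Tie-break: diagonal preferred over up (gap in b) over left (gap in a).
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  NumericMatrix S(n + 1, m + 1);
  IntegerMatrix P(n + 1, m + 1); // 0 diag, 1 up (gap in b), 2 left (gap in a)
  for (int i = 1; i <= n; ++i) { S(i, 0) = i * gap; P(i, 0) = 1; }
  for (int j = 1; j <= m; ++j) { S(0, j) = j * gap; P(0, j) = 2; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = S(i - 1, j - 1) + pair_score(a[i - 1], b[j - 1], match, mismatch);
      double u = S(i - 1, j) + gap;
      double l = S(i, j - 1) + gap;
      double best = d; int ptr = 0;
      if (u > best) { best = u; ptr = 1; }
      if (l > best) { best = l; ptr = 2; }
      S(i, j) = best; P(i, j) = ptr;
    }
  }
  std::string qa, ta;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int ptr = (i == 0) ? 2 : (j == 0) ? 1 : P(i, j);
    if (ptr == 0) {
      qa.push_back(a[i - 1]); ta.push_back(b[j - 1]); --i; --j;
    } else if (ptr == 1) {
      qa.push_back(a[i - 1]); ta.push_back('-'); --i;
    } else {
      qa.push_back('-'); ta.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ta.begin(), ta.end());
  int matches, mismatches, columns;
  count_columns(qa, ta, matches, mismatches, columns);
  return List::create(_["score"] = S(n, m),
                      _["aligned_a"] = qa, _["aligned_b"] = ta,
                      _["matches"] = matches, _["mismatches"] = mismatches,
                      _["columns"] = columns);
}

// ---- local alignment (Gotoh affine) -----------------------------------
// A gap of length L costs gap_open + (L - 1) * gap_extend (penalties are
// negative). Memory-light: a rolling forward pass locates the best end
// cell, a rolling pass over the reversed prefixes locates the start, and a
// full traceback DP runs only on the alignment window. Deterministic
// tie-break: highest score, then smallest end row, then smallest end
// column; traceback prefers stopping, then diagonal.

struct SwEnd { double score; int i, j; };

// rolling-score local DP; returns the best M-state cell (first occurrence
// in row-major order on ties)
static SwEnd sw_forward(const std::string &q, const std::string &t,
                        double match, double mismatch,
                        double gap_open, double gap_extend) {
  const int n = q.size(), m = t.size();
  const double NEG = -1e18, EPS = 1e-9;
  std::vector<double> Mp(m + 1, 0.0), Xp(m + 1, NEG), Yp(m + 1, NEG);
  std::vector<double> Mc(m + 1, 0.0), Xc(m + 1, NEG), Yc(m + 1, NEG);
  SwEnd best = {0.0, 0, 0};
  for (int i = 1; i <= n; ++i) {
    Mc[0] = 0.0; Xc[0] = NEG; Yc[0] = NEG;
    const char qi = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      double s = pair_score(qi, t[j - 1], match, mismatch);
      double prev = 0.0;
      if (Mp[j - 1] > prev) prev = Mp[j - 1];
      if (Xp[j - 1] > prev) prev = Xp[j - 1];
      if (Yp[j - 1] > prev) prev = Yp[j - 1];
      double mv = prev + s;
      Mc[j] = mv;
      double xo = Mp[j] + gap_open, xe = Xp[j] + gap_extend;
      Xc[j] = xo >= xe ? xo : xe;
      double yo = Mc[j - 1] + gap_open, ye = Yc[j - 1] + gap_extend;
      Yc[j] = yo >= ye ? yo : ye;
      if (mv > best.score + EPS) { best.score = mv; best.i = i; best.j = j; }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  return best;
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string q, std::string t,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  const double NEG = -1e18, EPS = 1e-9;
  SwEnd end = sw_forward(q, t, match, mismatch, gap_open, gap_extend);
  if (end.score <= EPS || end.i == 0) {
    return List::create(_["score"] = 0.0, _["empty"] = true);
  }
  // locate the start: best end of the reversed-prefix problem
  std::string qr(q.begin(), q.begin() + end.i);
  std::string tr(t.begin(), t.begin() + end.j);
  std::reverse(qr.begin(), qr.end());
  std::reverse(tr.begin(), tr.end());
  SwEnd rend = sw_forward(qr, tr, match, mismatch, gap_open, gap_extend);
  int qs = end.i - rend.i + 1, ts = end.j - rend.j + 1; // 1-based starts
  // full DP with traceback on the (small) alignment window
  const int n = end.i - qs + 1, m = end.j - ts + 1;
  auto idx = [m](int i, int j) { return (size_t) i * (m + 1) + j; };
  std::vector<double> M((size_t)(n + 1) * (m + 1), 0.0);
  std::vector<double> X((size_t)(n + 1) * (m + 1), NEG);
  std::vector<double> Y((size_t)(n + 1) * (m + 1), NEG);
  // the window contains an optimal path, but under score ties it need not
  // end exactly at the window corner: track the window's own best cell
  double wbest = 0.0; int wbi = 0, wbj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = pair_score(q[qs - 1 + i - 1], t[ts - 1 + j - 1],
                            match, mismatch);
      double prev = 0.0;
      if (M[idx(i - 1, j - 1)] > prev) prev = M[idx(i - 1, j - 1)];
      if (X[idx(i - 1, j - 1)] > prev) prev = X[idx(i - 1, j - 1)];
      if (Y[idx(i - 1, j - 1)] > prev) prev = Y[idx(i - 1, j - 1)];
      M[idx(i, j)] = prev + s;
      double xo = M[idx(i - 1, j)] + gap_open, xe = X[idx(i - 1, j)] + gap_extend;
      X[idx(i, j)] = xo >= xe ? xo : xe;
      double yo = M[idx(i, j - 1)] + gap_open, ye = Y[idx(i, j - 1)] + gap_extend;
      Y[idx(i, j)] = yo >= ye ? yo : ye;
      if (M[idx(i, j)] > wbest + EPS) { wbest = M[idx(i, j)]; wbi = i; wbj = j; }
    }
  }
  std::string qa, ta;
  int i = wbi, j = wbj, state = 0; // optimal local alignments end in M
  while (i > 0 && j > 0) {
    if (state == 0) {
      double s = pair_score(q[qs - 1 + i - 1], t[ts - 1 + j - 1],
                            match, mismatch);
      double prev = M[idx(i, j)] - s;
      qa.push_back(q[qs - 1 + i - 1]); ta.push_back(t[ts - 1 + j - 1]);
      --i; --j;
      if (std::fabs(prev) < EPS) break;                       // fresh start
      if (std::fabs(M[idx(i, j)] - prev) < EPS) state = 0;
      else if (std::fabs(X[idx(i, j)] - prev) < EPS) state = 1;
      else state = 2;
    } else if (state == 1) { // gap in t
      double cur = X[idx(i, j)];
      qa.push_back(q[qs - 1 + i - 1]); ta.push_back('-');
      if (std::fabs(M[idx(i - 1, j)] + gap_open - cur) < EPS) state = 0;
      --i;
    } else { // gap in q
      double cur = Y[idx(i, j)];
      qa.push_back('-'); ta.push_back(t[ts - 1 + j - 1]);
      if (std::fabs(M[idx(i, j - 1)] + gap_open - cur) < EPS) state = 0;
      --j;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ta.begin(), ta.end());
  int matches, mismatches, columns;
  count_columns(qa, ta, matches, mismatches, columns);
  return List::create(_["score"] = wbest, _["empty"] = false,
                      _["q_start"] = qs + i, _["q_end"] = qs - 1 + wbi,
                      _["t_start"] = ts + j, _["t_end"] = ts - 1 + wbj,
                      _["aligned_q"] = qa, _["aligned_t"] = ta,
                      _["matches"] = matches, _["mismatches"] = mismatches,
                      _["columns"] = columns);
}
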