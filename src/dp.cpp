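#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

static const double NEG = -std::numeric_limits<double>::infinity();

// Gotoh affine-gap global alignment.
// Gap run of length L costs gap_open + L * gap_extend (both negative).
// Traceback is deterministic: on ties prefer diagonal, then vertical
// (residue of `a` over a gap), then horizontal.
// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string a, std::string b, double match, double mismatch,
                 double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  // pointer codes: 0 = from M, 1 = from X, 2 = from Y
  std::vector<signed char> pM((n + 1) * W, -1), pX((n + 1) * W, -1),
      pY((n + 1) * W, -1);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = gap_open + i * gap_extend;
    pX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = gap_open + j * gap_extend;
    pY[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int k = i * W + j, kd = (i - 1) * W + (j - 1), ku = (i - 1) * W + j,
                kl = i * W + (j - 1);
      const double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      // M: prefer M, then X, then Y on ties
      double best = M[kd];
      signed char p = 0;
      if (X[kd] > best) { best = X[kd]; p = 1; }
      if (Y[kd] > best) { best = Y[kd]; p = 2; }
      M[k] = (best == NEG) ? NEG : best + s;
      pM[k] = p;
      // X (vertical, consumes a[i-1]): open from M, extend X, open from Y
      best = M[ku] + gap_open + gap_extend; p = 0;
      if (X[ku] + gap_extend > best) { best = X[ku] + gap_extend; p = 1; }
      if (Y[ku] + gap_open + gap_extend > best) {
        best = Y[ku] + gap_open + gap_extend; p = 2;
      }
      X[k] = best; pX[k] = p;
      // Y (horizontal, consumes b[j-1]): open from M, open from X, extend Y
      best = M[kl] + gap_open + gap_extend; p = 0;
      if (X[kl] + gap_open + gap_extend > best) {
        best = X[kl] + gap_open + gap_extend; p = 1;
      }
      if (Y[kl] + gap_extend > best) { best = Y[kl] + gap_extend; p = 2; }
      Y[k] = best; pY[k] = p;
    }
  }
  const int kend = n * W + m;
  int state = 0;
  double score = M[kend];
  if (X[kend] > score) { score = X[kend]; state = 1; }
  if (Y[kend] > score) { score = Y[kend]; state = 2; }
  std::string ga, gb;
  ga.reserve(n + m);
  gb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int k = i * W + j;
    if (state == 0) {
      ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
      state = pM[k]; --i; --j;
    } else if (state == 1) {
      ga.push_back(a[i - 1]); gb.push_back('-');
      state = pX[k]; --i;
    } else {
      ga.push_back('-'); gb.push_back(b[j - 1]);
      state = pY[k]; --j;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["aligned_a"] = ga, _["aligned_b"] = gb,
                      _["score"] = score);
}

static inline bool is_complement(char x, char y) {
  switch (x) {
    case 'A': return y == 'T';
    case 'C': return y == 'G';
    case 'G': return y == 'C';
    case 'T': return y == 'A';
    default: return false;
  }
}

// Inverted-repeat scan: Smith-Waterman of s against its own reverse
// complement with a linear per-position gap penalty, restricted to the
// triangle where the two aligned segments (arms) are disjoint and ordered.
// Emits every cell with score >= min_score as a candidate hit, traced back
// to arm coordinates (0-based, half-open, on s).
// Columns: arm1_start, arm1_end, arm2_start, arm2_end, score.
// [[Rcpp::export(name = ".ir_scan")]]
IntegerMatrix ir_scan(std::string s, double match, double mismatch,
                      double gap, double min_score) {
  const int n = s.size();
  const int W = n + 1;
  // t = reverse complement of s; t[j-1] pairs with s[n-j] (0-based)
  std::vector<double> H((size_t)(n + 1) * W, 0.0);
  std::vector<signed char> P((size_t)(n + 1) * W, 0);  // 0 stop, 1 diag, 2 up, 3 left
  std::vector<int> ci, cj;
  std::vector<double> cs;
  for (int i = 1; i <= n; ++i) {
    const int jmax = n - i;  // arms disjoint: i + j <= n
    for (int j = 1; j <= jmax; ++j) {
      const size_t k = (size_t)i * W + j;
      const char aj = s[i - 1];
      const char bj = s[n - j];  // t[j-1] complements s[n-j]
      const double sub = is_complement(aj, bj) ? match : mismatch;
      double best = 0.0;
      signed char p = 0;
      const double d = H[k - W - 1] + sub;
      if (d > best) { best = d; p = 1; }
      const double u = H[k - W] - gap;
      if (u > best) { best = u; p = 2; }
      const double l = H[k - 1] - gap;
      if (l > best) { best = l; p = 3; }
      H[k] = best;
      P[k] = p;
      if (best >= min_score) {
        ci.push_back(i); cj.push_back(j); cs.push_back(best);
      }
    }
  }
  const int nc = ci.size();
  IntegerMatrix out(nc, 5);
  for (int c = 0; c < nc; ++c) {
    int i = ci[c], j = cj[c];
    const int a1e = i, a2s = n - j;  // half-open ends fixed at the end cell
    while (P[(size_t)i * W + j] != 0) {
      const signed char p = P[(size_t)i * W + j];
      if (p == 1) { --i; --j; }
      else if (p == 2) { --i; }
      else { --j; }
    }
    out(c, 0) = i;          // arm1_start
    out(c, 1) = a1e;        // arm1_end
    out(c, 2) = a2s;        // arm2_start
    out(c, 3) = n - j;      // arm2_end
    out(c, 4) = (int)cs[c];
  }
  colnames(out) = CharacterVector::create("arm1_start", "arm1_end",
                                          "arm2_start", "arm2_end", "score");
  return out;
}
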