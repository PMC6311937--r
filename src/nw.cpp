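#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global alignment DP over integer-encoded sequences (0-based indices into
// the substitution matrix). Moves in the returned path: 0 = diagonal,
// 1 = up (residue of a against gap in b), 2 = left (gap in a).
//
// Gap model:
//   linear: every gap column costs gap_open.
//   affine: a gap run of length k costs gap_open + (k - 1) * gap_extend.
// Tie-breaks are fixed (diagonal > up > left; match-state > up-state >
// left-state) so tracebacks are deterministic.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List nw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                  double gap_open, double gap_extend, bool affine) {
  const int n = a.size(), m = b.size();
  const int W = m + 1;
  std::vector<int> moves;
  double score;

  if (!affine) {
    std::vector<double> M((n + 1) * W, NEG_INF);
    std::vector<unsigned char> dir((n + 1) * W, 0); // 0 diag, 1 up, 2 left
    M[0] = 0.0;
    for (int i = 1; i <= n; ++i) { M[i * W] = i * gap_open; dir[i * W] = 1; }
    for (int j = 1; j <= m; ++j) { M[j] = j * gap_open; dir[j] = 2; }
    for (int i = 1; i <= n; ++i) {
      for (int j = 1; j <= m; ++j) {
        double d = M[(i - 1) * W + (j - 1)] + sub(a[i - 1], b[j - 1]);
        double u = M[(i - 1) * W + j] + gap_open;
        double l = M[i * W + (j - 1)] + gap_open;
        double best = d; unsigned char bd = 0;
        if (u > best) { best = u; bd = 1; }
        if (l > best) { best = l; bd = 2; }
        M[i * W + j] = best; dir[i * W + j] = bd;
      }
    }
    score = M[n * W + m];
    int i = n, j = m;
    while (i > 0 || j > 0) {
      unsigned char d = dir[i * W + j];
      moves.push_back(d);
      if (d == 0) { --i; --j; } else if (d == 1) { --i; } else { --j; }
    }
  } else {
    // Gotoh: layer 0 = match (diag), layer 1 = gap-in-b (up), layer 2 = gap-in-a (left)
    std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
        Y((n + 1) * W, NEG_INF);
    std::vector<unsigned char> pM((n + 1) * W, 0), pX((n + 1) * W, 0),
        pY((n + 1) * W, 0); // predecessor layer
    M[0] = 0.0;
    for (int i = 1; i <= n; ++i) {
      X[i * W] = gap_open + (i - 1) * gap_extend;
      pX[i * W] = (i == 1) ? 0 : 1;
    }
    for (int j = 1; j <= m; ++j) {
      Y[j] = gap_open + (j - 1) * gap_extend;
      pY[j] = (j == 1) ? 0 : 2;
    }
    for (int i = 1; i <= n; ++i) {
      for (int j = 1; j <= m; ++j) {
        const int c = i * W + j, cd = (i - 1) * W + (j - 1),
                  cu = (i - 1) * W + j, cl = i * W + (j - 1);
        // match layer
        double s = sub(a[i - 1], b[j - 1]);
        double best = M[cd]; unsigned char bl = 0;
        if (X[cd] > best) { best = X[cd]; bl = 1; }
        if (Y[cd] > best) { best = Y[cd]; bl = 2; }
        M[c] = (best == NEG_INF) ? NEG_INF : best + s;
        pM[c] = bl;
        // up layer (consume a[i-1])
        best = M[cu] + gap_open; bl = 0;
        if (X[cu] + gap_extend > best) { best = X[cu] + gap_extend; bl = 1; }
        if (Y[cu] + gap_open > best) { best = Y[cu] + gap_open; bl = 2; }
        X[c] = best; pX[c] = bl;
        // left layer (consume b[j-1])
        best = M[cl] + gap_open; bl = 0;
        if (X[cl] + gap_open > best) { best = X[cl] + gap_open; bl = 1; }
        if (Y[cl] + gap_extend > best) { best = Y[cl] + gap_extend; bl = 2; }
        Y[c] = best; pY[c] = bl;
      }
    }
    const int e = n * W + m;
    int layer = 0; score = M[e];
    if (X[e] > score) { score = X[e]; layer = 1; }
    if (Y[e] > score) { score = Y[e]; layer = 2; }
    int i = n, j = m;
    while (i > 0 || j > 0) {
      const int c = i * W + j;
      if (layer == 0) { moves.push_back(0); layer = pM[c]; --i; --j; }
      else if (layer == 1) { moves.push_back(1); layer = pX[c]; --i; }
      else { moves.push_back(2); layer = pY[c]; --j; }
    }
  }

  std::reverse(moves.begin(), moves.end());
  return List::create(_["score"] = score,
                      _["moves"] = IntegerVector(moves.begin(), moves.end()));
}

// Hamming-style identity over two equal-length gapped rows encoded as raw
// bytes; '-' (45) is the gap. Returns c(matched, kept_length, dual_gap_cols).
// [[Rcpp::export]]
IntegerVector gapped_identity_counts_cpp(RawVector ra, RawVector rb) {
  const int L = ra.size();
  int matched = 0, dual = 0;
  for (int k = 0; k < L; ++k) {
    const unsigned char x = ra[k], y = rb[k];
    const bool gx = (x == 45), gy = (y == 45);
    if (gx && gy) { ++dual; continue; }
    if (!gx && !gy && x == y) ++matched;
  }
  return IntegerVector::create(matched, L - dual, dual);
}
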