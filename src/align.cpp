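// Global profile-profile alignment with affine gap costs (Gotoh).
//
// Profiles are 5 x L column-frequency matrices over A,C,G,T,'-'.
// The expected column-pair score sums match/mismatch over the joint
// residue frequencies; gap fractions inside a profile contribute 0.
// A gap of length k costs gap_open + (k - 1) * gap_extend.
// Tie-break during traceback: diagonal, then gap-in-B (up), then
// gap-in-A (left), which makes the output deterministic.

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List cpp_align_profiles(NumericMatrix A, NumericMatrix B,
                        double match, double mismatch,
                        double gap_open, double gap_extend) {
  const int la = A.ncol(), lb = B.ncol();
  // expected substitution score between columns i of A and j of B
  // (residues only; gaps in the profile are ignored)
  std::vector<double> sub((size_t)la * lb);
  for (int i = 0; i < la; ++i) {
    double fa[4];
    for (int x = 0; x < 4; ++x) fa[x] = A(x, i);
    for (int j = 0; j < lb; ++j) {
      double s = 0.0;
      for (int x = 0; x < 4; ++x) {
        if (fa[x] == 0.0) continue;
        for (int y = 0; y < 4; ++y) {
          double f = fa[x] * B(y, j);
          if (f != 0.0) s += f * (x == y ? match : mismatch);
        }
      }
      sub[(size_t)i * lb + j] = s;
    }
  }

  const size_t n = (size_t)(la + 1) * (lb + 1);
  std::vector<double> M(n, NEG_INF), X(n, NEG_INF), Y(n, NEG_INF);
  // X: gap in B (consume A, move "up"); Y: gap in A (consume B, "left")
  std::vector<signed char> tM(n, 0), tX(n, 0), tY(n, 0);
  auto at = [lb](int i, int j) { return (size_t)i * (lb + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= la; ++i) {
    X[at(i, 0)] = gap_open + (i - 1) * gap_extend;
    tX[at(i, 0)] = (i == 1) ? 0 : 1; // from M at first, then extend
  }
  for (int j = 1; j <= lb; ++j) {
    Y[at(0, j)] = gap_open + (j - 1) * gap_extend;
    tY[at(0, j)] = (j == 1) ? 0 : 1;
  }

  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      const size_t c = at(i, j), d = at(i - 1, j - 1),
                   u = at(i - 1, j), l = at(i, j - 1);
      // M: diagonal from best of M/X/Y at (i-1, j-1)
      double best = M[d]; signed char tb = 0;
      if (X[d] > best) { best = X[d]; tb = 1; }
      if (Y[d] > best) { best = Y[d]; tb = 2; }
      M[c] = best + sub[(size_t)(i - 1) * lb + (j - 1)];
      tM[c] = tb;
      // X: gap in B; open from M/Y or extend X
      double xo = std::max(M[u], Y[u]) + gap_open;
      double xe = X[u] + gap_extend;
      if (xe > xo) { X[c] = xe; tX[c] = 1; }
      else { X[c] = xo; tX[c] = (M[u] >= Y[u]) ? 0 : 2; }
      // Y: gap in A; open from M/X or extend Y
      double yo = std::max(M[l], X[l]) + gap_open;
      double ye = Y[l] + gap_extend;
      if (ye > yo) { Y[c] = ye; tY[c] = 1; }
      else { Y[c] = yo; tY[c] = (M[l] >= X[l]) ? 0 : 2; }
    }
  }

  // traceback from the best terminal state; prefer M, then X, then Y
  int i = la, j = lb;
  const size_t e = at(i, j);
  int state = 0;
  double score = M[e];
  if (X[e] > score) { score = X[e]; state = 1; }
  if (Y[e] > score) { score = Y[e]; state = 2; }

  std::vector<int> ma, mb; // reversed column maps (0 = gap)
  while (i > 0 || j > 0) {
    if (state == 0) {
      signed char tb = tM[at(i, j)];
      ma.push_back(i); mb.push_back(j);
      --i; --j;
      state = tb;
    } else if (state == 1) {
      signed char tb = tX[at(i, j)];
      ma.push_back(i); mb.push_back(0);
      --i;
      state = (tb == 1) ? 1 : (tb == 0 ? 0 : 2);
    } else {
      signed char tb = tY[at(i, j)];
      ma.push_back(0); mb.push_back(j);
      --j;
      state = (tb == 1) ? 2 : (tb == 0 ? 0 : 1);
    }
  }
  std::reverse(ma.begin(), ma.end());
  std::reverse(mb.begin(), mb.end());
  return List::create(_["map_a"] = wrap(ma), _["map_b"] = wrap(mb),
                      _["score"] = score);
}
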