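#include <Rcpp.h>
using namespace Rcpp;

// Three-state global (Needleman-Wunsch/Gotoh) alignment over a precomputed
// column-score matrix S (n x m): S(i,j) is the score of pairing position i+1
// of the first input with position j+1 of the second. A gap run of length L
// costs open + ext * L (Biostrings convention: the first gapped position
// already pays open + ext). End gaps are penalized (true global mode).
//
// Tie-breaking is deterministic: match/mismatch (diagonal) is preferred over
// a gap in the second input (up), which is preferred over a gap in the first
// (left), both when filling and when starting the traceback.
//
// Returns list(score, pa, pb): pa/pb are integer vectors over alignment
// columns holding 1-based source positions, 0 where that row has a gap.

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".gotoh_core")]]
List gotoh_core(NumericMatrix S, double open, double ext) {
  const int n = S.nrow(), m = S.ncol();
  const double oe = open + ext;
  NumericMatrix M(n + 1, m + 1), Ix(n + 1, m + 1), Iy(n + 1, m + 1);

  M(0, 0) = 0.0; Ix(0, 0) = NEG_INF; Iy(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF; Iy(i, 0) = NEG_INF;
    Ix(i, 0) = -(open + ext * i);
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF; Ix(0, j) = NEG_INF;
    Iy(0, j) = -(open + ext * j);
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double dm = M(i - 1, j - 1), dx = Ix(i - 1, j - 1), dy = Iy(i - 1, j - 1);
      double best = dm;
      if (dx > best) best = dx;
      if (dy > best) best = dy;
      M(i, j) = best + S(i - 1, j - 1);

      double xm = M(i - 1, j) - oe, xy = Iy(i - 1, j) - oe, xx = Ix(i - 1, j) - ext;
      best = xm; if (xy > best) best = xy; if (xx > best) best = xx;
      Ix(i, j) = best;

      double ym = M(i, j - 1) - oe, yx = Ix(i, j - 1) - oe, yy = Iy(i, j - 1) - ext;
      best = ym; if (yx > best) best = yx; if (yy > best) best = yy;
      Iy(i, j) = best;
    }
  }

  // state codes: 0 = M (diagonal), 1 = Ix (up), 2 = Iy (left)
  int i = n, j = m, state;
  double sc = M(n, m); state = 0;
  if (Ix(n, m) > sc) { sc = Ix(n, m); state = 1; }
  if (Iy(n, m) > sc) { sc = Iy(n, m); state = 2; }

  std::vector<int> pa, pb;
  const double tol = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      double target = M(i, j) - S(i - 1, j - 1);
      pa.push_back(i); pb.push_back(j);
      if (std::abs(M(i - 1, j - 1) - target) < tol)       state = 0;
      else if (std::abs(Ix(i - 1, j - 1) - target) < tol)  state = 1;
      else                                                 state = 2;
      --i; --j;
    } else if (state == 1) {
      pa.push_back(i); pb.push_back(0);
      if (i == 1 && j == 0) { --i; continue; }  // boundary column
      double v = Ix(i, j);
      if (std::abs(M(i - 1, j) - oe - v) < tol)            state = 0;
      else if (std::abs(Ix(i - 1, j) - ext - v) < tol)     state = 1;
      else                                                 state = 2;
      --i;
    } else {
      pa.push_back(0); pb.push_back(j);
      if (j == 1 && i == 0) { --j; continue; }
      double v = Iy(i, j);
      if (std::abs(M(i, j - 1) - oe - v) < tol)            state = 0;
      else if (std::abs(Iy(i, j - 1) - ext - v) < tol)     state = 2;
      else                                                 state = 1;
      --j;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = sc,
                      _["pa"] = IntegerVector(pa.begin(), pa.end()),
                      _["pb"] = IntegerVector(pb.begin(), pb.end()));
}
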