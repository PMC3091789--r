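#include <Rcpp.h>
using namespace Rcpp;

// Global affine-gap (Gotoh) alignment on a precomputed column-vs-column
// score matrix M (LA x LB). End gaps are penalized. A gap of length L
// costs gapOpen + L * gapExtend. Returns the optimal score and a merge
// path: 0 = match columns, 1 = gap in B (consume A column), 2 = gap in A.
// [[Rcpp::export(name = ".gotoh_profile")]]
List gotoh_profile(NumericMatrix M, double gapOpen, double gapExtend) {
  const int LA = M.nrow(), LB = M.ncol();
  const double NEG = -1e30;
  const double go = gapOpen + gapExtend;  // cost of opening (first position)
  // DP matrices: S = best ending in match, X = gap in B (A consumed),
  // Y = gap in A (B consumed)
  NumericMatrix S(LA + 1, LB + 1), X(LA + 1, LB + 1), Y(LA + 1, LB + 1);
  IntegerMatrix Sdir(LA + 1, LB + 1), Xdir(LA + 1, LB + 1),
      Ydir(LA + 1, LB + 1);
  S(0, 0) = 0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= LA; ++i) {
    S(i, 0) = NEG;
    X(i, 0) = -go - (i - 1) * gapExtend;
    Y(i, 0) = NEG;
    Xdir(i, 0) = (i == 1) ? 0 : 1;  // from S at origin, else extend
  }
  for (int j = 1; j <= LB; ++j) {
    S(0, j) = NEG;
    Y(0, j) = -go - (j - 1) * gapExtend;
    X(0, j) = NEG;
    Ydir(0, j) = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= LA; ++i) {
    for (int j = 1; j <= LB; ++j) {
      // S: diagonal move
      double sS = S(i - 1, j - 1), sX = X(i - 1, j - 1), sY = Y(i - 1, j - 1);
      double b = sS; int d = 0;
      if (sX > b) { b = sX; d = 1; }
      if (sY > b) { b = sY; d = 2; }
      S(i, j) = b + M(i - 1, j - 1);
      Sdir(i, j) = d;
      // X: consume A(i), gap in B
      double oS = S(i - 1, j) - go, oY = Y(i - 1, j) - go;
      double eX = X(i - 1, j) - gapExtend;
      double o = oS; int xd = 0;
      if (oY > o) { o = oY; xd = 2; }
      if (eX >= o) { X(i, j) = eX; Xdir(i, j) = 1; }
      else { X(i, j) = o; Xdir(i, j) = xd; }
      // Y: consume B(j), gap in A
      double pS = S(i, j - 1) - go, pX = X(i, j - 1) - go;
      double eY = Y(i, j - 1) - gapExtend;
      double p = pS; int yd = 0;
      if (pX > p) { p = pX; yd = 1; }
      if (eY >= p) { Y(i, j) = eY; Ydir(i, j) = 1; }
      else { Y(i, j) = p; Ydir(i, j) = yd; }
    }
  }
  double best = S(LA, LB); int state = 0;
  if (X(LA, LB) > best) { best = X(LA, LB); state = 1; }
  if (Y(LA, LB) > best) { best = Y(LA, LB); state = 2; }
  // traceback
  std::vector<int> path;
  int i = LA, j = LB;
  while (i > 0 || j > 0) {
    if (state == 0) {
      path.push_back(0);
      int d = Sdir(i, j);
      --i; --j;
      state = d;
    } else if (state == 1) {
      path.push_back(1);
      int d = Xdir(i, j);  // 0 = from S, 1 = extend in X, 2 = from Y
      --i;
      state = (d == 0) ? 0 : (d == 1 ? 1 : 2);
    } else {
      path.push_back(2);
      int d = Ydir(i, j);  // 0 = from S, 1 = extend in Y, 2 = from X
      --j;
      state = (d == 0) ? 0 : (d == 1 ? 2 : 1);
    }
  }
  std::reverse(path.begin(), path.end());
  return List::create(Named("score") = best,
                      Named("path") = IntegerVector(path.begin(), path.end()));
}
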