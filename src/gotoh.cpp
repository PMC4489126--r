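#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state DP) over integer-coded
// sequences. Codes are 1..20 into the score matrix; 0 means an ambiguity
// letter scored with `floorScore`. Gap costs follow the BLAST existence /
// extension convention: the first column of a gap run costs `gapFirst`, each
// further column `gapExt` (a run of length L costs gapFirst + gapExt*(L-1)).
//
// States: M = residues aligned, X = gap in b (a residue consumed),
// Y = gap in a. Traceback tie-break: prefer M, then X, then Y; in local mode
// a zero-valued start is preferred over extending the alignment.

static const double NEG_INF = -1e30;

static inline double subScore(const NumericMatrix& S, double floorScore,
                              int ai, int bj) {
  if (ai == 0 || bj == 0) return floorScore;
  return S(ai - 1, bj - 1);
}

// [[Rcpp::export(name = ".gotohAlign")]]
List gotohAlign(IntegerVector a, IntegerVector b, NumericMatrix S,
                double floorScore, double gapFirst, double gapExt,
                bool local) {
  const int n = a.size(), m = b.size();
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = X(i, j) = Y(i, j) = NEG_INF; }
  M(0, 0) = 0.0;
  if (!local) {
    for (int i = 1; i <= n; ++i) X(i, 0) = -(gapFirst + gapExt * (i - 1));
    for (int j = 1; j <= m; ++j) Y(0, j) = -(gapFirst + gapExt * (j - 1));
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double prev = std::max(M(i - 1, j - 1),
                             std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      if (local) prev = std::max(prev, 0.0);
      M(i, j) = subScore(S, floorScore, a[i - 1], b[j - 1]) + prev;
      X(i, j) = std::max(M(i - 1, j) - gapFirst,
                         std::max(X(i - 1, j) - gapExt,
                                  Y(i - 1, j) - gapFirst));
      Y(i, j) = std::max(M(i, j - 1) - gapFirst,
                         std::max(X(i, j - 1) - gapFirst,
                                  Y(i, j - 1) - gapExt));
    }
  }

  int ei, ej, state;
  double best;
  if (local) {
    best = 0.0; ei = 0; ej = 0; state = 0;
    for (int i = 1; i <= n; ++i)
      for (int j = 1; j <= m; ++j)
        if (M(i, j) > best + 1e-9) { best = M(i, j); ei = i; ej = j; }
  } else {
    ei = n; ej = m;
    best = M(n, m); state = 0;
    if (X(n, m) > best + 1e-9) { best = X(n, m); state = 1; }
    if (Y(n, m) > best + 1e-9) { best = Y(n, m); state = 2; }
  }

  const double tol = 1e-9;
  std::vector<int> outA, outB; // residue position (1-based) or 0 for gap
  int i = ei, j = ej;
  while (!(i == 0 && j == 0)) {
    if (state == 0) {
      if (i == 0 || j == 0) break; // cannot happen: M is -inf on the border
      double need = M(i, j) - subScore(S, floorScore, a[i - 1], b[j - 1]);
      outA.push_back(i); outB.push_back(j);
      --i; --j;
      if (local && std::fabs(need) < tol) break; // local start (fresh zero)
      if (std::fabs(M(i, j) - need) < tol) state = 0;
      else if (std::fabs(X(i, j) - need) < tol) state = 1;
      else if (std::fabs(Y(i, j) - need) < tol) state = 2;
      else stop("alignment traceback failure (M)");
    } else if (state == 1) {
      double v = X(i, j);
      outA.push_back(i); outB.push_back(0);
      --i;
      if (std::fabs(M(i, j) - (v + gapFirst)) < tol) state = 0;
      else if (std::fabs(X(i, j) - (v + gapExt)) < tol) state = 1;
      else if (std::fabs(Y(i, j) - (v + gapFirst)) < tol) state = 2;
      else stop("alignment traceback failure (X)");
    } else {
      double v = Y(i, j);
      outA.push_back(0); outB.push_back(j);
      --j;
      if (std::fabs(M(i, j) - (v + gapFirst)) < tol) state = 0;
      else if (std::fabs(X(i, j) - (v + gapFirst)) < tol) state = 1;
      else if (std::fabs(Y(i, j) - (v + gapExt)) < tol) state = 2;
      else stop("alignment traceback failure (Y)");
    }
  }
  std::reverse(outA.begin(), outA.end());
  std::reverse(outB.begin(), outB.end());
  return List::create(_["score"] = best,
                      _["pathA"] = wrap(outA), _["pathB"] = wrap(outB),
                      _["startA"] = i, _["startB"] = j,
                      _["endA"] = ei, _["endB"] = ej);
}

// Independent optimality oracle: exhaustively enumerates every gapped global
// alignment (sequences of match / gap-in-b / gap-in-a columns) by plain
// recursion, tracking the previous column type so maximal gap runs are
// charged gapFirst + gapExt*(L-1). No memoisation: this is a brute force,
// feasible only for short sequences.
static double bruteRec(const IntegerVector& a, const IntegerVector& b,
                       const NumericMatrix& S, double floorScore,
                       double gapFirst, double gapExt,
                       int i, int j, int last) {
  const int n = a.size(), m = b.size();
  if (i == n && j == m) return 0.0;
  double best = NEG_INF;
  if (i < n && j < m) {
    double v = subScore(S, floorScore, a[i], b[j]) +
      bruteRec(a, b, S, floorScore, gapFirst, gapExt, i + 1, j + 1, 0);
    if (v > best) best = v;
  }
  if (i < n) { // a residue opposite a gap in b
    double c = (last == 1) ? gapExt : gapFirst;
    double v = -c + bruteRec(a, b, S, floorScore, gapFirst, gapExt,
                             i + 1, j, 1);
    if (v > best) best = v;
  }
  if (j < m) {
    double c = (last == 2) ? gapExt : gapFirst;
    double v = -c + bruteRec(a, b, S, floorScore, gapFirst, gapExt,
                             i, j + 1, 2);
    if (v > best) best = v;
  }
  return best;
}

// [[Rcpp::export(name = ".bruteForceGlobalScore")]]
double bruteForceGlobalScore(IntegerVector a, IntegerVector b,
                             NumericMatrix S, double floorScore,
                             double gapFirst, double gapExt) {
  if (a.size() > 10 || b.size() > 10)
    stop("brute force limited to sequences of length <= 10");
  return bruteRec(a, b, S, floorScore, gapFirst, gapExt, 0, 0, 0);
}
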