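#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Sequential minimal optimisation for the soft-margin SVC dual
//   min 1/2 a' Q a - e' a,  Q_ij = y_i y_j K_ij,  0 <= a_i <= C, y'a = 0
// on a precomputed kernel matrix. Working-set selection is the maximal
// violating pair; the stopping rule is the KKT gap m(a) - M(a) <= tol.
// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(NumericMatrix K, NumericVector y, double C, double tol,
               int max_iter) {
  const int n = K.nrow();
  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  int iter = 0;
  double gap = R_PosInf;

  while (iter < max_iter) {
    int i = -1, j = -1;
    double Gmax = -R_PosInf, Gmin = R_PosInf;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool up = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (low && v < Gmin) { Gmin = v; j = t; }
    }
    gap = Gmax - Gmin;
    if (i < 0 || j < 0 || gap <= tol) break;

    double yi = y[i], yj = y[j];
    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 1e-12) quad = 1e-12;
    double delta = (-yi * G[i] + yj * G[j]) / quad;

    double ai_old = alpha[i], aj_old = alpha[j];
    double sum = yi * ai_old + yj * aj_old; // conserved by the update
    double ai = ai_old + yi * delta;
    if (ai < 0.0) ai = 0.0;
    if (ai > C) ai = C;
    double aj = yj * (sum - yi * ai);
    if (aj < 0.0) { aj = 0.0; ai = yi * sum; }
    if (aj > C)   { aj = C;   ai = yi * (sum - yj * C); }
    if (ai < 0.0) ai = 0.0;
    if (ai > C) ai = C;

    double di = (ai - ai_old) * yi, dj = (aj - aj_old) * yj;
    alpha[i] = ai;
    alpha[j] = aj;
    if (di != 0.0 || dj != 0.0) {
      for (int t = 0; t < n; ++t)
        G[t] += y[t] * (K(t, i) * di + K(t, j) * dj);
    }
    ++iter;
  }

  // recompute the final KKT gap for reporting
  double Gmax = -R_PosInf, Gmin = R_PosInf;
  for (int t = 0; t < n; ++t) {
    double v = -y[t] * G[t];
    bool up = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
    bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
    if (up && v > Gmax) Gmax = v;
    if (low && v < Gmin) Gmin = v;
  }
  gap = (Gmax > -R_PosInf && Gmin < R_PosInf) ? Gmax - Gmin : 0.0;

  // bias: mean of -y_i G_i over free support vectors, else the midpoint of
  // the feasible interval implied by the bound vectors
  double b = 0.0;
  int n_free = 0;
  const double eps = 1e-8 * (C > 1.0 ? C : 1.0);
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > eps && alpha[t] < C - eps) {
      b += -y[t] * G[t];
      ++n_free;
    }
  }
  if (n_free > 0) {
    b /= n_free;
  } else {
    b = (Gmax + Gmin) / 2.0;
  }

  double obj = 0.0, sum_ay = 0.0;
  for (int t = 0; t < n; ++t) {
    obj += 0.5 * alpha[t] * (G[t] - 1.0);
    sum_ay += alpha[t] * y[t];
  }

  return List::create(
    _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
    _["b"] = b,
    _["objective"] = obj,
    _["kkt_gap"] = gap,
    _["iterations"] = iter,
    _["converged"] = gap <= tol,
    _["sum_alpha_y"] = sum_ay
  );
}

// 4-connected component labelling of a logical matrix (BFS); returns an
// integer matrix with 0 for background and 1..k component ids.
// [[Rcpp::export(name = "label_components")]]
IntegerMatrix label_components(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        int cr = q.front().first, cc = q.front().second;
        q.pop();
        const int dr[4] = {-1, 1, 0, 0};
        const int dc[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int r2 = cr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            q.push(std::make_pair(r2, c2));
          }
        }
      }
    }
  }
  return lab;
}
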