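// Graphical lasso path by block coordinate descent (Friedman et al. style):
// for each penalty, cycle over columns solving the dual lasso subproblem
// beta = argmin 1/2 b'W11 b - s12'b + lambda |b|_1 by coordinate descent,
// warm-starting both within a fit and along the (descending) penalty path.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// lasso coordinate descent on: 1/2 b'V b - u'b + lambda |b|_1
// V is (p-1)x(p-1) SPD, b warm-started in place.
static void lasso_cd(const mat& V, const vec& u, double lambda, vec& b,
                     double tol, int maxit) {
  const uword m = b.n_elem;
  vec Vb = V * b;            // running V %*% b
  for (int it = 0; it < maxit; ++it) {
    double maxdel = 0.0;
    for (uword k = 0; k < m; ++k) {
      double bk = b(k);
      double gk = u(k) - (Vb(k) - V(k, k) * bk);   // partial residual
      double bnew = soft(gk, lambda) / V(k, k);
      double del = bnew - bk;
      if (del != 0.0) {
        b(k) = bnew;
        Vb += del * V.col(k);
        double ad = std::fabs(del);
        if (ad > maxdel) maxdel = ad;
      }
    }
    if (maxdel < tol) break;
  }
}

// [[Rcpp::export]]
List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                     double tol = 1e-4, int maxit = 200,
                     double inner_tol = 1e-6, int inner_maxit = 500,
                     bool penalize_diagonal = false) {
  const uword p = S.n_rows;
  const uword nl = lambdas.n_elem;

  mat W = S;                 // working covariance estimate
  mat B(p, p, fill::zeros);  // B.col(j): lasso coefficients for column j
  double sbar = mean(mean(abs(S - diagmat(S.diag()))));
  if (sbar <= 0) sbar = 1.0;

  List thetas(nl);
  IntegerVector iters(nl);

  for (uword li = 0; li < nl; ++li) {
    double lambda = lambdas(li);
    W.diag() = S.diag() + (penalize_diagonal ? lambda : 0.0);

    int it = 0;
    for (; it < maxit; ++it) {
      double maxdel = 0.0;
      for (uword j = 0; j < p; ++j) {
        uvec idx(p - 1);
        uword c = 0;
        for (uword k = 0; k < p; ++k) if (k != j) idx(c++) = k;
        mat W11 = W.submat(idx, idx);
        vec s12 = S.col(j);
        s12 = s12.elem(idx);
        vec b = B.col(j);
        b = b.elem(idx);
        lasso_cd(W11, s12, lambda, b, inner_tol * sbar, inner_maxit);
        vec w12 = W11 * b;
        for (uword k = 0; k < p - 1; ++k) {
          double del = std::fabs(W(idx(k), j) - w12(k));
          if (del > maxdel) maxdel = del;
          W(idx(k), j) = w12(k);
          W(j, idx(k)) = w12(k);
          B(idx(k), j) = b(k);
        }
      }
      if (maxdel < tol * sbar) { ++it; break; }
    }
    iters[li] = it;

    // recover the precision matrix from W and B
    mat Theta(p, p, fill::zeros);
    for (uword j = 0; j < p; ++j) {
      double quad = 0.0;
      for (uword k = 0; k < p; ++k)
        if (k != j) quad += W(k, j) * B(k, j);
      double tjj = 1.0 / (W(j, j) - quad);
      Theta(j, j) = tjj;
      for (uword k = 0; k < p; ++k)
        if (k != j) Theta(k, j) = -B(k, j) * tjj;
    }
    // exact zeros survive averaging only if both directions are zero,
    // which matches the lasso active set at convergence
    mat Ts = 0.5 * (Theta + Theta.t());
    for (uword j = 0; j < p; ++j)
      for (uword k = j + 1; k < p; ++k)
        if (B(k, j) == 0.0 && B(j, k) == 0.0) { Ts(k, j) = 0.0; Ts(j, k) = 0.0; }
    thetas[li] = Ts;
  }

  return List::create(_["theta"] = thetas, _["iterations"] = iters);
}
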