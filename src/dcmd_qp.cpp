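// Simplex-constrained least squares and the bootstrap model-averaging loop.
//
// The weight-fitting problem is min ||y - A w||^2 subject to sum(w) = 1,
// w >= 0: a convex QP over the probability simplex. It is solved exactly by
// a primal active-set method on the bordered KKT system, keeping every
// iterate feasible. Component pmf columns can be (near-)collinear (e.g. a
// collapsed high-count grid), so the KKT blocks carry a tiny ridge to make
// the solves deterministic; the objective is unaffected to well below the
// convergence tolerance.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct QPResult {
  vec w;
  double objective;
  bool converged;
};

// Equality-constrained subproblem: min 0.5 w'Qw - c'w  s.t. sum w_F = 1,
// w = 0 off F. Returns the free weights and the equality multiplier.
static bool solve_kkt(const mat& Q, const vec& c, const uvec& F,
                      vec& wf, double& lambda) {
  const uword k = F.n_elem;
  mat K(k + 1, k + 1, fill::zeros);
  K.submat(0, 0, k - 1, k - 1) = Q.submat(F, F);
  double ridge = 1e-12 * (1.0 + trace(Q) / Q.n_rows);
  for (uword i = 0; i < k; ++i) K(i, i) += ridge;
  for (uword i = 0; i < k; ++i) { K(i, k) = 1.0; K(k, i) = 1.0; }
  vec rhs(k + 1);
  rhs.head(k) = c.elem(F);
  rhs(k) = 1.0;
  vec sol;
  bool ok = solve(sol, K, rhs, solve_opts::no_approx);
  if (!ok || !sol.is_finite()) {
    mat Kp = pinv(K);
    sol = Kp * rhs;
    if (!sol.is_finite()) return false;
  }
  wf = sol.head(k);
  lambda = sol(k);
  return true;
}

static QPResult simplex_lsq_core(const mat& A, const vec& y) {
  const uword n = A.n_cols;
  mat Q = A.t() * A;
  vec c = A.t() * y;
  double scale = 1.0 + std::max(abs(Q).max(), abs(c).max());
  const double tol_p = 1e-11;
  const double tol_d = 1e-9 * scale;

  // start from the single best component (fitted solutions are sparse, so
  // growing the free set is far cheaper than shrinking from all-free)
  uword j0 = 0;
  double best0 = datum::inf;
  for (uword j = 0; j < n; ++j) {
    double obj = Q(j, j) - 2.0 * c(j);
    if (obj < best0) { best0 = obj; j0 = j; }
  }
  vec w(n, fill::zeros);
  w(j0) = 1.0;
  std::vector<bool> in_free(n, false);
  in_free[j0] = true;
  uvec F = {j0};
  bool converged = false;

  for (uword iter = 0; iter < 100 * (n + 1); ++iter) {
    vec wf;
    double lambda = 0.0;
    if (!solve_kkt(Q, c, F, wf, lambda)) break;
    vec w_new(n, fill::zeros);
    w_new.elem(F) = wf;

    if (wf.min() >= -tol_p) {
      w = clamp(w_new, 0.0, datum::inf);
      // dual feasibility of the bound variables
      // KKT border solves Q_FF w + lambda 1 = c_F, so the gradient on the
      // free set equals -lambda; a bound variable should enter when its
      // reduced cost g_j - g_free = g_j + lambda is negative
      vec g = Q * w - c;
      double best_rc = 0.0;
      sword best_j = -1;
      for (uword j = 0; j < n; ++j) {
        if (in_free[j]) continue;
        double rc = g(j) + lambda;
        if (rc < best_rc) { best_rc = rc; best_j = (sword)j; }
      }
      if (best_j < 0 || best_rc >= -tol_d) { converged = true; break; }
      in_free[best_j] = true;
      F = sort(join_cols(F, uvec{(uword)best_j}));
    } else {
      // step toward w_new until the first free variable hits zero
      double alpha = 1.0;
      sword blocking = -1;
      for (uword p = 0; p < F.n_elem; ++p) {
        uword j = F(p);
        if (w_new(j) < 0 && w(j) > w_new(j)) {
          double a = w(j) / (w(j) - w_new(j));
          if (a < alpha) { alpha = a; blocking = (sword)j; }
        }
      }
      if (blocking < 0) break; // cannot happen for a consistent system
      w += alpha * (w_new - w);
      w(blocking) = 0.0;
      in_free[blocking] = false;
      if (F.n_elem <= 1) break;
      F = F(find(F != (uword)blocking));
    }
  }

  w = clamp(w, 0.0, datum::inf);
  double s = accu(w);
  if (s > 0) w /= s;
  vec r = y - A * w;
  return QPResult{w, dot(r, r), converged};
}

// [[Rcpp::export]]
Rcpp::List simplex_lsq_cpp(const arma::mat& A, const arma::vec& y) {
  QPResult res = simplex_lsq_core(A, y);
  return Rcpp::List::create(Rcpp::Named("w") = res.w,
                            Rcpp::Named("objective") = res.objective,
                            Rcpp::Named("converged") = res.converged);
}

// Bootstrap model averaging over nested candidate component sets.
//
// P:    ncat x ncomp x nsamp cube of per-sample category probabilities
// cat:  0-based category index observed for each sample
// idx:  nsamp x B matrix of 0-based resample indices (drawn in R)
// cand: list of 0-based component-column index vectors, one per candidate
// Aorig, yorig: category-probability means and aggregate counts of the
//   original data; candidate selection on each bootstrap iteration scores
//   the resample-fitted weights against the ORIGINAL aggregate.
// [[Rcpp::export]]
Rcpp::List dcmd_bootstrap_cpp(const arma::cube& P, const arma::uvec& cat,
                              const arma::umat& idx, const Rcpp::List& cand,
                              const arma::mat& Aorig, const arma::vec& yorig) {
  const uword ncat = P.n_rows, ncomp = P.n_cols, nsamp = P.n_slices;
  const uword B = idx.n_cols, L = cand.size();
  const double I = (double)nsamp;

  std::vector<uvec> cols(L);
  for (uword l = 0; l < L; ++l)
    cols[l] = Rcpp::as<uvec>(cand[l]);

  Rcpp::IntegerVector sel(B);
  mat wsum(ncomp, L, fill::zeros);

  // resample means of the per-sample probability slices as one GEMM:
  // columns of AB are the flattened ncat x ncomp matrices A_b
  mat W(nsamp, B, fill::zeros);
  mat Y(ncat, B, fill::zeros);
  for (uword b = 0; b < B; ++b)
    for (uword i = 0; i < nsamp; ++i) {
      uword s = idx(i, b);
      W(s, b) += 1.0;
      Y(cat(s), b) += 1.0;
    }
  const mat Pflat(const_cast<double*>(P.memptr()), ncat * ncomp, nsamp,
                  false, true);
  mat AB = (Pflat * W) / I;

  for (uword b = 0; b < B; ++b) {
    mat Ab(AB.colptr(b), ncat, ncomp, false, true);
    vec yb = Y.col(b);

    double best = datum::inf;
    uword best_l = 0;
    std::vector<vec> wl(L);
    for (uword l = 0; l < L; ++l) {
      QPResult fit = simplex_lsq_core(I * Ab.cols(cols[l]), yb);
      wl[l] = fit.w;
      vec r = yorig - I * (Aorig.cols(cols[l]) * fit.w);
      double obj = dot(r, r);
      if (obj < best - 1e-12) { best = obj; best_l = l; }
    }
    sel[b] = (int)best_l + 1;
    for (uword l = 0; l < L; ++l) {
      vec full(ncomp, fill::zeros);
      full.elem(cols[l]) = wl[l];
      wsum.col(l) += full;
    }
  }

  return Rcpp::List::create(Rcpp::Named("selected") = sel,
                            Rcpp::Named("wsum") = wsum);
}
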