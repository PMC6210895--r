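// Stagewise orthogonal matching pursuit (StOMP) kernels.
// Per-block problems are small (N = M^2, m <= N), but a cube decode runs tens
// of thousands of them, so the stagewise loop lives in C++.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static vec support_lsq(const mat& As, const vec& y) {
  vec xs;
  bool ok = solve(xs, As, y, solve_opts::no_approx);
  if (!ok || !xs.is_finite()) {
    xs = pinv(As) * y;  // rank-deficient support: minimum-norm solution
  }
  return xs;
}

static vec stomp_one(const mat& A, const vec& y, double t, int max_stages,
                     double tol) {
  const uword m = A.n_rows, N = A.n_cols;
  vec x(N, fill::zeros);
  const double ny = norm(y);
  if (ny == 0.0) return x;

  // column norms concentrate near 1 but are not exactly 1; normalizing the
  // matched filter makes atom selection the true per-atom correlation test
  vec colnorm(N);
  for (uword j = 0; j < N; ++j) {
    double nj = norm(A.col(j));
    colnorm(j) = nj > 0 ? nj : 1.0;
  }

  vec r = y;
  std::vector<uword> support;
  std::vector<bool> in_support(N, false);
  vec xs;
  // the least-squares refit is only stable well below the sampling capacity;
  // past m/2 atoms it starts interpolating measurement/quantization noise
  const uword cap = std::max((uword)1, m / 2);

  for (int s = 0; s < max_stages; ++s) {
    vec c = A.t() * r;
    vec cn = abs(c) / colnorm;
    double sigma = norm(r) / std::sqrt((double)m);
    double thr = t * sigma;

    // new atoms above threshold, strongest first so the support-size cap
    // keeps the best candidates
    uvec ord = sort_index(cn, "descend");
    bool added = false;
    for (uword i = 0; i < N && support.size() < cap; ++i) {
      uword j = ord(i);
      if (cn(j) <= thr) break;
      if (!in_support[j]) {
        in_support[j] = true;
        support.push_back(j);
        added = true;
      }
    }
    if (!added && support.empty()) {
      // degenerate regime: with m <= t^2 no atom can clear t*sigma since
      // max normalized |c| <= ||r|| = sqrt(m)*sigma; fall back to one OMP
      // step so tiny measurement budgets still decode
      uword j = ord(0);
      in_support[j] = true;
      support.push_back(j);
      added = true;
    }
    if (!added) break;

    uvec sup(support.size());
    for (uword i = 0; i < support.size(); ++i) sup(i) = support[i];
    std::sort(sup.begin(), sup.end());
    mat As = A.cols(sup);
    xs = support_lsq(As, y);
    r = y - As * xs;

    x.zeros();
    x.elem(sup) = xs;
    if (norm(r) <= tol * ny) break;
  }

  // prune atoms whose fitted coefficient is negligible at the stopping
  // scale (spurious admissions from stages before convergence), then refit
  uvec nz = find(abs(x) > tol * ny);
  if (nz.n_elem > 0 && nz.n_elem < (uword)support.size()) {
    mat As = A.cols(nz);
    vec xp = support_lsq(As, y);
    x.zeros();
    x.elem(nz) = xp;
  }
  return x;
}

// [[Rcpp::export]]
arma::vec stomp_cpp(const arma::mat& A, const arma::vec& y, double t,
                    int max_stages, double tol) {
  return stomp_one(A, y, t, max_stages, tol);
}

// Batch solver: column i of Y holds m_per_col[i] measurements (rows beyond
// that are ignored); A holds the maximal measurement matrix, of which the
// first m_per_col[i] rows apply to column i.
// [[Rcpp::export]]
arma::mat stomp_batch_cpp(const arma::mat& A, const arma::mat& Y,
                          const arma::ivec& m_per_col, double t,
                          int max_stages, double tol) {
  const uword N = A.n_cols, nb = Y.n_cols;
  mat X(N, nb, fill::zeros);
  for (uword i = 0; i < nb; ++i) {
    if (m_per_col(i) <= 0) continue;  // zero-budget block decodes to zero
    uword mi = (uword)m_per_col(i);
    X.col(i) = stomp_one(A.rows(0, mi - 1), Y.col(i).head(mi), t, max_stages, tol);
  }
  return X;
}
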