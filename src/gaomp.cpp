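// Group orthogonal matching pursuit on the real embedding of a G2
// dictionary.  Each multivector entry occupies four consecutive real rows
// (components e0, e1, e2, e12) and each atom four consecutive columns of the
// left-operator embedding, so atom selection by magnitude of the GA
// correlation sum_i gp(reverse(D[i,m]), r[i]) is exactly selection by the
// Euclidean norm of the atom's 4-column correlation block.
//
// The pursuit uses the precomputed Gram matrix G = Demb' Demb, which makes
// per-iteration work O(M k) instead of O(N M) and lets the whole patch set
// share two BLAS products.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List gaomp_embed_cpp(const arma::mat& Demb, const arma::mat& Q,
                           const int J, const double rtol) {
  const uword M = Demb.n_cols / 4;
  const uword K = Q.n_cols;
  if (Demb.n_rows != Q.n_rows)
    Rcpp::stop("gaomp: dictionary and signals have different row dimension");
  if (J < 1) Rcpp::stop("gaomp: sparsity budget J must be >= 1");

  const mat G  = Demb.t() * Demb;   // 4M x 4M
  const mat G0 = Demb.t() * Q;      // 4M x K

  mat A(4 * M, K, fill::zeros);     // interleaved coefficients
  imat supp(J, K); supp.fill(0);    // 1-based atom indices, 0 = unused
  ivec nsel(K, fill::zeros);
  mat rhist(J, K); rhist.fill(datum::nan);
  vec rfinal(K, fill::zeros);

  std::vector<uword> sel;
  for (uword k = 0; k < K; ++k) {
    const vec g0 = G0.col(k);
    const double qn2 = dot(Q.col(k), Q.col(k));
    const double qn = std::sqrt(qn2);
    rfinal(k) = qn;
    if (qn == 0.0) continue;
    const double tol = rtol * qn;

    sel.clear();
    uvec active;
    vec x;
    for (int it = 0; it < J; ++it) {
      vec g = g0;
      if (!sel.empty()) g -= G.cols(active) * x;
      // group norms over unselected atoms; strict > keeps lowest index on ties
      sword best = -1;
      double bestv = -1.0;
      for (uword m = 0; m < M; ++m) {
        bool used = false;
        for (uword s : sel) if (s == m) { used = true; break; }
        if (used) continue;
        const double* gm = g.memptr() + 4 * m;
        double v = gm[0] * gm[0] + gm[1] * gm[1] + gm[2] * gm[2] + gm[3] * gm[3];
        if (v > bestv) { bestv = v; best = (sword) m; }
      }
      if (best < 0) break;
      sel.push_back((uword) best);

      const uword kk = sel.size();
      active.set_size(4 * kk);
      for (uword j = 0; j < kk; ++j)
        for (uword c = 0; c < 4; ++c) active(4 * j + c) = 4 * sel[j] + c;

      const mat Gs = G.submat(active, active);
      const vec gs = g0.elem(active);
      bool ok = solve(x, Gs, gs, solve_opts::no_approx);
      if (!ok || !x.is_finite())
        x = pinv(Demb.cols(active)) * Q.col(k);   // rank-deficient fallback

      // explicit residual: the Gram shortcut qn2 - x'gs cannot resolve
      // norms below sqrt(machine eps) * ||q||
      const vec r = Q.col(k) - Demb.cols(active) * x;
      double rn = norm(r, 2);
      rhist(it, k) = rn;
      rfinal(k) = rn;
      if (rn <= tol) break;
    }
    for (uword j = 0; j < sel.size(); ++j) {
      supp(j, k) = (int) sel[j] + 1;
      for (uword c = 0; c < 4; ++c) A(4 * sel[j] + c, k) = x(4 * j + c);
    }
    nsel(k) = (int) sel.size();
  }

  return Rcpp::List::create(
    Rcpp::Named("coef") = A,
    Rcpp::Named("support") = supp,
    Rcpp::Named("nsel") = nsel,
    Rcpp::Named("resid_history") = rhist,
    Rcpp::Named("resid") = rfinal);
}
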