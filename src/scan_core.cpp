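// Nested-model F-test scan core for founder-descent probability designs.
//
// The haplotype association test at a marker compares
//   null: y ~ X            (covariates, incl. intercept)
//   full: y ~ X + P[,-ref] (founder-descent probabilities, reference
//                           founder column dropped for identifiability)
// on mouse-level data. logP = -log10 of the partial-F P value, capped.
// All routines work from line-level probability matrices (L x 8 per
// marker) expanded to mice through a line index, so permutations of the
// line -> descent assignment are cheap.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double RANK_TOL = 1e-10;

// Orthonormal basis of the column space of X (n x q, assumed full rank
// after R-side aliasing removal).
static mat x_basis(const mat& X) {
  mat Q, R;
  qr_econ(Q, R, X);
  return Q;
}

// SVD-based reduced basis of M with numerical rank detection.
// Returns basis columns; rank in *rank_out.
static mat reduced_basis(const mat& M, uword* rank_out) {
  mat U;
  vec s;
  mat V;
  if (!svd_econ(U, s, V, M)) {
    *rank_out = 0;
    return mat(M.n_rows, 0);
  }
  double smax = s.n_elem > 0 ? s(0) : 0.0;
  uword r = 0;
  for (uword i = 0; i < s.n_elem; ++i)
    if (s(i) > RANK_TOL * std::max(smax, 1.0)) ++r;
  *rank_out = r;
  if (r == 0) return mat(M.n_rows, 0);
  return mat(U.cols(0, r - 1));
}

// -log10 upper-tail F probability, capped. `scale` is the squared norm
// of the phenotype, used to recognize numerically-zero null RSS
// (constant traits) rather than treating rounding dust as signal.
static double f_logp(double rss0, double rss1, double df1, double df2,
                     double cap, double scale) {
  if (df1 <= 0 || df2 <= 0 || rss0 <= 1e-12 * std::max(scale, 1e-300))
    return 0.0;
  if (rss1 <= 1e-14 * rss0) return cap;
  double F = ((rss0 - rss1) / df1) / (rss1 / df2);
  if (F <= 0) return 0.0;
  double lp = R::pf(F, df1, df2, 0, 1);  // log upper tail
  double logP = -lp / std::log(10.0);
  if (!std::isfinite(logP) || logP > cap) logP = cap;
  if (logP < 0) logP = 0.0;
  return logP;
}

// Expand line-level marker matrix (L x 8) to mice and drop the
// reference column; line_perm maps line i -> descent row line_perm[i].
static mat expand_probs(const mat& Pline, const uvec& line_idx,
                        const uvec& line_perm, uword drop) {
  mat Pm = Pline.rows(line_perm);
  Pm.shed_col(drop);
  return Pm.rows(line_idx);
}

// Full scan with effects and standard errors at every marker.
// Pline: cube L x 8 x M; line_idx: 0-based line of each mouse;
// drop: 0-based reference founder column.
// [[Rcpp::export]]
Rcpp::List cpp_scan(const arma::vec& y, const arma::mat& X,
                    const arma::cube& Pline, const arma::uvec& line_idx,
                    int drop, double cap) {
  const uword n = y.n_elem, M = Pline.n_slices, L = Pline.n_rows;
  const uword qx = X.n_cols;
  mat Qx = x_basis(X);
  vec yres = y - Qx * (Qx.t() * y);
  double rss0 = dot(yres, yres);
  uvec id = regspace<uvec>(0, L - 1);

  vec logP(M, fill::zeros);
  ivec dfnum(M, fill::zeros);
  mat eff(M, 8, fill::zeros), se(M, 8, fill::zeros);
  cube covb_all(8, 8, M, fill::zeros);
  Rcpp::LogicalVector degenerate(M);

  for (uword m = 0; m < M; ++m) {
    mat Pm = expand_probs(Pline.slice(m), line_idx, id, (uword)drop);
    mat Pres = Pm - Qx * (Qx.t() * Pm);
    mat U;
    vec s;
    mat V;
    if (!svd_econ(U, s, V, Pres)) { degenerate[m] = true; continue; }
    double smax = s(0);
    uword r = 0;
    for (uword i = 0; i < s.n_elem; ++i)
      if (s(i) > RANK_TOL * std::max(smax, 1.0)) ++r;
    dfnum(m) = (int)r;
    if (r == 0) { degenerate[m] = true; continue; }
    vec z = U.head_cols(r).t() * yres;
    double rss1 = rss0 - dot(z, z);
    if (rss1 < 0) rss1 = 0;
    double df2 = (double)n - (double)qx - (double)r;
    logP(m) = f_logp(rss0, rss1, (double)r, df2, cap, dot(y, y));
    if (r < Pres.n_cols) degenerate[m] = true;
    // coefficients of the (residualized) founder columns = full-model
    // founder coefficients (Frisch-Waugh); pseudo-inverse for rank < 7
    vec sinv(s.n_elem, fill::zeros);
    for (uword i = 0; i < r; ++i) sinv(i) = 1.0 / s(i);
    vec beta = V * (sinv % (U.t() * yres));
    double sigma2 = df2 > 0 ? rss1 / df2 : 0.0;
    mat covb = V * diagmat(square(sinv)) * V.t() * sigma2;
    uvec fmap(7);
    uword k = 0;
    for (uword f = 0; f < 8; ++f) {
      if ((int)f == drop) continue;
      eff(m, f) = beta(k);
      se(m, f) = std::sqrt(std::max(covb(k, k), 0.0));
      fmap(k) = f;
      ++k;
    }
    for (uword a = 0; a < 7; ++a)
      for (uword b = 0; b < 7; ++b)
        covb_all(fmap(a), fmap(b), m) = covb(a, b);
  }
  return Rcpp::List::create(
      Rcpp::Named("logP") = logP, Rcpp::Named("effects") = eff,
      Rcpp::Named("se") = se, Rcpp::Named("df_num") = dfnum,
      Rcpp::Named("covb") = covb_all,
      Rcpp::Named("degenerate") = degenerate);
}

// Maximum logP over all markers for each permutation of the
// line -> descent assignment. perms: n_perm x L, 0-based.
// [[Rcpp::export]]
arma::vec cpp_perm_max(const arma::vec& y, const arma::mat& X,
                       const arma::cube& Pline, const arma::uvec& line_idx,
                       const arma::umat& perms, int drop, double cap) {
  const uword n = y.n_elem, M = Pline.n_slices;
  const uword qx = X.n_cols, n_perm = perms.n_rows;
  mat Qx = x_basis(X);
  vec yres = y - Qx * (Qx.t() * y);
  double rss0 = dot(yres, yres);
  double yy = dot(y, y);
  vec out(n_perm, fill::zeros);

  for (uword p = 0; p < n_perm; ++p) {
    uvec perm = perms.row(p).t();
    double best = 0.0;
    for (uword m = 0; m < M; ++m) {
      mat Pm = expand_probs(Pline.slice(m), line_idx, perm, (uword)drop);
      mat Pres = Pm - Qx * (Qx.t() * Pm);
      uword r;
      mat U = reduced_basis(Pres, &r);
      if (r == 0) continue;
      vec z = U.t() * yres;
      double rss1 = std::max(rss0 - dot(z, z), 0.0);
      double lp = f_logp(rss0, rss1, (double)r, (double)n - qx - r, cap, yy);
      if (lp > best) best = lp;
    }
    out(p) = best;
    if (p % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// logP for many phenotype vectors over a fixed marker set (descent
// fixed): used by the residual-resampling CI rescans.
// Returns M x B matrix of logP.
// [[Rcpp::export]]
arma::mat cpp_scan_multi(const arma::mat& Y, const arma::mat& X,
                         const arma::cube& Pline, const arma::uvec& line_idx,
                         int drop, double cap) {
  const uword n = Y.n_rows, B = Y.n_cols, M = Pline.n_slices, L = Pline.n_rows;
  const uword qx = X.n_cols;
  mat Qx = x_basis(X);
  mat Yres = Y - Qx * (Qx.t() * Y);
  rowvec rss0 = sum(square(Yres), 0);
  uvec id = regspace<uvec>(0, L - 1);
  mat out(M, B, fill::zeros);

  for (uword m = 0; m < M; ++m) {
    mat Pm = expand_probs(Pline.slice(m), line_idx, id, (uword)drop);
    mat Pres = Pm - Qx * (Qx.t() * Pm);
    uword r;
    mat U = reduced_basis(Pres, &r);
    if (r == 0) continue;
    mat Z = U.t() * Yres;                  // r x B
    rowvec rss1 = rss0 - sum(square(Z), 0);
    double df2 = (double)n - (double)qx - (double)r;
    for (uword b = 0; b < B; ++b)
      out(m, b) = f_logp(rss0(b), std::max(rss1(b), 0.0), (double)r, df2,
                         cap, dot(Y.col(b), Y.col(b)));
    Rcpp::checkUserInterrupt();
  }
  return out;
}
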