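// Multivariate-normal LRT genome scan with per-locus backward elimination.
//
// Model: trait vector y_n = beta0 + x_nl beta_l + eps_n, eps ~ N(0, Sigma),
// with effects constrained to zero outside an active trait set K.  The
// constrained model is a seemingly-unrelated regression whose exact MLE
// factorizes as f(Y_Kbar | 1) * f(Y_K | 1, x, Y_Kbar); both factors are
// unrestricted multivariate regressions, so -2 logLik is available in
// closed form from residual cross-product determinants.  The factorization
// yields the identity
//
//   T(K) = T_full(all p traits) - T_full(Kbar traits only),
//
// where T_full(S) = N * (logdet C0[S,S] - logdet C1[S,S]) is the
// unrestricted joint LRT on the trait subset S, C0 = cross-product of
// intercept-only residuals and C1 = C0 - c c'/Sxx the cross-product of
// (1, x)-regression residuals (c = Yc'xc).  All scan statistics reduce to
// determinants of aligned submatrices of C0 and C1, and nestedness
// T(K) <= T(K') for K in K' is inherited exactly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double logdet_spd(const mat &C) {
  double val;
  if (!log_det_sympd(val, C)) {
    Rcpp::stop("singular residual covariance: model fit is degenerate");
  }
  return val;
}

// T_full on the trait subset S (indices into 0..p-1); empty S gives 0
static double t_subset(double N, const mat &C0, const mat &C1,
                       const uvec &S) {
  if (S.n_elem == 0) return 0.0;
  if (S.n_elem == 1)
    return N * (std::log(C0(S[0], S[0])) - std::log(C1(S[0], S[0])));
  return N * (logdet_spd(C0.submat(S, S)) - logdet_spd(C1.submat(S, S)));
}

static uvec which_idx(const std::vector<bool> &flag, bool value) {
  std::vector<uword> out;
  for (uword k = 0; k < flag.size(); ++k)
    if (flag[k] == value) out.push_back(k);
  return uvec(out);
}

// [[Rcpp::export]]
Rcpp::List cpp_scan(const arma::mat &X, const arma::mat &Y,
                    bool include_single = true) {
  const uword N = Y.n_rows, p = Y.n_cols, L = X.n_cols;
  if (X.n_rows != N) Rcpp::stop("genotype/phenotype row mismatch");

  mat Yc = Y.each_row() - mean(Y, 0);
  mat C0 = Yc.t() * Yc;
  logdet_spd(C0);                        // fail early on degenerate traits

  mat bestk(L, p), indiv(L, p), single_(L, p);
  imat order(L, p);
  Rcpp::LogicalVector mono(L);
  const double eps = 1e-12;
  const double dN = (double)N;

  for (uword l = 0; l < L; ++l) {
    vec x = X.col(l);
    vec xc = x - mean(x);
    double Sxx = dot(xc, xc);
    if (Sxx < eps * N) {                 // monomorphic locus: no information
      mono[l] = true;
      bestk.row(l).zeros();
      indiv.row(l).zeros();
      single_.row(l).zeros();
      for (uword k = 0; k < p; ++k) order(l, k) = (int)k + 1;
      continue;
    }
    mono[l] = false;
    vec c = Yc.t() * xc;
    mat C1 = C0 - (c * c.t()) / Sxx;
    double Tfull = dN * (logdet_spd(C0) - logdet_spd(C1));
    if (Tfull < 0) Tfull = 0;
    bestk(l, p - 1) = Tfull;

    // indiv: effect k given all others = T_full(all) - T(all \ {k}),
    // which collapses to the subset statistic on {k} alone
    for (uword k = 0; k < p; ++k) {
      double t = dN * (std::log(C0(k, k)) - std::log(C1(k, k)));
      indiv(l, k) = t > 0 ? t : 0;
    }

    // backward elimination: at each size drop the effect whose removal
    // reduces the joint LRT least, i.e. whose move into the trivial set
    // Kbar raises T_full(Kbar) least; ties go to the lowest trait index
    std::vector<bool> active(p, true);
    uword nact = p, step = 0;
    while (nact > 1) {
      double bestT = -datum::inf;
      uword drop = p;
      for (uword k = 0; k < p; ++k) {
        if (!active[k]) continue;
        active[k] = false;
        double Tk = Tfull - t_subset(dN, C0, C1, which_idx(active, false));
        active[k] = true;
        if (Tk > bestT) { bestT = Tk; drop = k; }
      }
      active[drop] = false;
      order(l, step++) = (int)drop + 1;
      --nact;
      bestk(l, nact - 1) = bestT > 0 ? bestT : 0;
    }
    for (uword k = 0; k < p; ++k)        // last survivor closes the order
      if (active[k]) order(l, step) = (int)k + 1;
    if (p == 1) indiv(l, 0) = Tfull;

    if (include_single) {                // effect k alone, others excluded
      std::vector<bool> one(p, false);
      for (uword k = 0; k < p; ++k) {
        one[k] = true;
        double t = Tfull - t_subset(dN, C0, C1, which_idx(one, false));
        single_(l, k) = t > 0 ? t : 0;
        one[k] = false;
      }
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("bestk") = bestk, Rcpp::Named("order") = order,
      Rcpp::Named("indiv") = indiv, Rcpp::Named("single") = single_,
      Rcpp::Named("monomorphic") = mono);
}

// Joint LRT of a fixed active trait set at every locus (1-based indices).
// Used for genome scans of a known effect set and their permutation nulls.
// [[Rcpp::export]]
arma::vec cpp_scan_fixed(const arma::mat &X, const arma::mat &Y,
                         const arma::ivec &active_set) {
  const uword N = Y.n_rows, p = Y.n_cols, L = X.n_cols;
  if (X.n_rows != N) Rcpp::stop("genotype/phenotype row mismatch");
  std::vector<bool> active(p, false);
  for (uword i = 0; i < active_set.n_elem; ++i) {
    int k = active_set[i];
    if (k < 1 || (uword)k > p) Rcpp::stop("active set index out of range");
    active[k - 1] = true;
  }
  uvec Kbar = which_idx(active, false);
  mat Yc = Y.each_row() - mean(Y, 0);
  mat C0 = Yc.t() * Yc;
  double ld0 = logdet_spd(C0);
  vec out(L, fill::zeros);
  for (uword l = 0; l < L; ++l) {
    vec xc = X.col(l) - mean(X.col(l));
    double Sxx = dot(xc, xc);
    if (Sxx < 1e-12 * N) continue;
    vec c = Yc.t() * xc;
    mat C1 = C0 - (c * c.t()) / Sxx;
    double Tfull = (double)N * (ld0 - logdet_spd(C1));
    double t = Tfull - t_subset((double)N, C0, C1, Kbar);
    out[l] = t > 0 ? t : 0;
  }
  return out;
}

// Joint LRT for one locus with QTL effects on an arbitrary active trait
// set (1-based indices).  Used for hypothesis tests on fixed sets.
// [[Rcpp::export]]
double cpp_lrt_joint(const arma::vec &x, const arma::mat &Y,
                     const arma::ivec &active_set) {
  const uword N = Y.n_rows, p = Y.n_cols;
  if (x.n_elem != N) Rcpp::stop("genotype/phenotype row mismatch");
  mat Yc = Y.each_row() - mean(Y, 0);
  mat C0 = Yc.t() * Yc;
  vec xc = x - mean(x);
  double Sxx = dot(xc, xc);
  if (Sxx < 1e-12 * N) return 0.0;
  vec c = Yc.t() * xc;
  mat C1 = C0 - (c * c.t()) / Sxx;
  std::vector<bool> active(p, false);
  for (uword i = 0; i < active_set.n_elem; ++i) {
    int k = active_set[i];
    if (k < 1 || (uword)k > p) Rcpp::stop("active set index out of range");
    active[k - 1] = true;
  }
  double Tfull = (double)N * (logdet_spd(C0) - logdet_spd(C1));
  double t = Tfull - t_subset((double)N, C0, C1, which_idx(active, false));
  return t > 0 ? t : 0;
}
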