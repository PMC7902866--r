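#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// De Jong's SIMPLS for a single response, on already-centered data.
// Fills Rmat (K x Lmax basis weights), qvec (response loadings) and the
// cumulative training R^2 per component count; returns the number of
// components actually extracted (deflation can exhaust the covariance
// before Lmax on rank-deficient data).
static int simpls_core(const mat& Xc, const vec& yc, int Lmax,
                       mat& Rmat, vec& qvec, vec& r2) {
  const uword K = Xc.n_cols;
  vec S = Xc.t() * yc;
  const double sstot = dot(yc, yc);
  const double s0 = norm(S) + 1e-300;
  mat V(K, (uword)Lmax, fill::zeros);
  Rmat.zeros(K, (uword)Lmax);
  qvec.zeros((uword)Lmax);
  r2.zeros((uword)Lmax);
  double ssexp = 0.0;
  int A = 0;
  for (int a = 0; a < Lmax; ++a) {
    if (norm(S) < 1e-12 * s0) break;
    vec r = S;
    vec t = Xc * r;
    double nt = norm(t);
    if (nt < 1e-300) break;
    t /= nt; r /= nt;
    // sign convention: first non-negligible weight entry positive
    for (uword k = 0; k < K; ++k) {
      if (std::abs(r(k)) > 1e-12) {
        if (r(k) < 0) { r = -r; t = -t; }
        break;
      }
    }
    vec p = Xc.t() * t;
    double q = dot(yc, t);
    vec v = p;
    if (a > 0) v -= V.cols(0, (uword)a - 1) * (V.cols(0, (uword)a - 1).t() * p);
    double nv = norm(v);
    Rmat.col((uword)a) = r;
    qvec((uword)a) = q;
    ssexp += q * q;
    r2((uword)a) = sstot > 0 ? ssexp / sstot : 0.0;
    A = a + 1;
    if (nv < 1e-300) break;  // basis exhausted
    v /= nv;
    S -= v * dot(v, S);
    V.col((uword)a) = v;
  }
  return A;
}

// Component-count rule shared by the R and C++ paths.
// criterion 0: smallest L with cumulative R^2 >= target (else the best L).
// criterion 1 (elbow): smallest L after which the next increment < thresh.
static int pick_ncomp(const vec& r2, int A, int criterion,
                      double target, double thresh) {
  if (A <= 1) return A > 0 ? A : 1;
  if (criterion == 0) {
    for (int a = 0; a < A; ++a)
      if (r2((uword)a) >= target - 1e-12) return a + 1;
    return A;
  }
  for (int a = 0; a < A - 1; ++a) {
    double inc = r2((uword)a + 1) - r2((uword)a);
    if (inc < thresh) return a + 1;
  }
  return A;
}

// [[Rcpp::export]]
Rcpp::List cpp_simpls(const arma::mat& X, const arma::vec& y, int Lmax) {
  rowvec xm = mean(X, 0);
  double ym = mean(y);
  mat Xc = X.each_row() - xm;
  vec yc = y - ym;
  mat Rmat; vec qvec; vec r2;
  int A = simpls_core(Xc, yc, Lmax, Rmat, qvec, r2);
  return Rcpp::List::create(
      Rcpp::Named("weights") = Rmat,
      Rcpp::Named("q") = qvec,
      Rcpp::Named("r2") = r2,
      Rcpp::Named("ncomp") = A,
      Rcpp::Named("xMean") = xm,
      Rcpp::Named("yMean") = ym);
}

// Leave-one-out cross-validation with a fresh SIMPLS fit per fold; the
// component count is re-selected on each training fold.
// [[Rcpp::export]]
Rcpp::List cpp_loo(const arma::mat& X, const arma::vec& y, int Lmax,
                   int criterion, double target, double thresh,
                   bool returnAlphas) {
  const uword N = X.n_rows, K = X.n_cols;
  int Leff = std::min<int>(Lmax, std::min<int>((int)K, (int)N - 2));
  if (Leff < 1) Leff = 1;
  vec pred(N, fill::zeros);
  ivec Lsel(N, fill::zeros);
  mat alphas;
  if (returnAlphas) alphas.zeros(N, K);
  mat Xt(N - 1, K);
  vec yt(N - 1);
  mat Rmat; vec qvec; vec r2;
  for (uword i = 0; i < N; ++i) {
    uword m = 0;
    for (uword j = 0; j < N; ++j) {
      if (j == i) continue;
      Xt.row(m) = X.row(j);
      yt(m) = y(j);
      ++m;
    }
    rowvec xm = mean(Xt, 0);
    double ym = mean(yt);
    mat Xc = Xt.each_row() - xm;
    vec yc = yt - ym;
    int A = simpls_core(Xc, yc, Leff, Rmat, qvec, r2);
    if (A < 1) {  // zero-variance training response: predict its mean
      pred(i) = ym;
      Lsel(i) = 0;
      continue;
    }
    int L = pick_ncomp(r2, A, criterion, target, thresh);
    vec beta = Rmat.cols(0, (uword)L - 1) * qvec.subvec(0, (uword)L - 1);
    pred(i) = dot(X.row(i) - xm, beta) + ym;
    Lsel(i) = L;
    if (returnAlphas) alphas.row(i) = beta.t();
  }
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("pred") = pred,
      Rcpp::Named("ncomp") = Lsel);
  if (returnAlphas) out["alphas"] = alphas;
  return out;
}
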