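// Kalman filtering/smoothing for linear-Gaussian state-space models with
// diagonal observation noise. Supports time-varying dynamics (one slice per
// frame) so that switching models can be smoothed under soft state
// assignments, missing observation frames (update skipped), and an additive
// per-frame input drive. The observation update uses the information form so
// cost per frame is O(D^3 + N*D), never O(N^3).
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline mat safe_inv(const mat& M) {
  mat Mi;
  if (!inv_sympd(Mi, symmatu(M))) {
    Mi = pinv(symmatu(M) + 1e-10 * eye(M.n_rows, M.n_cols));
  }
  return Mi;
}

// [[Rcpp::export]]
Rcpp::List kalman_smooth_cpp(const arma::mat& Y,      // N x T
                             const arma::mat& C,      // N x D
                             const arma::vec& d,      // N
                             const arma::vec& Sdiag,  // N (obs variances)
                             const arma::cube& A,     // D x D x (T or 1); slice t maps x_{t-1} -> x_t
                             const arma::mat& b,      // D x (T or 1)
                             const arma::cube& Q,     // D x D x (T or 1)
                             const arma::mat& U,      // D x (T or 1) additive input drive (0 if none)
                             const arma::vec& x0,
                             const arma::mat& V0,
                             const arma::uvec& obs) { // length T, 1 = observed
  const uword T = Y.n_cols, N = Y.n_rows, D = C.n_cols;
  const bool tvA = (A.n_slices > 1), tvb = (b.n_cols > 1),
             tvQ = (Q.n_slices > 1), tvU = (U.n_cols > 1);

  vec Sinv = 1.0 / Sdiag;
  mat CtSi = C.t() * diagmat(Sinv);       // D x N
  mat CtSiC = symmatu(CtSi * C);          // D x D
  double logdetS = accu(log(Sdiag));

  mat xf(D, T), xp(D, T);
  cube Pf(D, D, T), Pp(D, D, T);
  double loglik = 0.0;
  const double l2pi = std::log(2.0 * M_PI);

  for (uword t = 0; t < T; ++t) {
    vec xpt; mat Ppt;
    if (t == 0) {
      xpt = x0; Ppt = symmatu(V0);
    } else {
      const mat& At = A.slice(tvA ? t : 0);
      const mat& Qt = Q.slice(tvQ ? t : 0);
      vec bt = b.col(tvb ? t : 0) + U.col(tvU ? t : 0);
      xpt = At * xf.col(t - 1) + bt;
      Ppt = symmatu(At * Pf.slice(t - 1) * At.t() + Qt);
    }
    xp.col(t) = xpt; Pp.slice(t) = Ppt;

    if (obs(t)) {
      mat Ppinv = safe_inv(Ppt);
      mat M = symmatu(Ppinv + CtSiC);
      mat Pft = safe_inv(M);
      vec r = Y.col(t) - d - C * xpt;
      vec m = CtSi * r;
      vec xft = xpt + Pft * m;  // = Pft * (Ppinv*xpt + CtSi*(y-d))
      double rSr = accu(square(r) % Sinv);
      double quad = rSr - as_scalar(m.t() * Pft * m);
      double ld_pp, sign1, ld_m, sign2;
      log_det(ld_pp, sign1, Ppt + 1e-300 * eye(D, D));
      log_det(ld_m, sign2, M);
      double logdet = logdetS + ld_m + ld_pp;
      loglik += -0.5 * (N * l2pi + logdet + quad);
      xf.col(t) = xft; Pf.slice(t) = symmatu(Pft);
    } else {
      xf.col(t) = xpt; Pf.slice(t) = Ppt;
    }
  }

  // RTS smoother
  mat xs(D, T);
  cube Ps(D, D, T), Pcross(D, D, T, fill::zeros); // Pcross.slice(t) = Cov(x_t, x_{t-1})
  xs.col(T - 1) = xf.col(T - 1);
  Ps.slice(T - 1) = Pf.slice(T - 1);
  for (uword t = T - 1; t-- > 0;) {
    const mat& At1 = A.slice(tvA ? (t + 1) : 0);
    mat Ppinv = safe_inv(Pp.slice(t + 1));
    mat J = Pf.slice(t) * At1.t() * Ppinv;
    xs.col(t) = xf.col(t) + J * (xs.col(t + 1) - xp.col(t + 1));
    Ps.slice(t) = symmatu(Pf.slice(t) + J * (Ps.slice(t + 1) - Pp.slice(t + 1)) * J.t());
    Pcross.slice(t + 1) = Ps.slice(t + 1) * J.t();
  }

  return Rcpp::List::create(
    Rcpp::Named("xs") = xs, Rcpp::Named("Ps") = Ps,
    Rcpp::Named("Pcross") = Pcross, Rcpp::Named("loglik") = loglik,
    Rcpp::Named("xf") = xf, Rcpp::Named("Pf") = Pf,
    Rcpp::Named("xp") = xp, Rcpp::Named("Pp") = Pp);
}

// One-step-ahead predictive log-likelihood per frame (for model selection):
// runs the filter and returns the per-frame observation log-density under
// the prediction, without smoothing.
// [[Rcpp::export]]
arma::vec kalman_predictive_ll_cpp(const arma::mat& Y, const arma::mat& C,
                                   const arma::vec& d, const arma::vec& Sdiag,
                                   const arma::cube& A, const arma::mat& b,
                                   const arma::cube& Q, const arma::mat& U,
                                   const arma::vec& x0, const arma::mat& V0,
                                   const arma::uvec& obs) {
  const uword T = Y.n_cols, N = Y.n_rows, D = C.n_cols;
  const bool tvA = (A.n_slices > 1), tvb = (b.n_cols > 1),
             tvQ = (Q.n_slices > 1), tvU = (U.n_cols > 1);
  vec Sinv = 1.0 / Sdiag;
  mat CtSi = C.t() * diagmat(Sinv);
  mat CtSiC = symmatu(CtSi * C);
  double logdetS = accu(log(Sdiag));
  const double l2pi = std::log(2.0 * M_PI);

  vec ll(T, fill::zeros);
  vec xft = x0; mat Pft = symmatu(V0);
  for (uword t = 0; t < T; ++t) {
    vec xpt; mat Ppt;
    if (t == 0) { xpt = xft; Ppt = Pft; }
    else {
      const mat& At = A.slice(tvA ? t : 0);
      const mat& Qt = Q.slice(tvQ ? t : 0);
      vec bt = b.col(tvb ? t : 0) + U.col(tvU ? t : 0);
      xpt = At * xft + bt;
      Ppt = symmatu(At * Pft * At.t() + Qt);
    }
    mat Ppinv = safe_inv(Ppt);
    mat M = symmatu(Ppinv + CtSiC);
    mat Pnew = safe_inv(M);
    vec r = Y.col(t) - d - C * xpt;
    vec m = CtSi * r;
    double rSr = accu(square(r) % Sinv);
    double quad = rSr - as_scalar(m.t() * Pnew * m);
    double ld_pp, s1, ld_m, s2;
    log_det(ld_pp, s1, Ppt + 1e-300 * eye(D, D));
    log_det(ld_m, s2, M);
    ll(t) = -0.5 * (N * l2pi + logdetS + ld_m + ld_pp + quad);
    if (obs(t)) { xft = xpt + Pnew * m; Pft = symmatu(Pnew); }
    else { xft = xpt; Pft = Ppt; }
  }
  return ll;
}
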