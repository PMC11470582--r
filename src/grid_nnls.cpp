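// Coarse-grid variable-projection search for the four-compartment decay
// model. For each candidate (D_R, [D_H, alpha_H], D_F) the fractions are the
// non-negative least-squares solution of the per-b kernel system augmented
// with a heavily weighted sum-to-one row; the search returns the top
// candidates by residual sum of squares on the data rows.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lawson-Hanson NNLS, sized for a handful of columns.
static vec nnls_small(const mat& A, const vec& b, int maxit = 200) {
  const uword p = A.n_cols;
  vec x(p, fill::zeros);
  std::vector<bool> active(p, true);
  vec w = A.t() * (b - A * x);
  int it = 0;
  const double tol = 1e-12 * std::max(1.0, norm(b));
  while (it++ < maxit) {
    // most-violating inactive-set candidate
    int t = -1;
    double wmax = tol;
    for (uword j = 0; j < p; ++j)
      if (active[j] && w(j) > wmax) { wmax = w(j); t = (int)j; }
    if (t < 0) break;
    active[t] = false;
    for (;;) {
      uvec P(p);
      uword np = 0;
      for (uword j = 0; j < p; ++j) if (!active[j]) P(np++) = j;
      P.resize(np);
      vec z;
      bool ok = solve(z, A.cols(P), b, solve_opts::fast);
      if (!ok) { z = pinv(A.cols(P)) * b; }
      if (z.min() > 0) {
        x.zeros();
        x.elem(P) = z;
        break;
      }
      // step back to the boundary, move offending indices to active set
      double alpha = datum::inf;
      for (uword k = 0; k < np; ++k)
        if (z(k) <= 0) {
          double a = x(P(k)) / (x(P(k)) - z(k));
          if (a < alpha) alpha = a;
        }
      vec xp = x.elem(P);
      xp += alpha * (z - xp);
      x.zeros();
      x.elem(P) = xp;
      for (uword k = 0; k < np; ++k)
        if (x(P(k)) <= 1e-14) { active[P(k)] = true; x(P(k)) = 0; }
    }
    w = A.t() * (b - A * x);
  }
  return x;
}

// [[Rcpp::export]]
Rcpp::List grid_search_cpp(const arma::vec& y,
                           const arma::mat& KR,   // nb x nR restricted kernels
                           const arma::mat& KH,   // nb x nH hindered kernels (D_H x alpha grid, flattened)
                           const arma::vec& kUI,  // nb unimpeded kernel
                           const arma::mat& KF,   // nb x nF flow kernels
                           const arma::vec& DF,   // flow diffusivities (tie-break)
                           double wcon,           // sum-to-one row weight
                           int keep) {            // number of top candidates to return
  const uword nb = y.n_elem;
  const uword nR = KR.n_cols, nH = KH.n_cols, nF = KF.n_cols;
  const uword ncand = nR * nH * nF;
  if (keep < 1) keep = 1;
  if ((uword)keep > ncand) keep = (int)ncand;

  mat A(nb + 1, 4);
  A.row(nb).fill(wcon);
  vec baug(nb + 1);
  baug.subvec(0, nb - 1) = y;
  baug(nb) = wcon;
  A.col(2).subvec(0, nb - 1) = kUI;

  // best-first results
  std::vector<double> rss_all(ncand);
  mat frac_all(4, ncand);
  uword idx = 0;
  for (uword iR = 0; iR < nR; ++iR) {
    A.col(0).subvec(0, nb - 1) = KR.col(iR);
    for (uword iH = 0; iH < nH; ++iH) {
      A.col(1).subvec(0, nb - 1) = KH.col(iH);
      for (uword iF = 0; iF < nF; ++iF, ++idx) {
        A.col(3).subvec(0, nb - 1) = KF.col(iF);
        vec f = nnls_small(A, baug);
        double s = accu(f);
        if (s > 0) f /= s;  // exact renormalisation after the weighted constraint
        vec r = y - (f(0) * KR.col(iR) + f(1) * KH.col(iH) +
                     f(2) * kUI + f(3) * KF.col(iF));
        rss_all[idx] = dot(r, r);
        frac_all.col(idx) = f;
      }
    }
  }

  // order candidates: RSS ascending; near-ties (rel. 1e-9) prefer larger f_H
  // then lower D_F (the dominant-compartment tie-break)
  std::vector<uword> ord(ncand);
  for (uword i = 0; i < ncand; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](uword a, uword b) {
    double tol = 1e-9 * (1.0 + std::min(rss_all[a], rss_all[b]));
    if (std::abs(rss_all[a] - rss_all[b]) > tol) return rss_all[a] < rss_all[b];
    double fHa = frac_all(1, a), fHb = frac_all(1, b);
    if (fHa != fHb) return fHa > fHb;
    return DF(a % nF) < DF(b % nF);
  });

  Rcpp::IntegerMatrix top_idx(keep, 3);  // 1-based (iR, iH, iF)
  Rcpp::NumericMatrix top_frac(keep, 4);
  Rcpp::NumericVector top_rss(keep);
  for (int k = 0; k < keep; ++k) {
    uword id = ord[k];
    uword iR = id / (nH * nF);
    uword iH = (id / nF) % nH;
    uword iF = id % nF;
    top_idx(k, 0) = (int)iR + 1;
    top_idx(k, 1) = (int)iH + 1;
    top_idx(k, 2) = (int)iF + 1;
    for (int j = 0; j < 4; ++j) top_frac(k, j) = frac_all(j, id);
    top_rss[k] = rss_all[id];
  }
  double rss_max = *std::max_element(rss_all.begin(), rss_all.end());
  return Rcpp::List::create(Rcpp::Named("idx") = top_idx,
                            Rcpp::Named("fractions") = top_frac,
                            Rcpp::Named("rss") = top_rss,
                            Rcpp::Named("rss_max") = rss_max);
}

// [[Rcpp::export]]
arma::vec nnls_cpp(const arma::mat& A, const arma::vec& b) {
  return nnls_small(A, b);
}
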