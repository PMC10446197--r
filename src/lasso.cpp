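// Coordinate-descent lasso on the covariance (Gram) scale, with per-target
// network fitting and k-fold cross-validation.  The permutation test
// re-estimates every network T+1 times per subnetwork, so the whole
// target/fold/lambda loop lives here rather than in R.
//
// Objective (glmnet convention, observation weights w normalised to sum 1):
//   (1/2) * sum_i w_i (y_i - b0 - x_i' beta)^2 + lambda * ||beta||_1
// Predictors and the response are standardised internally (weighted mean 0,
// weighted population SD 1); coefficients are returned on the original scale.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Coordinate descent over a fixed decreasing lambda path, warm starts and
// an active-set strategy: full sweeps admit predictors, inner sweeps cycle
// only over the current nonzero set until convergence.
// C: correlation-scale Gram of the predictors (diag 1; zero rows for dropped
// predictors), c: correlations with the standardised response.
static void cd_path(const mat& C, const vec& c, const vec& lam,
                    mat& B, double tol, int maxit) {
  const uword p = c.n_elem;
  vec b(p, fill::zeros);
  vec Cb(p, fill::zeros);  // running C * b
  std::vector<uword> active;
  active.reserve(p);

  const double* Cp = C.memptr();  // column-major
  const double* cp = c.memptr();
  double* bp = b.memptr();
  double* Cbp = Cb.memptr();
  double g_cur = 0.0;
  auto update_one = [&](uword j) -> double {
    const double* Cj = Cp + j * p;
    const double cjj = Cj[j];
    if (cjj <= 0.0) return 0.0;
    const double rho = cp[j] - Cbp[j] + cjj * bp[j];
    const double bj = soft(rho, g_cur) / cjj;
    const double d = bj - bp[j];
    if (d != 0.0) {
      for (uword k = 0; k < p; ++k) Cbp[k] += Cj[k] * d;
      if (bp[j] == 0.0) active.push_back(j);
      bp[j] = bj;
    }
    return std::abs(d);
  };

  for (uword l = 0; l < lam.n_elem; ++l) {
    g_cur = lam(l);
    active.clear();
    for (uword j = 0; j < p; ++j) if (b(j) != 0.0) active.push_back(j);
    int it = 0;
    while (it < maxit) {
      double dmax = 0.0;  // full sweep
      for (uword j = 0; j < p; ++j) dmax = std::max(dmax, update_one(j));
      ++it;
      if (dmax < tol) break;
      while (it < maxit) {  // active-set sweeps (list may grow while looping)
        double d2 = 0.0;
        for (size_t a = 0; a < active.size(); ++a)
          d2 = std::max(d2, update_one(active[a]));
        ++it;
        if (d2 < tol) break;
      }
    }
    B.col(l) = b;
  }
}

// Weighted column means / population SDs. w must sum to 1.
static void col_stats(const mat& X, const vec& w, rowvec& m, rowvec& s) {
  m = w.t() * X;
  mat Xc = X.each_row() - m;
  s = sqrt(w.t() * square(Xc));
}

// Correlation-scale Gram for all columns; columns with SD <= eps are zeroed
// (their Gram row/col is 0, diagonal 0) and flagged in `dropped`.
static mat corr_gram(const mat& X, const vec& w, const rowvec& m,
                     const rowvec& s, uvec& dropped) {
  mat Z = X.each_row() - m;
  dropped.zeros(X.n_cols);
  for (uword j = 0; j < X.n_cols; ++j) {
    if (s(j) > 1e-12) Z.col(j) /= s(j); else { Z.col(j).zeros(); dropped(j) = 1; }
  }
  mat Zw = Z.each_col() % w;
  return Z.t() * Zw;
}

// Lasso path for one response at user-supplied lambdas (original y scale).
// Returns (p+1) x nlambda: first row intercepts, then coefficients.
// [[Rcpp::export]]
arma::mat cpp_lasso_path(const arma::mat& X, const arma::vec& y,
                         const arma::vec& w, const arma::vec& lambda,
                         double tol = 1e-8, int maxit = 1000) {
  vec wn = w / accu(w);
  rowvec m, s;
  col_stats(X, wn, m, s);
  uvec dropped;
  mat C = corr_gram(X, wn, m, s, dropped);
  double ym = dot(wn, y);
  vec yc = y - ym;
  double ys = std::sqrt(dot(wn, square(yc)));
  const uword p = X.n_cols;
  mat out(p + 1, lambda.n_elem, fill::zeros);
  if (ys <= 1e-12) { out.row(0).fill(ym); return out; }
  vec c(p, fill::zeros);
  for (uword j = 0; j < p; ++j)
    if (!dropped(j)) c(j) = dot(wn % yc, (X.col(j) - m(j)) / s(j)) / ys;
  vec lam_std = lambda / ys;  // standardised-response scale
  mat B(p, lambda.n_elem, fill::zeros);
  cd_path(C, c, lam_std, B, tol, maxit);
  for (uword l = 0; l < lambda.n_elem; ++l) {
    double b0 = ym;
    for (uword j = 0; j < p; ++j) {
      if (dropped(j)) continue;
      double beta = B(j, l) * ys / s(j);
      out(j + 1, l) = beta;
      b0 -= beta * m(j);
    }
    out(0, l) = b0;
  }
  return out;
}

struct FoldStats {
  mat C;        // Gram over training observations
  rowvec m, s;  // training means / SDs
  uvec dropped;
  vec wtrain;   // normalised training weights (0 on held-out rows)
};

// Fit a complete network over the columns of X: for every target column,
// an L1-penalised regression on all remaining columns.  rule: 0 = CV 1-SE,
// 1 = CV minimum, 2 = fixed lambda (no CV).  foldid is 1-based.
// Returns k x k coefficient matrix, rows = targets, cols = regulators.
// [[Rcpp::export]]
arma::mat cpp_fit_network(const arma::mat& X, const arma::vec& w,
                          const arma::ivec& foldid, int nfolds,
                          int nlambda, double lambda_min_ratio,
                          int rule, double fixed_lambda,
                          double tol = 1e-8, int maxit = 1000) {
  const uword n = X.n_rows, k = X.n_cols;
  vec wn = w / accu(w);
  rowvec m, s;
  col_stats(X, wn, m, s);
  uvec dropped;
  mat C = corr_gram(X, wn, m, s, dropped);

  std::vector<FoldStats> folds;
  std::vector<uvec> foldrows(nfolds);
  if (rule != 2) {
    folds.resize(nfolds);
    for (int f = 0; f < nfolds; ++f) {
      foldrows[f] = find(foldid == f + 1);
      vec wf = wn;
      for (uword i = 0; i < n; ++i) if (foldid(i) == f + 1) wf(i) = 0.0;
      wf /= accu(wf);
      col_stats(X, wf, folds[f].m, folds[f].s);
      folds[f].C = corr_gram(X, wf, folds[f].m, folds[f].s, folds[f].dropped);
      folds[f].wtrain = wf;
    }
  }

  mat coef(k, k, fill::zeros);
  uvec idx_all = regspace<uvec>(0, k - 1);

  for (uword t = 0; t < k; ++t) {
    if (dropped(t)) continue;  // constant response: all coefficients zero
    uvec idx = find(idx_all != t);
    vec c = C.submat(idx, uvec{t});
    mat Cs = C.submat(idx, idx);
    double ys = s(t);

    vec lam_std;
    if (rule == 2) {
      lam_std = vec{fixed_lambda / ys};
    } else {
      double lmax = std::max(max(abs(c)), 1e-3);
      lam_std = exp(linspace<vec>(std::log(lmax),
                                  std::log(lmax * lambda_min_ratio), nlambda));
    }
    mat B(idx.n_elem, lam_std.n_elem, fill::zeros);
    cd_path(Cs, c, lam_std, B, tol, maxit);

    uword chosen = lam_std.n_elem - 1;
    if (rule != 2) {
      // lambda path on the original response scale, shared across folds
      vec lam_orig = lam_std * ys;
      mat mse(nfolds, lam_std.n_elem, fill::zeros);
      vec wval(nfolds, fill::zeros);
      for (int f = 0; f < nfolds; ++f) {
        const FoldStats& F = folds[f];
        double ysf = F.s(t);
        const uvec& rows = foldrows[f];
        if (ysf <= 1e-12 || rows.n_elem == 0) continue;
        vec cf = F.C.submat(idx, uvec{t});
        mat Cf = F.C.submat(idx, idx);
        vec lam_f = lam_orig / ysf;
        mat Bf(idx.n_elem, lam_f.n_elem, fill::zeros);
        cd_path(Cf, cf, lam_f, Bf, tol, maxit);
        // held-out error computed on the fold-standardised scale, then
        // rescaled by ysf^2 to the original response scale
        mat Zv(rows.n_elem, idx.n_elem, fill::zeros);
        for (uword j = 0; j < idx.n_elem; ++j)
          if (!F.dropped(idx(j)))
            Zv.col(j) = (X.submat(rows, uvec{idx(j)}) - F.m(idx(j))) / F.s(idx(j));
        vec yv = (X.submat(rows, uvec{t}) - F.m(t)) / ysf;
        mat R = Zv * Bf;
        R.each_col() -= yv;
        vec wr = wn(rows);
        double wsum = accu(wr);
        for (uword l = 0; l < lam_f.n_elem; ++l)
          mse(f, l) = ysf * ysf * dot(wr, square(R.col(l))) / wsum;
        wval(f) = wsum;
      }
      vec cvm(lam_std.n_elem, fill::zeros);
      double wtot = accu(wval);
      for (uword l = 0; l < lam_std.n_elem; ++l)
        cvm(l) = (wtot > 0.0) ? dot(wval, mse.col(l)) / wtot : 0.0;
      uword lmin_i = cvm.index_min();
      if (rule == 1) {
        chosen = lmin_i;
      } else {
        double se = 0.0;
        {
          double mu = mean(mse.col(lmin_i));
          double v = 0.0;
          for (int f = 0; f < nfolds; ++f) v += std::pow(mse(f, lmin_i) - mu, 2);
          se = std::sqrt(v / std::max(1, nfolds - 1)) / std::sqrt((double)nfolds);
        }
        chosen = lmin_i;
        for (uword l = 0; l <= lmin_i; ++l)  // largest lambda within 1 SE
          if (cvm(l) <= cvm(lmin_i) + se) { chosen = l; break; }
      }
    }
    for (uword j = 0; j < idx.n_elem; ++j) {
      if (dropped(idx(j))) continue;
      coef(t, idx(j)) = B(j, chosen) * ys / s(idx(j));
    }
  }
  return coef;
}

// Per-gene medians of a matrix restricted to a row subset (used for the
// phenotype-level sample-specific regulatory effects).
// [[Rcpp::export]]
arma::rowvec cpp_col_medians(const arma::mat& E, const arma::uvec& rows) {
  mat sub = E.rows(rows);
  return median(sub, 0);
}

// Per-target penalties chosen by CV (same procedure as cpp_fit_network with
// rule 0/1) on the original response scale. Used to freeze the penalty
// before permutation re-estimation.
// [[Rcpp::export]]
arma::vec cpp_cv_lambdas(const arma::mat& X, const arma::vec& w,
                         const arma::ivec& foldid, int nfolds,
                         int nlambda, double lambda_min_ratio, int rule,
                         double tol = 1e-5, int maxit = 100) {
  const uword n = X.n_rows, k = X.n_cols;
  vec wn = w / accu(w);
  rowvec m, s;
  col_stats(X, wn, m, s);
  uvec dropped;
  mat C = corr_gram(X, wn, m, s, dropped);

  std::vector<FoldStats> folds(nfolds);
  std::vector<uvec> foldrows(nfolds);
  for (int f = 0; f < nfolds; ++f) {
    foldrows[f] = find(foldid == f + 1);
    vec wf = wn;
    for (uword i = 0; i < n; ++i) if (foldid(i) == f + 1) wf(i) = 0.0;
    wf /= accu(wf);
    col_stats(X, wf, folds[f].m, folds[f].s);
    folds[f].C = corr_gram(X, wf, folds[f].m, folds[f].s, folds[f].dropped);
    folds[f].wtrain = wf;
  }

  vec out(k, fill::zeros);
  uvec idx_all = regspace<uvec>(0, k - 1);
  for (uword t = 0; t < k; ++t) {
    if (dropped(t)) { out(t) = datum::inf; continue; }
    uvec idx = find(idx_all != t);
    vec c = C.submat(idx, uvec{t});
    double ys = s(t);
    double lmax = std::max(max(abs(c)), 1e-3);
    vec lam_std = exp(linspace<vec>(std::log(lmax),
                                    std::log(lmax * lambda_min_ratio),
                                    nlambda));
    vec lam_orig = lam_std * ys;
    mat mse(nfolds, lam_std.n_elem, fill::zeros);
    vec wval(nfolds, fill::zeros);
    for (int f = 0; f < nfolds; ++f) {
      const FoldStats& F = folds[f];
      double ysf = F.s(t);
      const uvec& rows = foldrows[f];
      if (ysf <= 1e-12 || rows.n_elem == 0) continue;
      vec cf = F.C.submat(idx, uvec{t});
      mat Cf = F.C.submat(idx, idx);
      vec lam_f = lam_orig / ysf;
      mat Bf(idx.n_elem, lam_f.n_elem, fill::zeros);
      cd_path(Cf, cf, lam_f, Bf, tol, maxit);
      mat Zv(rows.n_elem, idx.n_elem, fill::zeros);
      for (uword j = 0; j < idx.n_elem; ++j)
        if (!F.dropped(idx(j)))
          Zv.col(j) = (X.submat(rows, uvec{idx(j)}) - F.m(idx(j))) / F.s(idx(j));
      vec yv = (X.submat(rows, uvec{t}) - F.m(t)) / ysf;
      mat R = Zv * Bf;
      R.each_col() -= yv;
      vec wr = wn(rows);
      double wsum = accu(wr);
      for (uword l = 0; l < lam_f.n_elem; ++l)
        mse(f, l) = ysf * ysf * dot(wr, square(R.col(l))) / wsum;
      wval(f) = wsum;
    }
    vec cvm(lam_std.n_elem, fill::zeros);
    double wtot = accu(wval);
    for (uword l = 0; l < lam_std.n_elem; ++l)
      cvm(l) = (wtot > 0.0) ? dot(wval, mse.col(l)) / wtot : 0.0;
    uword lmin_i = cvm.index_min();
    uword chosen = lmin_i;
    if (rule == 0) {
      double mu = mean(mse.col(lmin_i)), v = 0.0;
      for (int f = 0; f < nfolds; ++f) v += std::pow(mse(f, lmin_i) - mu, 2);
      double se = std::sqrt(v / std::max(1, nfolds - 1)) /
                  std::sqrt((double)nfolds);
      for (uword l = 0; l <= lmin_i; ++l)
        if (cvm(l) <= cvm(lmin_i) + se) { chosen = l; break; }
    }
    out(t) = lam_orig(chosen);
  }
  return out;
}

// Fit one k x k network from X under observation weights w at fixed
// per-target penalties (original response scale). Shared by the
// sample-specific permutation kernel below.
static mat fit_network_fixed(const mat& X, const vec& w, const vec& lambda,
                             double tol, int maxit) {
  const uword k = X.n_cols;
  vec wn = w / accu(w);
  rowvec m, s;
  col_stats(X, wn, m, s);
  uvec dropped;
  mat C = corr_gram(X, wn, m, s, dropped);
  mat coef(k, k, fill::zeros);
  uvec idx_all = regspace<uvec>(0, k - 1);
  for (uword t = 0; t < k; ++t) {
    if (dropped(t) || !std::isfinite(lambda(t))) continue;
    uvec idx = find(idx_all != t);
    vec c = C.submat(idx, uvec{t});
    mat Cs = C.submat(idx, idx);
    double ys = s(t);
    vec lam_std = vec{lambda(t) / ys};
    mat B(idx.n_elem, 1, fill::zeros);
    cd_path(Cs, c, lam_std, B, tol, maxit);
    for (uword j = 0; j < idx.n_elem; ++j)
      if (!dropped(idx(j))) coef(t, idx(j)) = B(j, 0) * ys / s(idx(j));
  }
  return coef;
}

// Sample-specific per-gene statistics for one subnetwork and one label
// split. For each group, one network per cell line is estimated by
// kernel-weighted lasso (Gaussian kernel on the modulator, bandwidth h,
// fixed per-target penalties) from the group's cell lines only. Per-gene
// regulatory-effect vectors (coefficient times the cell line's own
// regulator expression) are aggregated by entrywise medians within the
// group; neighbourhoods (|coef| > thr, either direction) by union.
// Returns gamma_j and lambda_j for the subnetwork's genes.
// [[Rcpp::export]]
Rcpp::List cpp_ss_split_stats(const arma::mat& XA, const arma::vec& mA,
                              double hA,
                              const arma::mat& XB, const arma::vec& mB,
                              double hB,
                              const arma::vec& lambda, double thr,
                              double tol = 1e-5, int maxit = 100) {
  const uword k = XA.n_cols;

  auto group_stats = [&](const mat& X, const vec& mod, double h,
                         mat& med, umat& uni) {
    const uword n = X.n_rows;
    mat eff(n, 2 * k * k, fill::zeros);
    uni.zeros(k, k);
    for (uword a = 0; a < n; ++a) {
      vec w(n);
      if (h > 0.0) {
        for (uword i = 0; i < n; ++i) {
          double z = (mod(i) - mod(a)) / h;
          w(i) = std::exp(-0.5 * z * z);
        }
      } else {
        w.ones();
      }
      mat co = fit_network_fixed(X, w, lambda, tol, maxit);
      // effect blocks: co scaled per column by this cell line's expression
      mat M1 = co;
      for (uword j = 0; j < k; ++j) M1.col(j) *= X(a, j);
      mat blocks = join_cols(M1, M1.t());  // (2k) x k, column j = gene j
      eff.row(a) = vectorise(blocks).t();
      for (uword j = 0; j < k; ++j)
        for (uword l = 0; l < k; ++l)
          if (l != j && (std::abs(co(l, j)) > thr || std::abs(co(j, l)) > thr))
            uni(l, j) = 1;
    }
    med = reshape(median(eff, 0).t(), 2 * k, k);
  };

  mat medA, medB;
  umat uniA, uniB;
  group_stats(XA, mA, hA, medA, uniA);
  group_stats(XB, mB, hB, medB, uniB);

  vec gamma(k), lam(k);
  mat d2 = square(medA - medB);
  for (uword j = 0; j < k; ++j) {
    gamma(j) = accu(d2.col(j)) / (2.0 * k);
    double inter = 0.0, uni = 0.0;
    for (uword l = 0; l < k; ++l) {
      bool a = uniA(l, j) > 0, b = uniB(l, j) > 0;
      if (a && b) inter += 1.0;
      if (a || b) uni += 1.0;
    }
    lam(j) = (uni > 0.0) ? 1.0 - inter / uni : 0.0;
  }
  return Rcpp::List::create(Rcpp::Named("gamma") = gamma,
                            Rcpp::Named("lambda") = lam);
}
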