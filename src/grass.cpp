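// Ridge-penalized logistic regression with cross-validated tuning, and the
// permutation engine behind the GRASS pathway test.
//
// The permutation null re-runs the full fit (including tuning selection) for
// every permuted phenotype. Two structural facts make this fast:
//   (1) the design matrix and the fold assignment are fixed across
//       permutations, so one Cholesky factor per (fold, lambda) of the
//       curvature bound X'X/4 + lambda*D (D penalizes everything but the
//       intercept) is precomputed and shared; and
//   (2) the majorize-minimize update beta += (X'X/4 + lambda*D)^-1 grad is
//       linear in the gradient, so all permutations advance together as one
//       (p+1) x B matrix via level-3 BLAS.
// MM is monotone for the logistic likelihood because the Fisher weight
// mu(1-mu) never exceeds 1/4. The observed-data fit uses the same updates
// plus a Newton polish.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double MM_TOL_CV = 1e-7;    // fold fits (feed CV deviance)
static const double MM_TOL_FIT = 1e-9;   // coefficient-reporting fits

// Objective: -loglik + lambda/2 * ||beta_noint||^2 (intercept unpenalized).
static double ridge_objective(const vec &eta, const vec &y, const vec &beta,
                              double lambda) {
  double nll = 0.0;
  for (uword i = 0; i < eta.n_elem; ++i) {
    double e = eta[i];
    nll += (e > 0 ? e + std::log1p(std::exp(-e)) : std::log1p(std::exp(e)))
           - y[i] * e;
  }
  double pen = 0.0;
  for (uword j = 1; j < beta.n_elem; ++j) pen += beta[j] * beta[j];
  return nll + 0.5 * lambda * pen;
}

// Upper-triangular R with R'R = Xa'Xa/4 + lambda*D.
static mat bound_chol(const mat &Xa, double lambda) {
  mat M = (Xa.t() * Xa) / 4.0;
  for (uword j = 1; j < M.n_rows; ++j) M(j, j) += lambda;
  return chol(M);
}

// Batched MM: advance all columns of Beta (one fit per column of Y) until
// every column's step is below tol. Returns indices of columns that are
// still moving after max_iter (MM slows badly when a fit saturates and the
// Fisher weights collapse; those columns get Newton cleanup).
static uvec mm_fit_batch(const mat &Xa, const mat &Y, double lambda,
                         const mat &R, mat &Beta, int max_iter, double tol) {
  mat Eta, Mu, G, D;
  for (int it = 0; it < max_iter; ++it) {
    Eta = Xa * Beta;
    Mu = 1.0 / (1.0 + exp(-Eta));
    G = Xa.t() * (Y - Mu);
    G.rows(1, G.n_rows - 1) -= lambda * Beta.rows(1, Beta.n_rows - 1);
    D = solve(trimatu(R), solve(trimatl(R.t()), G));
    Beta += D;
    if (abs(D).max() < tol) return uvec();
  }
  mat Ad = abs(D);
  std::vector<uword> bad;
  for (uword c = 0; c < Ad.n_cols; ++c)
    if (Ad.col(c).max() >= tol) bad.push_back(c);
  return conv_to<uvec>::from(bad);
}

// Newton polish with step halving for a single fit.
static bool newton_polish(const mat &Xa, const vec &y, double lambda,
                          vec &beta, int max_iter, double tol) {
  const uword p1 = Xa.n_cols;
  for (int it = 0; it < max_iter; ++it) {
    vec eta = Xa * beta;
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec g = Xa.t() * (y - mu);
    for (uword j = 1; j < p1; ++j) g[j] -= lambda * beta[j];
    vec w = clamp(mu % (1.0 - mu), 1e-10, 0.25);
    mat H = Xa.t() * (Xa.each_col() % w);
    for (uword j = 1; j < p1; ++j) H(j, j) += lambda;
    vec d = solve(H, g, solve_opts::likely_sympd);
    double obj = ridge_objective(eta, y, beta, lambda);
    double step = 1.0;
    vec bn;
    for (int h = 0; h < 30; ++h) {
      bn = beta + step * d;
      vec etan = Xa * bn;
      if (ridge_objective(etan, y, bn, lambda) <= obj + 1e-12) break;
      step *= 0.5;
    }
    double delta = max(abs(bn - beta));
    beta = bn;
    if (delta < tol) return true;
  }
  return false;
}

// Hybrid fit: batched MM for the bulk, Newton cleanup for columns where MM
// stalls. Returns the number of genuinely non-converged fits.
static int fit_batch(const mat &Xa, const mat &Y, double lambda,
                     const mat &R, mat &Beta, int mm_max, double tol) {
  uvec bad = mm_fit_batch(Xa, Y, lambda, R, Beta, mm_max, tol);
  int fail = 0;
  for (uword i = 0; i < bad.n_elem; ++i) {
    vec b = Beta.col(bad[i]);
    if (!newton_polish(Xa, Y.col(bad[i]), lambda, b, 50, tol)) ++fail;
    Beta.col(bad[i]) = b;
  }
  return fail;
}

// Column-wise held-out binomial deviance: dev_c = 2 sum_i softplus(eta_ic) -
// y_ic eta_ic.
static rowvec test_deviance_batch(const mat &Xa, const mat &Y,
                                  const mat &Beta) {
  mat Eta = Xa * Beta;
  mat Sp = Eta;
  Sp.transform([](double e) {
    return e > 0 ? e + std::log1p(std::exp(-e)) : std::log1p(std::exp(e));
  });
  return 2.0 * (sum(Sp, 0) - sum(Y % Eta, 0));
}

struct CvPlan {
  std::vector<uvec> tr, te;
  std::vector<mat> Xtr, Xte;               // with intercept column
  std::vector<std::vector<mat>> chol_tr;   // per fold, per lambda
  mat Xfull;
  std::vector<mat> chol_full;              // per lambda
};

static CvPlan make_plan(const mat &X, const ivec &fold, const vec &lambdas) {
  CvPlan plan;
  plan.Xfull = join_horiz(ones(X.n_rows, 1), X);
  for (uword l = 0; l < lambdas.n_elem; ++l)
    plan.chol_full.push_back(bound_chol(plan.Xfull, lambdas[l]));
  int K = fold.max() + 1;
  for (int k = 0; k < K; ++k) {
    plan.tr.push_back(find(fold != k));
    plan.te.push_back(find(fold == k));
    plan.Xtr.push_back(plan.Xfull.rows(plan.tr.back()));
    plan.Xte.push_back(plan.Xfull.rows(plan.te.back()));
    std::vector<mat> ch;
    for (uword l = 0; l < lambdas.n_elem; ++l)
      ch.push_back(bound_chol(plan.Xtr.back(), lambdas[l]));
    plan.chol_tr.push_back(ch);
  }
  return plan;
}

static vec gene_gamma(const vec &beta, const ivec &gene_sizes) {
  vec g(gene_sizes.n_elem);
  uword pos = 1;
  for (uword j = 0; j < gene_sizes.n_elem; ++j) {
    double s = 0.0;
    for (int k = 0; k < gene_sizes[j]; ++k, ++pos) s += beta[pos] * beta[pos];
    g[j] = std::sqrt(s);
  }
  return g;
}

// Single-phenotype CV ridge fit (used for the observed data). The lambda
// grid must be sorted descending: CV-deviance ties resolve toward the
// stronger penalty, and fits warm-start down the path.
// [[Rcpp::export]]
Rcpp::List cpp_cv_ridge_fit(const arma::mat &X, const arma::vec &y,
                            const arma::vec &lambdas, const arma::ivec &fold,
                            int mm_max = 200) {
  CvPlan plan = make_plan(X, fold, lambdas);
  const uword L = lambdas.n_elem, p1 = X.n_cols + 1;
  vec cvdev(L, fill::zeros);
  int n_nonconv = 0;
  for (size_t k = 0; k < plan.tr.size(); ++k) {
    mat ytr = y.elem(plan.tr[k]), yte = y.elem(plan.te[k]);
    mat b(p1, 1, fill::zeros);
    for (uword l = 0; l < L; ++l) {
      n_nonconv += fit_batch(plan.Xtr[k], ytr, lambdas[l],
                             plan.chol_tr[k][l], b, mm_max, MM_TOL_CV);
      cvdev[l] += test_deviance_batch(plan.Xte[k], yte, b)[0];
    }
  }
  int best = (int)cvdev.index_min();
  mat bfull(p1, 1, fill::zeros);
  for (int l = 0; l <= best; ++l)
    fit_batch(plan.Xfull, y, lambdas[l], plan.chol_full[l], bfull,
              mm_max, l == best ? MM_TOL_FIT * 100 : 1e-4);
  vec beta = bfull.col(0);
  if (!newton_polish(plan.Xfull, y, lambdas[best], beta, 25, MM_TOL_FIT))
    ++n_nonconv;
  return Rcpp::List::create(
      Rcpp::Named("beta") = beta, Rcpp::Named("lambda_index") = best + 1,
      Rcpp::Named("cv_deviance") = cvdev,
      Rcpp::Named("n_nonconverged") = n_nonconv);
}

// Permutation engine: column b of `perms` holds 0-based subject indices;
// the whole CV + ridge pipeline is recomputed for every permuted phenotype,
// all permutations advancing in lock-step.
// [[Rcpp::export]]
Rcpp::List cpp_grass_permutations(const arma::mat &X, const arma::vec &y,
                                  const arma::ivec &gene_sizes,
                                  const arma::imat &perms,
                                  const arma::vec &lambdas,
                                  const arma::ivec &fold,
                                  int mm_max = 200) {
  CvPlan plan = make_plan(X, fold, lambdas);
  const uword B = perms.n_cols, L = lambdas.n_elem, p1 = X.n_cols + 1;
  mat Yp(y.n_elem, B);
  for (uword b = 0; b < B; ++b)
    for (uword i = 0; i < y.n_elem; ++i) Yp(i, b) = y[perms(i, b)];

  // cross-validated deviance for every (lambda, permutation)
  mat cvdev(L, B, fill::zeros);
  int n_nonconv = 0;
  for (size_t k = 0; k < plan.tr.size(); ++k) {
    mat Ytr = Yp.rows(plan.tr[k]), Yte = Yp.rows(plan.te[k]);
    mat Beta(p1, B, fill::zeros);      // warm start down the lambda path
    for (uword l = 0; l < L; ++l) {
      n_nonconv += fit_batch(plan.Xtr[k], Ytr, lambdas[l],
                             plan.chol_tr[k][l], Beta, mm_max, MM_TOL_CV);
      cvdev.row(l) += test_deviance_batch(plan.Xte[k], Yte, Beta);
      Rcpp::checkUserInterrupt();
    }
  }
  ucolvec best(B);
  for (uword b = 0; b < B; ++b) best[b] = cvdev.col(b).index_min();

  // final full-data fits, batched per selected lambda
  mat BetaFull(p1, B, fill::zeros);
  for (uword l = 0; l < L; ++l) {
    uvec cols = find(best == l);
    if (cols.is_empty()) continue;
    mat Bl(p1, cols.n_elem, fill::zeros);
    n_nonconv += fit_batch(plan.Xfull, Yp.cols(cols), lambdas[l],
                           plan.chol_full[l], Bl, mm_max, MM_TOL_FIT);
    BetaFull.cols(cols) = Bl;
    Rcpp::checkUserInterrupt();
  }

  mat gamma(B, gene_sizes.n_elem);
  ivec lambda_idx(B);
  for (uword b = 0; b < B; ++b) {
    gamma.row(b) = gene_gamma(BetaFull.col(b), gene_sizes).t();
    lambda_idx[b] = (int)best[b] + 1;
  }
  return Rcpp::List::create(Rcpp::Named("gamma") = gamma,
                            Rcpp::Named("lambda_index") = lambda_idx,
                            Rcpp::Named("n_nonconverged") = n_nonconv);
}
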