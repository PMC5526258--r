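// Compiled kernels for the three hot loops: GEE Fisher scoring with a
// moment-updated working correlation, the chained-equations draw cycle,
// and the multivariate-normal data-augmentation chain.  All random
// numbers come from R's RNG, so set.seed() on the R side governs
// reproducibility exactly as for the pure-R code paths.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// Apply a T x T matrix to every length-T cluster block of the columns of A
// (rows ordered cluster-major) in one reshape-multiply.
static arma::mat block_mult(const arma::mat& M, const arma::mat& A, int T) {
  arma::mat out(A.n_rows, A.n_cols);
  int ncl = A.n_rows / T;
  for (arma::uword j = 0; j < A.n_cols; ++j) {
    arma::mat blk(const_cast<double*>(A.colptr(j)), T, ncl, false, true);
    out.col(j) = arma::vectorise(M * blk);
  }
  return out;
}

// GEE scoring iterations for a balanced binary-outcome logit model.
// corstr: 0 = independence, 1 = exchangeable, 2 = unstructured.
// [[Rcpp::export]]
List gee_core(const arma::mat& X, const arma::vec& y, int T, int corstr,
              arma::vec beta, int maxit, double tol) {
  const int n_obs = X.n_rows, p = X.n_cols;
  const int n_cl = n_obs / T;
  bool converged = false, fallback = false;
  arma::mat Rw = arma::eye(T, T);
  int iters = 0;

  // The working correlation is re-estimated from Pearson residuals while
  // the coefficients still move materially, then frozen so the Newton
  // tail converges quadratically (a root-n-consistent beta suffices for
  // the moment estimator of the correlation).
  bool freeze = false;
  for (int it = 0; it < maxit; ++it) {
    ++iters;
    arma::vec mu = 1.0 / (1.0 + arma::exp(-(X * beta)));
    arma::vec a = arma::clamp(mu % (1.0 - mu), 1e-10, arma::datum::inf);
    arma::vec sa = arma::sqrt(a);
    arma::vec e = (y - mu) / sa;
    arma::mat E(e.memptr(), T, n_cl, false, true);
    double phi = arma::dot(e, e) / (n_obs - p);
    if (freeze) {
      // keep current Rw
    } else if (corstr == 2) {
      Rw = E * E.t() / ((n_cl - p) * phi);
      Rw.diag().ones();
      arma::vec ev;
      if (!arma::eig_sym(ev, Rw) || ev.min() < 1e-6) {
        fallback = true;
        double alpha = (arma::accu(Rw) - T) / (T * (T - 1.0));
        Rw.fill(alpha);
        Rw.diag().ones();
      }
    } else if (corstr == 1) {
      arma::rowvec s = arma::sum(E, 0);
      double alpha = (arma::dot(s, s) - arma::dot(e, e)) /
                     (T * (T - 1.0) * (n_cl - p) * phi);
      Rw.fill(alpha);
      Rw.diag().ones();
    }
    arma::mat Rinv = arma::inv_sympd(Rw);
    arma::mat Xt = X.each_col() % sa;
    arma::mat SX = block_mult(Rinv, Xt, T);
    arma::vec se_vec = arma::vectorise(Rinv * E);
    arma::mat H = Xt.t() * SX;
    arma::vec U = Xt.t() * se_vec;
    arma::vec delta = arma::solve(H, U, arma::solve_opts::likely_sympd);
    beta += delta;
    double step = arma::abs(delta).max();
    if (step < tol) { converged = true; break; }
    if (step < 1e-3) freeze = true;
  }

  // Robust (sandwich) covariance at the final coefficients.
  arma::vec mu = 1.0 / (1.0 + arma::exp(-(X * beta)));
  arma::vec a = arma::clamp(mu % (1.0 - mu), 1e-10, arma::datum::inf);
  arma::vec sa = arma::sqrt(a);
  arma::vec e = (y - mu) / sa;
  arma::mat E(e.memptr(), T, n_cl, false, true);
  arma::mat Rinv = arma::inv_sympd(Rw);
  arma::mat Xt = X.each_col() % sa;
  arma::mat SX = block_mult(Rinv, Xt, T);
  arma::mat H = Xt.t() * SX;
  arma::mat Hi = arma::inv(H);
  arma::vec se_vec = arma::vectorise(Rinv * E);
  arma::mat Es(se_vec.memptr(), T, n_cl, false, true);
  arma::mat G(n_cl, p);
  for (int j = 0; j < p; ++j) {
    arma::mat blk(const_cast<double*>(Xt.colptr(j)), T, n_cl, false, true);
    G.col(j) = arma::sum(blk % Es, 0).t();
  }
  arma::mat V = Hi * (G.t() * G) * Hi;

  return List::create(_["beta"] = beta, _["vcov"] = V, _["R"] = Rw,
                      _["converged"] = converged, _["fallback"] = fallback,
                      _["iterations"] = iters);
}

// One posterior-predictive draw from the Bayesian normal linear model of
// column `target` on the intercept plus columns `preds`, fitted on the
// rows where the target is observed; missing rows are overwritten in Z.
static void chained_draw(arma::mat& Z, const arma::uvec& obs,
                         const arma::uvec& mis, arma::uword target,
                         const arma::uvec& preds) {
  const arma::uword p = preds.n_elem + 1, n = obs.n_elem;
  arma::mat Xo(n, p);
  Xo.col(0).ones();
  Xo.cols(1, p - 1) = Z.submat(obs, preds);
  arma::vec yo = Z.col(target);
  yo = yo.elem(obs);
  arma::mat XtX = Xo.t() * Xo;
  XtX.diag() += 1e-8 * arma::trace(XtX) / p;
  arma::mat ch;
  if (!arma::chol(ch, XtX)) stop("degenerate imputation model: singular design");
  arma::vec Xty = Xo.t() * yo;
  arma::vec beta_hat = arma::solve(arma::trimatu(ch),
                       arma::solve(arma::trimatl(ch.t()), Xty));
  double rss = arma::dot(yo - Xo * beta_hat, yo - Xo * beta_hat);
  double df = static_cast<double>(n) - p;
  double sigma2 = rss / ::R::rchisq(df);
  arma::vec z(p);
  for (arma::uword j = 0; j < p; ++j) z(j) = ::R::norm_rand();
  arma::vec beta_star = beta_hat +
      std::sqrt(sigma2) * arma::solve(arma::trimatu(ch), z);
  arma::mat Xm(mis.n_elem, p);
  Xm.col(0).ones();
  Xm.cols(1, p - 1) = Z.submat(mis, preds);
  arma::vec draw = Xm * beta_star;
  for (arma::uword i = 0; i < draw.n_elem; ++i)
    draw(i) += ::R::norm_rand() * std::sqrt(sigma2);
  arma::vec col = Z.col(target);
  col.elem(mis) = draw;
  Z.col(target) = col;
}

// Run a schedule of chained-equation draws on a working matrix.
// targets/holes/preds are parallel per-variable lists (0-based indices);
// `schedule` gives the execution order as indices into those lists.
// [[Rcpp::export]]
arma::mat chained_run(arma::mat Z, IntegerVector targets, List holes,
                      List preds, IntegerVector schedule) {
  const arma::uword n = Z.n_rows;
  std::vector<arma::uvec> mis(targets.size()), obs(targets.size()),
      prd(targets.size());
  for (int v = 0; v < targets.size(); ++v) {
    mis[v] = as<arma::uvec>(holes[v]);
    prd[v] = as<arma::uvec>(preds[v]);
    arma::uvec all = arma::regspace<arma::uvec>(0, n - 1);
    std::vector<bool> ism(n, false);
    for (arma::uword k = 0; k < mis[v].n_elem; ++k) ism[mis[v](k)] = true;
    arma::uvec o(n - mis[v].n_elem);
    arma::uword kk = 0;
    for (arma::uword i = 0; i < n; ++i) if (!ism[i]) o(kk++) = i;
    obs[v] = o;
  }
  for (int s = 0; s < schedule.size(); ++s) {
    int v = schedule[s];
    chained_draw(Z, obs[v], mis[v], targets[v], prd[v]);
  }
  return Z;
}

// Inverse-Wishart(df, S) draw via the Bartlett decomposition of
// Wishart(df, inv(S)).
static arma::mat rinvwishart(double df, const arma::mat& S) {
  const int d = S.n_rows;
  arma::mat Sinv = arma::inv_sympd(S);
  arma::mat Lv = arma::chol(Sinv, "lower");
  arma::mat A(d, d, arma::fill::zeros);
  for (int i = 0; i < d; ++i) {
    A(i, i) = std::sqrt(::R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = ::R::norm_rand();
  }
  arma::mat L = Lv * A;           // W = L L' ~ Wishart(df, Sinv)
  return arma::inv_sympd(L * L.t());
}

// Data-augmentation chain for multivariate-normal imputation.  Y arrives
// with holes already initialised; pat_idx/pat_mc give, per missingness
// pattern, the row indices and missing-column indices (0-based).  Returns
// the m completed matrices saved every `thin` iterations after `burnin`.
// [[Rcpp::export]]
List mvn_da_core(arma::mat Y, List pat_idx, List pat_mc, int burnin,
                 int thin, int m) {
  const arma::uword n = Y.n_rows, d = Y.n_cols;
  const int G = pat_idx.size();
  std::vector<arma::uvec> gidx(G), gmc(G), goc(G);
  for (int g = 0; g < G; ++g) {
    gidx[g] = as<arma::uvec>(pat_idx[g]);
    gmc[g] = as<arma::uvec>(pat_mc[g]);
    std::vector<bool> ism(d, false);
    for (arma::uword k = 0; k < gmc[g].n_elem; ++k) ism[gmc[g](k)] = true;
    arma::uvec oc(d - gmc[g].n_elem);
    arma::uword kk = 0;
    for (arma::uword j = 0; j < d; ++j) if (!ism[j]) oc(kk++) = j;
    goc[g] = oc;
  }
  List out(m);
  int saved = 0, total = burnin + m * thin;
  for (int it = 1; it <= total; ++it) {
    // P-step
    arma::rowvec ybar = arma::mean(Y, 0);
    arma::mat S = Y.t() * Y - static_cast<double>(n) * (ybar.t() * ybar);
    S = arma::symmatu(S);
    arma::mat Sigma;
    bool ok = false;
    for (double jit : {0.0, 1e-8, 1e-6, 1e-4}) {
      arma::mat Sj = S + jit * arma::trace(S) / d * arma::eye(d, d);
      try {
        Sigma = rinvwishart(static_cast<double>(n) - 1.0, Sj);
        ok = true;
        break;
      } catch (...) { continue; }
    }
    if (!ok) stop("covariance draw failed to be positive-definite");
    arma::vec z(d);
    for (arma::uword j = 0; j < d; ++j) z(j) = ::R::norm_rand();
    arma::vec mu = ybar.t() +
        arma::chol(Sigma / static_cast<double>(n), "lower") * z;
    // I-step
    for (int g = 0; g < G; ++g) {
      const arma::uvec& mc = gmc[g];
      const arma::uvec& oc = goc[g];
      const arma::uvec& idx = gidx[g];
      arma::mat Soo = Sigma.submat(oc, oc);
      arma::mat Som = Sigma.submat(oc, mc);
      arma::mat B = arma::solve(Soo, Som,
                                arma::solve_opts::likely_sympd).t();
      arma::mat condC = arma::symmatu(Sigma.submat(mc, mc) - B * Som);
      arma::mat cc;
      if (!arma::chol(cc, condC)) {
        condC.diag() += 1e-10 * arma::trace(condC) / mc.n_elem;
        cc = arma::chol(condC);
      }
      arma::vec shift = mu.elem(mc) - B * mu.elem(oc);
      arma::mat cm = Y.submat(idx, oc) * B.t();
      cm.each_row() += shift.t();
      arma::mat zz(idx.n_elem, mc.n_elem);
      for (arma::uword i = 0; i < zz.n_elem; ++i) zz(i) = ::R::norm_rand();
      arma::mat draws = cm + zz * cc;
      for (arma::uword j = 0; j < mc.n_elem; ++j) {
        arma::vec col = Y.col(mc(j));
        col.elem(idx) = draws.col(j);
        Y.col(mc(j)) = col;
      }
    }
    if (it > burnin && (it - burnin) % thin == 0) out[saved++] = Y;
  }
  return out;
}
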