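// EM for the cell-type mixed-effect model y = X beta + A u + e.
// The marginal covariance V = A Sigma_u A' + sigma0^2 I is block-diagonal by
// subject (each column of A touches one subject's rows), so every E-step and
// likelihood evaluation decomposes into J small T_j x T_j problems.
//
// The plain EM map (E-step posterior moments, closed-form M-step) converges
// slowly along flat variance-component directions, so the driver wraps it in
// a squared-extrapolation (SQUAREM-type) accelerator with a monotonicity
// safeguard: an accelerated step is only accepted when its log-likelihood is
// no worse than the plain two-step EM move, hence the recorded trace is
// non-decreasing by construction.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List em_fit_cpp(const arma::vec& y, const arma::mat& X, const arma::mat& theta,
                const arma::ivec& subj, const int J,
                arma::vec beta_init, double s0_init, arma::vec sk_init,
                const double tol, const int max_iter, const double floor_var,
                const double floor_s0, const bool accelerate) {
  const int N = y.n_elem;
  const int K = theta.n_cols;
  const int P = X.n_cols;
  std::vector<arma::uvec> rows(J);
  {
    std::vector<std::vector<arma::uword>> tmp(J);
    for (int i = 0; i < N; ++i) tmp[subj[i] - 1].push_back(i);
    for (int j = 0; j < J; ++j) rows[j] = arma::uvec(tmp[j]);
  }
  // per-subject proportion blocks and Gram matrices, fixed across iterations
  std::vector<arma::mat> Th(J), ThtTh(J);
  std::vector<arma::vec> ysub(J);
  for (int j = 0; j < J; ++j) {
    Th[j] = theta.rows(rows[j]);
    ThtTh[j] = Th[j].t() * Th[j];
    ysub[j] = y.elem(rows[j]);
  }
  // least-squares via a thin QR of X: the normal equations square the
  // condition number and can break EM monotonicity on slope designs
  arma::mat Qx, Rx;
  if (!arma::qr_econ(Qx, Rx, X) ||
      arma::rank(Rx) < static_cast<arma::uword>(P)) {
    stop("rank-deficient fixed-effect design");
  }

  const double LOG2PI = std::log(2.0 * M_PI);
  const double log_floor = std::log(floor_var);
  const double log_floor_s0 = std::log(floor_s0);

  // parameter vector phi = [beta, log s0, log sk]
  auto pack = [&](const arma::vec& beta, double s0, const arma::vec& sk) {
    arma::vec phi(P + 1 + K);
    phi.head(P) = beta;
    phi(P) = std::log(s0);
    phi.tail(K) = arma::log(sk);
    return phi;
  };

  // E-step accumulators at the last evaluated parameters
  arma::mat mu(J, K, arma::fill::zeros);
  arma::vec Amu(N);
  double trASA = 0.0;
  arma::vec uku(K);
  arma::mat B, G, Sp, W2;
  arma::vec rj, vr, muj, Xb(N);
  int n_sweeps = 0;

  // log-likelihood + posterior accumulators at phi
  auto e_sweep = [&](const arma::vec& phi) -> double {
    const arma::vec beta = phi.head(P);
    const double s0 = std::exp(phi(P));
    const arma::vec sk = arma::exp(phi.tail(K));
    ++n_sweeps;
    Xb = X * beta;
    double ll = 0.0;
    trASA = 0.0;
    uku.zeros(K);
    for (int j = 0; j < J; ++j) {
      const int Tj = rows[j].n_elem;
      B = Th[j];
      B.each_row() %= sk.t();               // Th diag(sk)
      arma::mat Vj = B * Th[j].t();         // T x T marginal block
      Vj.diag() += s0;
      arma::mat ch;
      if (!arma::chol(ch, Vj)) {
        stop("marginal covariance block is singular during EM (subject %d)",
             j + 1);
      }
      rj = ysub[j] - Xb.elem(rows[j]);
      const arma::vec w = arma::solve(arma::trimatl(ch.t()), rj);
      ll += -0.5 * Tj * LOG2PI - arma::accu(arma::log(ch.diag()))
            - 0.5 * arma::dot(w, w);
      vr = arma::solve(arma::trimatu(ch), w);
      muj = sk % (Th[j].t() * vr);
      W2 = arma::solve(arma::trimatl(ch.t()), Th[j]);
      G = W2.t() * W2;                      // Th' V^-1 Th
      Sp = -(sk * sk.t()) % G;              // Sigma_p block
      Sp.diag() += sk;
      trASA += arma::accu(Sp % ThtTh[j]);
      uku += Sp.diag() + muj % muj;
      Amu.elem(rows[j]) = Th[j] * muj;
      mu.row(j) = muj.t();
    }
    return ll;
  };

  // one EM map application; returns the updated phi, stores ll(phi) in *ll
  auto em_step = [&](const arma::vec& phi, double* ll) -> arma::vec {
    *ll = e_sweep(phi);
    if (!std::isfinite(*ll)) {
      stop("non-finite marginal log-likelihood during EM");
    }
    // M-step: joint maximizer of the expected complete-data log-likelihood;
    // the residual part of E[s's] uses the updated beta.
    const arma::vec beta_new =
        arma::solve(arma::trimatu(Rx), Qx.t() * (y - Amu));
    const arma::vec res = y - X * beta_new - Amu;
    const double s0_new = std::max((trASA + arma::dot(res, res)) / N,
                                   floor_s0);
    const arma::vec sk_new = arma::clamp(uku / J, floor_var,
                                         arma::datum::inf);
    return pack(beta_new, s0_new, sk_new);
  };

  arma::vec phi = pack(beta_init, s0_init, sk_init);
  std::vector<double> trace;
  trace.reserve(max_iter + 1);
  bool converged = false;
  int n_iter = 0;

  for (int iter = 0; iter < max_iter; ++iter) {
    double ll0, ll1;
    const arma::vec phi1 = em_step(phi, &ll0);
    trace.push_back(ll0);
    n_iter = iter + 1;
    if (iter > 0 && std::fabs(ll0 - trace[iter - 1]) <
                        tol * (std::fabs(trace[iter - 1]) + 1e-8)) {
      converged = true;
      break;
    }
    if (!accelerate) {
      phi = phi1;
      continue;
    }
    const arma::vec phi2 = em_step(phi1, &ll1);
    const arma::vec r = phi1 - phi;
    const arma::vec v = (phi2 - phi1) - r;
    const double vv = arma::dot(v, v);
    if (vv < 1e-28) {
      phi = phi2;
      continue;
    }
    double alpha = -std::sqrt(arma::dot(r, r) / vv);
    if (alpha > -1.0) alpha = -1.0;
    arma::vec phi_acc = phi - 2.0 * alpha * r + (alpha * alpha) * v;
    // Trust region on the variance coordinates: extrapolating far beyond the
    // plain two-step move can collapse sigma0 to the floor while other
    // components explode, making V ill-conditioned enough that the
    // log-likelihood (and with it the monotonicity safeguard) cannot be
    // evaluated reliably.
    for (int i = P; i < P + 1 + K; ++i) {
      const double lo = phi2(i) - 4.0, hi = phi2(i) + 4.0;
      if (phi_acc(i) < lo) phi_acc(i) = lo;
      if (phi_acc(i) > hi) phi_acc(i) = hi;
      if (phi_acc(i) < (i == P ? log_floor_s0 : log_floor)) {
        phi_acc(i) = (i == P ? log_floor_s0 : log_floor);
      }
    }
    double ll_acc = -arma::datum::inf;
    arma::vec phi3;
    bool ok = true;
    try {
      phi3 = em_step(phi_acc, &ll_acc);
    } catch (...) {
      ok = false;
    }
    if (ok && std::isfinite(ll_acc) && ll_acc >= ll1) {
      phi = phi3;       // EM(phi_acc): ll >= ll_acc >= ll1 >= ll0
    } else {
      phi = phi2;       // plain double EM move
    }
  }

  // final posterior moments and log-likelihood at the returned parameters
  const double ll_final = e_sweep(phi);
  if (trace.empty() || std::fabs(ll_final - trace.back()) > 1e-12) {
    trace.push_back(ll_final);
  }

  const arma::vec beta = phi.head(P);
  const double s0 = std::exp(phi(P));
  const arma::vec sk = arma::exp(phi.tail(K));
  const bool boundary =
      (s0 <= floor_s0 * (1 + 1e-6)) || arma::any(sk <= floor_var * (1 + 1e-6));

  return List::create(
      _["beta"] = beta, _["sigma0_sq"] = s0, _["sigma_k_sq"] = sk,
      _["mu"] = mu, _["loglik"] = ll_final,
      _["loglik_trace"] = NumericVector(trace.begin(), trace.end()),
      _["converged"] = converged, _["n_iter"] = n_iter,
      _["n_sweeps"] = n_sweeps, _["boundary"] = boundary);
}
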