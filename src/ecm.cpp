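// ECM engine for Poisson NMF with held-out (missing) cells.
//
// One ECM iteration = E-step (impute held-out cells with the current model
// mean), CM1 (multiplicative update of W given H), CM2 (multiplicative
// update of H given the updated W).  With no held-out cells this reduces
// exactly to the classical generalized-KL multiplicative update algorithm.
//
// The observed-data log-likelihood (-KL over observed cells, Poisson
// constant dropped) is monitored every iteration for the stopping rule
// |l_t - l_{t-1}| / (|l_{t-1}| + 1) < tol.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double MEAN_FLOOR = 1e-12;

static inline void floor_means(mat& M) {
  double* p = M.memptr();
  const uword n = M.n_elem;
  for (uword i = 0; i < n; ++i)
    if (p[i] < MEAN_FLOOR) p[i] = MEAN_FLOOR;
}

// [[Rcpp::export(name = ".ecm_fit_cpp")]]
Rcpp::List ecm_fit_cpp(const arma::mat& V,
                       const arma::uvec& heldout,   // 0-based linear indices
                       arma::mat W, arma::mat H,
                       double tol, int max_iter) {
  const uword P = V.n_rows, N = V.n_cols;
  // observed = complement of heldout
  uvec obs;
  if (heldout.n_elem == 0) {
    obs = regspace<uvec>(0, P * N - 1);
  } else {
    uvec is_held(P * N, fill::zeros);
    is_held.elem(heldout).ones();
    obs = find(is_held == 0);
  }

  // constant part of -KL: sum over observed cells of (v - v log v)
  const vec vobs = V.elem(obs);
  double Cv = 0.0;
  for (uword i = 0; i < vobs.n_elem; ++i)
    Cv += (vobs[i] > 0.0) ? vobs[i] - vobs[i] * std::log(vobs[i]) : 0.0;

  mat Vstar = V;
  mat M(P, N), R(P, N);
  vec mobs(obs.n_elem), logm(obs.n_elem);

  M = W * H;
  floor_means(M);

  std::vector<double> trace;
  trace.reserve(256);
  double ll_prev = -datum::inf, ll = -datum::inf;
  bool converged = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    // E-step: impute held-out cells with the current model mean
    if (heldout.n_elem > 0) Vstar.elem(heldout) = M.elem(heldout);

    // CM1: W update (given H)
    R = Vstar / M;
    vec hsum = sum(H, 1);               // r x 1, Sum_n h_jn
    hsum.transform([](double x) { return std::max(x, MEAN_FLOOR); });
    W = W % (R * H.t());
    W.each_row() /= hsum.t();

    // CM2: H update (given updated W)
    M = W * H;
    floor_means(M);
    R = Vstar / M;
    rowvec wsum = sum(W, 0);            // 1 x r, Sum_p w_pj
    wsum.transform([](double x) { return std::max(x, MEAN_FLOOR); });
    H = H % (W.t() * R);
    H.each_col() /= wsum.t();

    M = W * H;
    floor_means(M);

    // observed-data log-likelihood: dot(v, log m) - sum(m) + Cv
    mobs = M.elem(obs);
    logm = log(mobs);
    ll = dot(vobs, logm) - accu(mobs) + Cv;
    trace.push_back(ll);
    if (!std::isfinite(ll)) {
      return Rcpp::List::create(
        Rcpp::Named("W") = W, Rcpp::Named("H") = H,
        Rcpp::Named("observed_loglik") = ll,
        Rcpp::Named("n_iterations") = iter,
        Rcpp::Named("converged") = false,
        Rcpp::Named("failed") = true,
        Rcpp::Named("loglik_trace") = trace);
    }
    if (iter > 1 && std::fabs(ll - ll_prev) / (std::fabs(ll_prev) + 1.0) < tol) {
      converged = true;
      break;
    }
    ll_prev = ll;
  }
  if (iter > max_iter) iter = max_iter;

  return Rcpp::List::create(
    Rcpp::Named("W") = W, Rcpp::Named("H") = H,
    Rcpp::Named("observed_loglik") = ll,
    Rcpp::Named("n_iterations") = iter,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("failed") = false,
    Rcpp::Named("loglik_trace") = trace);
}

// Generalized KL divergence over a cell subset (0-based linear indices;
// empty subset means all cells).  Mirrors the R-level kl_divergence() and
// is used by the fitting path.
// [[Rcpp::export(name = ".kl_cells_cpp")]]
double kl_cells_cpp(const arma::mat& V, const arma::mat& M,
                    const arma::uvec& cells, bool all_cells) {
  uvec idx = all_cells ? regspace<uvec>(0, V.n_elem - 1) : cells;
  double d = 0.0;
  for (uword i = 0; i < idx.n_elem; ++i) {
    const double v = V[idx[i]];
    const double m = std::max(M[idx[i]], MEAN_FLOOR);
    d += (v > 0.0) ? v * std::log(v / m) + m - v : m;
  }
  return d;
}
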