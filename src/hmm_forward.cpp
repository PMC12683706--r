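// Scaled forward recursion for the 3-state movement HMM with
// multinomial-logit transition probabilities driven by log(HRI).
// Emissions: gamma step lengths (mean/SD parameterization) x von Mises
// turns; missing turns contribute the length-only density. Compiled for
// speed: the likelihood is evaluated thousands of times across restarts.

#include <Rcpp.h>
using namespace Rcpp;

static const int NS = 3;

// log I0(kappa): exponentially scaled Bessel for moderate kappa, and the
// uniform asymptotic expansion for large kappa (bessel_i's running time
// grows with its argument, which would stall the optimizer when kappa
// drifts large)
static inline double log_i0(double kappa) {
  if (kappa < 50.0)
    return std::log(R::bessel_i(kappa, 0.0, 2.0)) + kappa;
  double ik = 1.0 / kappa;
  return kappa - 0.5 * std::log(2.0 * M_PI * kappa) +
    std::log1p(ik / 8.0 + 9.0 * ik * ik / 128.0);
}

static inline double vm_logdens(double x, double mu, double kappa) {
  return kappa * std::cos(x - mu) - std::log(2.0 * M_PI) - log_i0(kappa);
}

// fill row-stochastic Gamma(loghri); eta_ij = alpha_ij + beta_ij*loghri
// off-diagonal, diagonal reference 0; overflow-guarded softmax
static void fill_trans(double loghri, const NumericMatrix& alpha,
                       const NumericMatrix& beta, double G[NS][NS]) {
  for (int i = 0; i < NS; ++i) {
    double eta[NS], mx = 0.0;
    for (int j = 0; j < NS; ++j) {
      eta[j] = (i == j) ? 0.0 : alpha(i, j) + beta(i, j) * loghri;
      if (eta[j] > mx) mx = eta[j];
    }
    double s = 0.0;
    for (int j = 0; j < NS; ++j) { G[i][j] = std::exp(eta[j] - mx); s += G[i][j]; }
    for (int j = 0; j < NS; ++j) G[i][j] /= s;
  }
}

// stationary distribution of G via 3x3 Gaussian elimination on
// (I - G')pi = 0 with the normalization row; uniform fallback
static void stationary(const double G[NS][NS], double pi[NS]) {
  double A[NS][NS + 1];
  for (int i = 0; i < NS; ++i) {
    for (int j = 0; j < NS; ++j)
      A[i][j] = ((i == j) ? 1.0 : 0.0) - G[j][i];
    A[i][NS] = 0.0;
  }
  for (int j = 0; j < NS; ++j) A[NS - 1][j] = 1.0;
  A[NS - 1][NS] = 1.0;
  for (int c = 0; c < NS; ++c) {
    int piv = c;
    for (int r = c + 1; r < NS; ++r)
      if (std::fabs(A[r][c]) > std::fabs(A[piv][c])) piv = r;
    if (std::fabs(A[piv][c]) < 1e-12) { for (int k = 0; k < NS; ++k) pi[k] = 1.0 / NS; return; }
    if (piv != c) for (int k = c; k <= NS; ++k) std::swap(A[piv][k], A[c][k]);
    for (int r = 0; r < NS; ++r) {
      if (r == c) continue;
      double f = A[r][c] / A[c][c];
      for (int k = c; k <= NS; ++k) A[r][k] -= f * A[c][k];
    }
  }
  double s = 0.0;
  for (int k = 0; k < NS; ++k) { pi[k] = A[k][NS] / A[k][k]; if (pi[k] < 0) pi[k] = 0; s += pi[k]; }
  if (s <= 0) { for (int k = 0; k < NS; ++k) pi[k] = 1.0 / NS; }
  else for (int k = 0; k < NS; ++k) pi[k] /= s;
}

// [[Rcpp::export]]
double hmm_forward_nll_cpp(NumericVector sl, NumericVector turn,
                           NumericVector loghri, IntegerVector track,
                           NumericVector mean_, NumericVector sd_,
                           NumericVector vmu, NumericVector vkappa,
                           NumericMatrix alpha, NumericMatrix beta) {
  const int T = sl.size();
  // hoist per-state emission constants: gamma log-density is
  // (shape-1) log x - x/scale - [shape log scale + lgamma(shape)],
  // von Mises is kappa cos(x - mu) - [log 2pi + log I0(kappa)]
  double shape[NS], inv_scale[NS], gconst[NS], vconst[NS];
  for (int j = 0; j < NS; ++j) {
    if (mean_[j] <= 0 || sd_[j] <= 0 || vkappa[j] < 0) return 1e10;
    shape[j] = (mean_[j] / sd_[j]) * (mean_[j] / sd_[j]);
    double scale = sd_[j] * sd_[j] / mean_[j];
    inv_scale[j] = 1.0 / scale;
    gconst[j] = shape[j] * std::log(scale) + std::lgamma(shape[j]);
    vconst[j] = std::log(2.0 * M_PI) + log_i0(vkappa[j]);
  }
  double ll = 0.0;
  double phi[NS];
  double G[NS][NS];
  for (int t = 0; t < T; ++t) {
    // emission log-densities at step t
    double ld[NS], mx = -INFINITY;
    bool has_sl = R_finite(sl[t]) && sl[t] > 0;
    bool has_turn = R_finite(turn[t]);
    double lsl = has_sl ? std::log(sl[t]) : 0.0;
    double lh = R_finite(loghri[t]) ? loghri[t] : 0.0;
    for (int j = 0; j < NS; ++j) {
      double d = 0.0;
      if (has_sl)
        d += (shape[j] - 1.0) * lsl - sl[t] * inv_scale[j] - gconst[j];
      if (has_turn)
        d += vkappa[j] * std::cos(turn[t] - vmu[j]) - vconst[j];
      ld[j] = d;
      if (d > mx) mx = d;
    }
    if (!R_finite(mx)) mx = 0.0;
    bool newtrack = (t == 0) || (track[t] != track[t - 1]);
    double v[NS], s = 0.0;
    if (newtrack) {
      fill_trans(lh, alpha, beta, G);
      double pi0[NS];
      stationary(G, pi0);
      for (int j = 0; j < NS; ++j) { v[j] = pi0[j] * std::exp(ld[j] - mx); s += v[j]; }
    } else {
      fill_trans(lh, alpha, beta, G);
      for (int j = 0; j < NS; ++j) {
        double a = 0.0;
        for (int i = 0; i < NS; ++i) a += phi[i] * G[i][j];
        v[j] = a * std::exp(ld[j] - mx);
        s += v[j];
      }
    }
    if (!(s > 0.0) || !R_finite(s)) return 1e10;
    ll += std::log(s) + mx;
    for (int j = 0; j < NS; ++j) phi[j] = v[j] / s;
  }
  return -ll;
}
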