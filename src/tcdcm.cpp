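// Hot numerical kernels: frequency-domain transfer functions of the
// linearized model (one complex 64x64 solve per frequency) and the
// Euler-Maruyama time-domain integrator with delay buffers.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// H(w) = Cmat (i w I - A(w))^{-1} B with A(w) = A0 + e^{-iwd1} A1 + e^{-iwd8} A8.
// freqs in Hz; dynamics in 1/ms, so w = 2 pi f / 1000 rad/ms and the phase
// factors use the delays in ms. Returns a cube (2 x ncol(B) x nfreq).
// [[Rcpp::export]]
arma::cx_cube cpp_transfer(const arma::mat& A0, const arma::mat& A1,
                           const arma::mat& A8, const arma::mat& B,
                           const arma::mat& Cmat, const arma::vec& freqs,
                           double d1, double d8) {
  const arma::uword n = A0.n_rows, nf = freqs.n_elem, ns = B.n_cols,
                    no = Cmat.n_rows;
  arma::cx_mat cA0(A0, arma::zeros(n, n));
  arma::cx_mat cA1(A1, arma::zeros(n, n));
  arma::cx_mat cA8(A8, arma::zeros(n, n));
  arma::cx_mat cB(B, arma::zeros(n, ns));
  arma::cx_mat cC(Cmat, arma::zeros(no, n));
  arma::cx_cube H(no, ns, nf);
  const std::complex<double> I(0.0, 1.0);
  for (arma::uword k = 0; k < nf; ++k) {
    double w = 2.0 * arma::datum::pi * freqs(k) / 1000.0;
    arma::cx_mat Aw = cA0 + std::exp(-I * w * d1) * cA1 +
                      std::exp(-I * w * d8) * cA8;
    arma::cx_mat M = I * w * arma::cx_mat(arma::eye(n, n),
                                          arma::zeros(n, n)) - Aw;
    arma::cx_mat X;
    if (!arma::solve(X, M, cB)) {
      stop("singular frequency-domain system at %f Hz", freqs(k));
    }
    H.slice(k) = cC * X;
  }
  return H;
}

static inline double sigm(double v, double rho1, double rho2) {
  return 1.0 / (1.0 + std::exp(-rho1 * (v - rho2))) -
         1.0 / (1.0 + std::exp(rho1 * rho2));
}

// Euler integration of the nonlinear 64-state model with fixed
// transmission delays (lag1/lag8 steps on the firing-rate history) and a
// caller-supplied innovation series (2 x n_steps, already scaled) added to
// the AMPA afferents of SS and RL of each node.
// [[Rcpp::export]]
List cpp_integrate(const arma::mat& WA1, const arma::mat& WA8,
                   const arma::mat& WN1, const arma::mat& WN8,
                   const arma::mat& WG1, const arma::mat& WG8,
                   const arma::mat& kappa, const arma::mat& Cmat,
                   const arma::vec& x0, List constants,
                   double drive, double dt, int n_steps,
                   const arma::mat& u, const arma::ivec& noise_rows,
                   int lag1, int lag8, int thin, bool keep_states) {
  const double V_L = constants["V_L"], V_A = constants["V_AMPA"],
               V_N = constants["V_NMDA"], V_G = constants["V_GABA"],
               mg_a = constants["mg_alpha"], rho1 = constants["rho1"],
               rho2 = constants["rho2"], Cm = constants["C"],
               g_L = constants["g_L"], g_scale = constants["g_scale"];
  const int npop = 16;
  arma::vec x = x0;
  const int maxlag = std::max(lag1, lag8);
  // rate history ring buffer (column t mod (maxlag+1))
  arma::mat hist(npop, maxlag + 1);
  arma::vec r0(npop);
  for (int i = 0; i < npop; ++i) r0(i) = sigm(x(i) - V_L, rho1, rho2);
  hist.each_col() = r0;

  arma::mat obs(2, n_steps);
  int n_keep = keep_states ? (n_steps / thin) : 0;
  arma::mat traj(keep_states ? 64 : 1, std::max(n_keep, 1));

  for (int t = 0; t < n_steps; ++t) {
    int cur = t % (maxlag + 1);
    // record the rate at time t before reading lagged slots, so slot
    // (t - lag) mod (maxlag+1) always holds the rate at time t - lag
    for (int i = 0; i < npop; ++i) hist(i, cur) = sigm(x(i) - V_L, rho1, rho2);
    int i1 = (t - lag1 + 10 * (maxlag + 1)) % (maxlag + 1);
    int i8 = (t - lag8 + 10 * (maxlag + 1)) % (maxlag + 1);
    arma::vec r1 = hist.col(i1), r8 = hist.col(i8);
    arma::vec affA = g_scale * (WA1 * r1 + WA8 * r8);
    arma::vec affN = g_scale * (WN1 * r1 + WN8 * r8);
    arma::vec affG = g_scale * (WG1 * r1 + WG8 * r8);
    affA += drive;
    // innovations: one stream per node enters both SS and RL of that node
    for (arma::uword k = 0; k < noise_rows.n_elem; ++k) {
      int row = noise_rows(k) - 1;  // 1-based from R
      affA(row) += u((row < 8) ? 0 : 1, t);
    }
    for (int i = 0; i < npop; ++i) {
      if (affA(i) < 0) affA(i) = 0;
      if (affN(i) < 0) affN(i) = 0;
      if (affG(i) < 0) affG(i) = 0;
    }
    arma::vec V = x.subvec(0, 15), gA = x.subvec(16, 31),
              gN = x.subvec(32, 47), gG = x.subvec(48, 63);
    arma::vec m = 1.0 / (1.0 + 0.2 * arma::exp(-mg_a * V));
    arma::vec dV = (g_L * (V_L - V) + gA % (V_A - V) +
                    gN % m % (V_N - V) + gG % (V_G - V)) / Cm;
    x.subvec(0, 15) += dt * dV;
    x.subvec(16, 31) += dt * (kappa.col(0) % (affA - gA));
    x.subvec(32, 47) += dt * (kappa.col(1) % (affN - gN));
    x.subvec(48, 63) += dt * (kappa.col(2) % (affG - gG));
    if (arma::abs(x.subvec(0, 15)).max() > 500.0) {
      stop("numerical blow-up: |V| exceeded 500 mV at step %d", t + 1);
    }
    obs.col(t) = Cmat * x;
    if (keep_states && (t % thin == 0) && (t / thin) < n_keep) {
      traj.col(t / thin) = x;
    }
  }
  return List::create(_["obs"] = obs, _["state"] = x,
                      _["traj"] = keep_states ? wrap(traj) : R_NilValue);
}
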