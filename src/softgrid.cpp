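// Soft polar grid geodesic convolution: forward and backward passes.
//
// A layer maps per-member inputs (gathered over each patch) through a set of
// B learnable 2-D Gaussian kernels on (rho, theta), applies a linear filter,
// takes the maximum over a set of angular rotation offsets, and applies ReLU.
// The backward pass returns gradients for the filter weights, biases, kernel
// parameters (mu_rho, sigma_rho, mu_theta, sigma_theta) and the gathered
// member inputs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double wrap_angle(double x) {
  // map to (-pi, pi] (avoids fmod: glibc < 2.38 lacks its C23 symbol)
  const double twopi = 2.0 * M_PI;
  x -= twopi * std::floor(x / twopi);
  if (x > M_PI) x -= twopi;
  return x;
}

// scatter-add member gradients back to per-vertex rows;
// members: 1-based vertex index per (v, k) row of grad_Hm
// [[Rcpp::export]]
arma::mat scatter_rows_cpp(const arma::mat& grad_Hm, const arma::ivec& members,
                           const int nv) {
  const int C = grad_Hm.n_cols;
  arma::mat out(nv, C, arma::fill::zeros);
  for (arma::uword r = 0; r < grad_Hm.n_rows; ++r) {
    const int v = members[r] - 1;
    for (int c = 0; c < C; ++c) out(v, c) += grad_Hm(r, c);
  }
  return out;
}

// Hm: (V*K) x Cin, row index = (v * K + k), padded rows ignored via mask.
// mask, rho, theta: V x K. Kernel parameter vectors have length B.
// W: Cout x (B*Cin) with flat column index b + B*c. offsets: length R (radians).
// [[Rcpp::export]]
List sg_forward_cpp(const arma::mat& Hm, const arma::mat& mask,
                    const arma::mat& rho, const arma::mat& theta,
                    const arma::vec& mu_rho, const arma::vec& sig_rho,
                    const arma::vec& mu_the, const arma::vec& sig_the,
                    const arma::mat& W, const arma::vec& bias,
                    const arma::vec& offsets) {
  const int V = mask.n_rows, K = mask.n_cols;
  const int B = mu_rho.n_elem;
  const int Cin = Hm.n_cols;
  const int Cout = W.n_rows;
  const int R = offsets.n_elem;
  const double eps = 1e-8;

  arma::cube A(V, B * Cin, R, arma::fill::zeros);
  arma::cube denom(V, B, R, arma::fill::zeros);
  arma::mat Z(V, Cout);
  Z.fill(-arma::datum::inf);
  arma::imat amax(V, Cout, arma::fill::zeros);

  std::vector<double> sr2(B), st2(B);
  for (int b = 0; b < B; ++b) {
    sr2[b] = sig_rho[b] * sig_rho[b];
    st2[b] = sig_the[b] * sig_the[b];
  }

  std::vector<double> wsum(B), acc(B * Cin);
  for (int r = 0; r < R; ++r) {
    const double off = offsets[r];
    for (int v = 0; v < V; ++v) {
      std::fill(wsum.begin(), wsum.end(), 0.0);
      std::fill(acc.begin(), acc.end(), 0.0);
      for (int k = 0; k < K; ++k) {
        if (mask(v, k) == 0.0) continue;
        const double rh = rho(v, k);
        const double th = theta(v, k) + off;
        const int row = v * K + k;
        for (int b = 0; b < B; ++b) {
          const double dr = rh - mu_rho[b];
          const double dt = wrap_angle(th - mu_the[b]);
          const double e = std::exp(-(dr * dr) / (2.0 * sr2[b])
                                    - (dt * dt) / (2.0 * st2[b]));
          wsum[b] += e;
          for (int c = 0; c < Cin; ++c) acc[b + B * c] += e * Hm(row, c);
        }
      }
      for (int b = 0; b < B; ++b) {
        const double d = wsum[b] + eps;
        denom(v, b, r) = d;
        for (int c = 0; c < Cin; ++c) A(v, b + B * c, r) = acc[b + B * c] / d;
      }
    }
    arma::mat Zr = A.slice(r) * W.t();
    Zr.each_row() += bias.t();
    for (int v = 0; v < V; ++v)
      for (int co = 0; co < Cout; ++co)
        if (Zr(v, co) > Z(v, co)) { Z(v, co) = Zr(v, co); amax(v, co) = r; }
  }

  arma::mat out = arma::clamp(Z, 0.0, arma::datum::inf);
  return List::create(_["out"] = out, _["Z"] = Z, _["amax"] = amax,
                      _["A"] = A, _["denom"] = denom);
}

// [[Rcpp::export]]
List sg_backward_cpp(const arma::mat& grad_out,
                     const arma::mat& Hm, const arma::mat& mask,
                     const arma::mat& rho, const arma::mat& theta,
                     const arma::vec& mu_rho, const arma::vec& sig_rho,
                     const arma::vec& mu_the, const arma::vec& sig_the,
                     const arma::mat& W, const arma::vec& offsets,
                     const arma::mat& Z, const arma::imat& amax,
                     const arma::cube& A, const arma::cube& denom,
                     const bool need_grad_input) {
  const int V = mask.n_rows, K = mask.n_cols;
  const int B = mu_rho.n_elem;
  const int Cin = Hm.n_cols;
  const int Cout = W.n_rows;
  const int R = offsets.n_elem;

  arma::mat G = grad_out;
  for (int v = 0; v < V; ++v)
    for (int co = 0; co < Cout; ++co)
      if (Z(v, co) <= 0.0) G(v, co) = 0.0;

  arma::mat grad_W(Cout, B * Cin, arma::fill::zeros);
  arma::vec grad_b(Cout, arma::fill::zeros);
  arma::cube grad_A(V, B * Cin, R, arma::fill::zeros);

  for (int v = 0; v < V; ++v) {
    for (int co = 0; co < Cout; ++co) {
      const double g = G(v, co);
      if (g == 0.0) continue;
      grad_b[co] += g;
      const int r = amax(v, co);
      for (int j = 0; j < B * Cin; ++j) {
        grad_W(co, j) += g * A(v, j, r);
        grad_A(v, j, r) += g * W(co, j);
      }
    }
  }

  arma::vec g_mu_rho(B, arma::fill::zeros), g_sig_rho(B, arma::fill::zeros);
  arma::vec g_mu_the(B, arma::fill::zeros), g_sig_the(B, arma::fill::zeros);
  arma::mat grad_Hm;
  if (need_grad_input) grad_Hm.zeros(V * K, Cin);

  std::vector<double> sr2(B), st2(B);
  for (int b = 0; b < B; ++b) {
    sr2[b] = sig_rho[b] * sig_rho[b];
    st2[b] = sig_the[b] * sig_the[b];
  }

  for (int r = 0; r < R; ++r) {
    // skip rotations that received no gradient
    if (arma::accu(arma::abs(grad_A.slice(r))) == 0.0) continue;
    const double off = offsets[r];
    for (int v = 0; v < V; ++v) {
      bool any = false;
      for (int j = 0; j < B * Cin && !any; ++j)
        if (grad_A(v, j, r) != 0.0) any = true;
      if (!any) continue;
      for (int k = 0; k < K; ++k) {
        if (mask(v, k) == 0.0) continue;
        const double rh = rho(v, k);
        const double th = theta(v, k) + off;
        const int row = v * K + k;
        for (int b = 0; b < B; ++b) {
          const double dr = rh - mu_rho[b];
          const double dt = wrap_angle(th - mu_the[b]);
          const double e = std::exp(-(dr * dr) / (2.0 * sr2[b])
                                    - (dt * dt) / (2.0 * st2[b]));
          const double d = denom(v, b, r);
          double gw = 0.0; // dL/dw for this member/bin (w = e)
          for (int c = 0; c < Cin; ++c) {
            const double gA = grad_A(v, b + B * c, r);
            if (gA == 0.0) continue;
            gw += gA * (Hm(row, c) - A(v, b + B * c, r)) / d;
            if (need_grad_input) grad_Hm(row, c) += gA * e / d;
          }
          if (gw != 0.0) {
            const double ge = gw * e;
            g_mu_rho[b] += ge * dr / sr2[b];
            g_sig_rho[b] += ge * dr * dr / (sr2[b] * sig_rho[b]);
            g_mu_the[b] += ge * dt / st2[b];
            g_sig_the[b] += ge * dt * dt / (st2[b] * sig_the[b]);
          }
        }
      }
    }
  }

  return List::create(_["grad_W"] = grad_W, _["grad_b"] = grad_b,
                      _["grad_mu_rho"] = g_mu_rho, _["grad_sig_rho"] = g_sig_rho,
                      _["grad_mu_the"] = g_mu_the, _["grad_sig_the"] = g_sig_the,
                      _["grad_Hm"] = grad_Hm);
}
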