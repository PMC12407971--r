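#include <Rcpp.h>
using namespace Rcpp;

// Logistic firing-rate function
static inline double sigm(double v, double zmax, double r, double vth) {
  return zmax / (1.0 + std::exp(r * (vth - v)));
}

// Euler-Maruyama integration of the coupled two-subpopulation Jansen-Rit
// network with inhibitory synaptic plasticity (ISP).
//
// State per node and subpopulation: x0,x1,x2 (PSPs, mV), y0,y1,y2 (mV/s)
// plus one plasticity gain C4 per subpopulation. All derivatives are
// evaluated on the pre-step state (simultaneous explicit update); noise is
// drawn from the R RNG so that set.seed() in R gives bit-identical runs.
//
// noise_mode: 0 = per-step i.i.d. background input p ~ N(p_mean, p_sd),
//             1 = diffusion, A*a*p_sd*sqrt(dt)*N(0,1) added to the y1 update.
//
// Output series are block-averaged over `decim` consecutive steps (boxcar
// anti-aliasing) after discarding the first `discard_steps` steps.
// [[Rcpp::export]]
List jr_simulate_cpp(NumericMatrix M,
                     double r_alpha, double K,
                     double C1, double C2, double C3,
                     double c4_init,
                     double A_alpha, double a_alpha, double B_alpha, double b_alpha,
                     double A_gamma, double a_gamma, double B_gamma, double b_gamma,
                     double zmax, double rs, double vth,
                     double p_mean, double p_sd, int noise_mode,
                     bool isp, double rho, double tau, double beta,
                     double c4_min, double Cscale,
                     double dt, int n_steps, int discard_steps, int decim) {
  const int N = M.nrow();
  if (M.ncol() != N) stop("connectivity matrix must be square");
  const int n_keep = n_steps - discard_steps;
  if (n_keep <= 0) stop("t_discard must be smaller than t_sim");
  const int n_out = n_keep / decim;
  if (n_out < 1) stop("retained window shorter than one output sample");

  // state arrays: [subpop][var][node]; subpop 0 = alpha, 1 = gamma
  std::vector<std::vector<double>> x0(2, std::vector<double>(N, 0.0)), x1 = x0,
      x2 = x0, y0 = x0, y1 = x0, y2 = x0, C4(2, std::vector<double>(N, c4_init));
  const double A[2] = {A_alpha, A_gamma}, a[2] = {a_alpha, a_gamma};
  const double B[2] = {B_alpha, B_gamma}, b[2] = {b_alpha, b_gamma};

  NumericMatrix out_eeg(n_out, N), out_rate(n_out, N), out_x0(n_out, N),
      out_c4a(n_out, N), out_c4g(n_out, N);
  std::vector<double> acc_eeg(N), acc_rate(N), acc_x0(N), acc_c4a(N), acc_c4g(N);
  int acc_n = 0, out_i = 0;

  std::vector<double> vcomb(N), net(N), dy0v(N), dy1v(N), dy2v(N);
  const double sqdt = std::sqrt(dt);
  RNGScope scope;

  for (int step = 0; step < n_steps; ++step) {
    // combined pyramidal PSP and coupling drive (pre-step state)
    for (int i = 0; i < N; ++i)
      vcomb[i] = r_alpha * (x1[0][i] - x2[0][i]) +
                 (1.0 - r_alpha) * (x1[1][i] - x2[1][i]);
    if (K != 0.0) {
      for (int i = 0; i < N; ++i) {
        double acc = 0.0;
        for (int j = 0; j < N; ++j)
          if (j != i && M(i, j) != 0.0)
            acc += M(i, j) * sigm(vcomb[j], zmax, rs, vth);
        net[i] = K * Cscale * acc;
      }
    } else {
      std::fill(net.begin(), net.end(), 0.0);
    }

    for (int s = 0; s < 2; ++s) {
      const double As = A[s], as = a[s], Bs = B[s], bs = b[s];
      for (int i = 0; i < N; ++i) {
        const double v = x1[s][i] - x2[s][i];
        const double spyr = sigm(v, zmax, rs, vth);
        const double sinh_ = sigm(C3 * x0[s][i], zmax, rs, vth);
        double pt = p_mean;
        if (noise_mode == 0 && p_sd > 0.0) pt += p_sd * norm_rand();
        dy0v[i] = As * as * spyr - 2.0 * as * y0[s][i] - as * as * x0[s][i];
        dy1v[i] = As * as * (pt + C2 * sigm(C1 * x0[s][i], zmax, rs, vth) + net[i]) -
                  2.0 * as * y1[s][i] - as * as * x1[s][i];
        dy2v[i] = Bs * bs * C4[s][i] * sinh_ - 2.0 * bs * y2[s][i] -
                  bs * bs * x2[s][i];
        if (isp) {
          double g = (C4[s][i] - c4_min) / Cscale;
          if (g < 0.0) g = 0.0;
          const double soft = (beta == 1.0) ? g : std::pow(g, beta);
          C4[s][i] += dt * (1.0 / tau) * sinh_ * (spyr - rho) * soft;
          if (C4[s][i] < c4_min) C4[s][i] = c4_min;
        }
      }
      for (int i = 0; i < N; ++i) {
        x0[s][i] += dt * y0[s][i];
        x1[s][i] += dt * y1[s][i];
        x2[s][i] += dt * y2[s][i];
        y0[s][i] += dt * dy0v[i];
        double dn = 0.0;
        if (noise_mode == 1 && p_sd > 0.0)
          dn = As * as * p_sd * sqdt * norm_rand();
        y1[s][i] += dt * dy1v[i] + dn;
        y2[s][i] += dt * dy2v[i];
      }
    }

    if (step % 1000 == 999) {
      for (int i = 0; i < N; ++i)
        if (!std::isfinite(x1[0][i]) || !std::isfinite(x1[1][i]) ||
            std::fabs(x1[0][i]) > 1e9 || std::fabs(x1[1][i]) > 1e9)
          stop("simulation diverged (non-finite state) at t = %f s, node %d",
               (step + 1) * dt, i + 1);
    }

    if (step >= discard_steps && out_i < n_out) {
      for (int i = 0; i < N; ++i) {
        const double va = x1[0][i] - x2[0][i], vg = x1[1][i] - x2[1][i];
        acc_eeg[i] += r_alpha * va + (1.0 - r_alpha) * vg;
        acc_rate[i] += r_alpha * sigm(va, zmax, rs, vth) +
                       (1.0 - r_alpha) * sigm(vg, zmax, rs, vth);
        acc_x0[i] += r_alpha * x0[0][i] + (1.0 - r_alpha) * x0[1][i];
        acc_c4a[i] += C4[0][i];
        acc_c4g[i] += C4[1][i];
      }
      if (++acc_n == decim) {
        for (int i = 0; i < N; ++i) {
          out_eeg(out_i, i) = acc_eeg[i] / decim;
          out_rate(out_i, i) = acc_rate[i] / decim;
          out_x0(out_i, i) = acc_x0[i] / decim;
          out_c4a(out_i, i) = acc_c4a[i] / decim;
          out_c4g(out_i, i) = acc_c4g[i] / decim;
          acc_eeg[i] = acc_rate[i] = acc_x0[i] = acc_c4a[i] = acc_c4g[i] = 0.0;
        }
        acc_n = 0;
        ++out_i;
      }
    }
  }

  return List::create(_["eeg"] = out_eeg, _["rate_pyr"] = out_rate,
                      _["x0"] = out_x0, _["c4_alpha"] = out_c4a,
                      _["c4_gamma"] = out_c4g);
}

// Direct-form II transposed IIR filter with initial conditions, matching the
// conventional lfilter(b, a, x, zi) contract.
// [[Rcpp::export]]
NumericVector lfilter_cpp(NumericVector b, NumericVector a, NumericVector x,
                          NumericVector zi) {
  const int n = std::max(b.size(), a.size());
  std::vector<double> bb(n, 0.0), aa(n, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  if (aa[0] == 0.0) stop("a[1] must be non-zero");
  for (int i = 0; i < n; ++i) { bb[i] /= aa[0]; }
  for (int i = n - 1; i >= 0; --i) aa[i] /= aa[0];
  std::vector<double> z(n - 1, 0.0);
  if (zi.size() > 0) {
    if (zi.size() != n - 1) stop("zi must have length max(length(a), length(b)) - 1");
    for (int i = 0; i < n - 1; ++i) z[i] = zi[i];
  }
  const int m = x.size();
  NumericVector y(m);
  for (int k = 0; k < m; ++k) {
    const double xk = x[k];
    const double yk = bb[0] * xk + (n > 1 ? z[0] : 0.0);
    for (int i = 0; i < n - 2; ++i)
      z[i] = bb[i + 1] * xk + z[i + 1] - aa[i + 1] * yk;
    if (n > 1) z[n - 2] = bb[n - 1] * xk - aa[n - 1] * yk;
    y[k] = yk;
  }
  return y;
}
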