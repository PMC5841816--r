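#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step RK4 core for the delay-coupled Wilson-Cowan network with
// interpolated Gaussian noise and optional Euler updates of the slow
// inhibitory weights (ISP). Delayed excitatory inputs are read from a
// circular history buffer of past E, linearly interpolated between grid
// points at the RK half/full stages. Noise is drawn once per step per
// population (via R's RNG, so set.seed() governs reproducibility) and
// linearly interpolated at the stages.

static inline double sigm(double x, double mu, double inv_sigma) {
  double z = -(x - mu) * inv_sigma;
  if (z > 0) {
    double e = std::exp(-z);
    return e / (1.0 + e);
  }
  return 1.0 / (1.0 + std::exp(z));
}

// [[Rcpp::export]]
List wc_integrate_cpp(NumericMatrix W, IntegerMatrix delay_steps,
                      List params, NumericMatrix E_hist,
                      NumericVector I0, NumericVector cie0,
                      int n_steps, double dt,
                      bool isp_on, double tau_isp, double rho,
                      bool record, int cie_record_every,
                      NumericVector noise_e0, NumericVector noise_i0) {
  const int n = W.nrow();
  const int H = E_hist.ncol();           // history capacity (columns)
  const double c_ee = params["c_ee"], c_ei = params["c_ei"];
  const double mu = params["mu"], sigma = params["sigma"];
  const double P = params["P"], C = params["C"];
  const double tau_e = params["tau_e"], tau_i = params["tau_i"];
  const double noise_sd = params["noise_sd"];
  const double inv_sigma = 1.0 / sigma;

  int max_d = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (delay_steps(i, j) > max_d) max_d = delay_steps(i, j);
  if (max_d + 1 > H)
    stop("delay (%d steps) exceeds history buffer capacity (%d)", max_d, H);
  const bool zero_delay = (max_d == 0);

  // sparse-ish edge list per target region (skip zero weights)
  std::vector<std::vector<int> > nbr(n);
  std::vector<std::vector<double> > wgt(n);
  std::vector<std::vector<int> > del(n);
  for (int k = 0; k < n; ++k)
    for (int j = 0; j < n; ++j)
      if (W(k, j) != 0.0) {
        nbr[k].push_back(j);
        wgt[k].push_back(W(k, j));
        del[k].push_back(delay_steps(k, j));
      }

  // circular history buffer, column `cur` holds E at the current time
  std::vector<double> buf(n * H);
  for (int c = 0; c < H; ++c)
    for (int i = 0; i < n; ++i) buf[c * n + i] = E_hist(i, c);
  int cur = H - 1;

  std::vector<double> E(n), I(n), cie(n);
  for (int i = 0; i < n; ++i) {
    E[i] = E_hist(i, H - 1);
    I[i] = I0[i];
    cie[i] = cie0[i];
  }

  NumericMatrix E_out, I_out;
  if (record) {
    E_out = NumericMatrix(n, n_steps);
    I_out = NumericMatrix(n, n_steps);
  }
  int n_cie_rec = (cie_record_every > 0) ? n_steps / cie_record_every : 0;
  NumericMatrix cie_out(n, std::max(n_cie_rec, 0));
  IntegerVector cie_steps(std::max(n_cie_rec, 0));

  std::vector<double> ne0(n), ni0(n), ne1(n), ni1(n);
  bool have_noise0 = (noise_e0.size() == n && noise_i0.size() == n);
  RNGScope rngScope;
  for (int i = 0; i < n; ++i) {
    ne0[i] = have_noise0 ? noise_e0[i]
                         : (noise_sd > 0 ? R::rnorm(0.0, noise_sd) : 0.0);
    ni0[i] = have_noise0 ? noise_i0[i]
                         : (noise_sd > 0 ? R::rnorm(0.0, noise_sd) : 0.0);
  }

  std::vector<double> din0(n), dinh(n), din1(n);
  std::vector<double> k1e(n), k1i(n), k2e(n), k2i(n), k3e(n), k3i(n),
      k4e(n), k4i(n), Et(n), It(n);
  long clamp_count = 0;
  int cie_rec_i = 0;

  for (int s = 0; s < n_steps; ++s) {
    // next-step noise sample; stages interpolate between ne0 and ne1
    for (int i = 0; i < n; ++i) {
      ne1[i] = noise_sd > 0 ? R::rnorm(0.0, noise_sd) : 0.0;
      ni1[i] = noise_sd > 0 ? R::rnorm(0.0, noise_sd) : 0.0;
    }

    if (!zero_delay) {
      // delayed inputs at stage offsets 0, 1/2, 1 (linear interpolation
      // between history grid points; d = 0 edges use the start-of-step E)
      for (int k = 0; k < n; ++k) {
        double s0 = 0.0, sh = 0.0, s1 = 0.0;
        const int m = (int)nbr[k].size();
        for (int e = 0; e < m; ++e) {
          const int j = nbr[k][e];
          const double w = wgt[k][e];
          const int d = del[k][e];
          int c0 = cur - d; if (c0 < 0) c0 += H;
          const double a = buf[c0 * n + j];
          double b;
          if (d >= 1) {
            int c1 = c0 + 1; if (c1 >= H) c1 -= H;
            b = buf[c1 * n + j];
          } else {
            b = a;  // zero-delay edge: hold at start-of-step value
          }
          s0 += w * a;
          sh += w * 0.5 * (a + b);
          s1 += w * b;
        }
        din0[k] = s0; dinh[k] = sh; din1[k] = s1;
      }
    }

    // RK4 stages
    for (int stage = 0; stage < 4; ++stage) {
      const double th = (stage == 0) ? 0.0 : (stage == 3 ? 1.0 : 0.5);
      const std::vector<double> *kin_e = 0, *kin_i = 0;
      double hmul = 0.0;
      if (stage == 1) { kin_e = &k1e; kin_i = &k1i; hmul = 0.5 * dt; }
      else if (stage == 2) { kin_e = &k2e; kin_i = &k2i; hmul = 0.5 * dt; }
      else if (stage == 3) { kin_e = &k3e; kin_i = &k3i; hmul = dt; }
      for (int i = 0; i < n; ++i) {
        Et[i] = (stage == 0) ? E[i] : E[i] + hmul * (*kin_e)[i];
        It[i] = (stage == 0) ? I[i] : I[i] + hmul * (*kin_i)[i];
      }
      const std::vector<double> &din =
          (stage == 0) ? din0 : (stage == 3 ? din1 : dinh);
      std::vector<double> *koe = (stage == 0) ? &k1e :
          (stage == 1 ? &k2e : (stage == 2 ? &k3e : &k4e));
      std::vector<double> *koi = (stage == 0) ? &k1i :
          (stage == 1 ? &k2i : (stage == 2 ? &k3i : &k4i));
      for (int k = 0; k < n; ++k) {
        double lr;
        if (zero_delay) {
          // instantaneous coupling: use the stage state itself
          double acc = 0.0;
          const int m = (int)nbr[k].size();
          for (int e = 0; e < m; ++e) acc += wgt[k][e] * Et[nbr[k][e]];
          lr = acc;
        } else {
          lr = din[k];
        }
        const double ne = (1.0 - th) * ne0[k] + th * ne1[k];
        const double ni = (1.0 - th) * ni0[k] + th * ni1[k];
        const double de = c_ee * Et[k] + cie[k] * It[k] + P + ne + C * lr;
        (*koe)[k] = (-Et[k] + sigm(de, mu, inv_sigma)) / tau_e;
        (*koi)[k] = (-It[k] + sigm(c_ei * Et[k] + ni, mu, inv_sigma)) / tau_i;
      }
    }

    // slow ISP variable: forward Euler with start-of-step rates
    if (isp_on) {
      for (int i = 0; i < n; ++i) {
        cie[i] += dt * (-I[i] * (E[i] - rho) / tau_isp);
        if (cie[i] > 0.0) { cie[i] = 0.0; ++clamp_count; }
      }
    }

    for (int i = 0; i < n; ++i) {
      E[i] += dt / 6.0 * (k1e[i] + 2.0 * k2e[i] + 2.0 * k3e[i] + k4e[i]);
      I[i] += dt / 6.0 * (k1i[i] + 2.0 * k2i[i] + 2.0 * k3i[i] + k4i[i]);
    }

    ++cur; if (cur >= H) cur = 0;
    for (int i = 0; i < n; ++i) buf[cur * n + i] = E[i];
    std::swap(ne0, ne1);
    std::swap(ni0, ni1);

    if (record)
      for (int i = 0; i < n; ++i) { E_out(i, s) = E[i]; I_out(i, s) = I[i]; }
    if (cie_record_every > 0 && (s + 1) % cie_record_every == 0 &&
        cie_rec_i < n_cie_rec) {
      for (int i = 0; i < n; ++i) cie_out(i, cie_rec_i) = cie[i];
      cie_steps[cie_rec_i] = s + 1;
      ++cie_rec_i;
    }

    if ((s & 1023) == 0) {
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(E[i]))
          stop("non-finite state at t = %g s (step %d), region %d",
               (s + 1) * dt, s + 1, i + 1);
    }
  }
  for (int i = 0; i < n; ++i)
    if (!std::isfinite(E[i]) || !std::isfinite(I[i]))
      stop("non-finite state at end of segment, region %d", i + 1);

  // history tail for seamless continuation
  NumericMatrix tail(n, H);
  for (int c = 0; c < H; ++c) {
    int cc = cur - (H - 1) + c; while (cc < 0) cc += H;
    while (cc >= H) cc -= H;
    for (int i = 0; i < n; ++i) tail(i, c) = buf[cc * n + i];
  }

  return List::create(
      _["E"] = record ? E_out : NumericMatrix(0, 0),
      _["I"] = record ? I_out : NumericMatrix(0, 0),
      _["E_final"] = NumericVector(E.begin(), E.end()),
      _["I_final"] = NumericVector(I.begin(), I.end()),
      _["cie_final"] = NumericVector(cie.begin(), cie.end()),
      _["cie_traj"] = cie_out, _["cie_steps"] = cie_steps,
      _["E_hist_tail"] = tail,
      _["noise_e"] = NumericVector(ne0.begin(), ne0.end()),
      _["noise_i"] = NumericVector(ni0.begin(), ni0.end()),
      _["clamp_count"] = (double)clamp_count);
}
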