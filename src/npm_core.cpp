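#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Delay-buffered forward-Euler integrator for the two-population mean-field
// model on a mesh. Pair index order throughout: 0 = ee, 1 = ei, 2 = ie, 3 = ii
// (source population first). Long-range input is excitatory only and feeds the
// ee and ei channels through one shared per-vertex delay accumulator,
// multiplied by the respective long-range synapse counts.
//
// Transmission: each connection deposits weighted source rates into the
// target's ring buffer at the slot 'delay' steps ahead. Splined connections
// transmit only every u-th rate (a Catmull-Rom control point) and the
// receiving side reconstructs the intermediate values, exactly as in the
// explicit control-point exchange of a partitioned run.

static inline double sigmoid_rate_c(double h, double smax, double mu, double sg) {
  return smax / (1.0 + std::exp(-std::sqrt(2.0) * (h - mu) / sg));
}

// [[Rcpp::export(name = ".npm_core")]]
List npm_core(int n, int nsteps, double dt,
              List pars,
              IntegerVector conn_src,      // 0-based
              IntegerVector conn_dst,      // 0-based
              NumericVector conn_w,
              IntegerVector conn_delay,    // steps, >= 1
              LogicalVector conn_splined,
              int u_trans,
              NumericMatrix noise_ctrl,    // (segments + 3) x n, scaled
              int u_noise,
              double noise_mean,
              NumericVector he0, NumericVector hi0,
              NumericMatrix I0, NumericMatrix J0,   // n x 4
              int record_every,
              int mean_every,
              bool record_fields,
              bool record_controls) {
  const double tau_e = pars["tau_e"], tau_i = pars["tau_i"];
  const double hrest_e = pars["h_rest_e"], hrest_i = pars["h_rest_i"];
  const double smax_e = pars["S_max_e"], smax_i = pars["S_max_i"];
  const double mu_e = pars["mu_e"], mu_i = pars["mu_i"];
  const double sg_e = pars["sigma_e"], sg_i = pars["sigma_i"];
  const NumericVector heq = pars["h_eq"];        // length 4
  const NumericVector psi_den = pars["psi_den"]; // |h_eq - h_rest(target)|
  const NumericVector g1 = pars["g1"], g2 = pars["g2"], camp = pars["camp"];
  const NumericVector Na = pars["N_alpha"];      // length 4
  const double Nb_ee = pars["Nb_ee"], Nb_ei = pars["Nb_ei"];

  const int ncon = conn_src.size();
  int maxdelay = 0;
  for (int k = 0; k < ncon; ++k) {
    if (conn_delay[k] < 1) stop("connection delay must be >= 1 step");
    if (conn_splined[k] && conn_delay[k] <= 3 * u_trans)
      stop("splined delay <= 3*u steps (buffer sizing bug)");
    if (conn_delay[k] > maxdelay) maxdelay = conn_delay[k];
  }
  const int L = maxdelay + u_trans + 2;
  // split the (already canonically ordered) connection list by transmission
  // mode once, so the hot loop is branch-free
  std::vector<int> uns_src, uns_dst, uns_d, sp_src, sp_dst, sp_d;
  std::vector<double> uns_w, sp_w;
  for (int k = 0; k < ncon; ++k) {
    if (conn_splined[k]) {
      sp_src.push_back(conn_src[k]); sp_dst.push_back(conn_dst[k]);
      sp_d.push_back(conn_delay[k]); sp_w.push_back(conn_w[k]);
    } else {
      uns_src.push_back(conn_src[k]); uns_dst.push_back(conn_dst[k]);
      uns_d.push_back(conn_delay[k]); uns_w.push_back(conn_w[k]);
    }
  }
  const int n_uns = (int)uns_src.size(), n_sp = (int)sp_src.size();
  std::vector<double> buf((size_t)n * L, 0.0);

  std::vector<double> he(he0.begin(), he0.end()), hi(hi0.begin(), hi0.end());
  std::vector<double> I(4 * (size_t)n), Jd(4 * (size_t)n);
  for (int p = 0; p < 4; ++p)
    for (int a = 0; a < n; ++a) {
      I[(size_t)p * n + a] = I0(a, p);
      Jd[(size_t)p * n + a] = J0(a, p);
    }

  std::vector<double> se(n), si(n), phi(n), pnoise(n);
  // initial rates: history before t = 0 is constant at the initial rates
  for (int a = 0; a < n; ++a) {
    se[a] = sigmoid_rate_c(he[a], smax_e, mu_e, sg_e);
    si[a] = sigmoid_rate_c(hi[a], smax_i, mu_i, sg_i);
  }

  // prefill buffers with the constant pre-start history
  for (int k = 0; k < ncon; ++k) {
    const double v = conn_w[k] * se[conn_src[k]];
    const int d = conn_delay[k];
    const int t_end = conn_splined[k] ? d - 2 * u_trans + 1 : d; // events cover the rest
    for (int t = 0; t < t_end; ++t)
      buf[(size_t)conn_dst[k] * L + (t % L)] += v;
  }
  // control history per vertex (last 4 control points), all at initial rate
  std::vector<double> chist(4 * (size_t)n);
  for (int a = 0; a < n; ++a)
    for (int q = 0; q < 4; ++q) chist[(size_t)a * 4 + q] = se[a];
  bool any_splined = false;
  for (int k = 0; k < ncon; ++k) if (conn_splined[k]) { any_splined = true; break; }
  std::vector<double> segvals(any_splined ? (size_t)n * u_trans : 0);

  const int nrec_mean = (nsteps - 1) / mean_every + 1;
  NumericVector rec_t_mean(nrec_mean), rec_mhe(nrec_mean), rec_mhi(nrec_mean);
  int nrec_full = record_fields ? (nsteps - 1) / record_every + 1 : 0;
  NumericMatrix rec_he(record_fields ? n : 0, nrec_full);
  NumericMatrix rec_Aee(record_fields ? n : 0, nrec_full);
  NumericMatrix rec_Aei(record_fields ? n : 0, nrec_full);
  NumericVector rec_t_full(nrec_full);
  int nctrl_rec = record_controls ? (nsteps - 1) / u_trans + 1 : 0;
  NumericMatrix rec_ctrl(record_controls ? n : 0, nctrl_rec);

  const double sqrt2 = std::sqrt(2.0);
  std::vector<double> A(4 * (size_t)n);

  for (int t = 0; t < nsteps; ++t) {
    const int slot = t % L;
    // rates from the current state
    for (int a = 0; a < n; ++a) {
      se[a] = smax_e / (1.0 + std::exp(-sqrt2 * (he[a] - mu_e) / sg_e));
      si[a] = smax_i / (1.0 + std::exp(-sqrt2 * (hi[a] - mu_i) / sg_i));
    }
    // consume the current buffer slot, then reset it
    for (int a = 0; a < n; ++a) {
      phi[a] = buf[(size_t)a * L + slot];
      buf[(size_t)a * L + slot] = 0.0;
    }
    // control-point event: shift histories, reconstruct segment, deposit
    if (any_splined && t % u_trans == 0) {
      for (int a = 0; a < n; ++a) {
        double* ch = &chist[(size_t)a * 4];
        ch[0] = ch[1]; ch[1] = ch[2]; ch[2] = ch[3]; ch[3] = se[a];
        for (int q = 1; q <= u_trans; ++q) {
          const double x = (double)q / (double)u_trans;
          const double x2 = x * x, x3 = x2 * x;
          const double w0 = -0.5 * x3 + x2 - 0.5 * x;
          const double w1 = 1.5 * x3 - 2.5 * x2 + 1.0;
          const double w2 = -1.5 * x3 + 2.0 * x2 + 0.5 * x;
          const double w3 = 0.5 * x3 - 0.5 * x2;
          segvals[(size_t)a * u_trans + (q - 1)] =
            w0 * ch[0] + w1 * ch[1] + w2 * ch[2] + w3 * ch[3];
        }
      }
      if (record_controls)
        for (int a = 0; a < n; ++a) rec_ctrl(a, t / u_trans) = se[a];
    }
    // deposits, in canonical connection order (independent of partitioning)
    for (int k = 0; k < n_uns; ++k) {
      int idx = slot + uns_d[k];
      if (idx >= L) idx -= L;
      buf[(size_t)uns_dst[k] * L + idx] += uns_w[k] * se[uns_src[k]];
    }
    if (t % u_trans == 0) {
      for (int k = 0; k < n_sp; ++k) {
        // source times (t - 2u, t - u]; consumption strictly in the future
        const double w = sp_w[k];
        const double* sv = &segvals[(size_t)sp_src[k] * u_trans];
        double* row = &buf[(size_t)sp_dst[k] * L];
        int idx = slot + sp_d[k] - 2 * u_trans + 1;
        const int ts0 = t - 2 * u_trans + 1;
        if (idx >= L) idx -= L;
        for (int q = 0; q < u_trans; ++q) {
          if (ts0 + q + sp_d[k] >= 0) row[idx] += w * sv[q];
          if (++idx == L) idx = 0;
        }
      }
    }
    // noise drive (Catmull-Rom reconstruction of per-vertex control points)
    {
      const int m = t / u_noise;
      const double x = (double)(t % u_noise) / (double)u_noise;
      const double x2 = x * x, x3 = x2 * x;
      const double w0 = -0.5 * x3 + x2 - 0.5 * x;
      const double w1 = 1.5 * x3 - 2.5 * x2 + 1.0;
      const double w2 = -1.5 * x3 + 2.0 * x2 + 0.5 * x;
      const double w3 = 0.5 * x3 - 0.5 * x2;
      for (int a = 0; a < n; ++a)
        pnoise[a] = noise_mean + (w0 * noise_ctrl(m, a) + w1 * noise_ctrl(m + 1, a) +
                                  w2 * noise_ctrl(m + 2, a) + w3 * noise_ctrl(m + 3, a));
    }
    // synaptic activation A_lk
    for (int a = 0; a < n; ++a) {
      A[a] = Na[0] * se[a] + pnoise[a] + Nb_ee * phi[a];          // ee
      A[(size_t)n + a] = Na[1] * se[a] + Nb_ei * phi[a];          // ei
      A[(size_t)2 * n + a] = Na[2] * si[a];                       // ie
      A[(size_t)3 * n + a] = Na[3] * si[a];                       // ii
    }
    // record before the update so series start at the initial state
    if (t % mean_every == 0) {
      double mhe = 0.0, mhi = 0.0;
      for (int a = 0; a < n; ++a) { mhe += he[a]; mhi += hi[a]; }
      const int r = t / mean_every;
      rec_t_mean[r] = t * dt; rec_mhe[r] = mhe / n; rec_mhi[r] = mhi / n;
    }
    if (record_fields && t % record_every == 0) {
      const int r = t / record_every;
      rec_t_full[r] = t * dt;
      for (int a = 0; a < n; ++a) {
        rec_he(a, r) = he[a];
        rec_Aee(a, r) = A[a];
        rec_Aei(a, r) = A[(size_t)n + a];
      }
    }
    // forward-Euler update from pre-update values
    for (int a = 0; a < n; ++a) {
      const double Iee = I[a], Iei = I[(size_t)n + a];
      const double Iie = I[(size_t)2 * n + a], Iii = I[(size_t)3 * n + a];
      const double he_a = he[a], hi_a = hi[a];
      he[a] = he_a + dt * ((hrest_e - he_a +
               (heq[0] - he_a) / psi_den[0] * Iee +
               (heq[2] - he_a) / psi_den[2] * Iie) / tau_e);
      hi[a] = hi_a + dt * ((hrest_i - hi_a +
               (heq[1] - hi_a) / psi_den[1] * Iei +
               (heq[3] - hi_a) / psi_den[3] * Iii) / tau_i);
      for (int p = 0; p < 4; ++p) {
        const size_t ix = (size_t)p * n + a;
        const double Ip = I[ix], Jp = Jd[ix];
        I[ix] = Ip + dt * Jp;
        Jd[ix] = Jp + dt * (-(g1[p] + g2[p]) * Jp - g1[p] * g2[p] * Ip +
                            camp[p] * A[ix]);
      }
    }
    if (t % 2000 == 0) {
      for (int a = 0; a < n; ++a)
        if (!std::isfinite(he[a]) || !std::isfinite(hi[a]))
          stop("non-finite membrane potential at step %d (t = %g s)", t, t * dt);
    }
  }
  for (int a = 0; a < n; ++a)
    if (!std::isfinite(he[a]) || !std::isfinite(hi[a]))
      stop("non-finite membrane potential at the end of the run");

  NumericMatrix Iout(n, 4), Jout(n, 4);
  for (int p = 0; p < 4; ++p)
    for (int a = 0; a < n; ++a) {
      Iout(a, p) = I[(size_t)p * n + a];
      Jout(a, p) = Jd[(size_t)p * n + a];
    }
  return List::create(
    _["time_mean"] = rec_t_mean, _["mean_he"] = rec_mhe, _["mean_hi"] = rec_mhi,
    _["time_fields"] = rec_t_full, _["h_e"] = rec_he,
    _["A_ee"] = rec_Aee, _["A_ei"] = rec_Aei,
    _["controls"] = rec_ctrl,
    _["he_final"] = NumericVector(he.begin(), he.end()),
    _["hi_final"] = NumericVector(hi.begin(), hi.end()),
    _["I_final"] = Iout, _["J_final"] = Jout);
}
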