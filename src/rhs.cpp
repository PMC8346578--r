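#include <Rcpp.h>
using namespace Rcpp;

// quintic smoothstep ramp of the climate forcing
static inline double qramp(double tau) {
  if (tau < 0.0) return 0.0;
  if (tau > 1.0) return 1.0;
  return tau * tau * tau * (10.0 + tau * (-15.0 + 6.0 * tau));
}

// Right-hand side of the coupled density / trait-mean system, compiled for
// speed. Mirrors the R reference implementation (assemble_rhs) exactly:
// state y = c(vec(N), vec(mu)) with species varying fastest, parameters
// pre-flattened by rhs_parms().
// [[Rcpp::export]]
NumericVector rhs_flat(double t, NumericVector y, List p) {
  const int S_R = p["S_R"], S_C = p["S_C"], L = p["L"];
  const int S = S_R + S_C;
  const NumericVector rho = p["rho"], kappa = p["kappa"], sigma2 = p["sigma2"],
                      sigma2_G = p["sigma2_G"], m = p["m"], q = p["q"],
                      H = p["H"], eps = p["eps"];
  const double b_w = p["b_w"], a_w = p["a_w"], eta = p["eta"],
               sigma2_E = p["sigma2_E"], N_c = p["N_c"], N_floor = p["N_floor"];
  const bool tempdep = p["tempdep"], growth_on = p["growth_on"];
  const NumericMatrix a_mat = p["a_matrix"];
  const NumericMatrix Wo = p["W_omega"];  // S_C x S_R, W * omega premultiplied
  const double T_min = p["T_min"], T_max = p["T_max"],
               C_max = p["C_max"], C_min = p["C_min"], t_E = p["t_E"];

  NumericVector dy(2 * S * L);
  const double Q = qramp(t / t_E);

  std::vector<double> growth(S), sel(S), Nk(S), muk(S);

  for (int k = 0; k < L; ++k) {
    const double frac = double(k + 1) / double(L);
    const double T_loc = (T_min + (T_max - T_min) * frac) +
                         (C_max + (C_min - C_max) * frac) * Q;
    for (int i = 0; i < S; ++i) {
      double n = y[i + k * S];
      Nk[i] = n > 0.0 ? n : 0.0;
      muk[i] = y[S * L + i + k * S];
      growth[i] = 0.0;
      sel[i] = 0.0;
    }

    if (growth_on) {
      // intrinsic growth and directional selection (all species)
      for (int i = 0; i < S; ++i) {
        const double w = b_w - a_w * muk[i];
        const double v = w * w + sigma2[i];
        const double d = T_loc - muk[i];
        const double e = std::exp(-d * d / (2.0 * v));
        growth[i] = rho[i] / std::sqrt(v) * e - kappa[i];
        sel[i] = rho[i] * sigma2[i] * d / (v * std::sqrt(v)) * e;
      }
      // competition among resources
      if (tempdep) {
        for (int i = 0; i < S_R; ++i) {
          double comp = 0.0, selc = 0.0;
          for (int j = 0; j < S_R; ++j) {
            const double v = eta * eta / 2.0 + sigma2[i] + sigma2[j];
            const double d = muk[i] - muk[j];
            const double alpha = eta / std::sqrt(2.0 * v) *
                                 std::exp(-d * d / (2.0 * v));
            comp += alpha * Nk[j];
            selc += Nk[j] * alpha * d / v;
          }
          growth[i] -= comp;
          sel[i] += sigma2[i] * selc;
        }
      } else {
        for (int i = 0; i < S_R; ++i) {
          double comp = 0.0;
          for (int j = 0; j < S_R; ++j) comp += a_mat(i, j) * Nk[j];
          growth[i] -= comp;
        }
      }
      // trophic terms (phenotype-independent: no direct selection)
      if (S_C > 0) {
        for (int c = 0; c < S_C; ++c) {
          const int gi = S_R + c;
          double tot = 0.0;
          for (int j = 0; j < S_R; ++j) tot += Wo(c, j) * Nk[j];
          const double denom = 1.0 + q[gi] * H[gi] * tot;
          growth[gi] += eps[gi] * q[gi] * tot / denom;
          const double percap = Nk[gi] * q[gi] / denom;
          for (int j = 0; j < S_R; ++j) growth[j] -= percap * Wo(c, j);
        }
      }
    }

    // dispersal (reflecting pole, mirror-symmetric equator) and assembly
    for (int i = 0; i < S; ++i) {
      double dN_disp = 0.0, dmu_disp = 0.0;
      const double Nk_fl = Nk[i] > N_floor ? Nk[i] : N_floor;
      if (L > 1) {
        if (k > 0) {
          const double Nl = std::max(y[i + (k - 1) * S], 0.0);
          const double mul = y[S * L + i + (k - 1) * S];
          dN_disp += m[i] * (Nl - Nk[i]);
          dmu_disp += m[i] * (Nl / Nk_fl) * (mul - muk[i]);
        }
        if (k < L - 1) {
          const double Nl = std::max(y[i + (k + 1) * S], 0.0);
          const double mul = y[S * L + i + (k + 1) * S];
          dN_disp += m[i] * (Nl - Nk[i]);
          dmu_disp += m[i] * (Nl / Nk_fl) * (mul - muk[i]);
        }
      }
      const double s = Nk[i] * Nk[i] / (Nk[i] * Nk[i] + N_c * N_c);
      const double g_eff = sigma2_G[i] * s;
      const double h2_eff = g_eff / (g_eff + sigma2_E);
      dy[i + k * S] = Nk[i] * growth[i] + dN_disp;
      dy[S * L + i + k * S] = h2_eff * (sel[i] + dmu_disp);
    }
  }
  return dy;
}
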