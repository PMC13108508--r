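#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double sigm(double v, double phi0, double nu0, double r) {
  return 2.0 * phi0 / (1.0 + std::exp(r * (nu0 - v)));
}

// Table-driven RK4 integrator for a network of LaNMM columns.
//
// Population codes: 0=P1 1=SS 2=SST 3=P2 4=PV.  Source codes additionally
// 5=e1, 6=e2 (external input rates, held constant within a step) and the
// long-range slots 7 (P1->P1 lateral), 8 (P1->P2 feedback), 9 (P2->P2
// feedforward), whose input is G * w * sum_j W[j,i] * phi_j computed at every
// RK4 substage (instantaneous coupling, no conduction delays).
//
// Each synapse s obeys  u_s'' = A_s a_s C_s phi_in - 2 a_s u_s' - a_s^2 u_s
// and membrane potentials are signed sums of the u_s incoming to a
// population.  A is per-parcel (column of Amat) so receptor-weighted gain
// modulation enters here.
// [[Rcpp::export]]
List lanmm_integrate(IntegerVector src, IntegerVector tgt,
                     arma::mat Amat, NumericVector avec, NumericVector Cvec,
                     NumericVector sgn, NumericMatrix sig, arma::mat W,
                     double G, double w_lat, double w_fb, double w_ff,
                     arma::mat e1rate, arma::mat e2rate,
                     double dt, int n_steps, double bound,
                     LogicalVector store_v, LogicalVector store_phi,
                     int decim) {
  const int S = src.size(), N = W.n_rows, P = 5;
  arma::mat u(S, N, arma::fill::zeros), du(S, N, arma::fill::zeros);
  arma::mat v(P, N), phi(P, N);
  arma::mat k1u(S, N), k1d(S, N), k2u(S, N), k2d(S, N),
            k3u(S, N), k3d(S, N), k4u(S, N), k4d(S, N);
  arma::vec s1(N, arma::fill::zeros), s2(N, arma::fill::zeros);
  const bool coupled = G > 0.0 && N > 1;

  const int n_out = (n_steps + decim - 1) / decim;
  std::vector<arma::mat> vout(P), pout(P);
  for (int p = 0; p < P; ++p) {
    if (store_v[p]) vout[p].zeros(n_out, N);
    if (store_phi[p]) pout[p].zeros(n_out, N);
  }

  int kstep = 0;

  auto deriv = [&](const arma::mat& uu, const arma::mat& dd,
                   arma::mat& ou, arma::mat& od) {
    v.zeros();
    for (int s = 0; s < S; ++s) {
      const int t = tgt[s];
      for (int i = 0; i < N; ++i) v(t, i) += sgn[s] * uu(s, i);
    }
    for (int p = 0; p < P; ++p) {
      const double p0 = sig(p, 0), n0 = sig(p, 1), rr = sig(p, 2);
      for (int i = 0; i < N; ++i) phi(p, i) = sigm(v(p, i), p0, n0, rr);
    }
    if (coupled) {
      s1 = W.t() * phi.row(0).t();
      s2 = W.t() * phi.row(3).t();
    }
    for (int s = 0; s < S; ++s) {
      const double a = avec[s], C = Cvec[s], a2 = a * a, ta = 2.0 * a;
      const int sc = src[s];
      for (int i = 0; i < N; ++i) {
        double fin;
        switch (sc) {
          case 5: fin = e1rate(kstep, i); break;
          case 6: fin = e2rate(kstep, i); break;
          case 7: fin = coupled ? G * w_lat * s1(i) : 0.0; break;
          case 8: fin = coupled ? G * w_fb * s1(i) : 0.0; break;
          case 9: fin = coupled ? G * w_ff * s2(i) : 0.0; break;
          default: fin = phi(sc, i);
        }
        ou(s, i) = dd(s, i);
        od(s, i) = Amat(s, i) * a * C * fin - ta * dd(s, i) - a2 * uu(s, i);
      }
    }
  };

  arma::mat tu(S, N), td(S, N);
  for (kstep = 0; kstep < n_steps; ++kstep) {
    if (kstep % decim == 0) {
      const int row = kstep / decim;
      v.zeros();
      for (int s = 0; s < S; ++s)
        for (int i = 0; i < N; ++i) v(tgt[s], i) += sgn[s] * u(s, i);
      for (int p = 0; p < P; ++p) {
        if (store_v[p]) vout[p].row(row) = v.row(p);
        if (store_phi[p])
          for (int i = 0; i < N; ++i)
            pout[p](row, i) = sigm(v(p, i), sig(p, 0), sig(p, 1), sig(p, 2));
      }
      const double mx = arma::abs(v).max();
      if (!std::isfinite(mx) || mx > bound) {
        const arma::uword idx = arma::abs(v).index_max();
        return List::create(_["ok"] = false, _["t"] = kstep * dt,
                            _["parcel"] = (int)(idx / P) + 1);
      }
    }
    deriv(u, du, k1u, k1d);
    tu = u + 0.5 * dt * k1u; td = du + 0.5 * dt * k1d;
    deriv(tu, td, k2u, k2d);
    tu = u + 0.5 * dt * k2u; td = du + 0.5 * dt * k2d;
    deriv(tu, td, k3u, k3d);
    tu = u + dt * k3u; td = du + dt * k3d;
    deriv(tu, td, k4u, k4d);
    u += (dt / 6.0) * (k1u + 2.0 * k2u + 2.0 * k3u + k4u);
    du += (dt / 6.0) * (k1d + 2.0 * k2d + 2.0 * k3d + k4d);
  }

  List Lv(P), Lp(P);
  for (int p = 0; p < P; ++p) {
    if (store_v[p]) Lv[p] = wrap(vout[p]);
    if (store_phi[p]) Lp[p] = wrap(pout[p]);
  }
  return List::create(_["ok"] = true, _["v"] = Lv, _["phi"] = Lp);
}

// Balloon-Windkessel hemodynamic model, RK4, one column per parcel.
// States: vasodilatory signal s, inflow f, volume v, deoxyhemoglobin q;
// drive z is held constant within each integration step.
// BOLD = V0 * (k1 (1-q) + k2 (1 - q/v) + k3 (1 - v)),
// k1 = 7 E0, k2 = 2, k3 = 2 E0 - 0.2.
// [[Rcpp::export]]
arma::mat balloon_bold(arma::mat z, double dt, double kappa, double gam,
                       double tau, double alpha, double E0, double V0) {
  const int T = z.n_rows, N = z.n_cols;
  arma::mat out(T, N);
  const double k1 = 7.0 * E0, k2 = 2.0, k3 = 2.0 * E0 - 0.2;
  const double ia = 1.0 / alpha;

  for (int i = 0; i < N; ++i) {
    double s = 0.0, f = 1.0, vv = 1.0, q = 1.0;
    for (int t = 0; t < T; ++t) {
      const double zt = z(t, i);
      double ys[4] = {s, f, vv, q};
      double k[4][4];
      for (int stage = 0; stage < 4; ++stage) {
        double ss = ys[0], ff = ys[1], vvv = ys[2], qq = ys[3];
        if (ff < 1e-6) ff = 1e-6;
        if (vvv < 1e-6) vvv = 1e-6;
        const double fv = std::pow(vvv, ia);
        const double Ef = 1.0 - std::pow(1.0 - E0, 1.0 / ff);
        k[stage][0] = zt - kappa * ss - gam * (ff - 1.0);
        k[stage][1] = ss;
        k[stage][2] = (ff - fv) / tau;
        k[stage][3] = (ff * Ef / E0 - fv * qq / vvv) / tau;
        const double h = (stage < 2) ? 0.5 * dt : dt;
        if (stage < 3) {
          ys[0] = s + h * k[stage][0];
          ys[1] = f + h * k[stage][1];
          ys[2] = vv + h * k[stage][2];
          ys[3] = q + h * k[stage][3];
        }
      }
      s  += dt / 6.0 * (k[0][0] + 2 * k[1][0] + 2 * k[2][0] + k[3][0]);
      f  += dt / 6.0 * (k[0][1] + 2 * k[1][1] + 2 * k[2][1] + k[3][1]);
      vv += dt / 6.0 * (k[0][2] + 2 * k[1][2] + 2 * k[2][2] + k[3][2]);
      q  += dt / 6.0 * (k[0][3] + 2 * k[1][3] + 2 * k[2][3] + k[3][3]);
      out(t, i) = V0 * (k1 * (1.0 - q) + k2 * (1.0 - q / vv) + k3 * (1.0 - vv));
    }
  }
  return out;
}

// LZW compression over a binary alphabet: returns the number of emitted
// codes and the final dictionary size.  Description length (in bits) and
// rho0 are computed on the R side.
// [[Rcpp::export]]
IntegerVector lzw_encode_stats(IntegerVector bits) {
  const int n = bits.size();
  // dictionary as a trie over {0,1}: child[node][symbol] -> node id or -1
  std::vector<std::array<int, 2>> child;
  child.reserve(4096);
  child.push_back({-1, -1});  // 0: root
  // initial alphabet entries
  int root0 = 1, root1 = 2;
  child.push_back({-1, -1});
  child.push_back({-1, -1});
  child[0][0] = root0;
  child[0][1] = root1;
  int dict_size = 2, n_codes = 0, node = 0;
  for (int i = 0; i < n; ++i) {
    const int b = bits[i];
    int nxt = child[node][b];
    if (nxt >= 0) {
      node = nxt;
    } else {
      ++n_codes;                       // emit code for current prefix
      child.push_back({-1, -1});      // extend dictionary with prefix+b
      child[node][b] = (int)child.size() - 1;
      ++dict_size;
      node = child[0][b];             // restart from the single symbol
    }
  }
  if (node != 0) ++n_codes;           // flush the last prefix
  return IntegerVector::create(n_codes, dict_size);
}
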