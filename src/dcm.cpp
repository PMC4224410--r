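#include <Rcpp.h>
using namespace Rcpp;

// Bilinear neural dynamics zdot = (A + um(t) B) z + C ud(t), integrated by
// fixed-step RK4 with inputs frozen over each step. States are stored at the
// input grid points t_i = (i-1) * dt, with z(t_1) = z0.

static inline void deriv(const int n, const double *A, const double *B,
                         const double *C, const double um, const double ud,
                         const double *z, double *dz) {
  for (int r = 0; r < n; ++r) {
    double acc = C[r] * ud;
    for (int c = 0; c < n; ++c)
      acc += (A[r + n * c] + um * B[r + n * c]) * z[c];
    dz[r] = acc;
  }
}

// [[Rcpp::export]]
NumericMatrix dcm_integrate_cpp(NumericMatrix A, NumericMatrix B,
                                NumericVector C, NumericVector ud,
                                NumericVector um, NumericVector z0,
                                double dt) {
  const int n = A.nrow();
  const int nT = ud.size();
  NumericMatrix Z(nT, n);
  std::vector<double> z(n), k1(n), k2(n), k3(n), k4(n), tmp(n);
  for (int r = 0; r < n; ++r) z[r] = z0[r];
  const double *a = A.begin(), *b = B.begin(), *cc = C.begin();
  for (int i = 0; i < nT; ++i) {
    for (int r = 0; r < n; ++r) Z(i, r) = z[r];
    if (i + 1 == nT) break;
    const double u_d = ud[i], u_m = um[i];
    deriv(n, a, b, cc, u_m, u_d, z.data(), k1.data());
    for (int r = 0; r < n; ++r) tmp[r] = z[r] + 0.5 * dt * k1[r];
    deriv(n, a, b, cc, u_m, u_d, tmp.data(), k2.data());
    for (int r = 0; r < n; ++r) tmp[r] = z[r] + 0.5 * dt * k2[r];
    deriv(n, a, b, cc, u_m, u_d, tmp.data(), k3.data());
    for (int r = 0; r < n; ++r) tmp[r] = z[r] + dt * k3[r];
    deriv(n, a, b, cc, u_m, u_d, tmp.data(), k4.data());
    bool bad = false;
    for (int r = 0; r < n; ++r) {
      z[r] += dt / 6.0 * (k1[r] + 2.0 * k2[r] + 2.0 * k3[r] + k4[r]);
      if (!std::isfinite(z[r]) || std::fabs(z[r]) > 1e12) bad = true;
    }
    if (bad) {  // diverged: flag with NaN and stop integrating
      for (int j = i + 1; j < nT; ++j)
        for (int r = 0; r < n; ++r) Z(j, r) = NA_REAL;
      return Z;
    }
  }
  return Z;
}

static void matmul(const int n, const double *X, const double *Yv,
                   double *out) {
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int k = 0; k < n; ++k) acc += X[i + n * k] * Yv[k + n * j];
      out[i + n * j] = acc;
    }
}

// One-step RK4 propagator for the frozen-input linear system
// zdot = M z + b over a step h: z+ = R z + S b with
// R = I + hM + h^2/2 M^2 + h^3/6 M^3 + h^4/24 M^4 and
// S = h (I + h/2 M + h^2/6 M^2 + h^3/24 M^3). Arithmetic-identical to the
// stepwise classic RK4 with inputs frozen over the step.
static void rk4_propagator(const int n, const double *M, const double h,
                           double *R, double *S) {
  std::vector<double> M2(n * n), M3(n * n), M4(n * n);
  matmul(n, M, M, M2.data());
  matmul(n, M2.data(), M, M3.data());
  matmul(n, M3.data(), M, M4.data());
  for (int i = 0; i < n * n; ++i) {
    R[i] = h * M[i] + h * h / 2.0 * M2[i] + h * h * h / 6.0 * M3[i] +
           h * h * h * h / 24.0 * M4[i];
    S[i] = h * (h / 2.0 * M[i] + h * h / 6.0 * M2[i] +
                h * h * h / 24.0 * M3[i]);
  }
  for (int i = 0; i < n; ++i) {
    R[i + n * i] += 1.0;
    S[i + n * i] += h;
  }
}

// integrate one session (z0 = 0) and write the HRF-convolved prediction at
// the volume grid indices into rows [row0, row0+nS) of Y. Returns false on
// divergence. The modulatory input takes few distinct values (unit
// boxcars), so one RK4 propagator per distinct level is precomputed and
// each step is a single matrix-vector update.
static bool forward_session(const int n, const double *A, const double *B,
                            const double *C, const double *ud,
                            const double *um, const int nT, const double dt,
                            const double *hrf, const int nH,
                            const int *sample_idx, const int nS,
                            double *Y, const int yrows, const int row0) {
  std::vector<double> Z((size_t)nT * n, 0.0);
  std::vector<double> z(n, 0.0), k1(n), k2(n), k3(n), k4(n), tmp(n);

  // distinct modulatory levels (fallback below when too many)
  std::vector<double> levels;
  for (int i = 0; i < nT && (int)levels.size() <= 8; ++i) {
    bool seen = false;
    for (double lv : levels) if (lv == um[i]) { seen = true; break; }
    if (!seen) levels.push_back(um[i]);
  }
  const bool fast = (int)levels.size() <= 8;
  std::vector<double> Rs, Sb;
  if (fast) {
    std::vector<double> M(n * n), R(n * n), S(n * n);
    Rs.resize(levels.size() * n * n);
    Sb.resize(levels.size() * n);
    for (size_t l = 0; l < levels.size(); ++l) {
      for (int i = 0; i < n * n; ++i) M[i] = A[i] + levels[l] * B[i];
      rk4_propagator(n, M.data(), dt, R.data(), S.data());
      std::copy(R.begin(), R.end(), Rs.begin() + l * n * n);
      for (int r = 0; r < n; ++r) {
        double acc = 0.0;
        for (int c = 0; c < n; ++c) acc += S[r + n * c] * C[c];
        Sb[l * n + r] = acc;
      }
    }
  }

  if (fast && n == 3) {  // register-resident specialization
    double z0v = 0.0, z1v = 0.0, z2v = 0.0;
    for (int i = 0; i < nT; ++i) {
      double *zi = &Z[(size_t)i * 3];
      zi[0] = z0v; zi[1] = z1v; zi[2] = z2v;
      if (i + 1 == nT) break;
      size_t l = 0;
      while (levels[l] != um[i]) ++l;
      const double *R = Rs.data() + l * 9;
      const double *sb = Sb.data() + l * 3;
      const double u = ud[i];
      const double n0 = u * sb[0] + R[0] * z0v + R[3] * z1v + R[6] * z2v;
      const double n1 = u * sb[1] + R[1] * z0v + R[4] * z1v + R[7] * z2v;
      const double n2 = u * sb[2] + R[2] * z0v + R[5] * z1v + R[8] * z2v;
      z0v = n0; z1v = n1; z2v = n2;
      if (!(std::fabs(z0v) < 1e12 && std::fabs(z1v) < 1e12 &&
            std::fabs(z2v) < 1e12))
        return false;
    }
    for (int s = 0; s < nS; ++s) {
      const int idx = sample_idx[s] - 1;
      const int tmax = std::min(nH - 1, idx);
      double a0 = 0.0, a1 = 0.0, a2 = 0.0;
      const double *zp = &Z[(size_t)idx * 3];
      for (int tau = 0; tau <= tmax; ++tau) {
        const double h = hrf[tau];
        a0 += h * zp[0]; a1 += h * zp[1]; a2 += h * zp[2];
        zp -= 3;
      }
      Y[(size_t)(row0 + s)] = a0 * dt;
      Y[(size_t)(row0 + s) + (size_t)yrows] = a1 * dt;
      Y[(size_t)(row0 + s) + 2 * (size_t)yrows] = a2 * dt;
    }
    return true;
  }

  for (int i = 0; i < nT; ++i) {
    for (int r = 0; r < n; ++r) Z[(size_t)i * n + r] = z[r];
    if (i + 1 == nT) break;
    if (fast) {
      size_t l = 0;
      while (levels[l] != um[i]) ++l;
      const double *R = Rs.data() + l * n * n;
      const double *sb = Sb.data() + l * n;
      for (int r = 0; r < n; ++r) {
        double acc = ud[i] * sb[r];
        for (int c = 0; c < n; ++c) acc += R[r + n * c] * z[c];
        tmp[r] = acc;
      }
      bool bad = false;
      for (int r = 0; r < n; ++r) {
        z[r] = tmp[r];
        if (!std::isfinite(z[r]) || std::fabs(z[r]) > 1e12) bad = true;
      }
      if (bad) return false;
      continue;
    }
    deriv(n, A, B, C, um[i], ud[i], z.data(), k1.data());
    for (int r = 0; r < n; ++r) tmp[r] = z[r] + 0.5 * dt * k1[r];
    deriv(n, A, B, C, um[i], ud[i], tmp.data(), k2.data());
    for (int r = 0; r < n; ++r) tmp[r] = z[r] + 0.5 * dt * k2[r];
    deriv(n, A, B, C, um[i], ud[i], tmp.data(), k3.data());
    for (int r = 0; r < n; ++r) tmp[r] = z[r] + dt * k3[r];
    deriv(n, A, B, C, um[i], ud[i], tmp.data(), k4.data());
    for (int r = 0; r < n; ++r) {
      z[r] += dt / 6.0 * (k1[r] + 2.0 * k2[r] + 2.0 * k3[r] + k4[r]);
      if (!std::isfinite(z[r]) || std::fabs(z[r]) > 1e12) return false;
    }
  }
  for (int s = 0; s < nS; ++s) {
    const int idx = sample_idx[s] - 1;
    const int tmax = std::min(nH - 1, idx);
    for (int r = 0; r < n; ++r) {
      double acc = 0.0;
      for (int tau = 0; tau <= tmax; ++tau)
        acc += hrf[tau] * Z[(size_t)(idx - tau) * n + r];
      Y[(size_t)(row0 + s) + (size_t)yrows * r] = acc * dt;
    }
  }
  return true;
}

// Forward model for one session: integrate from rest, convolve each
// region's neural state with the HRF kernel, and evaluate only at the
// requested (1-based) grid indices of the scan volumes.
// [[Rcpp::export]]
NumericMatrix dcm_forward_session_cpp(NumericMatrix A, NumericMatrix B,
                                      NumericVector C, NumericVector ud,
                                      NumericVector um, double dt,
                                      NumericVector hrf,
                                      IntegerVector sample_idx) {
  const int n = A.nrow();
  const int nS = sample_idx.size();
  NumericMatrix Y(nS, n);
  bool ok = forward_session(n, A.begin(), B.begin(), C.begin(), ud.begin(),
                            um.begin(), ud.size(), dt, hrf.begin(),
                            hrf.size(), sample_idx.begin(), nS, Y.begin(),
                            nS, 0);
  if (!ok) std::fill(Y.begin(), Y.end(), NA_REAL);
  return Y;
}

// Profiled residual sum of squares across concatenated equal-length
// sessions: the prediction is computed for a unit driving weight, the
// weight c* minimizing the RSS against Y is profiled out analytically
// (the forward model is linear in the driving weight), and (rss, c*) is
// returned. A diverged integration reports a large penalty RSS.
// [[Rcpp::export]]
NumericVector dcm_profiled_rss_cpp(NumericMatrix A, NumericMatrix B,
                                   NumericVector C, NumericVector ud,
                                   NumericVector um, int n_sessions,
                                   double dt, NumericVector hrf,
                                   IntegerVector sample_idx,
                                   NumericMatrix Y) {
  const int n = A.nrow();
  const int nS = sample_idx.size();
  const int sess_len = ud.size() / n_sessions;
  const int yrows = n_sessions * nS;
  std::vector<double> Yhat((size_t)yrows * n, 0.0);
  for (int s = 0; s < n_sessions; ++s) {
    bool ok = forward_session(n, A.begin(), B.begin(), C.begin(),
                              ud.begin() + (size_t)s * sess_len,
                              um.begin() + (size_t)s * sess_len, sess_len,
                              dt, hrf.begin(), hrf.size(),
                              sample_idx.begin(), nS, Yhat.data(), yrows,
                              s * nS);
    if (!ok) return NumericVector::create(1e10, 0.0);
  }
  double num = 0.0, den = 0.0;
  const size_t nobs = (size_t)yrows * n;
  for (size_t i = 0; i < nobs; ++i) {
    num += Y[i] * Yhat[i];
    den += Yhat[i] * Yhat[i];
  }
  const double cstar = den > 1e-12 ? num / den : 0.0;
  double rss = 0.0;
  for (size_t i = 0; i < nobs; ++i) {
    const double r = Y[i] - cstar * Yhat[i];
    rss += r * r;
  }
  if (!std::isfinite(rss)) return NumericVector::create(1e10, 0.0);
  return NumericVector::create(rss, cstar);
}
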