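#include <Rcpp.h>
#include <complex>
using namespace Rcpp;

typedef std::complex<double> cplx;

// sphere form amplitude F(q, R) = 3 V (sin x - x cos x) / x^3, x = qR.
// Series expansion below x ~ 0.04 keeps the q -> 0 limit exact (F -> V).
static inline double sphere_F(double q, double R) {
  const double V = 4.0 * M_PI * R * R * R / 3.0;
  const double x = q * R;
  if (x < 0.04) {
    const double x2 = x * x;
    return V * (1.0 - x2 / 10.0 + x2 * x2 / 280.0);
  }
  return 3.0 * V * (std::sin(x) - x * std::cos(x)) / (x * x * x);
}

// [[Rcpp::export]]
NumericVector cpp_sphere_form_amplitude(NumericVector q, double R) {
  const int n = q.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sphere_F(q[i], R);
  return out;
}

// Polydisperse-sphere SAXS intensity with Gaussian size distribution and
// Gaussian q-resolution smearing:
//   I(q) = I0 * [ sum_m w_m sum_k p_k F^2(q_m, R_k) / sum_k p_k V^2(R_k) ] + Ib
// R-integral: Gauss-Legendre nodes glx (on [-1,1]) mapped onto
// [max(R - trunc_R*sigR, eps), R + trunc_R*sigR]; p_k = glw_k * N(R_k; R, sigR).
// q-kernel: n_ker equally spaced nodes on q + sigq*[-trunc_q, trunc_q] with
// normal weights renormalised to unit sum (nodes pushed below q > 0 dropped).
// [[Rcpp::export]]
NumericVector cpp_saxs_intensity(NumericVector q, double I0, double Ib,
                                 double R, double sigR, double sigq,
                                 NumericVector glx, NumericVector glw,
                                 double trunc_R, int n_ker, double trunc_q) {
  const int nq = q.size(), nR = glx.size();
  NumericVector out(nq);

  // size-distribution nodes (shared across q)
  const double lo = std::max(R - trunc_R * sigR, 1e-6);
  const double hi = R + trunc_R * sigR;
  const double half = 0.5 * (hi - lo), mid = 0.5 * (hi + lo);
  std::vector<double> Rk(nR), pk(nR), V2(nR);
  double denom = 0.0;
  for (int k = 0; k < nR; ++k) {
    Rk[k] = mid + half * glx[k];
    const double zrel = (Rk[k] - R) / sigR;
    pk[k] = half * glw[k] * std::exp(-0.5 * zrel * zrel);
    const double V = 4.0 * M_PI * Rk[k] * Rk[k] * Rk[k] / 3.0;
    V2[k] = V * V;
    denom += pk[k] * V2[k];
  }

  // resolution kernel node offsets / weights
  const bool smear = sigq > 0.0 && n_ker > 1;
  const int nm = smear ? n_ker : 1;
  std::vector<double> toff(nm), twt(nm);
  if (smear) {
    for (int m = 0; m < nm; ++m) {
      const double t = -trunc_q + 2.0 * trunc_q * m / (nm - 1);
      toff[m] = t;
      twt[m] = std::exp(-0.5 * t * t);
    }
  } else {
    toff[0] = 0.0; twt[0] = 1.0;
  }

  for (int i = 0; i < nq; ++i) {
    double num = 0.0, wsum = 0.0;
    for (int m = 0; m < nm; ++m) {
      const double qm = q[i] + sigq * toff[m];
      if (qm <= 0.0) continue;          // truncated node; renormalised below
      double inner = 0.0;
      for (int k = 0; k < nR; ++k) {
        const double F = sphere_F(qm, Rk[k]);
        inner += pk[k] * F * F;
      }
      num += twt[m] * inner;
      wsum += twt[m];
    }
    out[i] = (wsum > 0.0) ? I0 * (num / wsum) / denom + Ib : Ib;
  }
  return out;
}

// kz in medium with dispersion/absorption (delta, beta) for ambient-referenced
// qz: kz^2 = (q/2)^2 - 2 k0^2 (delta - delta_amb) + 2 i k0^2 (beta - beta_amb)
// For the common non-absorbing case the argument is real and kz is either
// purely real (propagating) or purely imaginary (evanescent), which avoids
// the complex sqrt/exp in the hot loop.
static inline cplx kz_medium(double kza, double k0sq,
                             double delta, double beta,
                             double delta_amb, double beta_amb) {
  const double re = kza * kza - 2.0 * k0sq * (delta - delta_amb);
  const double im = 2.0 * k0sq * (beta - beta_amb);
  if (im == 0.0) {
    if (re >= 0.0) return cplx(std::sqrt(re), 0.0);
    return cplx(0.0, std::sqrt(-re));
  }
  return std::sqrt(cplx(re, im));
}

// exp(i * kz * d), cheap for purely real / purely imaginary kz
static inline cplx expikd(cplx kz, double d) {
  const double re = std::real(kz), im = std::imag(kz);
  const double damp = (im == 0.0) ? 1.0 : std::exp(-im * d);
  if (re == 0.0) return cplx(damp, 0.0);
  return cplx(damp * std::cos(re * d), damp * std::sin(re * d));
}

// Dynamical (Parratt) recursion on a sliced profile. q is the wave-vector
// transfer in the ambient; slabs listed top (ambient side) to bottom, each of
// thickness dz. Returns |r|^2.
// [[Rcpp::export]]
NumericVector cpp_parratt(NumericVector q,
                          NumericVector delta, NumericVector beta, double dz,
                          double delta_amb, double beta_amb,
                          double delta_sub, double beta_sub, double lambda) {
  const int nq = q.size(), ns = delta.size();
  const double k0 = 2.0 * M_PI / lambda, k0sq = k0 * k0;
  NumericVector out(nq);

  std::vector<cplx> kz(ns + 2);
  for (int i = 0; i < nq; ++i) {
    const double kza = 0.5 * q[i];
    kz[0] = cplx(kza, 0.0);
    for (int j = 0; j < ns; ++j)
      kz[j + 1] = kz_medium(kza, k0sq, delta[j], beta[j], delta_amb, beta_amb);
    kz[ns + 1] = kz_medium(kza, k0sq, delta_sub, beta_sub, delta_amb, beta_amb);

    cplx Rcum(0.0, 0.0);
    for (int j = ns; j >= 0; --j) {
      const cplx kj = kz[j], kj1 = kz[j + 1];
      const cplx F = (kj - kj1) / (kj + kj1);
      cplx Radj = Rcum;
      if (j < ns) Radj = Rcum * expikd(kj1, 2.0 * dz);
      Rcum = (F + Radj) / (1.0 + F * Radj);
    }
    out[i] = std::norm(Rcum);
  }
  return out;
}

// Depth-resolved standing-wave intensity |E(z)|^2 in a sliced multilayer,
// unit incident amplitude, one column per angle. Field evaluated at slab
// midpoints. Also returns |r|^2 and the substrate-transmitted flux fraction
// for energy-balance checks.
// [[Rcpp::export]]
List cpp_efield(NumericVector alpha_rad, double lambda,
                NumericVector delta, NumericVector beta, double dz,
                double delta_amb, double beta_amb,
                double delta_sub, double beta_sub) {
  const int na = alpha_rad.size(), ns = delta.size();
  const double k0 = 2.0 * M_PI / lambda, k0sq = k0 * k0;
  NumericMatrix e2(ns, na);
  NumericVector r2(na), tflux(na);

  std::vector<cplx> kz(ns + 2), T(ns + 2), Rr(ns + 2);
  for (int a = 0; a < na; ++a) {
    const double kza = k0 * std::sin(alpha_rad[a]);
    kz[0] = cplx(kza, 0.0);
    for (int j = 0; j < ns; ++j)
      kz[j + 1] = kz_medium(kza, k0sq, delta[j], beta[j], delta_amb, beta_amb);
    kz[ns + 1] = kz_medium(kza, k0sq, delta_sub, beta_sub, delta_amb, beta_amb);

    // bottom-up Parratt pass for the total reflected amplitude
    cplx Rcum(0.0, 0.0);
    for (int j = ns; j >= 0; --j) {
      const cplx F = (kz[j] - kz[j + 1]) / (kz[j] + kz[j + 1]);
      cplx Radj = Rcum;
      if (j < ns) Radj = Rcum * expikd(kz[j + 1], 2.0 * dz);
      Rcum = (F + Radj) / (1.0 + F * Radj);
    }
    r2[a] = std::norm(Rcum);

    // top-down amplitude propagation (continuity of E and dE/dz)
    T[0] = cplx(1.0, 0.0);
    Rr[0] = Rcum;
    for (int j = 0; j <= ns; ++j) {
      const cplx aph = (j == 0) ? cplx(1.0, 0.0) : expikd(kz[j], dz);
      const cplx s = kz[j] / kz[j + 1];
      const cplx Ta = T[j] * aph, Rb = Rr[j] / aph;
      T[j + 1] = 0.5 * (Ta * (1.0 + s) + Rb * (1.0 - s));
      Rr[j + 1] = 0.5 * (Ta * (1.0 - s) + Rb * (1.0 + s));
    }
    for (int m = 0; m < ns; ++m) {
      const cplx ph = expikd(kz[m + 1], 0.5 * dz);
      e2(m, a) = std::norm(T[m + 1] * ph + Rr[m + 1] / ph);
    }
    tflux[a] = std::norm(T[ns + 1]) * std::real(kz[ns + 1]) / kza;
  }
  return List::create(_["e2"] = e2, _["r2"] = r2, _["tflux"] = tflux);
}
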