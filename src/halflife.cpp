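// Fast half-life kernels for the three-compartment trafficking model.
// These mirror the R implementations (terminal_half_life(), time_to_half())
// and exist only to make the MCMC hot path cheap; the R routes are kept and
// cross-checked in the test suite.

#include <Rcpp.h>
#include <complex>
using namespace Rcpp;

typedef std::complex<double> cplx;

// rate-matrix entries, row-major
static void rate_entries(double Vp, double Ve, double Q, double Qu,
                         double fs, double fr, double a[9]) {
  a[0] = -Q;     a[1] = Q;               a[2] = 0.0;
  a[3] = Q / Vp; a[4] = -(Q + Qu) / Vp;  a[5] = Qu * fs * fr / Vp;
  a[6] = 0.0;    a[7] = Qu / Ve;
  a[8] = Qu * ((1.0 - fr) * fs - 1.0) / Ve;
}

static cplx cbrtc(cplx z) {
  double r = std::abs(z);
  if (r == 0.0 || !std::isfinite(r)) return cplx(0.0, 0.0);
  return std::polar(std::cbrt(r), std::arg(z) / 3.0);
}

// roots of the characteristic cubic det(lambda I - M) = 0 via Cardano;
// returns false when the coefficients are not finite
static bool char_roots(const double a[9], cplx r[3]) {
  double tr = a[0] + a[4] + a[8];
  double m2 = a[0] * a[4] - a[1] * a[3] + a[0] * a[8] + a[4] * a[8] -
              a[5] * a[7];
  double det = a[0] * (a[4] * a[8] - a[5] * a[7]) - a[1] * a[3] * a[8];
  if (!std::isfinite(tr) || !std::isfinite(m2) || !std::isfinite(det)) {
    return false;
  }
  // lambda^3 + c2 l^2 + c1 l + c0
  double c2 = -tr, c1 = m2, c0 = -det;
  double s = c2 / 3.0;
  double p = c1 - c2 * c2 / 3.0;
  double q = 2.0 * c2 * c2 * c2 / 27.0 - c2 * c1 / 3.0 + c0;
  if (!std::isfinite(p) || !std::isfinite(q)) return false;
  cplx sqrtD = std::sqrt(cplx(q * q / 4.0 + p * p * p / 27.0, 0.0));
  cplx u = cbrtc(-q / 2.0 + sqrtD);
  if (std::abs(u) < 1e-300) u = cbrtc(-q / 2.0 - sqrtD);
  cplx v = (std::abs(u) < 1e-300) ? cplx(0.0, 0.0) : -p / (3.0 * u);
  const cplx w(-0.5, 0.8660254037844386);
  const cplx wb(-0.5, -0.8660254037844386);
  r[0] = u + v - s;
  r[1] = w * u + wb * v - s;
  r[2] = wb * u + w * v - s;
  return true;
}

static double slowest_real(const cplx r[3], const double a[9]) {
  double slow = std::max(std::max(r[0].real(), r[1].real()), r[2].real());
  double scale = std::max(1.0, std::max(std::abs(a[0]),
                          std::max(std::abs(a[4]), std::abs(a[8]))));
  if (slow >= -1e-12 * scale) return 0.0;
  return slow;
}

static double terminal_hl(const double a[9]) {
  cplx r[3];
  if (!char_roots(a, r)) return NA_REAL;
  double slow = slowest_real(r, a);
  if (slow == 0.0) return R_PosInf;
  return M_LN2 / std::fabs(slow);
}

// central concentration C_c(t)/C_c(0) after a bolus (1, 0, 0):
// sum of residues r_i exp(lambda_i t) with
// r_i = M11(lambda_i) / prod_{j != i} (lambda_i - lambda_j),
// M11(l) = (l - a4)(l - a8) - a5 a7 (first minor of (l I - M)).
static bool residues(const double a[9], const cplx lam[3], cplx res[3]) {
  for (int i = 0; i < 3; ++i) {
    cplx num = (lam[i] - a[4]) * (lam[i] - a[8]) - a[5] * a[7];
    cplx den(1.0, 0.0);
    for (int j = 0; j < 3; ++j) {
      if (j == i) den *= 1.0; else den *= (lam[i] - lam[j]);
    }
    if (std::abs(den) < 1e-10) return false; // near-degenerate spectrum
    res[i] = num / den;
  }
  return true;
}

static double cc_at(const cplx lam[3], const cplx res[3], double t) {
  cplx s(0.0, 0.0);
  for (int i = 0; i < 3; ++i) s += res[i] * std::exp(lam[i] * t);
  return s.real();
}

static double time_to_half_impl(double Vp, double Ve, double Q, double Qu,
                                double fs, double fr) {
  double a[9];
  rate_entries(Vp, Ve, Q, Qu, fs, fr, a);
  cplx lam[3], res[3];
  if (!char_roots(a, lam)) return NA_REAL;
  if (!residues(a, lam, res)) {
    // tiny deterministic perturbation off the degenerate manifold
    rate_entries(Vp, Ve, Q, Qu * (1.0 + 1e-7) + 1e-12, fs, fr, a);
    if (!char_roots(a, lam)) return NA_REAL;
    if (!residues(a, lam, res)) return NA_REAL;
  }
  double lo = 0.0, hi = 1.0;
  int n_double = 0;
  while (cc_at(lam, res, hi) > 0.5) {
    lo = hi;
    hi *= 2.0;
    if (++n_double > 60) return R_PosInf; // never reaches half
  }
  for (int it = 0; it < 200; ++it) {
    double mid = 0.5 * (lo + hi);
    if (cc_at(lam, res, mid) > 0.5) lo = mid; else hi = mid;
    if ((hi - lo) <= 1e-12 * hi) break;
  }
  return 0.5 * (lo + hi);
}

// [[Rcpp::export(name = ".cpp_half_life")]]
double cpp_half_life(double Vp, double Ve, double Q, double Qu,
                     double fs, double fr, int type) {
  if (!std::isfinite(Vp) || !std::isfinite(Ve) || !std::isfinite(Q) ||
      !std::isfinite(Qu) || Vp <= 0.0 || Ve <= 0.0) {
    return NA_REAL;
  }
  double a[9];
  rate_entries(Vp, Ve, Q, Qu, fs, fr, a);
  if (type == 0) return terminal_hl(a);
  return time_to_half_impl(Vp, Ve, Q, Qu, fs, fr);
}

// log likelihood over variants: half-lives of the trafficking model vs
// normal(mean, scale) observations. fs/fr are per-observation fractions.
// [[Rcpp::export(name = ".cpp_loglik")]]
double cpp_loglik(double Vp, double Ve, double Q, double Qu,
                  NumericVector fs, NumericVector fr,
                  NumericVector obs_mean, NumericVector obs_scale,
                  int type) {
  int n = obs_mean.size();
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double hl = cpp_half_life(Vp, Ve, Q, Qu, fs[i], fr[i], type);
    if (!R_finite(hl)) return R_NegInf;
    double z = (hl - obs_mean[i]) / obs_scale[i];
    ll += -0.5 * z * z - std::log(obs_scale[i]) -
          0.9189385332046727; // log(sqrt(2*pi))
  }
  return ll;
}
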