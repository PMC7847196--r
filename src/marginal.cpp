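// Marginal likelihood of the linear-radius (or volume) growth model with
// lognormal animal-level random effects and proportional residual error.
//
// Observation j of animal i:  y_ij ~ N(m_ij, (s3 * m_ij)^2)  with
//   m_ij = r_ij            (radius scale)   r_ij = a_i + b_i t_ij
//   m_ij = (4pi/3) r_ij^3  (volume scale)
// Random effects u = (log a_i, log b_i), Normal with SDs (s1, s2) and means
// (mu1, mu2 + c * T_i). The per-animal integral over u is approximated by a
// Laplace expansion at the posterior mode (damped Newton, analytic
// derivatives) or, as a cross-check, by 5x5 adaptive Gauss-Hermite
// quadrature centred at the same mode.

#include <Rcpp.h>
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// 5-node Gauss-Hermite abscissae / weights (physicists' convention)
static const double GH_X[5] = {-2.0201828704560856329,
                               -0.95857246461381850711,
                               0.0,
                               0.95857246461381850711,
                               2.0201828704560856329};
static const double GH_W[5] = {0.019953242059045913208,
                               0.39361932315224115983,
                               0.94530872048294188123,
                               0.39361932315224115983,
                               0.019953242059045913208};

struct Animal {
  const double *y;
  const double *t;
  int n;
  double nu1, nu2;   // prior means of u1, u2
  double s1, s2, s3; // SDs
  int scale;         // 0 radius, 1 volume
};

// negative joint log-density (up to constants handled by the caller):
// g(u) = sum_j [ log m_j + z_j^2/(2 s3^2) ] + prior quadratics
// with z_j = y_j/m_j - 1. Fills gradient and Hessian when requested.
static double g_eval(const Animal &A, const double u1, const double u2,
                     double *grad, double *hess) {
  const double a = std::exp(u1), b = std::exp(u2);
  const double inv_s3sq = 1.0 / (A.s3 * A.s3);
  const double k = 4.0 * M_PI / 3.0;
  double g = 0.0;
  double g1 = 0.0, g2 = 0.0, h11 = 0.0, h12 = 0.0, h22 = 0.0;
  for (int j = 0; j < A.n; ++j) {
    const double bt = b * A.t[j];
    const double r = a + bt;
    double m, mp, mpp;
    if (A.scale == 0) {
      m = r; mp = 1.0; mpp = 0.0;
    } else {
      m = k * r * r * r; mp = 3.0 * k * r * r; mpp = 6.0 * k * r;
    }
    const double yj = A.y[j];
    const double z = yj / m - 1.0;
    g += std::log(m) + 0.5 * z * z * inv_s3sq;
    if (grad) {
      const double phi1 = 1.0 / m - z * yj * inv_s3sq / (m * m);
      const double phi2 = -1.0 / (m * m) +
        yj * yj * inv_s3sq / (m * m * m * m) +
        2.0 * yj * z * inv_s3sq / (m * m * m);
      const double d1 = mp * a, d2 = mp * bt;      // dm/du
      const double d11 = mpp * a * a + mp * a;     // d2m/du2
      const double d12 = mpp * a * bt;
      const double d22 = mpp * bt * bt + mp * bt;
      g1 += phi1 * d1;
      g2 += phi1 * d2;
      h11 += phi2 * d1 * d1 + phi1 * d11;
      h12 += phi2 * d1 * d2 + phi1 * d12;
      h22 += phi2 * d2 * d2 + phi1 * d22;
    }
  }
  const double p1 = (u1 - A.nu1) / (A.s1 * A.s1);
  const double p2 = (u2 - A.nu2) / (A.s2 * A.s2);
  g += 0.5 * (u1 - A.nu1) * p1 + 0.5 * (u2 - A.nu2) * p2;
  if (grad) {
    grad[0] = g1 + p1;
    grad[1] = g2 + p2;
    hess[0] = h11 + 1.0 / (A.s1 * A.s1);
    hess[1] = h12;
    hess[2] = h22 + 1.0 / (A.s2 * A.s2);
  }
  return g;
}

// damped Newton to the posterior mode; returns g at the mode, fills u, H
static double inner_mode(const Animal &A, double *u, double *H) {
  double grad[2];
  double g = g_eval(A, u[0], u[1], grad, H);
  double lambda = 1e-6;
  for (int it = 0; it < 200; ++it) {
    const double gnorm = std::max(std::fabs(grad[0]), std::fabs(grad[1]));
    if (gnorm < 1e-9 * (1.0 + std::fabs(g))) break;
    // solve (H + lambda I) d = -grad, retrying with larger damping
    bool accepted = false;
    for (int k = 0; k < 40 && !accepted; ++k) {
      const double h11 = H[0] + lambda, h12 = H[1], h22 = H[2] + lambda;
      const double det = h11 * h22 - h12 * h12;
      if (det > 0.0 && h11 > 0.0) {
        const double d1 = (-grad[0] * h22 + grad[1] * h12) / det;
        const double d2 = (-grad[1] * h11 + grad[0] * h12) / det;
        const double u1n = u[0] + d1, u2n = u[1] + d2;
        if (std::isfinite(u1n) && std::isfinite(u2n) &&
            std::fabs(u1n) < 50.0 && std::fabs(u2n) < 50.0) {
          const double gn = g_eval(A, u1n, u2n, nullptr, nullptr);
          if (std::isfinite(gn) && gn <= g + 1e-12) {
            u[0] = u1n; u[1] = u2n;
            g = g_eval(A, u[0], u[1], grad, H);
            lambda = std::max(lambda / 3.0, 1e-10);
            accepted = true;
          }
        }
      }
      if (!accepted) lambda *= 10.0;
    }
    if (!accepted) break; // cannot improve further
  }
  return g;
}

// [[Rcpp::export]]
double marginal_nll_cpp(NumericVector theta, NumericVector y, NumericVector t,
                        IntegerVector start, IntegerVector treated, int scale,
                        int method) {
  const double mu1 = theta[0], mu2 = theta[1];
  const double s1 = std::exp(theta[2]);
  const double s2 = std::exp(theta[3]);
  const double s3 = std::exp(theta[4]);
  const double c = theta[5];
  const int n_animals = treated.size();
  double ll = 0.0;
  for (int i = 0; i < n_animals; ++i) {
    Animal A;
    A.y = &y[start[i]];
    A.t = &t[start[i]];
    A.n = start[i + 1] - start[i];
    A.nu1 = mu1;
    A.nu2 = mu2 + (treated[i] ? c : 0.0);
    A.s1 = s1; A.s2 = s2; A.s3 = s3;
    A.scale = scale;
    double u[2] = {A.nu1, A.nu2};
    double H[3];
    const double gmode = inner_mode(A, u, H);
    const double det = H[0] * H[2] - H[1] * H[1];
    if (!std::isfinite(gmode) || det <= 0.0) return 1e10;
    double li;
    if (method == 0) { // Laplace
      li = -gmode - 0.5 * std::log(det);
    } else {           // adaptive Gauss-Hermite 5x5 around the mode
      // C with C C^T = H^{-1} from the closed-form 2x2 Cholesky of H
      const double u11 = std::sqrt(H[0]);
      const double u12 = H[1] / u11;
      const double u22 = std::sqrt(H[2] - u12 * u12);
      double sum = 0.0;
      for (int p = 0; p < 5; ++p) {
        for (int q = 0; q < 5; ++q) {
          const double z1 = GH_X[p], z2 = GH_X[q];
          // u = mode + sqrt(2) * U^{-1} z (back-substitution)
          const double w2 = z2 / u22;
          const double w1 = (z1 - u12 * w2) / u11;
          const double du1 = M_SQRT2 * w1, du2 = M_SQRT2 * w2;
          const double gq = g_eval(A, u[0] + du1, u[1] + du2,
                                   nullptr, nullptr);
          sum += GH_W[p] * GH_W[q] *
            std::exp(z1 * z1 + z2 * z2 - (gq - gmode));
        }
      }
      li = -gmode + std::log(2.0) - 0.5 * std::log(det) + std::log(sum) -
        std::log(2.0 * M_PI);
    }
    // observation and prior normalising constants (the prior's 2D Gaussian
    // constant cancels against the Laplace (2pi)^{d/2} factor)
    ll += li - 0.5 * A.n * LOG2PI - A.n * theta[4] - theta[2] - theta[3];
    if (!std::isfinite(ll)) return 1e10;
  }
  return -ll;
}
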