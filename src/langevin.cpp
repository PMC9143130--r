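#include <Rcpp.h>
using namespace Rcpp;

// Analytic-surface energy/force kernels.  Form codes:
//   1 harmonic            params {kappa, center}
//   2 double_well         params {h, b}
//   3 separable_2d (y~k)  params {h, b, ky}
//   4 separable_2d (y~dw) params {h, b, hy, by}
//   5 coupled_2d          params {h, b, ky, c}
static inline double eval_force(int form, const double* p,
                                const double* x, int dim, double* f) {
  double e = 0.0;
  switch (form) {
  case 1: {
    double dx = x[0] - p[1];
    e = 0.5 * p[0] * dx * dx;
    f[0] = -p[0] * dx;
    break;
  }
  case 2: {
    double s = (x[0] / p[1]) * (x[0] / p[1]) - 1.0;
    e = p[0] * s * s;
    f[0] = -4.0 * p[0] * x[0] * s / (p[1] * p[1]);
    break;
  }
  case 3: {
    double s = (x[0] / p[1]) * (x[0] / p[1]) - 1.0;
    e = p[0] * s * s + 0.5 * p[2] * x[1] * x[1];
    f[0] = -4.0 * p[0] * x[0] * s / (p[1] * p[1]);
    f[1] = -p[2] * x[1];
    break;
  }
  case 4: {
    double s = (x[0] / p[1]) * (x[0] / p[1]) - 1.0;
    double t = (x[1] / p[3]) * (x[1] / p[3]) - 1.0;
    e = p[0] * s * s + p[2] * t * t;
    f[0] = -4.0 * p[0] * x[0] * s / (p[1] * p[1]);
    f[1] = -4.0 * p[2] * x[1] * t / (p[3] * p[3]);
    break;
  }
  case 5: {
    double s = (x[0] / p[1]) * (x[0] / p[1]) - 1.0;
    e = p[0] * s * s + 0.5 * p[2] * x[1] * x[1] +
      p[3] * x[0] * x[0] * x[1] * x[1];
    f[0] = -4.0 * p[0] * x[0] * s / (p[1] * p[1]) -
      2.0 * p[3] * x[0] * x[1] * x[1];
    f[1] = -p[2] * x[1] - 2.0 * p[3] * x[0] * x[0] * x[1];
    break;
  }
  default:
    stop("unknown surface form code");
  }
  return e;
}

// BAOAB Langevin integrator with optional per-axis harmonic bias.
// Uses R's RNG (norm_rand), so set.seed() in R fixes the trajectory.
// [[Rcpp::export]]
NumericMatrix langevin_kernel(int form, NumericVector params, NumericVector x0,
                              int n_sample, int stride, int n_discard,
                              double dt, double kT, double friction,
                              double mass, NumericVector bias_center,
                              NumericVector bias_k) {
  const int dim = x0.size();
  if (dim < 1 || dim > 2) stop("kernel supports 1 or 2 dimensions");
  double x[2], v[2], f[2], fb[2];
  for (int d = 0; d < dim; ++d) {
    x[d] = x0[d];
    v[d] = (kT > 0.0) ? std::sqrt(kT / mass) * norm_rand() : 0.0;
  }
  const double c1 = std::exp(-friction * dt);
  const double c2 = (kT > 0.0) ? std::sqrt((1.0 - c1 * c1) * kT / mass) : 0.0;
  eval_force(form, params.begin(), x, dim, f);
  for (int d = 0; d < dim; ++d)
    f[d] -= bias_k[d] * (x[d] - bias_center[d]);

  NumericMatrix out(n_sample, dim);
  const long total = (long)n_discard + (long)n_sample * stride;
  long kept = 0;
  for (long step = 1; step <= total; ++step) {
    for (int d = 0; d < dim; ++d) {
      v[d] += 0.5 * dt * f[d] / mass;
      x[d] += 0.5 * dt * v[d];
      v[d] = c1 * v[d] + c2 * norm_rand();
      x[d] += 0.5 * dt * v[d];
    }
    double e = eval_force(form, params.begin(), x, dim, f);
    for (int d = 0; d < dim; ++d) {
      fb[d] = bias_k[d] * (x[d] - bias_center[d]);
      e += 0.5 * bias_k[d] * (x[d] - bias_center[d]) * (x[d] - bias_center[d]);
      f[d] -= fb[d];
      v[d] += 0.5 * dt * f[d] / mass;
    }
    if (!std::isfinite(e) || e > 1e10)
      stop("Langevin trajectory diverged (energy overflow at step %ld)", step);
    if (step > n_discard && ((step - n_discard) % stride) == 0) {
      for (int d = 0; d < dim; ++d) out(kept, d) = x[d];
      ++kept;
    }
  }
  return out;
}
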