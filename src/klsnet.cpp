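#include <Rcpp.h>
using namespace Rcpp;

// Diffusion-bandwidth fixed point of Botev, Grotowski & Kroese (2010).
// a2: squared (halved) DCT-II coefficients of the binned sample, without the
// DC term; N: effective sample size; t is squared bandwidth on the unit-range
// scale. Evaluates t - xi * gamma^[l](t) with the usual l = 7 stages.
// sum_i I^s a2_i exp(-I pi^2 t), I = i^2, as one exponential per term
// (exp(s log I - I pi^2 t) * a2_i); terms are abandoned once they stop
// contributing at double precision.
static double stage_sum(const double t, const int s,
                        const std::vector<double>& a2,
                        const std::vector<double>& logI) {
  const int m = a2.size();
  const double pi2t = M_PI * M_PI * t;
  double f = 0.0;
  int tiny_run = 0;
  for (int i = 1; i <= m; ++i) {
    if (a2[i - 1] == 0.0) continue;
    const double I = static_cast<double>(i) * i;
    const double e = s * logI[i - 1] - I * pi2t;
    if (e < -745.0) {
      // decaying region once the quadratic term dominates
      if (I * pi2t > s) break;
      continue;
    }
    const double term = a2[i - 1] * std::exp(e);
    f += term;
    if (term < f * 1e-17 && I * pi2t > s) {
      if (++tiny_run >= 4) break;
    } else tiny_run = 0;
  }
  return f;
}

static double fixed_point(const double t, const double N,
                          const std::vector<double>& a2,
                          const std::vector<double>& logI, const int l) {
  const double pi = M_PI;
  double f = 2.0 * std::pow(pi, 2.0 * l) * stage_sum(t, l, a2, logI);
  for (int s = l - 1; s >= 2; --s) {
    double K0 = 1.0;
    for (int k = 1; k <= 2 * s - 1; k += 2) K0 *= k;
    K0 /= std::sqrt(2.0 * pi);
    const double cst = (1.0 + std::pow(0.5, s + 0.5)) / 3.0;
    const double time = std::pow(2.0 * cst * K0 / (N * f), 2.0 / (3.0 + 2.0 * s));
    f = 2.0 * std::pow(pi, 2.0 * s) * stage_sum(time, s, a2, logI);
  }
  return t - std::pow(2.0 * N * std::sqrt(pi) * f, -0.4);
}

// [[Rcpp::export(name = ".cpp_botev_root")]]
double cpp_botev_root(NumericVector a2, double N, int l = 7) {
  std::vector<double> a2v(a2.begin(), a2.end());
  const int m = a2v.size();
  std::vector<double> logI(m);
  for (int i = 1; i <= m; ++i)
    logI[i - 1] = std::log(static_cast<double>(i) * i);
  // bracket the smallest root by scanning t geometrically, then bisect
  double t_lo = NA_REAL, t_hi = NA_REAL, f_lo = NA_REAL;
  double prev_t = 1e-12;
  double prev_f = fixed_point(prev_t, N, a2v, logI, l);
  if (!std::isfinite(prev_f)) return NA_REAL;
  for (double t = 8e-12; t <= 0.2; t *= 8.0) {
    const double ft = fixed_point(t, N, a2v, logI, l);
    if (!std::isfinite(ft)) return NA_REAL;
    if ((prev_f < 0.0 && ft >= 0.0) || (prev_f > 0.0 && ft <= 0.0)) {
      t_lo = prev_t; t_hi = t; f_lo = prev_f;
      break;
    }
    prev_t = t; prev_f = ft;
  }
  if (!std::isfinite(t_lo)) return NA_REAL;  // caller falls back to Silverman
  for (int it = 0; it < 60; ++it) {
    const double mid = 0.5 * (t_lo + t_hi);
    const double f_mid = fixed_point(mid, N, a2v, logI, l);
    if ((f_lo <= 0.0) == (f_mid <= 0.0)) {
      t_lo = mid; f_lo = f_mid;
    } else {
      t_hi = mid;
    }
    if (t_hi - t_lo < 1e-9 * t_hi) break;
  }
  return 0.5 * (t_lo + t_hi);
}

// Gaussian smoothing of linear-binned counts: dens[j] = sum_i cnt[i] *
// dnorm((j - i) * step, sd = h). Contributions beyond 8 h are dropped;
// the caller renormalizes on the grid afterwards.
// [[Rcpp::export(name = ".cpp_gauss_smooth")]]
NumericVector cpp_gauss_smooth(NumericVector counts, double step, double h) {
  const int n = counts.size();
  NumericVector dens(n);
  const int half = std::min(n - 1, static_cast<int>(std::ceil(8.0 * h / step)));
  std::vector<double> kern(half + 1);
  const double norm = 1.0 / (h * std::sqrt(2.0 * M_PI));
  for (int d = 0; d <= half; ++d) {
    const double z = d * step / h;
    kern[d] = norm * std::exp(-0.5 * z * z);
  }
  for (int i = 0; i < n; ++i) {
    const double c = counts[i];
    if (c == 0.0) continue;
    const int j0 = std::max(0, i - half), j1 = std::min(n - 1, i + half);
    for (int j = j0; j <= j1; ++j) dens[j] += c * kern[std::abs(j - i)];
  }
  return dens;
}
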