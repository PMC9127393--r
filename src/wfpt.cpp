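#include <Rcpp.h>
using namespace Rcpp;

// First-passage-time density of a Wiener diffusion (unit diffusion
// coefficient) between absorbing boundaries 0 and a, start point w*a,
// drift v. Series-switching evaluation (small-time vs large-time
// expansion, term counts chosen from the standard truncation bounds).
// f_lower(t) is the defect density of absorption at the LOWER boundary.

static const double PI_ = 3.141592653589793238462643383280;

// standardized density f(u; 0, 1, w): drift 0, boundary 1, start w
static double fpt_std(double u, double w, double eps) {
  // choose number of terms for each expansion
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * PI_ * u) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u * std::log(2.0 * eps * std::sqrt(2.0 * PI_ * u)));
    ks = std::max(ks, std::sqrt(u) + 1.0);
  } else {
    ks = 2.0;
  }
  if (PI_ * u * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(PI_ * u * eps) / (PI_ * PI_ * u));
    kl = std::max(kl, 1.0 / (PI_ * std::sqrt(u)));
  } else {
    kl = 1.0 / (PI_ * std::sqrt(u));
  }
  double f = 0.0;
  if (ks < kl) {               // small-time expansion
    int K = (int)std::ceil(ks);
    int lo = -((K - 1) / 2), hi = (K - 1) / 2 + ((K - 1) % 2);
    for (int k = lo; k <= hi; ++k) {
      double z = w + 2.0 * k;
      f += z * std::exp(-z * z / (2.0 * u));
    }
    f /= std::sqrt(2.0 * PI_ * u * u * u);
  } else {                     // large-time expansion
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      f += k * std::exp(-k * k * PI_ * PI_ * u / 2.0) * std::sin(k * PI_ * w);
    }
    f *= PI_;
  }
  return f;
}

static double wfpt_lower(double t, double v, double a, double w, double eps) {
  if (t <= 0.0 || a <= 0.0 || w <= 0.0 || w >= 1.0) return 0.0;
  double u = t / (a * a);
  double f = fpt_std(u, w, eps);
  if (f < 0.0) f = 0.0; // series truncation can undershoot near 0
  return f * std::exp(-v * a * w - v * v * t / 2.0) / (a * a);
}

//' @noRd
// [[Rcpp::export(name = ".wfpt_pdf_cpp")]]
NumericVector wfpt_pdf_cpp(NumericVector t, LogicalVector upper,
                           NumericVector v, NumericVector a,
                           NumericVector tau, double w, double eps = 1e-10) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double vi = v[v.size() == 1 ? 0 : i];
    double ai = a[a.size() == 1 ? 0 : i];
    double ti = t[i] - tau[tau.size() == 1 ? 0 : i];
    if (ti <= 0.0 || ai <= 0.0) { out[i] = 0.0; continue; }
    if (upper[upper.size() == 1 ? 0 : i]) {
      out[i] = wfpt_lower(ti, -vi, ai, 1.0 - w, eps);
    } else {
      out[i] = wfpt_lower(ti, vi, ai, w, eps);
    }
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".wfpt_loglik_cpp")]]
double wfpt_loglik_cpp(NumericVector t, LogicalVector upper,
                       NumericVector v, NumericVector a,
                       NumericVector tau, double w, double eps = 1e-9) {
  int n = t.size();
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double vi = v[v.size() == 1 ? 0 : i];
    double ai = a[a.size() == 1 ? 0 : i];
    double taui = tau[tau.size() == 1 ? 0 : i];
    if (ai <= 0.0 || taui < 0.0) return R_NegInf;
    double ti = t[i] - taui;
    if (ti <= 0.0) return R_NegInf;
    double f;
    if (upper[upper.size() == 1 ? 0 : i]) {
      f = wfpt_lower(ti, -vi, ai, 1.0 - w, eps);
    } else {
      f = wfpt_lower(ti, vi, ai, w, eps);
    }
    if (f <= 0.0 || !R_finite(f)) return R_NegInf;
    ll += std::log(f);
  }
  return ll;
}

// Euler-Maruyama diffusion simulator with Brownian-bridge crossing
// correction (probability of an intra-step boundary hit), which removes
// the leading discretisation bias of the naive scheme.
//' @noRd
// [[Rcpp::export(name = ".ddm_sim_cpp")]]
List ddm_sim_cpp(NumericVector v, NumericVector a, NumericVector tau,
                 double w, double dt, int n) {
  NumericVector rt(n);
  LogicalVector up(n);
  RNGScope scope;
  double sdt = std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double vi = v[v.size() == 1 ? 0 : i];
    double ai = a[a.size() == 1 ? 0 : i];
    double taui = tau[tau.size() == 1 ? 0 : i];
    double x = 0.5 * ai;
    double t = 0.0;
    bool hit_up = false;
    for (;;) {
      double xn = x + vi * dt + sdt * norm_rand();
      t += dt;
      if (xn >= ai) { hit_up = true; break; }
      if (xn <= 0.0) { hit_up = false; break; }
      // bridge probability of touching a boundary inside the step
      double pu = std::exp(-2.0 * (ai - x) * (ai - xn) / dt);
      double pl = std::exp(-2.0 * x * xn / dt);
      double u = unif_rand();
      if (u < pu) { hit_up = true; break; }
      if (u < pu + pl) { hit_up = false; break; }
      x = xn;
      if (t > 60.0) { t = NA_REAL; break; } // pathological parameters
    }
    rt[i] = R_finite(t) ? (t - 0.5 * dt + taui) : NA_REAL;
    up[i] = hit_up;
  }
  return List::create(_["rt"] = rt, _["upper"] = up);
}
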