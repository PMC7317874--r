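// Numerical kernels: Gaussian-phase-distribution (GPD) attenuation for
// diffusion restricted in impermeable spheres (Murday-Cotts series), forward
// signal models, and a bounded multi-start Nelder-Mead least-squares fitter.
//
// Units at the interface: R in um, diffusivities in um^2/ms, G in mT/m,
// times in ms, b in s/mm^2. Conversions to SI happen internally.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double GAMMA = 2.6752219e8; // rad s^-1 T^-1

// sum_m C_m * bracket_m / lambda_m^2 for a rectangular pulse pair of width
// delta and separation Delta (seconds), sphere radius R_si (m), diffusivity
// D_si (m^2/s). Attenuation = exp(-2 gamma^2 G_si^2 * sum). Series cut when a
// term's relative contribution drops below 1e-12 (max over supplied roots).
static double gpd_time_sum(double R_si, double D_si, double delta_s,
                           double Delta_s, const std::vector<double>& mu) {
  double acc = 0.0;
  const double R2 = R_si * R_si;
  for (size_t m = 0; m < mu.size(); ++m) {
    const double mu2 = mu[m] * mu[m];
    const double lam = mu2 * D_si / R2;           // 1/s
    const double C   = R2 / (mu2 * (mu2 - 2.0));  // m^2
    const double ld = lam * delta_s, lD = lam * Delta_s;
    const double br = 2.0 * (ld - 1.0 + std::exp(-ld))
                    + 2.0 * std::exp(-lD)
                    - std::exp(-(lD - ld)) - std::exp(-(lD + ld));
    const double term = C * br / (lam * lam);
    acc += term;
    if (m >= 2 && term < 1e-12 * acc) break;
  }
  return acc; // m^2 s^2
}

// [[Rcpp::export]]
NumericVector cpp_sphere_attn(double R, double Di, NumericVector G,
                              NumericVector delta_eff, NumericVector Delta,
                              NumericVector roots) {
  const double R_si = R * 1e-6, D_si = Di * 1e-9;
  std::vector<double> mu(roots.begin(), roots.end());
  const int n = G.size();
  NumericVector out(n);
  for (int j = 0; j < n; ++j) {
    if (G[j] == 0.0) { out[j] = 1.0; continue; }
    const double T = gpd_time_sum(R_si, D_si, delta_eff[j] * 1e-3,
                                  Delta[j] * 1e-3, mu);
    const double Gsi = G[j] * 1e-3;
    out[j] = std::exp(-2.0 * GAMMA * GAMMA * Gsi * Gsi * T);
  }
  return out;
}

// Protocol cache: unique (delta_eff, Delta) timings so the root sum is
// evaluated once per timing, not once per gradient amplitude.
struct Proto {
  std::vector<double> G_si;   // T/m
  std::vector<double> b_ms;   // b * 1e-3 so exp(-b_ms * D[um^2/ms]) is direct
  std::vector<int> tid;       // index into timing table
  std::vector<double> ud_s, uD_s; // unique delta_eff, Delta in seconds
  int n;
};

static Proto make_proto(NumericVector G, NumericVector b, IntegerVector tid,
                        NumericVector udelta, NumericVector uDelta) {
  Proto p;
  p.n = G.size();
  p.G_si.resize(p.n); p.b_ms.resize(p.n); p.tid.resize(p.n);
  for (int j = 0; j < p.n; ++j) {
    p.G_si[j] = G[j] * 1e-3;
    p.b_ms[j] = b[j] * 1e-3;
    p.tid[j] = tid[j];
  }
  for (int u = 0; u < udelta.size(); ++u) {
    p.ud_s.push_back(udelta[u] * 1e-3);
    p.uD_s.push_back(uDelta[u] * 1e-3);
  }
  return p;
}

// model ids
enum { MODEL_TID = 0, MODEL_MM4 = 1, MODEL_MM3 = 2 };

// Predict the normalised signal at measurement j for the given model.
// par layouts: TID {Dprime}; MM4 {R, Di, De, fi}; MM3 {R, De, fi} (Di fixed).
static void predict(int model, const double* par, double fixed_di,
                    const Proto& p, const std::vector<double>& mu,
                    std::vector<double>& out) {
  if (model == MODEL_TID) {
    for (int j = 0; j < p.n; ++j) out[j] = std::exp(-p.b_ms[j] * par[0]);
    return;
  }
  const double R = par[0];
  const double Di = (model == MODEL_MM4) ? par[1] : fixed_di;
  const double De = (model == MODEL_MM4) ? par[2] : par[1];
  const double fi = (model == MODEL_MM4) ? par[3] : par[2];
  const double R_si = R * 1e-6, D_si = Di * 1e-9;
  std::vector<double> T(p.ud_s.size());
  for (size_t u = 0; u < p.ud_s.size(); ++u)
    T[u] = gpd_time_sum(R_si, D_si, p.ud_s[u], p.uD_s[u], mu);
  for (int j = 0; j < p.n; ++j) {
    const double attn = (p.G_si[j] == 0.0) ? 1.0
      : std::exp(-2.0 * GAMMA * GAMMA * p.G_si[j] * p.G_si[j] * T[p.tid[j]]);
    out[j] = fi * attn + (1.0 - fi) * std::exp(-p.b_ms[j] * De);
  }
}

// [[Rcpp::export]]
NumericVector cpp_predict(int model, NumericVector par, double fixed_di,
                          NumericVector G, NumericVector b, IntegerVector tid,
                          NumericVector udelta, NumericVector uDelta,
                          NumericVector roots) {
  Proto p = make_proto(G, b, tid, udelta, uDelta);
  std::vector<double> mu(roots.begin(), roots.end());
  std::vector<double> out(p.n);
  predict(model, REAL(par), fixed_di, p, mu, out);
  return NumericVector(out.begin(), out.end());
}

struct Objective {
  int model;
  double fixed_di;
  const Proto* proto;
  const std::vector<double>* mu;
  const std::vector<int>* keep;      // 0-based retained indices
  const std::vector<double>* y;      // observed, full length
  const std::vector<double>* lb, *ub;
  mutable std::vector<double> pred;
  mutable long neval = 0;

  // logistic map from unconstrained t to the bounded box
  void to_box(const double* t, double* par, int npar) const {
    for (int i = 0; i < npar; ++i)
      par[i] = (*lb)[i] + ((*ub)[i] - (*lb)[i]) / (1.0 + std::exp(-t[i]));
  }
  double operator()(const double* t, int npar) const {
    double par[4];
    to_box(t, par, npar);
    predict(model, par, fixed_di, *proto, *mu, pred);
    double sse = 0.0;
    for (size_t k = 0; k < keep->size(); ++k) {
      const int j = (*keep)[k];
      const double r = pred[j] - (*y)[j];
      sse += r * r;
    }
    ++neval;
    return sse;
  }
};

// Nelder-Mead on the unconstrained (logistic-transformed) space.
// Stops when both the function spread and the simplex parameter spread fall
// below tol (relative), or at maxeval evaluations.
static double nelder_mead(const Objective& f, std::vector<double>& t,
                          double tol, int maxeval, bool& converged) {
  const int n = (int)t.size();
  const int m = n + 1;
  std::vector<std::vector<double>> simp(m, t);
  std::vector<double> fv(m);
  for (int i = 1; i < m; ++i)
    simp[i][i - 1] += (simp[i][i - 1] != 0.0) ? 0.10 * std::fabs(simp[i][i - 1]) + 0.25 : 0.25;
  for (int i = 0; i < m; ++i) fv[i] = f(simp[i].data(), n);
  long start_eval = f.neval;
  converged = false;
  std::vector<double> cen(n), xr(n), xe(n), xc(n);
  while (f.neval - start_eval < maxeval) {
    // order
    std::vector<int> ord(m);
    for (int i = 0; i < m; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b){ return fv[a] < fv[b]; });
    std::vector<std::vector<double>> s2(m);
    std::vector<double> f2(m);
    for (int i = 0; i < m; ++i) { s2[i] = simp[ord[i]]; f2[i] = fv[ord[i]]; }
    simp.swap(s2); fv.swap(f2);
    // convergence
    double fspread = std::fabs(fv[m - 1] - fv[0]);
    double xspread = 0.0;
    for (int i = 1; i < m; ++i)
      for (int k = 0; k < n; ++k)
        xspread = std::max(xspread, std::fabs(simp[i][k] - simp[0][k]));
    if (fspread <= tol * (std::fabs(fv[0]) + 1e-12) && xspread <= tol) {
      converged = true; break;
    }
    // centroid of best n
    for (int k = 0; k < n; ++k) {
      double c = 0.0;
      for (int i = 0; i < n; ++i) c += simp[i][k];
      cen[k] = c / n;
    }
    for (int k = 0; k < n; ++k) xr[k] = cen[k] + (cen[k] - simp[n][k]);
    double fr = f(xr.data(), n);
    if (fr < fv[0]) {
      for (int k = 0; k < n; ++k) xe[k] = cen[k] + 2.0 * (cen[k] - simp[n][k]);
      double fe = f(xe.data(), n);
      if (fe < fr) { simp[n] = xe; fv[n] = fe; }
      else { simp[n] = xr; fv[n] = fr; }
    } else if (fr < fv[n - 1]) {
      simp[n] = xr; fv[n] = fr;
    } else {
      bool outside = fr < fv[n];
      if (outside) {
        for (int k = 0; k < n; ++k) xc[k] = cen[k] + 0.5 * (cen[k] - simp[n][k]);
        double fc = f(xc.data(), n);
        if (fc <= fr) { simp[n] = xc; fv[n] = fc; continue; }
      } else {
        for (int k = 0; k < n; ++k) xc[k] = cen[k] - 0.5 * (cen[k] - simp[n][k]);
        double fc = f(xc.data(), n);
        if (fc < fv[n]) { simp[n] = xc; fv[n] = fc; continue; }
      }
      // shrink
      for (int i = 1; i < m; ++i) {
        for (int k = 0; k < n; ++k)
          simp[i][k] = simp[0][k] + 0.5 * (simp[i][k] - simp[0][k]);
        fv[i] = f(simp[i].data(), n);
      }
    }
  }
  // final best
  int best = 0;
  for (int i = 1; i < m; ++i) if (fv[i] < fv[best]) best = i;
  t = simp[best];
  return fv[best];
}

// Multi-start bounded least-squares fit of one voxel.
// starts: matrix (n_starts x npar) of start points inside the box.
// Returns the best-of-starts parameters (box scale), SSE, and diagnostics.
// [[Rcpp::export]]
List cpp_fit_voxel(NumericVector y, IntegerVector keep, int model,
                   double fixed_di, NumericMatrix starts, NumericVector lb,
                   NumericVector ub, NumericVector G, NumericVector b,
                   IntegerVector tid, NumericVector udelta,
                   NumericVector uDelta, NumericVector roots,
                   double tol = 1e-6, int maxeval = 2000) {
  Proto proto = make_proto(G, b, tid, udelta, uDelta);
  std::vector<double> mu(roots.begin(), roots.end());
  std::vector<int> kp(keep.begin(), keep.end());
  std::vector<double> yy(y.begin(), y.end());
  std::vector<double> lbv(lb.begin(), lb.end()), ubv(ub.begin(), ub.end());
  const int npar = lb.size();

  Objective f;
  f.model = model; f.fixed_di = fixed_di; f.proto = &proto; f.mu = &mu;
  f.keep = &kp; f.y = &yy; f.lb = &lbv; f.ub = &ubv;
  f.pred.resize(proto.n);

  double best_sse = std::numeric_limits<double>::infinity();
  std::vector<double> best_t(npar, 0.0);
  bool any_conv = false;
  for (int s = 0; s < starts.nrow(); ++s) {
    std::vector<double> t(npar);
    for (int k = 0; k < npar; ++k) {
      double frac = (starts(s, k) - lbv[k]) / (ubv[k] - lbv[k]);
      frac = std::min(std::max(frac, 1e-9), 1.0 - 1e-9);
      t[k] = std::log(frac / (1.0 - frac));
    }
    bool conv = false;
    double sse = nelder_mead(f, t, tol, maxeval, conv);
    if (sse < best_sse) { best_sse = sse; best_t = t; any_conv = conv; }
    else if (sse == best_sse && conv) any_conv = true;
  }
  NumericVector par(npar);
  {
    double tmp[4];
    f.to_box(best_t.data(), tmp, npar);
    for (int k = 0; k < npar; ++k) par[k] = tmp[k];
  }
  return List::create(_["par"] = par, _["rss"] = best_sse,
                      _["converged"] = any_conv, _["neval"] = (double)f.neval);
}
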