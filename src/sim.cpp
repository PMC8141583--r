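#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Value-function kinds share integer codes with the R side:
// 0 linear, 1 output_saturation, 2 component_saturation,
// 3 gaussian_complexity.  Constants are packed flat:
//   output_saturation:    [alpha, beta]
//   component_saturation: [alpha1, beta1, alpha2, beta2]
//   gaussian_complexity:  [center, width, theta]  (theta precomputed in R)

static inline double eval_mu(int kind, const double* k,
                             double w1, double w2, double u1, double u2) {
  switch (kind) {
  case 0: return w1 * u1 + w2 * u2;
  case 1: return std::tanh(k[0] * (w1 * u1 + w2 * u2 - k[1]) / 2.0);
  case 2: return std::tanh(k[0] * (w1 * u1 - k[1]) / 2.0) +
                 std::tanh(k[2] * (w2 * u2 - k[3]) / 2.0);
  case 3: {
    double d = u2 - k[0];
    return w1 * (-1.0 + 2.0 * u1) +
           w2 * (std::exp(-d * d / (2.0 * k[1] * k[1])) - k[2]);
  }
  }
  return NA_REAL;
}

static inline void grad_mu(int kind, const double* k,
                           double w1, double w2, double u1, double u2,
                           double* g) {
  switch (kind) {
  case 0: g[0] = u1; g[1] = u2; return;
  case 1: {
    double t = std::tanh(k[0] * (w1 * u1 + w2 * u2 - k[1]) / 2.0);
    double f = 0.5 * k[0] * (1.0 - t * t);
    g[0] = f * u1; g[1] = f * u2; return;
  }
  case 2: {
    double t1 = std::tanh(k[0] * (w1 * u1 - k[1]) / 2.0);
    double t2 = std::tanh(k[2] * (w2 * u2 - k[3]) / 2.0);
    g[0] = 0.5 * k[0] * u1 * (1.0 - t1 * t1);
    g[1] = 0.5 * k[2] * u2 * (1.0 - t2 * t2);
    return;
  }
  case 3: {
    double d = u2 - k[0];
    g[0] = -1.0 + 2.0 * u1;
    g[1] = std::exp(-d * d / (2.0 * k[1] * k[1])) - k[2];
    return;
  }
  }
}

// Gaussian truncated to [0,1] by rejection; acceptance > 0.99 at sd = 1/6.
static inline double rtrunc01(double mean, double sd) {
  if (sd <= 0.0) return mean;
  for (int i = 0; i < 100000; ++i) {
    double x = R::rnorm(mean, sd);
    if (x >= 0.0 && x <= 1.0) return x;
  }
  return mean; // unreachable for sd <= 1
}

// [[Rcpp::export]]
NumericMatrix sample_stimulus_cpp(int n, NumericVector mean, double sd) {
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = rtrunc01(mean[0], sd);
    out(i, 1) = rtrunc01(mean[1], sd);
  }
  return out;
}

// Squared point-to-segment distance, writing the nearest point to (px, py).
static inline double seg_dist2(double x, double y,
                               double ax, double ay, double bx, double by,
                               double* px, double* py) {
  double dx = bx - ax, dy = by - ay;
  double L2 = dx * dx + dy * dy;
  double t = 0.0;
  if (L2 > 0.0) {
    t = ((x - ax) * dx + (y - ay) * dy) / L2;
    if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  }
  *px = ax + t * dx;
  *py = ay + t * dy;
  double ex = x - *px, ey = y - *py;
  return ex * ex + ey * ey;
}

// Closest point on the level set of mu(u : .) over a square weight grid,
// found by marching squares: every cell edge straddling the level
// contributes a linearly interpolated crossing, crossings are paired into
// segments, and the nearest segment point to (wx, wy) is kept.  If the
// level is outside the grid's value range it is clamped just inside
// (fallback flagged); the projection then lands on the nearest extreme
// isoline.
static bool grid_closest_point(int kind, const double* k,
                               double u1, double u2,
                               double level, double wx, double wy,
                               double lo, double hi, int res,
                               std::vector<double>& f,
                               double* ox, double* oy, bool* fallback) {
  const double step = (hi - lo) / (res - 1);
  double fmin = R_PosInf, fmax = R_NegInf;
  for (int j = 0; j < res; ++j) {       // j indexes w2
    double w2 = lo + j * step;
    for (int i = 0; i < res; ++i) {     // i indexes w1
      double v = eval_mu(kind, k, lo + i * step, w2, u1, u2);
      f[j * res + i] = v;
      if (v < fmin) fmin = v;
      if (v > fmax) fmax = v;
    }
  }
  *fallback = false;
  double eps = 1e-9 * (fmax - fmin > 0 ? fmax - fmin : 1.0);
  if (level <= fmin + eps) { level = fmin + eps; *fallback = true; }
  else if (level >= fmax - eps) { level = fmax - eps; *fallback = true; }

  double best = R_PosInf;
  bool found = false;
  double cx[4], cy[4];
  for (int j = 0; j < res - 1; ++j) {
    double y0 = lo + j * step, y1 = y0 + step;
    for (int i = 0; i < res - 1; ++i) {
      double x0 = lo + i * step, x1 = x0 + step;
      double f00 = f[j * res + i],       f10 = f[j * res + i + 1];
      double f01 = f[(j + 1) * res + i], f11 = f[(j + 1) * res + i + 1];
      int nc = 0;
      // bottom, right, top, left edges
      if ((f00 - level) * (f10 - level) < 0) {
        double t = (level - f00) / (f10 - f00);
        cx[nc] = x0 + t * step; cy[nc] = y0; ++nc;
      }
      if ((f10 - level) * (f11 - level) < 0) {
        double t = (level - f10) / (f11 - f10);
        cx[nc] = x1; cy[nc] = y0 + t * step; ++nc;
      }
      if ((f01 - level) * (f11 - level) < 0) {
        double t = (level - f01) / (f11 - f01);
        cx[nc] = x0 + t * step; cy[nc] = y1; ++nc;
      }
      if ((f00 - level) * (f01 - level) < 0) {
        double t = (level - f00) / (f01 - f00);
        cx[nc] = x0; cy[nc] = y0 + t * step; ++nc;
      }
      if (nc >= 2) {
        double px, py;
        double d2 = seg_dist2(wx, wy, cx[0], cy[0], cx[1], cy[1], &px, &py);
        if (d2 < best) { best = d2; *ox = px; *oy = py; found = true; }
        if (nc == 4) { // saddle cell: second segment from remaining pair
          d2 = seg_dist2(wx, wy, cx[2], cy[2], cx[3], cy[3], &px, &py);
          if (d2 < best) { best = d2; *ox = px; *oy = py; found = true; }
        }
      }
    }
  }
  return found;
}

// [[Rcpp::export]]
List run_sim_cpp(int n_iter, int thin, int tail_window,
                 int reward_kind, NumericVector reward_w,
                 NumericVector reward_consts, double noise_sd,
                 int value_kind, NumericVector value_consts,
                 int rule, int grad_kind, NumericVector grad_consts,
                 double eps, NumericVector w0,
                 NumericVector stim_mean, double stim_sd,
                 int motiv_form, double m_floor, double m_center,
                 double m_width,
                 NumericVector grid_bounds, int grid_res) {
  if (n_iter < 1) stop("n_iter must be >= 1");
  if (thin < 1) thin = 1;
  if (tail_window > n_iter) tail_window = n_iter;
  const int tail_start = n_iter - tail_window + 1;

  int n_store = 0;
  for (int t = 1; t <= n_iter; ++t)
    if (t % thin == 0 || t >= tail_start) ++n_store;

  IntegerVector s_t(n_store);
  NumericVector s_w1(n_store), s_w2(n_store), s_delta(n_store),
    s_ub(n_store), s_uc(n_store), s_r(n_store), s_m(n_store);

  const double* rk = reward_consts.size() ? REAL(reward_consts) : nullptr;
  const double* vk = value_consts.size() ? REAL(value_consts) : nullptr;
  const double* gk = grad_consts.size() ? REAL(grad_consts) : nullptr;
  const double rw1 = reward_w[0], rw2 = reward_w[1];
  const double glo = grid_bounds[0], ghi = grid_bounds[1];
  const double inv2mw2 = 1.0 / (2.0 * m_width * m_width);

  std::vector<double> fgrid;
  if (rule == 1 && value_kind != 0)
    fgrid.resize((size_t)grid_res * grid_res);

  double w1 = w0[0], w2 = w0[1];
  int phi_fallbacks = 0;
  int idx = 0;
  double g[2];

  for (int t = 1; t <= n_iter; ++t) {
    double u1 = rtrunc01(stim_mean[0], stim_sd);
    double u2 = rtrunc01(stim_mean[1], stim_sd);
    double mr = eval_mu(reward_kind, rk, rw1, rw2, u1, u2);
    double r = (noise_sd > 0.0) ? R::rnorm(mr, noise_sd) : mr;
    double mbar = (motiv_form == 0)
      ? 1.0
      : m_floor + (1.0 - m_floor) *
          std::exp(-(u2 - m_center) * (u2 - m_center) * inv2mw2);
    double mu = eval_mu(value_kind, vk, w1, w2, u1, u2);
    double delta = mbar * (r - mu);

    if (rule == 0) { // gradient (delta) rule
      grad_mu(grad_kind, gk, w1, w2, u1, u2, g);
      w1 += eps * delta * g[0];
      w2 += eps * delta * g[1];
    } else {         // shortest-path (Phi) rule
      // The step moves toward the closest point on the target isoline
      // with speed eps * mbar * |r - mu|.  Equivalently, the direction
      // multiplying the signed error carries the gradient's sign
      // convention (it equals the normalised gradient at the projected
      // point up to the sign of the error); pairing the signed error
      // with the raw geometric direction instead would push the weights
      // away from the isoline whenever the value overestimates the
      // reward, and diverges.
      double phx = 0.0, phy = 0.0;
      if (value_kind == 0) { // analytic orthogonal projection onto w.u = r
        double den = u1 * u1 + u2 * u2;
        if (den > 0.0) {
          double proj = (r - (w1 * u1 + w2 * u2)) / den;
          double dx = proj * u1, dy = proj * u2;
          double d = std::sqrt(dx * dx + dy * dy);
          if (d > 0.0) { phx = dx / d; phy = dy / d; }
        }
      } else {
        double ox, oy; bool fb;
        bool ok = grid_closest_point(value_kind, vk, u1, u2, r, w1, w2,
                                     glo, ghi, grid_res, fgrid, &ox, &oy, &fb);
        if (fb) ++phi_fallbacks;
        if (ok) {
          double dx = ox - w1, dy = oy - w2;
          double d = std::sqrt(dx * dx + dy * dy);
          if (d > 0.0) { phx = dx / d; phy = dy / d; }
        }
      }
      double speed = eps * mbar * std::fabs(r - mu);
      w1 += speed * phx;
      w2 += speed * phy;
    }

    if (!std::isfinite(w1) || !std::isfinite(w2) ||
        std::fabs(w1) > 1e6 || std::fabs(w2) > 1e6)
      stop("weight overflow at iteration %d (w = [%g, %g]); "
           "reduce the learning rate", t, w1, w2);

    if (t % thin == 0 || t >= tail_start) {
      s_t[idx] = t;
      s_w1[idx] = w1; s_w2[idx] = w2;
      s_delta[idx] = delta;
      s_ub[idx] = u1; s_uc[idx] = u2;
      s_r[idx] = r; s_m[idx] = mbar;
      ++idx;
    }
  }

  return List::create(
    _["t"] = s_t, _["w1"] = s_w1, _["w2"] = s_w2, _["delta"] = s_delta,
    _["u_b"] = s_ub, _["u_c"] = s_uc, _["r_star"] = s_r, _["m_bar"] = s_m,
    _["phi_fallbacks"] = phi_fallbacks, _["tail_start"] = tail_start);
}
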