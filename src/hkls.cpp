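#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline int clampi(int i, int n) { return i < 0 ? 0 : (i >= n ? n - 1 : i); }

// Sliding min/max filter with a w x w square window (w odd).
// pad_na = true: window clipped at the image border (border values ignored);
// pad_na = false: out-of-image samples take the value `pad`.
// Separability of min/max over a square window makes this two 1-D passes.
// [[Rcpp::export]]
NumericMatrix window_filter_cpp(NumericMatrix x, int w, bool maximum,
                                double pad, bool pad_na) {
  int H = x.nrow(), W = x.ncol(), h = w / 2;
  NumericMatrix tmp(H, W), out(H, W);
  // pass 1: along rows (vertical window)
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double best = NA_REAL;
      bool init = false;
      for (int k = -h; k <= h; ++k) {
        int ii = i + k;
        double v;
        if (ii < 0 || ii >= H) {
          if (pad_na) continue;
          v = pad;
        } else v = x(ii, j);
        if (!init) { best = v; init = true; }
        else best = maximum ? std::max(best, v) : std::min(best, v);
      }
      tmp(i, j) = best;
    }
  }
  // pass 2: along columns (horizontal window)
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      double best = NA_REAL;
      bool init = false;
      for (int k = -h; k <= h; ++k) {
        int jj = j + k;
        double v;
        if (jj < 0 || jj >= W) {
          if (pad_na) continue;
          v = pad;
        } else v = tmp(i, jj);
        if (!init) { best = v; init = true; }
        else best = maximum ? std::max(best, v) : std::min(best, v);
      }
      out(i, j) = best;
    }
  }
  return out;
}

// Separable Gaussian smoothing, kernel truncated at 4*sigma, replicate border.
// [[Rcpp::export]]
NumericMatrix gauss_blur_cpp(NumericMatrix x, double sigma) {
  int H = x.nrow(), W = x.ncol();
  int r = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &v : k) v /= s;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += k[d + r] * x(clampi(i + d, H), j);
      tmp(i, j) = acc;
    }
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += k[d + r] * tmp(i, clampi(j + d, W));
      out(i, j) = acc;
    }
  return out;
}

// 8- or 4-connected component labeling of a logical matrix.
// Labels are 1..n in scan order of each component's first pixel; background 0.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix m, int connectivity) {
  int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  int nn = (connectivity == 8) ? 8 : 4;
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!m(i, j) || lab(i, j)) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * H);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % H, pj = p / H;
        for (int q = 0; q < nn; ++q) {
          int ni = pi + dr[q], nj = pj + dc[q];
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (m(ni, nj) && !lab(ni, nj)) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * H);
          }
        }
      }
    }
  return lab;
}

// Directed Hausdorff distance: max over rows of `a` of the Euclidean distance
// to the nearest row of `b` (n x 2 point matrices), with early-break scan.
// [[Rcpp::export]]
double hausdorff_directed_cpp(NumericMatrix a, NumericMatrix b) {
  int na = a.nrow(), nb = b.nrow();
  double cmax = 0.0;
  for (int i = 0; i < na; ++i) {
    double cmin = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double dx = a(i, 0) - b(j, 0), dy = a(i, 1) - b(j, 1);
      double d2 = dx * dx + dy * dy;
      if (d2 < cmin) {
        cmin = d2;
        if (cmin <= cmax) break; // cannot raise the max
      }
    }
    if (cmin > cmax && R_finite(cmin)) cmax = cmin;
  }
  return std::sqrt(cmax);
}

// ---- DRLSE --------------------------------------------------------------
// Explicit gradient flow:
//   phi += dt * ( mu * distreg(phi)
//               + lam * dirac(phi) * div(g * grad(phi)/|grad(phi)|)
//               + alpha * g * dirac(phi) )
// distreg uses the double-well potential p with wells at |grad phi| = 0, 1:
//   p(s) = (1/(2 pi)^2)(1 - cos 2 pi s), s <= 1;  (1/2)(s-1)^2, s >= 1
//   d_p(s) = p'(s)/s, d_p(0) = 1.
// Replicate (zero normal derivative) boundary condition applied each step,
// central-difference gradients, 5-point Laplacian.  No reinitialization.

static void neumann(NumericMatrix &f) {
  int H = f.nrow(), W = f.ncol();
  if (H < 3 || W < 3) return;
  for (int j = 0; j < W; ++j) { f(0, j) = f(2, j); f(H - 1, j) = f(H - 3, j); }
  for (int i = 0; i < H; ++i) { f(i, 0) = f(i, 2); f(i, W - 1) = f(i, W - 3); }
}

// central differences, one-sided at borders (MATLAB gradient convention)
static void grad_central(const NumericMatrix &f, NumericMatrix &gr,
                         NumericMatrix &gc) {
  int H = f.nrow(), W = f.ncol();
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      int ip = (i == H - 1) ? i : i + 1, im = (i == 0) ? i : i - 1;
      int jp = (j == W - 1) ? j : j + 1, jm = (j == 0) ? j : j - 1;
      gr(i, j) = (f(ip, j) - f(im, j)) / (double)(ip - im);
      gc(i, j) = (f(i, jp) - f(i, jm)) / (double)(jp - jm);
    }
}

static inline double dirac_eps(double x, double eps) {
  if (std::fabs(x) > eps) return 0.0;
  return (1.0 / (2.0 * eps)) * (1.0 + std::cos(M_PI * x / eps));
}

static inline double heaviside_eps(double x, double eps) {
  if (x > eps) return 1.0;
  if (x < -eps) return 0.0;
  return 0.5 * (1.0 + x / eps + std::sin(M_PI * x / eps) / M_PI);
}

// [[Rcpp::export]]
List drlse_run_cpp(NumericMatrix phi0, NumericMatrix g, double mu, double lam,
                   double alpha, double eps, double dt, int n_iter,
                   bool early_stop, int early_window, double early_tol,
                   bool track_energy) {
  int H = phi0.nrow(), W = phi0.ncol();
  NumericMatrix phi = clone(phi0);
  NumericMatrix vr(H, W), vc(H, W);         // grad of g
  grad_central(g, vr, vc);
  NumericMatrix pr(H, W), pc(H, W), nr(H, W), nc(H, W);
  NumericMatrix fr(H, W), fc(H, W), dvr(H, W), dvc(H, W);
  std::vector<double> area, energy;
  area.reserve(n_iter);
  if (track_energy) energy.reserve(n_iter);
  int bad_iter = -1, iters_done = 0;
  const double tiny = 1e-10, twopi = 2.0 * M_PI;

  for (int it = 0; it < n_iter; ++it) {
    neumann(phi);
    grad_central(phi, pr, pc);
    // distance-regularization flux (d_p(s) - 1) * grad phi, plus Laplacian
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double s = std::sqrt(pr(i, j) * pr(i, j) + pc(i, j) * pc(i, j));
        double ps = (s <= 1.0) ? std::sin(twopi * s) / twopi : (s - 1.0);
        double dps = ((ps != 0.0) ? ps : 1.0) / ((s != 0.0) ? s : 1.0);
        fr(i, j) = (dps - 1.0) * pr(i, j);
        fc(i, j) = (dps - 1.0) * pc(i, j);
        double sn = s + tiny;
        nr(i, j) = pr(i, j) / sn;
        nc(i, j) = pc(i, j) / sn;
      }
    grad_central(fr, dvr, dvc); NumericMatrix div_fr = clone(dvr);
    grad_central(fc, dvr, dvc); NumericMatrix div_fc = clone(dvc);
    grad_central(nr, dvr, dvc); NumericMatrix div_nr = clone(dvr);
    grad_central(nc, dvr, dvc); NumericMatrix div_nc = clone(dvc);

    bool bad = false;
    int inside = 0;
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        int ip = (i == H - 1) ? i : i + 1, im = (i == 0) ? i : i - 1;
        int jp = (j == W - 1) ? j : j + 1, jm = (j == 0) ? j : j - 1;
        double lap = phi(ip, j) + phi(im, j) + phi(i, jp) + phi(i, jm)
                     - 4.0 * phi(i, j);
        double distreg = div_fr(i, j) + div_fc(i, j) + lap;
        double curv = div_nr(i, j) + div_nc(i, j);
        double d = dirac_eps(phi(i, j), eps);
        double edge = d * (vr(i, j) * nr(i, j) + vc(i, j) * nc(i, j))
                      + d * g(i, j) * curv;
        double areaf = d * g(i, j);
        double nv = phi(i, j)
                    + dt * (mu * distreg + lam * edge + alpha * areaf);
        if (!std::isfinite(nv)) bad = true;
        phi(i, j) = nv;
        if (nv < 0.0) ++inside;
      }
    iters_done = it + 1;
    if (bad) { bad_iter = it + 1; break; }
    area.push_back((double)inside);
    if (track_energy) {
      // discrete energy with the same gradient discretization
      neumann(phi);
      grad_central(phi, pr, pc);
      double E = 0.0;
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          double s = std::sqrt(pr(i, j) * pr(i, j) + pc(i, j) * pc(i, j));
          double p = (s <= 1.0)
                         ? (1.0 - std::cos(twopi * s)) / (twopi * twopi)
                         : 0.5 * (s - 1.0) * (s - 1.0);
          double d = dirac_eps(phi(i, j), eps);
          E += mu * p + lam * g(i, j) * d * s
               + alpha * g(i, j) * heaviside_eps(-phi(i, j), eps);
        }
      energy.push_back(E);
    }
    if (early_stop && (int)area.size() > early_window) {
      double prev = area[area.size() - 1 - early_window];
      if (std::fabs(area.back() - prev) < early_tol) break;
    }
  }
  return List::create(_["phi"] = phi,
                      _["iterations"] = iters_done,
                      _["area_trace"] = wrap(area),
                      _["energy_trace"] = wrap(energy),
                      _["bad_iter"] = bad_iter);
}
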