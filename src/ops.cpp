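#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Parallel-beam multi-slice Joseph projector.
//
// Image: column-major (nx, ny, nz), in-plane pixel size (sx, sy) mm, grid
// centred on the origin: x_i = (i - (nx-1)/2) * sx. Slices are independent.
// Sinogram: (nrad, nang, nz); radial position of bin r is
// (r - (nrad-1)/2) * ds. A ray (theta, t) is the line
// { p : p.x*cos(theta) + p.y*sin(theta) = t }.
//
// Joseph's method: march along the axis most parallel to the ray and
// linearly interpolate across the other; step length is the in-plane path
// length per row/column. Forward and back share one loop body so the pair
// is an exact adjoint.

// [[Rcpp::export]]
NumericVector joseph_fwd(NumericVector img, int nx, int ny, int nz,
                         double sx, double sy,
                         NumericVector angles, int nrad, double ds) {
  const int nang = angles.size();
  NumericVector sino(static_cast<R_xlen_t>(nrad) * nang * nz);
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const double ct = (nrad - 1) / 2.0;
  const double *im = img.begin();
  double *sn = sino.begin();

  for (int a = 0; a < nang; ++a) {
    const double co = std::cos(angles[a]), si = std::sin(angles[a]);
    const bool march_y = std::fabs(co) >= std::fabs(si);
    const double step = march_y ? sy / std::fabs(co) : sx / std::fabs(si);
    for (int r = 0; r < nrad; ++r) {
      const double t = (r - ct) * ds;
      for (int k = 0; k < nz; ++k) {
        const double *imk = im + static_cast<R_xlen_t>(k) * nx * ny;
        double acc = 0.0;
        if (march_y) {
          for (int j = 0; j < ny; ++j) {
            const double y = (j - cy) * sy;
            const double x = (t - y * si) / co;
            const double u = x / sx + cx;
            const int i0 = static_cast<int>(std::floor(u));
            const double w = u - i0;
            if (i0 >= 0 && i0 < nx)
              acc += (1.0 - w) * imk[i0 + static_cast<R_xlen_t>(j) * nx];
            if (i0 + 1 >= 0 && i0 + 1 < nx)
              acc += w * imk[i0 + 1 + static_cast<R_xlen_t>(j) * nx];
          }
        } else {
          for (int i = 0; i < nx; ++i) {
            const double x = (i - cx) * sx;
            const double y = (t - x * co) / si;
            const double v = y / sy + cy;
            const int j0 = static_cast<int>(std::floor(v));
            const double w = v - j0;
            if (j0 >= 0 && j0 < ny)
              acc += (1.0 - w) * imk[i + static_cast<R_xlen_t>(j0) * nx];
            if (j0 + 1 >= 0 && j0 + 1 < ny)
              acc += w * imk[i + static_cast<R_xlen_t>(j0 + 1) * nx];
          }
        }
        sn[r + static_cast<R_xlen_t>(a) * nrad +
           static_cast<R_xlen_t>(k) * nrad * nang] = acc * step;
      }
    }
  }
  sino.attr("dim") = IntegerVector::create(nrad, nang, nz);
  return sino;
}

// [[Rcpp::export]]
NumericVector joseph_back(NumericVector sino, int nx, int ny, int nz,
                          double sx, double sy,
                          NumericVector angles, int nrad, double ds) {
  const int nang = angles.size();
  NumericVector img(static_cast<R_xlen_t>(nx) * ny * nz);
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const double ct = (nrad - 1) / 2.0;
  const double *sn = sino.begin();
  double *im = img.begin();

  for (int a = 0; a < nang; ++a) {
    const double co = std::cos(angles[a]), si = std::sin(angles[a]);
    const bool march_y = std::fabs(co) >= std::fabs(si);
    const double step = march_y ? sy / std::fabs(co) : sx / std::fabs(si);
    for (int r = 0; r < nrad; ++r) {
      const double t = (r - ct) * ds;
      for (int k = 0; k < nz; ++k) {
        double *imk = im + static_cast<R_xlen_t>(k) * nx * ny;
        const double val = step * sn[r + static_cast<R_xlen_t>(a) * nrad +
                                     static_cast<R_xlen_t>(k) * nrad * nang];
        if (val == 0.0) continue;
        if (march_y) {
          for (int j = 0; j < ny; ++j) {
            const double y = (j - cy) * sy;
            const double x = (t - y * si) / co;
            const double u = x / sx + cx;
            const int i0 = static_cast<int>(std::floor(u));
            const double w = u - i0;
            if (i0 >= 0 && i0 < nx)
              imk[i0 + static_cast<R_xlen_t>(j) * nx] += (1.0 - w) * val;
            if (i0 + 1 >= 0 && i0 + 1 < nx)
              imk[i0 + 1 + static_cast<R_xlen_t>(j) * nx] += w * val;
          }
        } else {
          for (int i = 0; i < nx; ++i) {
            const double x = (i - cx) * sx;
            const double y = (t - x * co) / si;
            const double v = y / sy + cy;
            const int j0 = static_cast<int>(std::floor(v));
            const double w = v - j0;
            if (j0 >= 0 && j0 < ny)
              imk[i + static_cast<R_xlen_t>(j0) * nx] += (1.0 - w) * val;
            if (j0 + 1 >= 0 && j0 + 1 < ny)
              imk[i + static_cast<R_xlen_t>(j0 + 1) * nx] += w * val;
          }
        }
      }
    }
  }
  img.attr("dim") = IntegerVector::create(nx, ny, nz);
  return img;
}

// Separable Gaussian convolution, zero-padded boundaries, kernel truncated
// at 4 sigma. sigma_vox given per axis in voxel units; sigma 0 skips an axis.
static void blur_axis(std::vector<double> &buf, std::vector<double> &tmp,
                      int nx, int ny, int nz, int axis, double sigma) {
  if (sigma <= 0.0) return;
  const int R = std::max(1, static_cast<int>(std::ceil(6.0 * sigma)));
  std::vector<double> kern(2 * R + 1);
  double ksum = 0.0;
  for (int t = -R; t <= R; ++t) {
    kern[t + R] = std::exp(-0.5 * t * t / (sigma * sigma));
    ksum += kern[t + R];
  }
  for (double &k : kern) k /= ksum;

  const int n[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, static_cast<R_xlen_t>(nx),
                              static_cast<R_xlen_t>(nx) * ny};
  const int o1 = (axis == 0) ? 1 : 0;
  const int o2 = (axis == 2) ? 1 : 2;
  const int na = n[axis];
  const R_xlen_t sa = stride[axis];

  for (int b = 0; b < n[o2]; ++b)
    for (int a = 0; a < n[o1]; ++a) {
      const R_xlen_t base = static_cast<R_xlen_t>(a) * stride[o1] +
                            static_cast<R_xlen_t>(b) * stride[o2];
      for (int p = 0; p < na; ++p) tmp[p] = buf[base + p * sa];
      for (int p = 0; p < na; ++p) {
        double acc = 0.0;
        const int lo = std::max(-R, -p), hi = std::min(R, na - 1 - p);
        for (int t = lo; t <= hi; ++t) acc += kern[t + R] * tmp[p + t];
        buf[base + p * sa] = acc;
      }
    }
}

// [[Rcpp::export]]
NumericVector gauss_blur_cpp(NumericVector img, int nx, int ny, int nz,
                             double sig_x, double sig_y, double sig_z) {
  std::vector<double> buf(img.begin(), img.end());
  std::vector<double> tmp(std::max(nx, std::max(ny, nz)));
  blur_axis(buf, tmp, nx, ny, nz, 0, sig_x);
  blur_axis(buf, tmp, nx, ny, nz, 1, sig_y);
  blur_axis(buf, tmp, nx, ny, nz, 2, sig_z);
  NumericVector out(buf.begin(), buf.end());
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// Bowsher neighbour selection: for each voxel, the n in-bounds neighbours
// (from the given offset list, canonical order) with the smallest absolute
// anatomical difference; ties resolved by offset order (stable sort).
// Returns 0-based linear neighbour indices (-1 = unavailable) and the pair
// weights 1/||offset|| of the selected offsets.
// [[Rcpp::export]]
List bowsher_select_cpp(NumericVector anat, int nx, int ny, int nz,
                        IntegerMatrix offsets, int nsel) {
  const int K = offsets.nrow();
  const R_xlen_t nvox = static_cast<R_xlen_t>(nx) * ny * nz;
  IntegerMatrix idx(nvox, nsel);
  NumericMatrix wsel(nvox, nsel);
  std::vector<double> woff(K);
  for (int m = 0; m < K; ++m) {
    const double d = std::sqrt(double(offsets(m, 0) * offsets(m, 0) +
                                      offsets(m, 1) * offsets(m, 1) +
                                      offsets(m, 2) * offsets(m, 2)));
    woff[m] = 1.0 / d;
  }
  std::vector<int> cand(K);
  std::vector<double> diff(K);
  std::vector<int> ord(K);
  const double *an = anat.begin();

  R_xlen_t v = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++v) {
        int nc = 0;
        for (int m = 0; m < K; ++m) {
          const int ii = i + offsets(m, 0), jj = j + offsets(m, 1),
                    kk = k + offsets(m, 2);
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          const R_xlen_t nb = ii + static_cast<R_xlen_t>(jj) * nx +
                              static_cast<R_xlen_t>(kk) * nx * ny;
          cand[nc] = m;
          diff[nc] = std::fabs(an[v] - an[nb]);
          ++nc;
        }
        for (int m = 0; m < nc; ++m) ord[m] = m;
        std::stable_sort(ord.begin(), ord.begin() + nc,
                         [&](int a, int b) { return diff[a] < diff[b]; });
        const int take = std::min(nsel, nc);
        for (int m = 0; m < nsel; ++m) {
          if (m < take) {
            const int off = cand[ord[m]];
            const R_xlen_t nb =
                (i + offsets(off, 0)) +
                static_cast<R_xlen_t>(j + offsets(off, 1)) * nx +
                static_cast<R_xlen_t>(k + offsets(off, 2)) * nx * ny;
            idx(v, m) = static_cast<int>(nb);
            wsel(v, m) = woff[off];
          } else {
            idx(v, m) = -1;
            wsel(v, m) = 0.0;
          }
        }
      }
  return List::create(_["idx"] = idx, _["w"] = wsel);
}

// Full (non-selective) neighbour graph for a set of offsets: every in-bounds
// neighbour in canonical order. Same layout as bowsher_select_cpp.
// [[Rcpp::export]]
List full_graph_cpp(int nx, int ny, int nz, IntegerMatrix offsets) {
  const int K = offsets.nrow();
  const R_xlen_t nvox = static_cast<R_xlen_t>(nx) * ny * nz;
  IntegerMatrix idx(nvox, K);
  NumericMatrix wsel(nvox, K);
  std::vector<double> woff(K);
  for (int m = 0; m < K; ++m) {
    const double d = std::sqrt(double(offsets(m, 0) * offsets(m, 0) +
                                      offsets(m, 1) * offsets(m, 1) +
                                      offsets(m, 2) * offsets(m, 2)));
    woff[m] = 1.0 / d;
  }
  R_xlen_t v = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++v) {
        int nc = 0;
        for (int m = 0; m < K; ++m) {
          const int ii = i + offsets(m, 0), jj = j + offsets(m, 1),
                    kk = k + offsets(m, 2);
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          idx(v, nc) = static_cast<int>(ii + static_cast<R_xlen_t>(jj) * nx +
                                        static_cast<R_xlen_t>(kk) * nx * ny);
          wsel(v, nc) = woff[m];
          ++nc;
        }
        for (int m = nc; m < K; ++m) {
          idx(v, m) = -1;
          wsel(v, m) = 0.0;
        }
      }
  return List::create(_["idx"] = idx, _["w"] = wsel);
}

// Relative-difference pairwise penalty on a neighbour graph:
//   P = (beta/2) * sum_j sum_{k in N_j} w_jk (f_j-f_k)^2 /
//                                         (f_j+f_k+gamma|f_j-f_k|+eps)
// The 1/2 makes P equal the unordered-pair sum on symmetric graphs, so that
// RD with gamma=0 coincides with a Bowsher graph using the full
// neighbourhood. Returns the value and the exact analytic gradient
// (each pair term contributes to both of its endpoints).
// [[Rcpp::export]]
List rd_penalty_cpp(NumericVector f, IntegerMatrix idx, NumericMatrix w,
                    double gamma, double eps, double beta) {
  const R_xlen_t nvox = f.size();
  const int m = idx.ncol();
  NumericVector grad(nvox);
  NumericVector curv(nvox);
  double val = 0.0;
  const double *fp = f.begin();
  double *gp = grad.begin();
  double *cp = curv.begin();
  const double half = 0.5 * beta;

  for (int c = 0; c < m; ++c) {
    const int *idxc = &idx(0, c);
    const double *wc = &w(0, c);
    for (R_xlen_t j = 0; j < nvox; ++j) {
      const double fj = fp[j];
      const int kb = idxc[j];
      if (kb < 0) continue;
      const double wjk = wc[j];
      const double fk = fp[kb];
      const double d = fj - fk;
      const double ad = std::fabs(d);
      const double den = fj + fk + gamma * ad + eps;
      if (den <= 0.0) continue; // both ~0: term and gradient vanish
      const double phi = d * d / den;
      val += half * wjk * phi;
      const double sgn = (d > 0.0) ? 1.0 : ((d < 0.0) ? -1.0 : 0.0);
      const double den2 = den * den;
      // d(phi)/dfj and d(phi)/dfk
      const double dj = (2.0 * d * den - d * d * (1.0 + gamma * sgn)) / den2;
      const double dk = (-2.0 * d * den - d * d * (1.0 - gamma * sgn)) / den2;
      gp[j] += half * wjk * dj;
      gp[kb] += half * wjk * dk;
      // separable-surrogate curvature (De Pierro) of the pair term with
      // the denominator frozen at the current iterate
      const double cc = 4.0 * half * wjk / den;
      cp[j] += cc;
      cp[kb] += cc;
    }
  }
  return List::create(_["value"] = val, _["grad"] = grad,
                      _["curv"] = curv);
}

// Smoothed isotropic total variation with forward differences:
//   P = beta * sum_j sqrt(dx^2 + dy^2 + dz^2 + eps^2)
// Returns the value, the exact gradient, and the separable quadratic
// surrogate curvature (each pair based at voxel j contributes 2/t_j to both
// endpoints).
// [[Rcpp::export]]
List tv_penalty_cpp(NumericVector f, int nx, int ny, int nz,
                    double eps, double beta) {
  const R_xlen_t nvox = static_cast<R_xlen_t>(nx) * ny * nz;
  NumericVector grad(nvox), curv(nvox);
  std::vector<double> t(nvox), dx(nvox), dy(nvox), dz(nvox);
  const double *fp = f.begin();
  const R_xlen_t sy = nx, sz = static_cast<R_xlen_t>(nx) * ny;
  double val = 0.0;

  R_xlen_t v = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++v) {
        const double a = fp[v];
        const double ddx = (i < nx - 1) ? fp[v + 1] - a : 0.0;
        const double ddy = (j < ny - 1) ? fp[v + sy] - a : 0.0;
        const double ddz = (k < nz - 1) ? fp[v + sz] - a : 0.0;
        const double tt = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz +
                                    eps * eps);
        t[v] = tt; dx[v] = ddx; dy[v] = ddy; dz[v] = ddz;
        val += tt;
      }
  double *gp = grad.begin(), *cp = curv.begin();
  v = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++v) {
        const double q = 1.0 / t[v];
        gp[v] -= (dx[v] + dy[v] + dz[v]) * q;
        if (i < nx - 1) {
          gp[v + 1] += dx[v] * q;
          cp[v] += 2.0 * q; cp[v + 1] += 2.0 * q;
        }
        if (j < ny - 1) {
          gp[v + sy] += dy[v] * q;
          cp[v] += 2.0 * q; cp[v + sy] += 2.0 * q;
        }
        if (k < nz - 1) {
          gp[v + sz] += dz[v] * q;
          cp[v] += 2.0 * q; cp[v + sz] += 2.0 * q;
        }
      }
  for (R_xlen_t u = 0; u < nvox; ++u) { gp[u] *= beta; cp[u] *= beta; }
  return List::create(_["value"] = beta * val, _["grad"] = grad,
                      _["curv"] = curv);
}
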