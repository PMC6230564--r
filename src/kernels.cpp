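#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int d1, int d2) {
  return i + d1 * (j + d2 * k);
}

// Separable convolution along one axis, zero padding outside the grid.
// Accumulates over kernel taps so every memory access is unit-stride.
static void conv_axis(const std::vector<double> &in, std::vector<double> &out,
                      int d1, int d2, int d3, const NumericVector &ker, int axis) {
  int r = (ker.size() - 1) / 2;
  int dims[3] = { d1, d2, d3 };
  int strides[3] = { 1, d1, d1 * d2 };
  int da = dims[axis], sa = strides[axis];
  std::fill(out.begin(), out.end(), 0.0);
  int n = d1 * d2 * d3;
  for (int t = -r; t <= r; ++t) {
    double w = ker[t + r];
    // voxels whose axis index a satisfies 0 <= a + t < da contribute
    int lo = std::max(0, -t), hi = std::min(da - 1, da - 1 - t);
    if (lo > hi) continue;
    if (axis == 0) {
      for (int base = 0; base < n; base += d1) {
        const double *src = &in[base + lo + t];
        double *dst = &out[base + lo];
        for (int i = lo; i <= hi; ++i) *dst++ += w * *src++;
      }
    } else {
      int outer = (axis == 1) ? d3 : 1;
      int outer_stride = (axis == 1) ? d1 * d2 : 0;
      int runs = (axis == 1) ? d1 : d1 * d2;
      for (int o = 0; o < outer; ++o)
        for (int a = lo; a <= hi; ++a) {
          const double *src = &in[o * outer_stride + (a + t) * sa];
          double *dst = &out[o * outer_stride + a * sa];
          for (int q = 0; q < runs; ++q) dst[q] += w * src[q];
        }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_sep(NumericVector arr, NumericVector kx,
                             NumericVector ky, NumericVector kz) {
  IntegerVector dm = arr.attr("dim");
  int d1 = dm[0], d2 = dm[1], d3 = dm[2];
  int n = d1 * d2 * d3;
  std::vector<double> a(arr.begin(), arr.end()), b(n);
  conv_axis(a, b, d1, d2, d3, kx, 0);
  conv_axis(b, a, d1, d2, d3, ky, 1);
  conv_axis(a, b, d1, d2, d3, kz, 2);
  NumericVector out(b.begin(), b.end());
  out.attr("dim") = dm;
  return out;
}

// Cubic-window maximum filter (separable: max over a cube = three axis passes).
// [[Rcpp::export]]
NumericVector cpp_maxfilter3(NumericVector arr, int radius) {
  IntegerVector dm = arr.attr("dim");
  int d1 = dm[0], d2 = dm[1], d3 = dm[2];
  int n = d1 * d2 * d3;
  std::vector<double> a(arr.begin(), arr.end()), b(n);
  for (int axis = 0; axis < 3; ++axis) {
    for (int k = 0; k < d3; ++k)
      for (int j = 0; j < d2; ++j)
        for (int i = 0; i < d1; ++i) {
          double m = -INFINITY;
          for (int t = -radius; t <= radius; ++t) {
            int ii = i, jj = j, kk = k;
            if (axis == 0) ii += t; else if (axis == 1) jj += t; else kk += t;
            if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3) continue;
            double v = a[idx3(ii, jj, kk, d1, d2)];
            if (v > m) m = v;
          }
          b[idx3(i, j, k, d1, d2)] = m;
        }
    a.swap(b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dm;
  return out;
}

// Resample `arr` on an output grid of dims `dout`. A is a 3x4 matrix taking
// 0-based output voxel indices (i,j,k,1) to 0-based continuous input voxel
// coordinates. mode 0 = trilinear, 1 = nearest. Out-of-fov voxels get 0 and
// valid = FALSE.
// [[Rcpp::export]]
List cpp_resample_affine(NumericVector arr, IntegerVector dout,
                         NumericMatrix A, int mode) {
  IntegerVector dm = arr.attr("dim");
  int d1 = dm[0], d2 = dm[1], d3 = dm[2];
  int o1 = dout[0], o2 = dout[1], o3 = dout[2];
  int n = o1 * o2 * o3;
  NumericVector out(n);
  LogicalVector valid(n);
  for (int k = 0; k < o3; ++k)
    for (int j = 0; j < o2; ++j)
      for (int i = 0; i < o1; ++i) {
        double x = A(0,0)*i + A(0,1)*j + A(0,2)*k + A(0,3);
        double y = A(1,0)*i + A(1,1)*j + A(1,2)*k + A(1,3);
        double z = A(2,0)*i + A(2,1)*j + A(2,2)*k + A(2,3);
        int o = idx3(i, j, k, o1, o2);
        if (mode == 1) {
          int xi = (int) std::lround(x), yi = (int) std::lround(y), zi = (int) std::lround(z);
          if (xi < 0 || xi >= d1 || yi < 0 || yi >= d2 || zi < 0 || zi >= d3) {
            out[o] = 0.0; valid[o] = false;
          } else {
            out[o] = arr[idx3(xi, yi, zi, d1, d2)]; valid[o] = true;
          }
        } else {
          int x0 = (int) std::floor(x), y0 = (int) std::floor(y), z0 = (int) std::floor(z);
          if (x0 < 0 || x0 + 1 >= d1 || y0 < 0 || y0 + 1 >= d2 || z0 < 0 || z0 + 1 >= d3) {
            // allow exact upper-edge hits
            if (x >= 0 && x <= d1 - 1 && y >= 0 && y <= d2 - 1 && z >= 0 && z <= d3 - 1) {
              int xi = std::min(x0, d1 - 2), yi = std::min(y0, d2 - 2), zi = std::min(z0, d3 - 2);
              if (xi < 0) xi = 0; if (yi < 0) yi = 0; if (zi < 0) zi = 0;
              double fx = x - xi, fy = y - yi, fz = z - zi;
              double v = 0.0;
              for (int c = 0; c < 8; ++c) {
                int ax = c & 1, ay = (c >> 1) & 1, az = (c >> 2) & 1;
                double w = (ax ? fx : 1 - fx) * (ay ? fy : 1 - fy) * (az ? fz : 1 - fz);
                v += w * arr[idx3(xi + ax, yi + ay, zi + az, d1, d2)];
              }
              out[o] = v; valid[o] = true;
            } else {
              out[o] = 0.0; valid[o] = false;
            }
          } else {
            double fx = x - x0, fy = y - y0, fz = z - z0;
            double v = 0.0;
            for (int c = 0; c < 8; ++c) {
              int ax = c & 1, ay = (c >> 1) & 1, az = (c >> 2) & 1;
              double w = (ax ? fx : 1 - fx) * (ay ? fy : 1 - fy) * (az ? fz : 1 - fz);
              v += w * arr[idx3(x0 + ax, y0 + ay, z0 + az, d1, d2)];
            }
            out[o] = v; valid[o] = true;
          }
        }
      }
  out.attr("dim") = dout;
  valid.attr("dim") = dout;
  return List::create(_["values"] = out, _["valid"] = valid);
}

// Connected-component labelling, 6- or 26-connectivity, iterative BFS.
// [[Rcpp::export]]
IntegerVector cpp_cc_label(LogicalVector mask, int connectivity) {
  IntegerVector dm = mask.attr("dim");
  int d1 = dm[0], d2 = dm[1], d3 = dm[2];
  int n = d1 * d2 * d3;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  stack.reserve(1024);
  int next = 0;
  for (int s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int ci = cur % d1, cj = (cur / d1) % d2, ck = cur / (d1 * d2);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1) continue;
            int ii = ci + dx, jj = cj + dy, kk = ck + dz;
            if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3) continue;
            int q = idx3(ii, jj, kk, d1, d2);
            if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
          }
    }
  }
  lab.attr("dim") = dm;
  return lab;
}

// Red-black Gauss-Seidel relaxation of Laplace's equation. `code`: 0 = fixed
// (Dirichlet, value taken from init), 1 = free. 6-neighbour Laplacian with
// 1/h^2 weights; out-of-grid neighbours are dropped from the stencil. The
// Dirichlet surface is taken to lie on the face between a free and a fixed
// voxel (distance h/2), giving a Shortley-Weller-style one-sided stencil
// (weight doubled for boundary neighbours) that halves the boundary-placement
// bias of naive centre conditions.
// [[Rcpp::export]]
List cpp_laplace_gs(IntegerVector code, NumericVector init, NumericVector spacing,
                    double tol, int maxit) {
  IntegerVector dm = code.attr("dim");
  int d1 = dm[0], d2 = dm[1], d3 = dm[2];
  std::vector<double> u(init.begin(), init.end());
  double w1 = 1.0 / (spacing[0] * spacing[0]);
  double w2 = 1.0 / (spacing[1] * spacing[1]);
  double w3 = 1.0 / (spacing[2] * spacing[2]);
  std::vector<int> red, black;
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        int s = idx3(i, j, k, d1, d2);
        if (code[s] == 1) ((i + j + k) % 2 == 0 ? red : black).push_back(s);
      }
  double maxupd = 0.0;
  int it = 0;
  const std::vector<int> *cols[2] = { &red, &black };
  for (it = 1; it <= maxit; ++it) {
    maxupd = 0.0;
    for (int c = 0; c < 2; ++c) {
      for (size_t t = 0; t < cols[c]->size(); ++t) {
        int s = (*cols[c])[t];
        int i = s % d1, j = (s / d1) % d2, k = s / (d1 * d2);
        double num = 0.0, den = 0.0;
        #define NB(cond, off, w) if (cond) { int q = s + (off); \
          double ww = (code[q] == 1) ? (w) : 2.0 * (w); \
          num += ww * u[q]; den += ww; }
        NB(i > 0,      -1,       w1)
        NB(i < d1 - 1,  1,       w1)
        NB(j > 0,      -d1,      w2)
        NB(j < d2 - 1,  d1,      w2)
        NB(k > 0,      -d1 * d2, w3)
        NB(k < d3 - 1,  d1 * d2, w3)
        #undef NB
        double nu = num / den;
        double dl = std::fabs(nu - u[s]);
        if (dl > maxupd) maxupd = dl;
        u[s] = nu;
      }
    }
    if (maxupd < tol) break;
  }
  NumericVector sol(u.begin(), u.end());
  sol.attr("dim") = dm;
  return List::create(_["solution"] = sol,
                      _["iterations"] = std::min(it, maxit),
                      _["max_update"] = maxupd,
                      _["converged"] = maxupd < tol);
}

// Fuzzy c-means with a 6-neighbour membership smoothness penalty (beta = 0
// gives classic FCM). Alternating updates; centroid update is the standard
// weighted mean (the penalty does not involve centroids).
// [[Rcpp::export]]
List cpp_fcm(NumericVector x, LogicalVector mask, NumericVector centroids0,
             double m, double beta, double tol, int maxit) {
  IntegerVector dm = x.attr("dim");
  int d1 = dm[0], d2 = dm[1], d3 = dm[2];
  int n = d1 * d2 * d3;
  int K = centroids0.size();
  std::vector<int> vox;
  for (int s = 0; s < n; ++s) if (mask[s]) vox.push_back(s);
  int nv = vox.size();
  std::vector<double> cen(centroids0.begin(), centroids0.end());
  // memberships on the full grid (zero outside mask) so neighbour lookups are direct
  std::vector<std::vector<double>> u(K, std::vector<double>(n, 0.0));
  std::vector<std::vector<double>> um(K, std::vector<double>(n, 0.0)); // u^m
  std::vector<double> umtot(n, 0.0);
  // init memberships from distances to initial centroids (beta ignored once)
  std::vector<double> obj;
  bool converged = false;
  int it;
  int offs[6];
  offs[0] = -1; offs[1] = 1; offs[2] = -d1; offs[3] = d1; offs[4] = -d1 * d2; offs[5] = d1 * d2;
  auto neighbour_ok = [&](int s, int o) {
    int i = s % d1, j = (s / d1) % d2, k = s / (d1 * d2);
    switch (o) {
      case 0: return i > 0;      case 1: return i < d1 - 1;
      case 2: return j > 0;      case 3: return j < d2 - 1;
      case 4: return k > 0;      default: return k < d3 - 1;
    }
  };
  double expo = 1.0 / (m - 1.0);
  // first membership pass without penalty
  for (int t = 0; t < nv; ++t) {
    int s = vox[t];
    double ssum = 0.0;
    std::vector<double> e(K);
    int zero = -1;
    for (int k = 0; k < K; ++k) {
      double d = x[s] - cen[k];
      e[k] = d * d;
      if (e[k] < 1e-300) zero = k;
    }
    if (zero >= 0) {
      for (int k = 0; k < K; ++k) u[k][s] = (k == zero) ? 1.0 : 0.0;
    } else {
      for (int k = 0; k < K; ++k) { u[k][s] = std::pow(e[k], -expo); ssum += u[k][s]; }
      for (int k = 0; k < K; ++k) u[k][s] /= ssum;
    }
  }
  for (it = 1; it <= maxit; ++it) {
    // u^m caches
    for (int t = 0; t < nv; ++t) {
      int s = vox[t];
      double tot = 0.0;
      for (int k = 0; k < K; ++k) { um[k][s] = std::pow(u[k][s], m); tot += um[k][s]; }
      umtot[s] = tot;
    }
    // centroid update
    std::vector<double> cnew(K);
    double shift = 0.0;
    for (int k = 0; k < K; ++k) {
      double num = 0.0, den = 0.0;
      for (int t = 0; t < nv; ++t) {
        int s = vox[t];
        num += um[k][s] * x[s];
        den += um[k][s];
      }
      cnew[k] = den > 0 ? num / den : cen[k];
      shift = std::max(shift, std::fabs(cnew[k] - cen[k]));
    }
    cen = cnew;
    // membership update with spatial penalty (uses cached um from current u)
    double J = 0.0;
    for (int t = 0; t < nv; ++t) {
      int s = vox[t];
      std::vector<double> e(K);
      int zero = -1;
      for (int k = 0; k < K; ++k) {
        double d = x[s] - cen[k];
        double pen = 0.0;
        if (beta > 0) {
          for (int o = 0; o < 6; ++o) {
            if (!neighbour_ok(s, o)) continue;
            int q = s + offs[o];
            if (!mask[q]) continue;
            pen += umtot[q] - um[k][q];
          }
        }
        e[k] = d * d + beta * pen;
        J += um[k][s] * (d * d + 0.5 * beta * pen);
        if (e[k] < 1e-300) zero = k;
      }
      if (zero >= 0) {
        for (int k = 0; k < K; ++k) u[k][s] = (k == zero) ? 1.0 : 0.0;
      } else {
        double ssum = 0.0;
        for (int k = 0; k < K; ++k) { u[k][s] = std::pow(e[k], -expo); ssum += u[k][s]; }
        for (int k = 0; k < K; ++k) u[k][s] /= ssum;
      }
    }
    obj.push_back(J);
    if (shift < tol) { converged = true; break; }
  }
  List mem(K);
  for (int k = 0; k < K; ++k) {
    NumericVector mk(u[k].begin(), u[k].end());
    mk.attr("dim") = dm;
    mem[k] = mk;
  }
  return List::create(_["memberships"] = mem,
                      _["centroids"] = NumericVector(cen.begin(), cen.end()),
                      _["objective"] = NumericVector(obj.begin(), obj.end()),
                      _["iterations"] = std::min(it, maxit),
                      _["converged"] = converged);
}

// Fused resample + normalized cross-correlation: the registration metric.
// Trilinearly samples `mov` at A * (output voxel of the `fix` grid) and
// accumulates NCC sums over in-fov voxels in one pass, with no allocation.
// [[Rcpp::export]]
double cpp_ncc_affine(NumericVector fix, NumericVector mov, NumericMatrix A) {
  IntegerVector df = fix.attr("dim"), dm = mov.attr("dim");
  int f1 = df[0], f2 = df[1], f3 = df[2];
  int d1 = dm[0], d2 = dm[1], d3 = dm[2];
  double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
  long nok = 0;
  for (int k = 0; k < f3; ++k)
    for (int j = 0; j < f2; ++j) {
      double xb = A(0,1)*j + A(0,2)*k + A(0,3);
      double yb = A(1,1)*j + A(1,2)*k + A(1,3);
      double zb = A(2,1)*j + A(2,2)*k + A(2,3);
      for (int i = 0; i < f1; ++i) {
        double x = A(0,0)*i + xb, y = A(1,0)*i + yb, z = A(2,0)*i + zb;
        int x0 = (int) std::floor(x), y0 = (int) std::floor(y), z0 = (int) std::floor(z);
        if (x0 < 0 || x0 + 1 >= d1 || y0 < 0 || y0 + 1 >= d2 || z0 < 0 || z0 + 1 >= d3)
          continue;
        double fx = x - x0, fy = y - y0, fz = z - z0;
        const double *p = &mov[idx3(x0, y0, z0, d1, d2)];
        double c00 = p[0] * (1 - fx) + p[1] * fx;
        double c10 = p[d1] * (1 - fx) + p[d1 + 1] * fx;
        double c01 = p[d1 * d2] * (1 - fx) + p[d1 * d2 + 1] * fx;
        double c11 = p[d1 * d2 + d1] * (1 - fx) + p[d1 * d2 + d1 + 1] * fx;
        double b = (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
                   (c01 * (1 - fy) + c11 * fy) * fz;
        double a = fix[idx3(i, j, k, f1, f2)];
        sa += a; sb += b; saa += a * a; sbb += b * b; sab += a * b; ++nok;
      }
    }
  if (nok < 32) return 0.0;
  double cov = sab - sa * sb / nok;
  double va = saa - sa * sa / nok, vb = sbb - sb * sb / nok;
  if (va <= 0 || vb <= 0) return 0.0;
  return cov / std::sqrt(va * vb);
}

// One-pass 6-connectivity (cross element) binary morphology.
// op 0 = erode, 1 = dilate.
// [[Rcpp::export]]
LogicalVector cpp_morph6(LogicalVector mask, int op) {
  IntegerVector dm = mask.attr("dim");
  int d1 = dm[0], d2 = dm[1], d3 = dm[2];
  int n = d1 * d2 * d3;
  LogicalVector out(n);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        int s = idx3(i, j, k, d1, d2);
        bool v = mask[s];
        if (op == 0) { // erode: all cross neighbours (in-grid) must be set
          if (v) {
            if (i > 0 && !mask[s - 1]) v = false;
            else if (i < d1 - 1 && !mask[s + 1]) v = false;
            else if (j > 0 && !mask[s - d1]) v = false;
            else if (j < d2 - 1 && !mask[s + d1]) v = false;
            else if (k > 0 && !mask[s - d1 * d2]) v = false;
            else if (k < d3 - 1 && !mask[s + d1 * d2]) v = false;
          }
        } else {       // dilate: any cross neighbour set
          if (!v) {
            if ((i > 0 && mask[s - 1]) || (i < d1 - 1 && mask[s + 1]) ||
                (j > 0 && mask[s - d1]) || (j < d2 - 1 && mask[s + d1]) ||
                (k > 0 && mask[s - d1 * d2]) || (k < d3 - 1 && mask[s + d1 * d2]))
              v = true;
          }
        }
        out[s] = v;
      }
  out.attr("dim") = dm;
  return out;
}

// Block-mean downsampling by integer factor (trailing partial blocks dropped).
// [[Rcpp::export]]
NumericVector cpp_block_mean(NumericVector arr, int f) {
  IntegerVector dm = arr.attr("dim");
  int d1 = dm[0], d2 = dm[1], d3 = dm[2];
  int o1 = d1 / f, o2 = d2 / f, o3 = d3 / f;
  NumericVector out(o1 * o2 * o3);
  for (int k = 0; k < o3; ++k)
    for (int j = 0; j < o2; ++j)
      for (int i = 0; i < o1; ++i) {
        double acc = 0.0;
        for (int dz = 0; dz < f; ++dz)
          for (int dy = 0; dy < f; ++dy)
            for (int dx = 0; dx < f; ++dx)
              acc += arr[idx3(i * f + dx, j * f + dy, k * f + dz, d1, d2)];
        out[idx3(i, j, k, o1, o2)] = acc / (f * f * f);
      }
  out.attr("dim") = IntegerVector::create(o1, o2, o3);
  return out;
}
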