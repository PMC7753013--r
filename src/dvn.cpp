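#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// All routines use column-major layout matching R arrays and the same
// index rule: out(i) = sum_r in(i + r - floor(k/2)) * ker(r)  (0-based),
// i.e. greatest-integer centering with zero contribution out of bounds.

// [[Rcpp::export]]
NumericVector cpp_conv3(NumericVector vol, IntegerVector vdim,
                        NumericVector ker, IntegerVector kdim) {
  const int n1 = vdim[0], n2 = vdim[1], n3 = vdim[2];
  const int k1 = kdim[0], k2 = kdim[1], k3 = kdim[2];
  const int o1 = k1 / 2, o2 = k2 / 2, o3 = k3 / 2;
  NumericVector out(vol.size());
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        double acc = 0.0;
        for (int t = 0; t < k3; ++t) {
          const int T = k + t - o3;
          if (T < 0 || T >= n3) continue;
          for (int s = 0; s < k2; ++s) {
            const int S = j + s - o2;
            if (S < 0 || S >= n2) continue;
            const double *vp = &vol[0] + (size_t)n1 * (S + (size_t)n2 * T);
            const double *kp = &ker[0] + (size_t)k1 * (s + (size_t)k2 * t);
            for (int r = 0; r < k1; ++r) {
              const int R = i + r - o1;
              if (R < 0 || R >= n1) continue;
              acc += vp[R] * kp[r];
            }
          }
        }
        out[i + (size_t)n1 * (j + (size_t)n2 * k)] = acc;
      }
  out.attr("dim") = vdim;
  return out;
}

// Multi-channel convolution layer forward pass.
// x: (n1,n2,n3,ci), w: (k1,k2,k3,ci,co), b: (co) -> y: (n1,n2,n3,co)
// [[Rcpp::export]]
NumericVector cpp_layer_fwd(NumericVector x, IntegerVector xdim,
                            NumericVector w, IntegerVector wdim,
                            NumericVector b, bool add_bias) {
  const int n1 = xdim[0], n2 = xdim[1], n3 = xdim[2], ci = xdim[3];
  const int k1 = wdim[0], k2 = wdim[1], k3 = wdim[2], co = wdim[4];
  const int o1 = k1 / 2, o2 = k2 / 2, o3 = k3 / 2;
  const size_t nvox = (size_t)n1 * n2 * n3;
  const size_t kvox = (size_t)k1 * k2 * k3;
  NumericVector y(nvox * co);
  for (int c = 0; c < co; ++c) {
    double *yp = &y[0] + nvox * c;
    if (add_bias) {
      const double bc = b[c];
      for (size_t v = 0; v < nvox; ++v) yp[v] = bc;
    }
    for (int ic = 0; ic < ci; ++ic) {
      const double *xp = &x[0] + nvox * ic;
      const double *wp = &w[0] + kvox * (ic + (size_t)ci * c);
      for (int k = 0; k < n3; ++k)
        for (int j = 0; j < n2; ++j)
          for (int i = 0; i < n1; ++i) {
            double acc = 0.0;
            for (int t = 0; t < k3; ++t) {
              const int T = k + t - o3;
              if (T < 0 || T >= n3) continue;
              for (int s = 0; s < k2; ++s) {
                const int S = j + s - o2;
                if (S < 0 || S >= n2) continue;
                const double *xr = xp + (size_t)n1 * (S + (size_t)n2 * T);
                const double *wr = wp + (size_t)k1 * (s + (size_t)k2 * t);
                for (int r = 0; r < k1; ++r) {
                  const int R = i + r - o1;
                  if (R < 0 || R >= n1) continue;
                  acc += xr[R] * wr[r];
                }
              }
            }
            yp[i + (size_t)n1 * (j + (size_t)n2 * k)] += acc;
          }
    }
  }
  y.attr("dim") = IntegerVector::create(n1, n2, n3, co);
  return y;
}

// Backward pass: gradients w.r.t. input, weights and bias.
// [[Rcpp::export]]
List cpp_layer_bwd(NumericVector x, IntegerVector xdim,
                   NumericVector w, IntegerVector wdim,
                   NumericVector gy) {
  const int n1 = xdim[0], n2 = xdim[1], n3 = xdim[2], ci = xdim[3];
  const int k1 = wdim[0], k2 = wdim[1], k3 = wdim[2], co = wdim[4];
  const int o1 = k1 / 2, o2 = k2 / 2, o3 = k3 / 2;
  const size_t nvox = (size_t)n1 * n2 * n3;
  const size_t kvox = (size_t)k1 * k2 * k3;
  NumericVector gx(nvox * ci), gw(kvox * ci * co), gb(co);
  for (int c = 0; c < co; ++c) {
    const double *gyp = &gy[0] + nvox * c;
    double bacc = 0.0;
    for (size_t v = 0; v < nvox; ++v) bacc += gyp[v];
    gb[c] = bacc;
    for (int ic = 0; ic < ci; ++ic) {
      const double *xp = &x[0] + nvox * ic;
      double *gxp = &gx[0] + nvox * ic;
      const double *wp = &w[0] + kvox * (ic + (size_t)ci * c);
      double *gwp = &gw[0] + kvox * (ic + (size_t)ci * c);
      for (int k = 0; k < n3; ++k)
        for (int j = 0; j < n2; ++j)
          for (int i = 0; i < n1; ++i) {
            const double g = gyp[i + (size_t)n1 * (j + (size_t)n2 * k)];
            if (g == 0.0) continue;
            for (int t = 0; t < k3; ++t) {
              const int T = k + t - o3;
              if (T < 0 || T >= n3) continue;
              for (int s = 0; s < k2; ++s) {
                const int S = j + s - o2;
                if (S < 0 || S >= n2) continue;
                const size_t xoff = (size_t)n1 * (S + (size_t)n2 * T);
                const size_t woff = (size_t)k1 * (s + (size_t)k2 * t);
                for (int r = 0; r < k1; ++r) {
                  const int R = i + r - o1;
                  if (R < 0 || R >= n1) continue;
                  gxp[xoff + R] += g * wp[woff + r];
                  gwp[woff + r] += g * xp[xoff + R];
                }
              }
            }
          }
    }
  }
  gx.attr("dim") = xdim;
  gw.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Mark voxels whose center lies within distance `radius` of the segment
// p1-p2 (a capsule: finite cylinder with hemispherical caps). Coordinates
// are 1-based voxel centers. `mask` is modified in place and returned.
// [[Rcpp::export]]
LogicalVector cpp_capsule_fill(LogicalVector mask, IntegerVector dim,
                               NumericVector p1, NumericVector p2,
                               double radius) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const double ax = p1[0], ay = p1[1], az = p1[2];
  const double dx = p2[0] - ax, dy = p2[1] - ay, dz = p2[2] - az;
  const double len2 = dx * dx + dy * dy + dz * dz;
  const double r2 = radius * radius;
  int lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    const double mn = std::min(p1[a], p2[a]) - radius;
    const double mx = std::max(p1[a], p2[a]) + radius;
    lo[a] = std::max(1, (int)std::floor(mn));
    hi[a] = std::min(dim[a], (int)std::ceil(mx));
  }
  for (int k = lo[2]; k <= hi[2]; ++k)
    for (int j = lo[1]; j <= hi[1]; ++j)
      for (int i = lo[0]; i <= hi[0]; ++i) {
        const double px = i - ax, py = j - ay, pz = k - az;
        double t = 0.0;
        if (len2 > 0.0) {
          t = (px * dx + py * dy + pz * dz) / len2;
          if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
        }
        const double qx = px - t * dx, qy = py - t * dy, qz = pz - t * dz;
        if (qx * qx + qy * qy + qz * qz <= r2)
          mask[(size_t)(i - 1) +
               (size_t)n1 * ((j - 1) + (size_t)n2 * (k - 1))] = true;
      }
  return mask;
}

// 26-connected component labeling of a binary 3-D mask (BFS).
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::queue<size_t> q;
  for (size_t v = 0; v < (size_t)mask.size(); ++v) {
    if (!mask[v] || lab[v] != 0) continue;
    lab[v] = ++next;
    q.push(v);
    while (!q.empty()) {
      const size_t u = q.front(); q.pop();
      const int i = u % n1, j = (u / n1) % n2, k = u / ((size_t)n1 * n2);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            const int I = i + di, J = j + dj, K = k + dk;
            if (I < 0 || I >= n1 || J < 0 || J >= n2 || K < 0 || K >= n3)
              continue;
            const size_t w = I + (size_t)n1 * (J + (size_t)n2 * K);
            if (mask[w] && lab[w] == 0) { lab[w] = next; q.push(w); }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
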