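// Low-level 3D image kernels.
//
// All volumes are dense R arrays with dim = c(nz, ny, nx); the first axis
// (fastest-varying in memory) is z. A voxel index i (0-based) along an axis
// with spacing d has its physical centre at (i + 0.5) * d micrometres.

#include <Rcpp.h>
#include <cmath>
#include <queue>
#include <vector>
#include <limits>
using namespace Rcpp;

static void dims3(const RObject &x, int d[3]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 3) stop("expected a 3-D array");
  d[0] = dm[0]; d[1] = dm[1]; d[2] = dm[2];
}

// reflect index into [0, n) (mirror about the sample, scipy 'reflect' a|abc|c)
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  if (i >= n) i = period - 1 - i;
  return i;
}

// ---------------------------------------------------------------- blur -----

// One separable pass along `ax`; cache-friendly: for the z axis the inner
// loop runs along contiguous z lines, for y/x the accumulation runs over
// contiguous slabs so memory is touched sequentially.
static void blur_axis(const double *in, double *out, int d[3], int ax,
                      const std::vector<double> &k, int r) {
  int n = d[ax];
  if (ax == 0) {
    R_xlen_t nlines = (R_xlen_t)d[1] * d[2];
    for (R_xlen_t l = 0; l < nlines; l++) {
      const double *src = in + l * d[0];
      double *dst = out + l * d[0];
      for (int i = 0; i < n; i++) {
        double acc = 0.0;
        for (int j = -r; j <= r; j++)
          acc += k[j + r] * src[reflect(i + j, n)];
        dst[i] = acc;
      }
    }
  } else if (ax == 2) {
    R_xlen_t slab = (R_xlen_t)d[0] * d[1];
    std::fill(out, out + slab * n, 0.0);
    for (int i = 0; i < n; i++) {
      double *dst = out + (R_xlen_t)i * slab;
      for (int j = -r; j <= r; j++) {
        const double *src = in + (R_xlen_t)reflect(i + j, n) * slab;
        double w = k[j + r];
        for (R_xlen_t t = 0; t < slab; t++) dst[t] += w * src[t];
      }
    }
  } else {
    R_xlen_t run = d[0];
    std::fill(out, out + (R_xlen_t)d[0] * d[1] * d[2], 0.0);
    for (int x = 0; x < d[2]; x++) {
      const double *inx = in + (R_xlen_t)x * d[0] * d[1];
      double *outx = out + (R_xlen_t)x * d[0] * d[1];
      for (int i = 0; i < n; i++) {
        double *dst = outx + (R_xlen_t)i * run;
        for (int j = -r; j <= r; j++) {
          const double *src = inx + (R_xlen_t)reflect(i + j, n) * run;
          double w = k[j + r];
          for (R_xlen_t t = 0; t < run; t++) dst[t] += w * src[t];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_blur3(NumericVector vol, NumericVector sigma_vox) {
  int d[3]; dims3(vol, d);
  if (sigma_vox.size() != 3) stop("sigma_vox must have length 3");
  NumericVector cur = clone(vol);
  NumericVector tmp(vol.size());

  for (int ax = 0; ax < 3; ax++) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(4.0 * s);
    if (r < 1) r = 1;
    std::vector<double> k(2 * r + 1);
    double sum = 0.0;
    for (int j = -r; j <= r; j++) {
      k[j + r] = std::exp(-0.5 * j * j / (s * s));
      sum += k[j + r];
    }
    for (double &w : k) w /= sum;
    blur_axis(REAL(cur), REAL(tmp), d, ax, k, r);
    std::swap(cur, tmp);
  }
  cur.attr("dim") = vol.attr("dim");
  return cur;
}

// ------------------------------------------------- distance transform ------

// Felzenszwalb & Huttenlocher 1-D squared distance transform with
// anisotropic weight w (distance contribution w^2 * (i - j)^2).
// "No site" is encoded as the large finite DT_BIG, not IEEE Inf.
static const double DT_BIG = 1e20;

static void dt1d(std::vector<double> &f, std::vector<double> &dOut,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double w2) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * (double)v[k] * v[k])) /
               (2.0 * w2 * (q - v[k]));
    while (s <= z[k]) {
      k--;
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * (double)v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (double)(q - v[k]);
    dOut[q] = w2 * dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance (physical units) from every voxel to the nearest
// TRUE voxel of `sites`. Voxels that are sites get 0; Inf if no site exists.
// [[Rcpp::export]]
NumericVector cpp_edt3(LogicalVector sites, NumericVector spacing_zyx) {
  int d[3]; dims3(sites, d);
  R_xlen_t N = (R_xlen_t)d[0] * d[1] * d[2];
  NumericVector dist2(N);
  for (R_xlen_t i = 0; i < N; i++) dist2[i] = sites[i] ? 0.0 : DT_BIG;

  int stride[3] = {1, d[0], d[0] * d[1]};
  int nmax = std::max(d[0], std::max(d[1], d[2]));
  std::vector<double> f(nmax), dOut(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  for (int ax = 0; ax < 3; ax++) {
    double w = spacing_zyx[ax];
    double w2 = w * w;
    int n = d[ax];
    int o1 = (ax == 0) ? d[1] : d[0];
    int o2 = (ax == 2) ? d[1] : d[2];
    int s1 = (ax == 0) ? stride[1] : stride[0];
    int s2 = (ax == 2) ? stride[1] : stride[2];
    int sa = stride[ax];
    for (int a = 0; a < o1; a++) {
      for (int b = 0; b < o2; b++) {
        R_xlen_t base = (R_xlen_t)a * s1 + (R_xlen_t)b * s2;
        for (int i = 0; i < n; i++)
          f[i] = dist2[base + (R_xlen_t)i * sa];
        dt1d(f, dOut, v, z, n, w2);
        for (int i = 0; i < n; i++)
          dist2[base + (R_xlen_t)i * sa] = dOut[i];
      }
    }
  }
  for (R_xlen_t i = 0; i < N; i++)
    dist2[i] = (dist2[i] >= DT_BIG) ? R_PosInf : std::sqrt(dist2[i]);
  dist2.attr("dim") = sites.attr("dim");
  return dist2;
}

// ------------------------------------------------------- neighbourhoods ----

static void neighbour_offsets(int d[3], bool conn26,
                              std::vector<R_xlen_t> &off,
                              std::vector<int> &dz, std::vector<int> &dy,
                              std::vector<int> &dx) {
  for (int iz = -1; iz <= 1; iz++)
    for (int iy = -1; iy <= 1; iy++)
      for (int ix = -1; ix <= 1; ix++) {
        if (iz == 0 && iy == 0 && ix == 0) continue;
        int manh = std::abs(iz) + std::abs(iy) + std::abs(ix);
        if (!conn26 && manh != 1) continue;
        off.push_back((R_xlen_t)iz + (R_xlen_t)iy * d[0] +
                      (R_xlen_t)ix * d[0] * d[1]);
        dz.push_back(iz); dy.push_back(iy); dx.push_back(ix);
      }
}

// Connected-component labelling (26-connectivity by default); labels are
// assigned in scan order of the first voxel encountered, so deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label3(LogicalVector mask, bool conn26 = true) {
  int d[3]; dims3(mask, d);
  R_xlen_t N = (R_xlen_t)d[0] * d[1] * d[2];
  IntegerVector lab(N, 0);
  std::vector<R_xlen_t> off; std::vector<int> dz, dy, dx;
  neighbour_offsets(d, conn26, off, dz, dy, dx);
  std::vector<R_xlen_t> stack;
  int next = 0;

  for (R_xlen_t i = 0; i < N; i++) {
    if (!mask[i] || lab[i] != 0) continue;
    next++;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int pz = (int)(p % d[0]);
      int py = (int)((p / d[0]) % d[1]);
      int px = (int)(p / ((R_xlen_t)d[0] * d[1]));
      for (size_t k = 0; k < off.size(); k++) {
        int qz = pz + dz[k], qy = py + dy[k], qx = px + dx[k];
        if (qz < 0 || qz >= d[0] || qy < 0 || qy >= d[1] ||
            qx < 0 || qx >= d[2]) continue;
        R_xlen_t q = p + off[k];
        if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  lab.attr("dim") = mask.attr("dim");
  return lab;
}

// ------------------------------------------------------------ watershed ----

struct WsNode {
  double h;
  R_xlen_t idx;
  long order;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.h != b.h) return a.h < b.h;       // max-heap on height
    return a.order > b.order;               // FIFO tie-break: deterministic
  }
};

// Marker-based watershed: flood downhill from markers on `height`, restricted
// to `mask`. Every masked voxel reachable from a marker gets that marker's
// label; flooding order is highest-intensity-first with FIFO tie-breaks.
// [[Rcpp::export]]
IntegerVector cpp_watershed3(NumericVector height, IntegerVector markers,
                             LogicalVector mask, bool conn26 = true) {
  int d[3]; dims3(height, d);
  R_xlen_t N = (R_xlen_t)d[0] * d[1] * d[2];
  IntegerVector lab(N, 0);
  std::vector<R_xlen_t> off; std::vector<int> dz, dy, dx;
  neighbour_offsets(d, conn26, off, dz, dy, dx);

  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long order = 0;
  for (R_xlen_t i = 0; i < N; i++) {
    if (markers[i] > 0 && mask[i]) {
      lab[i] = markers[i];
      pq.push(WsNode{height[i], i, order++});
    }
  }
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    R_xlen_t p = nd.idx;
    int pz = (int)(p % d[0]);
    int py = (int)((p / d[0]) % d[1]);
    int px = (int)(p / ((R_xlen_t)d[0] * d[1]));
    for (size_t k = 0; k < off.size(); k++) {
      int qz = pz + dz[k], qy = py + dy[k], qx = px + dx[k];
      if (qz < 0 || qz >= d[0] || qy < 0 || qy >= d[1] ||
          qx < 0 || qx >= d[2]) continue;
      R_xlen_t q = p + off[k];
      if (mask[q] && lab[q] == 0) {
        lab[q] = lab[p];
        pq.push(WsNode{height[q], q, order++});
      }
    }
  }
  lab.attr("dim") = height.attr("dim");
  return lab;
}

// ---------------------------------------------------------- local maxima ---

// 1-based linear indices of local maxima of `vol` within `mask`, using an
// ellipsoidal neighbourhood with per-axis voxel radii. Plateau ties resolved
// by lowest linear index.
// [[Rcpp::export]]
IntegerVector cpp_locmax3(NumericVector vol, LogicalVector mask,
                          NumericVector radius_vox, double threshold) {
  int d[3]; dims3(vol, d);
  R_xlen_t N = (R_xlen_t)d[0] * d[1] * d[2];
  double r1 = std::max(radius_vox[0], 0.0);
  double r2 = std::max(radius_vox[1], 0.0);
  double r3 = std::max(radius_vox[2], 0.0);
  int R1 = (int)std::floor(r1), R2 = (int)std::floor(r2), R3 = (int)std::floor(r3);

  std::vector<int> oz, oy, ox;
  for (int iz = -R1; iz <= R1; iz++)
    for (int iy = -R2; iy <= R2; iy++)
      for (int ix = -R3; ix <= R3; ix++) {
        if (iz == 0 && iy == 0 && ix == 0) continue;
        double e = 0.0;
        if (r1 > 0) e += (double)iz * iz / (r1 * r1); else if (iz != 0) continue;
        if (r2 > 0) e += (double)iy * iy / (r2 * r2); else if (iy != 0) continue;
        if (r3 > 0) e += (double)ix * ix / (r3 * r3); else if (ix != 0) continue;
        if (e <= 1.0) { oz.push_back(iz); oy.push_back(iy); ox.push_back(ix); }
      }

  std::vector<int> out;
  for (R_xlen_t p = 0; p < N; p++) {
    if (!mask[p] || vol[p] < threshold) continue;
    int pz = (int)(p % d[0]);
    int py = (int)((p / d[0]) % d[1]);
    int px = (int)(p / ((R_xlen_t)d[0] * d[1]));
    bool is_max = true;
    for (size_t k = 0; k < oz.size() && is_max; k++) {
      int qz = pz + oz[k], qy = py + oy[k], qx = px + ox[k];
      if (qz < 0 || qz >= d[0] || qy < 0 || qy >= d[1] ||
          qx < 0 || qx >= d[2]) continue;
      R_xlen_t q = (R_xlen_t)qz + (R_xlen_t)qy * d[0] +
                   (R_xlen_t)qx * d[0] * d[1];
      if (vol[q] > vol[p] || (vol[q] == vol[p] && q < p)) is_max = false;
    }
    if (is_max) out.push_back((int)(p + 1));
  }
  return wrap(out);
}

// --------------------------------------------------- grayscale morphology --

// Separable min (erode) or max (dilate) filter with a box structuring
// element of per-axis half-width radius_vox (rounded down); voxels outside
// the volume do not constrain the result. The box SE is the separable
// stand-in for a rolling ball at background-estimation scales.
static void morph_axis(const double *in, double *out, int d[3], int ax,
                       int r, bool dilate) {
  int n = d[ax];
  R_xlen_t stride = (ax == 0) ? 1 : (ax == 1 ? d[0] : (R_xlen_t)d[0] * d[1]);
  int o1 = (ax == 0) ? d[1] : d[0];
  int o2 = (ax == 2) ? d[1] : d[2];
  R_xlen_t s1 = (ax == 0) ? d[0] : 1;
  R_xlen_t s2 = (ax == 2) ? d[0] : (R_xlen_t)d[0] * d[1];
  std::vector<double> buf(n);
  for (int a = 0; a < o1; a++) {
    for (int b = 0; b < o2; b++) {
      R_xlen_t base = (R_xlen_t)a * s1 + (R_xlen_t)b * s2;
      for (int i = 0; i < n; i++) buf[i] = in[base + (R_xlen_t)i * stride];
      for (int i = 0; i < n; i++) {
        int lo = std::max(0, i - r), hi = std::min(n - 1, i + r);
        double best = buf[lo];
        for (int q = lo + 1; q <= hi; q++) {
          if (dilate) { if (buf[q] > best) best = buf[q]; }
          else        { if (buf[q] < best) best = buf[q]; }
        }
        out[base + (R_xlen_t)i * stride] = best;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gray_morph3(NumericVector vol, NumericVector radius_vox,
                              bool dilate) {
  int d[3]; dims3(vol, d);
  NumericVector cur = clone(vol);
  NumericVector tmp(vol.size());
  for (int ax = 0; ax < 3; ax++) {
    int r = (int)std::floor(std::max(radius_vox[ax], 0.0));
    if (r < 1) continue;
    morph_axis(REAL(cur), REAL(tmp), d, ax, r, dilate);
    std::swap(cur, tmp);
  }
  cur.attr("dim") = vol.attr("dim");
  return cur;
}

// ---------------------------------------------------- sphere rasterisation -

// Adds, for each sphere, the fraction of every voxel covered by the sphere
// (estimated on an ss^3 subgrid) to `out`. Centres are physical (z, y, x) in
// micrometres; voxel i spans [i*d, (i+1)*d) with centre (i+0.5)*d.
// [[Rcpp::export]]
NumericVector cpp_raster_spheres(IntegerVector dim_zyx,
                                 NumericVector spacing_zyx,
                                 NumericMatrix centers_zyx_um,
                                 NumericVector radii_um,
                                 NumericVector amplitude,
                                 int ss = 3) {
  int d[3] = {dim_zyx[0], dim_zyx[1], dim_zyx[2]};
  double sp[3] = {spacing_zyx[0], spacing_zyx[1], spacing_zyx[2]};
  R_xlen_t N = (R_xlen_t)d[0] * d[1] * d[2];
  NumericVector out(N);
  int n = centers_zyx_um.nrow();
  double cell = 1.0 / (ss * ss * ss);

  for (int s = 0; s < n; s++) {
    double cz = centers_zyx_um(s, 0), cy = centers_zyx_um(s, 1),
           cx = centers_zyx_um(s, 2);
    double r = radii_um[s], r2 = r * r;
    double amp = amplitude[s];
    int z0 = std::max(0, (int)std::floor((cz - r) / sp[0]));
    int z1 = std::min(d[0] - 1, (int)std::floor((cz + r) / sp[0]));
    int y0 = std::max(0, (int)std::floor((cy - r) / sp[1]));
    int y1 = std::min(d[1] - 1, (int)std::floor((cy + r) / sp[1]));
    int x0 = std::max(0, (int)std::floor((cx - r) / sp[2]));
    int x1 = std::min(d[2] - 1, (int)std::floor((cx + r) / sp[2]));
    for (int iz = z0; iz <= z1; iz++)
      for (int iy = y0; iy <= y1; iy++)
        for (int ix = x0; ix <= x1; ix++) {
          int cnt = 0;
          for (int az = 0; az < ss; az++) {
            double pz = (iz + (az + 0.5) / ss) * sp[0] - cz;
            for (int ay = 0; ay < ss; ay++) {
              double py = (iy + (ay + 0.5) / ss) * sp[1] - cy;
              for (int ax = 0; ax < ss; ax++) {
                double px = (ix + (ax + 0.5) / ss) * sp[2] - cx;
                if (pz * pz + py * py + px * px <= r2) cnt++;
              }
            }
          }
          if (cnt > 0)
            out[(R_xlen_t)iz + (R_xlen_t)iy * d[0] +
                (R_xlen_t)ix * d[0] * d[1]] += amp * cnt * cell;
        }
  }
  out.attr("dim") = IntegerVector::create(d[0], d[1], d[2]);
  return out;
}

// ------------------------------------------- supersampled object volumes ---

// For each label, counts ss^3-subsampled points (within that label's voxels)
// at which the trilinearly interpolated intensity is >= the label's
// threshold. Grid for interpolation: integer coordinates = voxel centres.
// [[Rcpp::export]]
NumericVector cpp_label_volume_ss(NumericVector vol, IntegerVector labels,
                                  int nlab, NumericVector thr, int ss = 3) {
  int d[3]; dims3(vol, d);
  R_xlen_t N = (R_xlen_t)d[0] * d[1] * d[2];
  NumericVector cnt(nlab);
  double inv = 1.0 / ss;

  for (R_xlen_t p = 0; p < N; p++) {
    int L = labels[p];
    if (L <= 0) continue;
    double t = thr[L - 1];
    int pz = (int)(p % d[0]);
    int py = (int)((p / d[0]) % d[1]);
    int px = (int)(p / ((R_xlen_t)d[0] * d[1]));
    int c = 0;
    for (int az = 0; az < ss; az++) {
      double fz = pz + (az + 0.5) * inv - 0.5;
      int z0 = (int)std::floor(fz); double wz = fz - z0;
      int z0c = std::min(std::max(z0, 0), d[0] - 1);
      int z1c = std::min(std::max(z0 + 1, 0), d[0] - 1);
      for (int ay = 0; ay < ss; ay++) {
        double fy = py + (ay + 0.5) * inv - 0.5;
        int y0 = (int)std::floor(fy); double wy = fy - y0;
        int y0c = std::min(std::max(y0, 0), d[1] - 1);
        int y1c = std::min(std::max(y0 + 1, 0), d[1] - 1);
        for (int ax = 0; ax < ss; ax++) {
          double fx = px + (ax + 0.5) * inv - 0.5;
          int x0 = (int)std::floor(fx); double wx = fx - x0;
          int x0c = std::min(std::max(x0, 0), d[2] - 1);
          int x1c = std::min(std::max(x0 + 1, 0), d[2] - 1);
          #define V(zz, yy, xx) vol[(R_xlen_t)(zz) + (R_xlen_t)(yy) * d[0] + \
                                    (R_xlen_t)(xx) * d[0] * d[1]]
          double v =
            (1 - wz) * ((1 - wy) * ((1 - wx) * V(z0c, y0c, x0c) + wx * V(z0c, y0c, x1c)) +
                        wy * ((1 - wx) * V(z0c, y1c, x0c) + wx * V(z0c, y1c, x1c))) +
            wz * ((1 - wy) * ((1 - wx) * V(z1c, y0c, x0c) + wx * V(z1c, y0c, x1c)) +
                  wy * ((1 - wx) * V(z1c, y1c, x0c) + wx * V(z1c, y1c, x1c)));
          #undef V
          if (v >= t) c++;
        }
      }
    }
    cnt[L - 1] += c;
  }
  double cell = 1.0 / (ss * ss * ss);
  for (int i = 0; i < nlab; i++) cnt[i] *= cell;
  return cnt;   // in voxel units; multiply by voxel volume in R
}

// --------------------------------------------------------- label stats -----

// Per-label summaries: voxel count, intensity sum, max, intensity-weighted
// centroid (voxel coords) and weighted second central moments.
// Returns matrix nlab x 13:
// count, sum, max, mz, my, mx, czz, cyy, cxx, czy, czx, cyx, (peak index)
// [[Rcpp::export]]
NumericMatrix cpp_label_stats(NumericVector vol, IntegerVector labels,
                              int nlab) {
  int d[3]; dims3(vol, d);
  R_xlen_t N = (R_xlen_t)d[0] * d[1] * d[2];
  NumericMatrix out(nlab, 13);
  std::vector<double> W(nlab, 0.0), mz(nlab, 0.0), my(nlab, 0.0), mx(nlab, 0.0);
  std::vector<double> mzz(nlab, 0.0), myy(nlab, 0.0), mxx(nlab, 0.0),
      mzy(nlab, 0.0), mzx(nlab, 0.0), myx(nlab, 0.0);
  std::vector<double> vmax(nlab, -1.0);
  std::vector<R_xlen_t> pk(nlab, 0);
  std::vector<double> cntv(nlab, 0.0);

  for (R_xlen_t p = 0; p < N; p++) {
    int L = labels[p];
    if (L <= 0) continue;
    int i = L - 1;
    double w = vol[p];
    if (w < 0) w = 0;
    int pz = (int)(p % d[0]);
    int py = (int)((p / d[0]) % d[1]);
    int px = (int)(p / ((R_xlen_t)d[0] * d[1]));
    cntv[i] += 1;
    W[i] += w;
    mz[i] += w * pz; my[i] += w * py; mx[i] += w * px;
    mzz[i] += w * (double)pz * pz; myy[i] += w * (double)py * py;
    mxx[i] += w * (double)px * px;
    mzy[i] += w * (double)pz * py; mzx[i] += w * (double)pz * px;
    myx[i] += w * (double)py * px;
    if (vol[p] > vmax[i]) { vmax[i] = vol[p]; pk[i] = p; }
  }
  for (int i = 0; i < nlab; i++) {
    double w = W[i];
    out(i, 0) = cntv[i];
    out(i, 1) = W[i];
    out(i, 2) = vmax[i] < 0 ? NA_REAL : vmax[i];
    if (w > 0) {
      double cz = mz[i] / w, cy = my[i] / w, cx = mx[i] / w;
      out(i, 3) = cz; out(i, 4) = cy; out(i, 5) = cx;
      out(i, 6) = mzz[i] / w - cz * cz;
      out(i, 7) = myy[i] / w - cy * cy;
      out(i, 8) = mxx[i] / w - cx * cx;
      out(i, 9) = mzy[i] / w - cz * cy;
      out(i, 10) = mzx[i] / w - cz * cx;
      out(i, 11) = myx[i] / w - cy * cx;
    } else {
      for (int j = 3; j <= 11; j++) out(i, j) = NA_REAL;
    }
    out(i, 12) = (double)(pk[i] + 1);
  }
  return out;
}

// --------------------------------------------------------- laplacian -------

// Second-derivative sum with physical spacing (reflect boundary); used by the
// scale-normalised LoG spot detector.
// [[Rcpp::export]]
NumericVector cpp_laplacian3(NumericVector vol, NumericVector spacing_zyx) {
  int d[3]; dims3(vol, d);
  R_xlen_t N = (R_xlen_t)d[0] * d[1] * d[2];
  NumericVector out(N);
  double is2[3] = {1.0 / (spacing_zyx[0] * spacing_zyx[0]),
                   1.0 / (spacing_zyx[1] * spacing_zyx[1]),
                   1.0 / (spacing_zyx[2] * spacing_zyx[2])};
  for (R_xlen_t p = 0; p < N; p++) {
    int pz = (int)(p % d[0]);
    int py = (int)((p / d[0]) % d[1]);
    int px = (int)(p / ((R_xlen_t)d[0] * d[1]));
    double v = vol[p], acc = 0.0;
    int zm = reflect(pz - 1, d[0]), zp = reflect(pz + 1, d[0]);
    int ym = reflect(py - 1, d[1]), yp = reflect(py + 1, d[1]);
    int xm = reflect(px - 1, d[2]), xp = reflect(px + 1, d[2]);
    #define AT(zz, yy, xx) vol[(R_xlen_t)(zz) + (R_xlen_t)(yy) * d[0] + \
                               (R_xlen_t)(xx) * d[0] * d[1]]
    acc += (AT(zm, py, px) - 2 * v + AT(zp, py, px)) * is2[0];
    acc += (AT(pz, ym, px) - 2 * v + AT(pz, yp, px)) * is2[1];
    acc += (AT(pz, py, xm) - 2 * v + AT(pz, py, xp)) * is2[2];
    #undef AT
    out[p] = acc;
  }
  out.attr("dim") = vol.attr("dim");
  return out;
}
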