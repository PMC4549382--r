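#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---- symmetric 3x3 eigen-decomposition (cyclic Jacobi) ----

static void jacobi3(double a[3][3], double d[3], double v[3][3]) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) v[i][j] = (i == j) ? 1.0 : 0.0;
  for (int sweep = 0; sweep < 50; ++sweep) {
    double off = std::fabs(a[0][1]) + std::fabs(a[0][2]) + std::fabs(a[1][2]);
    if (off < 1e-15) break;
    for (int p = 0; p < 2; ++p) {
      for (int q = p + 1; q < 3; ++q) {
        if (std::fabs(a[p][q]) < 1e-18) continue;
        double theta = (a[q][q] - a[p][p]) / (2.0 * a[p][q]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0);
        double s = t * c;
        double app = a[p][p], aqq = a[q][q], apq = a[p][q];
        a[p][p] = c * c * app - 2.0 * s * c * apq + s * s * aqq;
        a[q][q] = s * s * app + 2.0 * s * c * apq + c * c * aqq;
        a[p][q] = a[q][p] = 0.0;
        int r = 3 - p - q;
        double arp = a[r][p], arq = a[r][q];
        a[r][p] = a[p][r] = c * arp - s * arq;
        a[r][q] = a[q][r] = s * arp + c * arq;
        for (int i = 0; i < 3; ++i) {
          double vip = v[i][p], viq = v[i][q];
          v[i][p] = c * vip - s * viq;
          v[i][q] = s * vip + c * viq;
        }
      }
    }
  }
  for (int i = 0; i < 3; ++i) d[i] = a[i][i];
}

// Eigenvalues (descending) and principal eigenvector per row of a V x 6
// symmetric-tensor matrix (order xx, yy, zz, xy, xz, yz).
// [[Rcpp::export]]
List eig3_sym_cpp(NumericMatrix D) {
  int n = D.nrow();
  NumericMatrix values(n, 3), e1(n, 3);
  for (int i = 0; i < n; ++i) {
    if (NumericVector::is_na(D(i, 0))) {
      for (int k = 0; k < 3; ++k) {
        values(i, k) = NA_REAL;
        e1(i, k) = NA_REAL;
      }
      continue;
    }
    double a[3][3] = {{D(i, 0), D(i, 3), D(i, 4)},
                      {D(i, 3), D(i, 1), D(i, 5)},
                      {D(i, 4), D(i, 5), D(i, 2)}};
    double d[3], v[3][3];
    jacobi3(a, d, v);
    int ord[3] = {0, 1, 2};
    for (int p = 0; p < 2; ++p)
      for (int q = p + 1; q < 3; ++q)
        if (d[ord[q]] > d[ord[p]]) std::swap(ord[p], ord[q]);
    for (int k = 0; k < 3; ++k) values(i, k) = d[ord[k]];
    for (int k = 0; k < 3; ++k) e1(i, k) = v[k][ord[0]];
  }
  return List::create(_["values"] = values, _["e1"] = e1);
}

// ---- PCG32 random stream (per-streamline substreams) ----

struct Pcg32 {
  uint64_t state, inc;
  bool has_cached;
  double cached;
  explicit Pcg32(uint64_t seed, uint64_t seq = 54u)
      : state(0u), inc((seq << 1u) | 1u), has_cached(false), cached(0.0) {
    next();
    state += seed;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31u));
  }
  double unif() { return (next() + 0.5) * (1.0 / 4294967296.0); }
  double norm() {  // Box-Muller, cached pair
    if (has_cached) {
      has_cached = false;
      return cached;
    }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    cached = r * std::sin(2.0 * M_PI * u2);
    has_cached = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

static inline int voxel_flat(const double *p, double voxel_mm, const int *dims) {
  int i = (int)std::floor(p[0] / voxel_mm);
  int j = (int)std::floor(p[1] / voxel_mm);
  int k = (int)std::floor(p[2] / voxel_mm);
  if (i < 0 || j < 0 || k < 0 || i >= dims[0] || j >= dims[1] || k >= dims[2])
    return -1;
  return i + dims[0] * (j + dims[1] * k);
}

static inline double norm3(const double *v) {
  return std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
}

// sample the next unit direction about the local principal eigenvector;
// returns false when propagation must stop
static bool sample_direction(const NumericMatrix &e1, const NumericVector &fa,
                             int vox, const double *prev, double dispersion,
                             double fa_thresh, double cos_max, Pcg32 &rng,
                             double *out) {
  double fav = fa[vox];
  if (NumericVector::is_na(fav) || fav < fa_thresh) return false;
  double e[3] = {e1(vox, 0), e1(vox, 1), e1(vox, 2)};
  if (ISNAN(e[0])) return false;
  double dp = e[0] * prev[0] + e[1] * prev[1] + e[2] * prev[2];
  if (dp < 0) {
    e[0] = -e[0]; e[1] = -e[1]; e[2] = -e[2];
    dp = -dp;
  }
  if (dp < cos_max) return false;  // field itself bends past the constraint
  if (dispersion <= 0.0) {
    out[0] = e[0]; out[1] = e[1]; out[2] = e[2];
    return true;
  }
  double sd = dispersion * (1.0 - fav);
  for (int tries = 0; tries < 10; ++tries) {
    double d[3] = {e[0] + sd * rng.norm(), e[1] + sd * rng.norm(),
                   e[2] + sd * rng.norm()};
    double nn = norm3(d);
    if (nn < 1e-12) continue;
    d[0] /= nn; d[1] /= nn; d[2] /= nn;
    if (d[0] * prev[0] + d[1] * prev[1] + d[2] * prev[2] >= cos_max) {
      out[0] = d[0]; out[1] = d[1]; out[2] = d[2];
      return true;
    }
  }
  // the eigenvector itself satisfies the curvature constraint (checked
  // above), so fall back to it rather than terminating on unlucky draws
  out[0] = e[0]; out[1] = e[1]; out[2] = e[2];
  return true;
}

// propagate one direction from a seed; returns the visited points
// (excluding the seed itself)
static std::vector<double> propagate(const NumericMatrix &e1,
                                     const NumericVector &fa, const int *dims,
                                     double voxel_mm, const double *seed,
                                     const double *init_dir, double step,
                                     double fa_thresh, double cos_max,
                                     double dispersion, int max_steps,
                                     Pcg32 &rng) {
  std::vector<double> pts;
  double p[3] = {seed[0], seed[1], seed[2]};
  double prev[3] = {init_dir[0], init_dir[1], init_dir[2]};
  for (int s = 0; s < max_steps; ++s) {
    int vox = voxel_flat(p, voxel_mm, dims);
    if (vox < 0) break;
    double dir[3];
    if (!sample_direction(e1, fa, vox, prev, dispersion, fa_thresh, cos_max,
                          rng, dir))
      break;
    p[0] += step * dir[0];
    p[1] += step * dir[1];
    p[2] += step * dir[2];
    if (voxel_flat(p, voxel_mm, dims) < 0) break;  // never record points
                                                   // outside the volume
    pts.push_back(p[0]);
    pts.push_back(p[1]);
    pts.push_back(p[2]);
    prev[0] = dir[0]; prev[1] = dir[1]; prev[2] = dir[2];
  }
  return pts;
}

// Bidirectional probabilistic streamline propagation.
// e1: V x 3 principal eigenvectors; fa: V values; dims: volume dimensions
// (column-major flat indexing); seeds: n x 3 world-mm start points;
// substream_seeds: one RNG seed per streamline.
// [[Rcpp::export]]
List track_streamlines_cpp(NumericMatrix e1, NumericVector fa,
                           IntegerVector dims, double voxel_mm,
                           NumericMatrix seeds, NumericVector substream_seeds,
                           double step, double fa_thresh, double max_angle_rad,
                           double dispersion, int max_steps) {
  int n = seeds.nrow();
  int dm[3] = {dims[0], dims[1], dims[2]};
  double cos_max = std::cos(max_angle_rad);
  List out(n);
  for (int s = 0; s < n; ++s) {
    Pcg32 rng((uint64_t)substream_seeds[s]);
    double seed[3] = {seeds(s, 0), seeds(s, 1), seeds(s, 2)};
    int vox = voxel_flat(seed, voxel_mm, dm);
    if (vox < 0 || NumericVector::is_na(fa[vox]) || fa[vox] < fa_thresh ||
        ISNAN(e1(vox, 0))) {
      NumericMatrix m(1, 3);
      m(0, 0) = seed[0]; m(0, 1) = seed[1]; m(0, 2) = seed[2];
      out[s] = m;
      continue;
    }
    double d0[3] = {e1(vox, 0), e1(vox, 1), e1(vox, 2)};
    double bk[3] = {-d0[0], -d0[1], -d0[2]};
    std::vector<double> fwd = propagate(e1, fa, dm, voxel_mm, seed, d0, step,
                                        fa_thresh, cos_max, dispersion,
                                        max_steps, rng);
    std::vector<double> rev = propagate(e1, fa, dm, voxel_mm, seed, bk, step,
                                        fa_thresh, cos_max, dispersion,
                                        max_steps, rng);
    int nf = (int)fwd.size() / 3, nr = (int)rev.size() / 3;
    NumericMatrix m(nr + 1 + nf, 3);
    for (int i = 0; i < nr; ++i)  // reversed backward half first
      for (int k = 0; k < 3; ++k) m(i, k) = rev[3 * (nr - 1 - i) + k];
    for (int k = 0; k < 3; ++k) m(nr, k) = seed[k];
    for (int i = 0; i < nf; ++i)
      for (int k = 0; k < 3; ++k) m(nr + 1 + i, k) = fwd[3 * i + k];
    out[s] = m;
  }
  return out;
}
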