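#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Patch texture features for a set of voxel centers.
//
// For every center the (2*rs+1)^3 patch is extracted with edge replication
// against the volume border, z-scored (sample sd; constant patches map to
// all zeros), and run through the filter bank.  Filters read the z-scored
// patch through a 1-voxel replicate border of the patch itself, so the
// feature vector depends only on the patch content.
//
// Block layout (each block has (2*rs+1)^3 entries, patch voxels ordered
// x-fastest):
//   0      intensity (z-scored patch)
//   1- 3   1st-order central difference along x, y, z
//   4- 6   2nd-order difference (1,-2,1) along x, y, z
//   7- 9   hyperplane: mean of the 3x3 plane normal to x/y/z minus center
//  10-12   3D Sobel along x, y, z (smoothing [1,2,1] x [1,2,1])
//  13      27-point Laplacian (neighbor sum minus 27x center)
//  14      range: max - min over the 3x3x3 neighborhood
//
// `centers` holds 0-based (i,j,k) voxel indices, one row per center.
static void patch_features_core(const double* v, const int* dim,
                                const IntegerMatrix& centers, int rs,
                                double* outbase) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int s = 2 * rs + 1, s3 = s * s * s;
  const int se = s + 2;
  const int nfeat = 15 * s3;
  const int n = centers.nrow();
  std::vector<double> P(s3), E((size_t)se * se * se);
  const double w3[3] = {1.0, 2.0, 1.0};

  for (int c = 0; c < n; ++c) {
    const int ci = centers(c, 0), cj = centers(c, 1), ck = centers(c, 2);
    if (ci < 0 || ci >= nx || cj < 0 || cj >= ny || ck < 0 || ck >= nz)
      stop("patch center outside the volume");
    for (int z = 0; z < s; ++z) {
      const int kk = clampi(ck + z - rs, 0, nz - 1);
      for (int y = 0; y < s; ++y) {
        const int jj = clampi(cj + y - rs, 0, ny - 1);
        for (int x = 0; x < s; ++x) {
          const int ii = clampi(ci + x - rs, 0, nx - 1);
          P[x + s * (y + s * z)] =
              v[(size_t)ii + (size_t)nx * ((size_t)jj + (size_t)ny * kk)];
        }
      }
    }
    double mu = 0.0;
    for (int i = 0; i < s3; ++i) mu += P[i];
    mu /= s3;
    double ss = 0.0;
    for (int i = 0; i < s3; ++i) {
      const double d = P[i] - mu;
      ss += d * d;
    }
    const double sd = s3 > 1 ? std::sqrt(ss / (s3 - 1)) : 0.0;
    if (sd < 1e-12) {
      std::fill(P.begin(), P.end(), 0.0);
    } else {
      for (int i = 0; i < s3; ++i) P[i] = (P[i] - mu) / sd;
    }
    for (int z = 0; z < se; ++z) {
      const int pz = clampi(z - 1, 0, s - 1);
      for (int y = 0; y < se; ++y) {
        const int py = clampi(y - 1, 0, s - 1);
        for (int x = 0; x < se; ++x) {
          const int px = clampi(x - 1, 0, s - 1);
          E[x + se * (y + (size_t)se * z)] = P[px + s * (py + s * pz)];
        }
      }
    }
    double* col = outbase + (size_t)c * nfeat;
    for (int z = 0; z < s; ++z) {
      for (int y = 0; y < s; ++y) {
        for (int x = 0; x < s; ++x) {
          const int q = x + s * (y + s * z);
          const int ex = x + 1, ey = y + 1, ez = z + 1;
          const size_t b = ex + se * (ey + (size_t)se * ez);
#define EAT(dx, dy, dz) E[b + (dx) + se * ((dy) + (size_t)se * (dz))]
          const double c0 = E[b];
          col[q] = c0;
          col[1 * s3 + q] = EAT(1, 0, 0) - EAT(-1, 0, 0);
          col[2 * s3 + q] = EAT(0, 1, 0) - EAT(0, -1, 0);
          col[3 * s3 + q] = EAT(0, 0, 1) - EAT(0, 0, -1);
          col[4 * s3 + q] = EAT(1, 0, 0) - 2.0 * c0 + EAT(-1, 0, 0);
          col[5 * s3 + q] = EAT(0, 1, 0) - 2.0 * c0 + EAT(0, -1, 0);
          col[6 * s3 + q] = EAT(0, 0, 1) - 2.0 * c0 + EAT(0, 0, -1);
          double hx = 0.0, hy = 0.0, hz = 0.0;
          for (int a = -1; a <= 1; ++a)
            for (int bb = -1; bb <= 1; ++bb) {
              hx += EAT(0, a, bb);
              hy += EAT(a, 0, bb);
              hz += EAT(a, bb, 0);
            }
          col[7 * s3 + q] = hx / 9.0 - c0;
          col[8 * s3 + q] = hy / 9.0 - c0;
          col[9 * s3 + q] = hz / 9.0 - c0;
          double sx = 0.0, sy = 0.0, sz = 0.0, sum = 0.0;
          double mx = c0, mn = c0;
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                const double e = EAT(dx, dy, dz);
                sx += dx * w3[dy + 1] * w3[dz + 1] * e;
                sy += dy * w3[dx + 1] * w3[dz + 1] * e;
                sz += dz * w3[dx + 1] * w3[dy + 1] * e;
                sum += e;
                if (e > mx) mx = e;
                if (e < mn) mn = e;
              }
          col[10 * s3 + q] = sx;
          col[11 * s3 + q] = sy;
          col[12 * s3 + q] = sz;
          col[13 * s3 + q] = sum - 27.0 * c0;
          col[14 * s3 + q] = mx - mn;
#undef EAT
        }
      }
    }
  }
}

// Returns a (15 * (2*rs+1)^3) x n matrix, one column per center.
// [[Rcpp::export]]
NumericMatrix cpp_patch_features(NumericVector vol, IntegerVector dim,
                                 IntegerMatrix centers, int rs) {
  const int s = 2 * rs + 1;
  NumericMatrix out(15 * s * s * s, centers.nrow());
  patch_features_core(REAL(vol), INTEGER(dim), centers, rs, REAL(out));
  return out;
}

// Fill one feature matrix for several volumes on a shared grid: column
// block a (0-based) holds the features of volume a at all `centers`, so
// the result is nfeat x (n * n_vols).  Avoids per-volume matrices and
// their concatenation copy on the fusion hot path.
// [[Rcpp::export]]
NumericMatrix cpp_patch_features_multi(List vols, IntegerVector dim,
                                       IntegerMatrix centers, int rs) {
  const int nv = vols.size();
  const int s = 2 * rs + 1;
  const int nfeat = 15 * s * s * s;
  const int n = centers.nrow();
  NumericMatrix out(nfeat, n * nv);
  for (int a = 0; a < nv; ++a) {
    NumericVector v = vols[a];
    patch_features_core(REAL(v), INTEGER(dim), centers, rs,
                        REAL(out) + (size_t)a * n * nfeat);
  }
  return out;
}
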