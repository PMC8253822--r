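// Voxel-level inner loops for subtomogram work: trilinear affine resampling
// and masked normalized cross-correlation over rotation/shift grids.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Trilinear interpolation at 0-based voxel coordinates; outside -> 0.
static inline double trilin(const arma::cube& v, double x, double y, double z) {
  const int nx = v.n_rows, ny = v.n_cols, nz = v.n_slices;
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return 0.0;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 == nx - 1) i0--;
  if (j0 == ny - 1) j0--;
  if (k0 == nz - 1) k0--;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double c000 = v(i0, j0, k0),     c100 = v(i0 + 1, j0, k0);
  double c010 = v(i0, j0 + 1, k0), c110 = v(i0 + 1, j0 + 1, k0);
  double c001 = v(i0, j0, k0 + 1), c101 = v(i0 + 1, j0, k0 + 1);
  double c011 = v(i0, j0 + 1, k0 + 1), c111 = v(i0 + 1, j0 + 1, k0 + 1);
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// out(p) = vol(M * (p - c_out - t_pre) + c_in + t_post); p, t in voxel units,
// c_out/c_in are the box centers ((dim-1)/2).
// [[Rcpp::export]]
arma::cube cpp_resample(const arma::cube& vol, const arma::mat& M,
                        const arma::vec& t_pre, const arma::vec& t_post,
                        const IntegerVector& out_dim) {
  const int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  arma::cube out(ox, oy, oz);
  const double cxo = (ox - 1) / 2.0, cyo = (oy - 1) / 2.0, czo = (oz - 1) / 2.0;
  const double cxi = (vol.n_rows - 1) / 2.0, cyi = (vol.n_cols - 1) / 2.0,
               czi = (vol.n_slices - 1) / 2.0;
  for (int k = 0; k < oz; ++k) {
    for (int j = 0; j < oy; ++j) {
      for (int i = 0; i < ox; ++i) {
        const double px = i - cxo - t_pre[0];
        const double py = j - cyo - t_pre[1];
        const double pz = k - czo - t_pre[2];
        const double qx = M(0, 0) * px + M(0, 1) * py + M(0, 2) * pz + cxi + t_post[0];
        const double qy = M(1, 0) * px + M(1, 1) * py + M(1, 2) * pz + cyi + t_post[1];
        const double qz = M(2, 0) * px + M(2, 1) * py + M(2, 2) * pz + czi + t_post[2];
        out(i, j, k) = trilin(vol, qx, qy, qz);
      }
    }
  }
  return out;
}

// Masked NCC of `sub` against `ref` resampled under every (rotation, shift)
// candidate: score(k, s) = NCC_mask( sub(p), ref(M_k (p - t_s) + c_ref) ).
// Ms holds K row-stacked 3x3 matrices (3K x 3); shifts is 3 x S in INTEGER
// voxel units. Each rotation is resampled once into a padded cube and
// reused across the shift grid. Returns a K x S score matrix.
// [[Rcpp::export]]
NumericMatrix cpp_score_grid(const arma::cube& sub, const arma::cube& ref,
                             const arma::cube& mask, const arma::mat& Ms,
                             const arma::mat& shifts) {
  const int K = Ms.n_rows / 3, S = shifts.n_cols;
  const int nx = sub.n_rows, ny = sub.n_cols, nz = sub.n_slices;
  const double cxs = (nx - 1) / 2.0, cys = (ny - 1) / 2.0, czs = (nz - 1) / 2.0;
  const double cxr = (ref.n_rows - 1) / 2.0, cyr = (ref.n_cols - 1) / 2.0,
               czr = (ref.n_slices - 1) / 2.0;
  int m = 0;
  for (int s = 0; s < S; ++s)
    for (int d = 0; d < 3; ++d)
      m = std::max(m, (int)std::ceil(std::fabs(shifts(d, s))));

  // collect masked voxels once
  std::vector<double> wv, av;
  std::vector<int> ix, iy, iz;
  double wsum = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double w = mask(i, j, k);
        if (w > 1e-3) {
          wv.push_back(w);
          av.push_back(sub(i, j, k));
          ix.push_back(i); iy.push_back(j); iz.push_back(k);
          wsum += w;
        }
      }
  const size_t n = wv.size();
  double amean = 0;
  for (size_t t = 0; t < n; ++t) amean += wv[t] * av[t];
  amean /= wsum;
  double avar = 0;
  for (size_t t = 0; t < n; ++t) {
    double d = av[t] - amean;
    avar += wv[t] * d * d;
  }

  const int pxn = nx + 2 * m, pyn = ny + 2 * m, pzn = nz + 2 * m;
  arma::cube rot(pxn, pyn, pzn);
  NumericMatrix out(K, S);
  for (int kk = 0; kk < K; ++kk) {
    arma::mat M = Ms.rows(3 * kk, 3 * kk + 2);
    for (int k = 0; k < pzn; ++k)
      for (int j = 0; j < pyn; ++j)
        for (int i = 0; i < pxn; ++i) {
          const double x = i - m - cxs, y = j - m - cys, z = k - m - czs;
          rot(i, j, k) = trilin(ref,
            M(0, 0) * x + M(0, 1) * y + M(0, 2) * z + cxr,
            M(1, 0) * x + M(1, 1) * y + M(1, 2) * z + cyr,
            M(2, 0) * x + M(2, 1) * y + M(2, 2) * z + czr);
        }
    for (int ss = 0; ss < S; ++ss) {
      const int sx = (int)std::lround(shifts(0, ss));
      const int sy = (int)std::lround(shifts(1, ss));
      const int sz = (int)std::lround(shifts(2, ss));
      double bsum = 0, cov = 0, bvar = 0;
      std::vector<double> bv(n);
      for (size_t t = 0; t < n; ++t) {
        bv[t] = rot(ix[t] + m - sx, iy[t] + m - sy, iz[t] + m - sz);
        bsum += wv[t] * bv[t];
      }
      const double bmean = bsum / wsum;
      for (size_t t = 0; t < n; ++t) {
        const double db = bv[t] - bmean;
        cov += wv[t] * (av[t] - amean) * db;
        bvar += wv[t] * db * db;
      }
      const double den = std::sqrt(avar * bvar);
      out(kk, ss) = (den > 0) ? cov / den : 0.0;
    }
  }
  return out;
}
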