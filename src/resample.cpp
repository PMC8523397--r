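#include <Rcpp.h>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int n1, int n2) {
  return i + n1 * (j + n2 * k);
}

// Trilinear sampling of a 3-D array at continuous 1-based voxel coordinates.
// [[Rcpp::export]]
NumericVector sample_trilinear_cpp(NumericVector vol, IntegerVector dims,
                                   NumericVector xs, NumericVector ys,
                                   NumericVector zs, double background) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  int m = xs.size();
  NumericVector out(m);
  for (int s = 0; s < m; ++s) {
    double x = xs[s] - 1.0, y = ys[s] - 1.0, z = zs[s] - 1.0;
    if (x < 0 || y < 0 || z < 0 || x > n1 - 1 || y > n2 - 1 || z > n3 - 1) {
      out[s] = background;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    int x1 = std::min(x0 + 1, n1 - 1);
    int y1 = std::min(y0 + 1, n2 - 1);
    int z1 = std::min(z0 + 1, n3 - 1);
    double fx = x - x0, fy = y - y0, fz = z - z0;
    double c000 = vol[idx3(x0, y0, z0, n1, n2)];
    double c100 = vol[idx3(x1, y0, z0, n1, n2)];
    double c010 = vol[idx3(x0, y1, z0, n1, n2)];
    double c110 = vol[idx3(x1, y1, z0, n1, n2)];
    double c001 = vol[idx3(x0, y0, z1, n1, n2)];
    double c101 = vol[idx3(x1, y0, z1, n1, n2)];
    double c011 = vol[idx3(x0, y1, z1, n1, n2)];
    double c111 = vol[idx3(x1, y1, z1, n1, n2)];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[s] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Nearest-neighbour sampling at continuous 1-based voxel coordinates.
// [[Rcpp::export]]
NumericVector sample_nearest_cpp(NumericVector vol, IntegerVector dims,
                                 NumericVector xs, NumericVector ys,
                                 NumericVector zs, double background) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  int m = xs.size();
  NumericVector out(m);
  for (int s = 0; s < m; ++s) {
    int x = (int)std::floor(xs[s] - 1.0 + 0.5);
    int y = (int)std::floor(ys[s] - 1.0 + 0.5);
    int z = (int)std::floor(zs[s] - 1.0 + 0.5);
    if (x < 0 || y < 0 || z < 0 || x >= n1 || y >= n2 || z >= n3) {
      out[s] = background;
      continue;
    }
    out[s] = vol[idx3(x, y, z, n1, n2)];
  }
  return out;
}

// Block matching for non-rigid refinement: for each control point, find the
// integer displacement d (|d| <= search, per axis) maximizing the normalized
// cross-correlation between moving(c + d + p) and fixed(c + p) over the
// patch p in [-patch, patch]^3. Zero-variance fixed patches get d = 0.
// Returns an (nctrl x 3) matrix of displacements in voxels.
// [[Rcpp::export]]
NumericMatrix block_match_cpp(NumericVector fixedv, NumericVector movingv,
                              IntegerVector dims, IntegerMatrix ctrl,
                              int patch, int search) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  int nc = ctrl.nrow();
  NumericMatrix out(nc, 3);
  for (int c = 0; c < nc; ++c) {
    int ci = ctrl(c, 0) - 1, cj = ctrl(c, 1) - 1, ck = ctrl(c, 2) - 1;
    // gather fixed patch
    std::vector<double> f;
    std::vector<int> pi, pj, pk;
    for (int dk = -patch; dk <= patch; ++dk)
      for (int dj = -patch; dj <= patch; ++dj)
        for (int di = -patch; di <= patch; ++di) {
          int ii = ci + di, jj = cj + dj, kk = ck + dk;
          if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
            continue;
          f.push_back(fixedv[idx3(ii, jj, kk, n1, n2)]);
          pi.push_back(ii); pj.push_back(jj); pk.push_back(kk);
        }
    int m = f.size();
    if (m < 8) continue;
    double fm = 0.0;
    for (int s = 0; s < m; ++s) fm += f[s];
    fm /= m;
    double fss = 0.0;
    for (int s = 0; s < m; ++s) fss += (f[s] - fm) * (f[s] - fm);
    if (fss < 1e-10) continue;  // flat patch: keep zero displacement
    double best = -2.0;
    int bi = 0, bj = 0, bk = 0;
    for (int dk = -search; dk <= search; ++dk)
      for (int dj = -search; dj <= search; ++dj)
        for (int di = -search; di <= search; ++di) {
          double gm = 0.0;
          bool ok = true;
          std::vector<double> g(m);
          for (int s = 0; s < m; ++s) {
            int ii = pi[s] + di, jj = pj[s] + dj, kk = pk[s] + dk;
            if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 ||
                kk < 0 || kk >= n3) { ok = false; break; }
            g[s] = movingv[idx3(ii, jj, kk, n1, n2)];
            gm += g[s];
          }
          if (!ok) continue;
          gm /= m;
          double gss = 0.0, cross = 0.0;
          for (int s = 0; s < m; ++s) {
            double gd = g[s] - gm;
            gss += gd * gd;
            cross += (f[s] - fm) * gd;
          }
          if (gss < 1e-10) continue;
          double ncc = cross / std::sqrt(fss * gss);
          if (ncc > best + 1e-12) {  // deterministic tie-break: first best wins
            best = ncc;
            bi = di; bj = dj; bk = dk;
          }
        }
    out(c, 0) = bi;
    out(c, 1) = bj;
    out(c, 2) = bk;
  }
  return out;
}
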