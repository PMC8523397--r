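#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int n1, int n2) {
  return i + n1 * (j + n2 * k);
}

// Symmetric grey-level co-occurrence counts for one voxel offset.
// q holds levels 1..G (anything else ignored); mask marks in-VOI voxels.
// [[Rcpp::export]]
IntegerMatrix glcm_pairs_cpp(IntegerVector q, LogicalVector mask,
                             IntegerVector dims, IntegerVector offset, int G) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  int o1 = offset[0], o2 = offset[1], o3 = offset[2];
  IntegerMatrix out(G, G);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        int a = idx3(i, j, k, n1, n2);
        if (!mask[a]) continue;
        int ii = i + o1, jj = j + o2, kk = k + o3;
        if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
          continue;
        int b = idx3(ii, jj, kk, n1, n2);
        if (!mask[b]) continue;
        int ga = q[a], gb = q[b];
        if (ga < 1 || ga > G || gb < 1 || gb > G) continue;
        out(ga - 1, gb - 1) += 1;
        out(gb - 1, ga - 1) += 1;
      }
  return out;
}

// Maximal run counts along one direction: G x maxlen matrix.
// A run starts at a voxel whose predecessor along the direction is not a
// same-level in-mask voxel; runs are broken by the mask and the grid border.
// [[Rcpp::export]]
IntegerMatrix glrlm_runs_cpp(IntegerVector q, LogicalVector mask,
                             IntegerVector dims, IntegerVector dir, int G) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  int d1 = dir[0], d2 = dir[1], d3 = dir[2];
  int maxlen = std::max(n1, std::max(n2, n3));
  IntegerMatrix out(G, maxlen);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        int a = idx3(i, j, k, n1, n2);
        if (!mask[a]) continue;
        int g = q[a];
        if (g < 1 || g > G) continue;
        int pi = i - d1, pj = j - d2, pk = k - d3;
        if (pi >= 0 && pi < n1 && pj >= 0 && pj < n2 && pk >= 0 && pk < n3) {
          int p = idx3(pi, pj, pk, n1, n2);
          if (mask[p] && q[p] == g) continue;  // not a run start
        }
        int len = 1;
        int ci = i + d1, cj = j + d2, ck = k + d3;
        while (ci >= 0 && ci < n1 && cj >= 0 && cj < n2 && ck >= 0 && ck < n3) {
          int c = idx3(ci, cj, ck, n1, n2);
          if (!mask[c] || q[c] != g) break;
          ++len;
          ci += d1; cj += d2; ck += d3;
        }
        if (len > maxlen) len = maxlen;
        out(g - 1, len - 1) += 1;
      }
  return out;
}

// 26-connected constant-level zones: returns a (nzones x 2) matrix of
// (level, size) pairs in deterministic scan order.
// [[Rcpp::export]]
IntegerMatrix glszm_zones_cpp(IntegerVector q, LogicalVector mask,
                              IntegerVector dims, int G) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  int n = n1 * n2 * n3;
  std::vector<char> seen(n, 0);
  std::vector<int> lev, siz;
  std::vector<int> stack;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        int a = idx3(i, j, k, n1, n2);
        if (!mask[a] || seen[a]) continue;
        int g = q[a];
        if (g < 1 || g > G) continue;
        int size = 0;
        stack.clear();
        stack.push_back(a);
        seen[a] = 1;
        while (!stack.empty()) {
          int cur = stack.back();
          stack.pop_back();
          ++size;
          int ck = cur / (n1 * n2);
          int cj = (cur / n1) % n2;
          int ci = cur % n1;
          for (int dk = -1; dk <= 1; ++dk)
            for (int dj = -1; dj <= 1; ++dj)
              for (int di = -1; di <= 1; ++di) {
                if (di == 0 && dj == 0 && dk == 0) continue;
                int ii = ci + di, jj = cj + dj, kk = ck + dk;
                if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 ||
                    kk < 0 || kk >= n3) continue;
                int b = idx3(ii, jj, kk, n1, n2);
                if (!mask[b] || seen[b] || q[b] != g) continue;
                seen[b] = 1;
                stack.push_back(b);
              }
        }
        lev.push_back(g);
        siz.push_back(size);
      }
  IntegerMatrix out(lev.size(), 2);
  for (size_t z = 0; z < lev.size(); ++z) {
    out(z, 0) = lev[z];
    out(z, 1) = siz[z];
  }
  return out;
}

// NGTDM accumulators: per level, the count of voxels with at least one valid
// 26-neighbour and the summed absolute difference to the neighbourhood mean.
// [[Rcpp::export]]
NumericMatrix ngtdm_table_cpp(IntegerVector q, LogicalVector mask,
                              IntegerVector dims, int G) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  NumericMatrix out(G, 2);  // col 0: n_i, col 1: s_i
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        int a = idx3(i, j, k, n1, n2);
        if (!mask[a]) continue;
        int g = q[a];
        if (g < 1 || g > G) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 ||
                  kk < 0 || kk >= n3) continue;
              int b = idx3(ii, jj, kk, n1, n2);
              if (!mask[b]) continue;
              sum += q[b];
              ++cnt;
            }
        if (cnt == 0) continue;
        out(g - 1, 0) += 1.0;
        out(g - 1, 1) += std::fabs((double)g - sum / cnt);
      }
  return out;
}

// Connected-component labelling of a binary mask (connectivity 6 or 26).
// Labels are assigned in scan order starting at 1.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  int n = n1 * n2 * n3;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        int a = idx3(i, j, k, n1, n2);
        if (!mask[a] || lab[a] != 0) continue;
        ++next;
        stack.clear();
        stack.push_back(a);
        lab[a] = next;
        while (!stack.empty()) {
          int cur = stack.back();
          stack.pop_back();
          int ck = cur / (n1 * n2);
          int cj = (cur / n1) % n2;
          int ci = cur % n1;
          for (int dk = -1; dk <= 1; ++dk)
            for (int dj = -1; dj <= 1; ++dj)
              for (int di = -1; di <= 1; ++di) {
                int ad = std::abs(di) + std::abs(dj) + std::abs(dk);
                if (ad == 0) continue;
                if (connectivity == 6 && ad > 1) continue;
                int ii = ci + di, jj = cj + dj, kk = ck + dk;
                if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 ||
                    kk < 0 || kk >= n3) continue;
                int b = idx3(ii, jj, kk, n1, n2);
                if (!mask[b] || lab[b] != 0) continue;
                lab[b] = next;
                stack.push_back(b);
              }
        }
      }
  lab.attr("dim") = dims;
  return lab;
}
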