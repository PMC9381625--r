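#include <Rcpp.h>
using namespace Rcpp;

// Per-slice texture matrix builders. Input is an integer matrix of gray
// levels (1..ng) with NA marking voxels outside the VOI. All neighborhoods
// are in-plane (forced 2D), distance 1: 8 neighbors for the isotropic
// families, 4 symmetric directions for GLCM/GLRLM.

static inline bool valid(const IntegerMatrix& m, int i, int j) {
  return i >= 0 && j >= 0 && i < m.nrow() && j < m.ncol() &&
         m(i, j) != NA_INTEGER;
}

// Symmetric co-occurrence counts for one direction (di, dj).
// [[Rcpp::export]]
NumericMatrix cpp_glcm_slice(IntegerMatrix m, int di, int dj, int ng) {
  NumericMatrix P(ng, ng);
  for (int i = 0; i < m.nrow(); i++)
    for (int j = 0; j < m.ncol(); j++) {
      if (m(i, j) == NA_INTEGER) continue;
      if (!valid(m, i + di, j + dj)) continue;
      int a = m(i, j) - 1, b = m(i + di, j + dj) - 1;
      P(a, b) += 1.0;
      P(b, a) += 1.0;
    }
  return P;
}

// Run-length counts for one direction; runs break at NA and slice edges.
// [[Rcpp::export]]
NumericMatrix cpp_glrlm_slice(IntegerMatrix m, int di, int dj, int ng) {
  int maxlen = std::max(m.nrow(), m.ncol());
  NumericMatrix P(ng, maxlen);
  for (int i = 0; i < m.nrow(); i++)
    for (int j = 0; j < m.ncol(); j++) {
      if (m(i, j) == NA_INTEGER) continue;
      int lev = m(i, j);
      // run start: predecessor along (di,dj) absent or different level
      if (valid(m, i - di, j - dj) && m(i - di, j - dj) == lev) continue;
      int len = 1;
      int ci = i + di, cj = j + dj;
      while (valid(m, ci, cj) && m(ci, cj) == lev) {
        len++; ci += di; cj += dj;
      }
      P(lev - 1, len - 1) += 1.0;
    }
  return P;
}

// 8-connected equal-level zones; returns one row (level, size) per zone.
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_slice(IntegerMatrix m) {
  int nr = m.nrow(), nc = m.ncol();
  std::vector<bool> seen((size_t)nr * nc, false);
  std::vector<int> levs, sizes;
  std::vector<std::pair<int,int> > stack;
  for (int i = 0; i < nr; i++)
    for (int j = 0; j < nc; j++) {
      if (m(i, j) == NA_INTEGER || seen[(size_t)i * nc + j]) continue;
      int lev = m(i, j), size = 0;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      seen[(size_t)i * nc + j] = true;
      while (!stack.empty()) {
        std::pair<int,int> p = stack.back(); stack.pop_back();
        size++;
        for (int di = -1; di <= 1; di++)
          for (int dj = -1; dj <= 1; dj++) {
            if (di == 0 && dj == 0) continue;
            int ci = p.first + di, cj = p.second + dj;
            if (!valid(m, ci, cj)) continue;
            if (m(ci, cj) != lev) continue;
            if (seen[(size_t)ci * nc + cj]) continue;
            seen[(size_t)ci * nc + cj] = true;
            stack.push_back(std::make_pair(ci, cj));
          }
      }
      levs.push_back(lev);
      sizes.push_back(size);
    }
  IntegerMatrix out(levs.size(), 2);
  for (int z = 0; z < (int)levs.size(); z++) {
    out(z, 0) = levs[z];
    out(z, 1) = sizes[z];
  }
  return out;
}

// Dependence counts: for each VOI voxel, j = 1 + number of 8-neighbors whose
// level differs by at most alpha; returns ng x 9 count matrix.
// [[Rcpp::export]]
NumericMatrix cpp_gldm_slice(IntegerMatrix m, int ng, int alpha) {
  NumericMatrix P(ng, 9);
  for (int i = 0; i < m.nrow(); i++)
    for (int j = 0; j < m.ncol(); j++) {
      if (m(i, j) == NA_INTEGER) continue;
      int lev = m(i, j), dep = 0;
      for (int di = -1; di <= 1; di++)
        for (int dj = -1; dj <= 1; dj++) {
          if (di == 0 && dj == 0) continue;
          if (!valid(m, i + di, j + dj)) continue;
          if (std::abs(m(i + di, j + dj) - lev) <= alpha) dep++;
        }
      P(lev - 1, dep) += 1.0;
    }
  return P;
}

// Neighboring gray-tone difference: per level, count n_i and the summed
// absolute difference s_i between the level and the mean of its valid
// 8-neighborhood; voxels with no valid neighbor are excluded.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm_slice(IntegerMatrix m, int ng) {
  NumericMatrix out(ng, 2);  // columns: n_i, s_i
  for (int i = 0; i < m.nrow(); i++)
    for (int j = 0; j < m.ncol(); j++) {
      if (m(i, j) == NA_INTEGER) continue;
      double sum = 0.0; int cnt = 0;
      for (int di = -1; di <= 1; di++)
        for (int dj = -1; dj <= 1; dj++) {
          if (di == 0 && dj == 0) continue;
          if (!valid(m, i + di, j + dj)) continue;
          sum += m(i + di, j + dj); cnt++;
        }
      if (cnt == 0) continue;
      int lev = m(i, j);
      out(lev - 1, 0) += 1.0;
      out(lev - 1, 1) += std::fabs(lev - sum / cnt);
    }
  return out;
}
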