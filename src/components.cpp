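// 26-connected component labelling on a 3D binary mask; returns the mask of
// the largest component (ties broken by lowest starting linear index).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
LogicalVector cpp_largest_component(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> comp(n, 0);
  std::vector<R_xlen_t> stack;
  int ncomp = 0;
  R_xlen_t best_size = 0;
  int best_comp = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || comp[start]) continue;
    ++ncomp;
    R_xlen_t size = 0;
    stack.clear();
    stack.push_back(start);
    comp[start] = ncomp;
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      ++size;
      int x = p % nx, y = (p / nx) % ny, z = p / ((R_xlen_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            R_xlen_t q = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (mask[q] && !comp[q]) {
              comp[q] = ncomp;
              stack.push_back(q);
            }
          }
    }
    if (size > best_size) { best_size = size; best_comp = ncomp; }
  }
  LogicalVector keep(n);
  for (R_xlen_t i = 0; i < n; ++i) keep[i] = comp[i] == best_comp && best_comp > 0;
  return keep;
}
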