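#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labeling of a logical mask by breadth-first
// search, at 6-, 18- or 26-connectivity. Labels are dense from 1 in
// order of first (column-major) encounter. Used for cluster extraction
// in t-maps and for permutation max-extent nulls, where it is called
// many times per analysis.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbor offsets by connectivity class
  std::vector<int> dx, dy, dz;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }

  IntegerVector labels(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int idx = 0; idx < n; ++idx) {
    if (!mask[idx] || labels[idx] != 0) continue;
    ++next;
    labels[idx] = next;
    stack.clear();
    stack.push_back(idx);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int x = cur % nx, y = (cur / nx) % ny, z = cur / (nx * ny);
      for (size_t k = 0; k < dx.size(); ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int nb = xx + nx * (yy + ny * zz);
        if (mask[nb] && labels[nb] == 0) {
          labels[nb] = next;
          stack.push_back(nb);
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}
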