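// 3D connected-component labeling with 26-connectivity (flood fill).
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int D = dims[0], H = dims[1], W = dims[2];
  if ((size_t)D * H * W != (size_t)mask.size()) stop("mask length does not match dims");
  IntegerVector lab(mask.size(), 0);
  std::vector<size_t> stack;
  int next = 0;
  for (size_t s = 0; s < (size_t)mask.size(); ++s) {
    if (mask[s] != TRUE || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const size_t cur = stack.back();
      stack.pop_back();
      const int z = cur % D, y = (cur / D) % H, x = cur / ((size_t)D * H);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            const int nz = z + dz, ny = y + dy, nx = x + dx;
            if (nz < 0 || nz >= D || ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
            const size_t q = (size_t)nz + (size_t)D * ((size_t)ny + (size_t)H * (size_t)nx);
            if (mask[q] == TRUE && lab[q] == 0) {
              lab[q] = next;
              stack.push_back(q);
            }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
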