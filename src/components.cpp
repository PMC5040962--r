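#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of a logical mask by iterative flood fill.
// Labels are 1..n in scan order of the first pixel encountered.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity = 8) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(256);
  int next = 0;
  const int di8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int di4[4] = {-1, 0, 0, 1};
  const int dj4[4] = {0, -1, 1, 0};
  const int *di = connectivity == 8 ? di8 : di4;
  const int *dj = connectivity == 8 ? dj8 : dj4;
  const int nn = connectivity;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int k = 0; k < nn; ++k) {
          int qi = pi + di[k], qj = pj + dj[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) && !lab(qi, qj)) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  return lab;
}
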