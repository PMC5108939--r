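#include <Rcpp.h>
using namespace Rcpp;

// Does the matrix contain any 2x2 checkerboard ([[1,0],[0,1]] or its mirror)?
// For each column pair it suffices that some row has (1,0) and some row (0,1).
static bool has_checkerboard(const IntegerMatrix& m) {
  const int nr = m.nrow(), nc = m.ncol();
  for (int c = 0; c < nc - 1; ++c) {
    for (int d = c + 1; d < nc; ++d) {
      bool ten = false, one = false;
      for (int r = 0; r < nr; ++r) {
        const int a = m(r, c), b = m(r, d);
        if (a == 1 && b == 0) ten = true;
        else if (a == 0 && b == 1) one = true;
        if (ten && one) break;
      }
      if (ten && one) return true;
    }
  }
  return false;
}

// Independent-swap kernel: perform n_swaps successful checkerboard swaps by
// rejection sampling of row and column pairs. Row and column sums are
// conserved by construction. Uses R's RNG so set.seed() governs the draw.
// [[Rcpp::export(name = ".swap_kernel")]]
List swap_kernel(IntegerMatrix mat, int n_swaps, double attempt_factor = 200.0) {
  IntegerMatrix m = clone(mat);
  const int nr = m.nrow(), nc = m.ncol();
  int done = 0;
  bool exhausted = false;

  if (nr < 2 || nc < 2) {
    return List::create(_["matrix"] = m, _["done"] = 0,
                        _["no_checkerboard"] = true);
  }

  long long max_attempts =
      (long long)std::max(1000.0, attempt_factor * std::max(1, n_swaps));
  long long attempts = 0;

  while (done < n_swaps) {
    if (attempts >= max_attempts) {
      // rejection sampling is stalling: decide whether any checkerboard
      // remains before declaring the matrix unswappable
      if (!has_checkerboard(m)) { exhausted = true; break; }
      attempts = 0;  // checkerboards exist, keep sampling
    }
    ++attempts;
    int a = (int)(unif_rand() * nr);
    int b = (int)(unif_rand() * (nr - 1)); if (b >= a) ++b;
    int c = (int)(unif_rand() * nc);
    int d = (int)(unif_rand() * (nc - 1)); if (d >= c) ++d;
    const int x = m(a, c), y = m(a, d), z = m(b, c), w = m(b, d);
    if (x == 1 && w == 1 && y == 0 && z == 0) {
      m(a, c) = 0; m(b, d) = 0; m(a, d) = 1; m(b, c) = 1; ++done;
    } else if (x == 0 && w == 0 && y == 1 && z == 1) {
      m(a, c) = 1; m(b, d) = 1; m(a, d) = 0; m(b, c) = 0; ++done;
    }
  }
  return List::create(_["matrix"] = m, _["done"] = done,
                      _["no_checkerboard"] = exhausted && done == 0);
}
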