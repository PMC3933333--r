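#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Sequential dart-throwing selection with a hard-core (minimum separation)
// constraint. Candidate points are scanned in order; a candidate is kept iff
// no previously kept point lies within `minsep` (3D Euclidean). Scanning stops
// once `target` points are kept. Returns 1-based indices of kept candidates
// (length < target signals packing failure to the caller).
//
// A uniform cell grid of edge `minsep` is used so each candidate only checks
// the 27 neighbouring cells.

static inline int64_t cell_key(int ix, int iy, int iz) {
  // pack three 21-bit signed ints into one 64-bit key
  const int64_t B = 1 << 20;
  return (((int64_t)(ix + B)) << 42) | (((int64_t)(iy + B)) << 21) |
         ((int64_t)(iz + B));
}

// [[Rcpp::export(name = ".hardcoreSelect")]]
IntegerVector hardcoreSelect(NumericMatrix pts, double minsep, int target) {
  const int n = pts.nrow();
  if (minsep <= 0.0 || target <= 0) {
    IntegerVector out(std::min(n, target));
    for (int i = 0; i < out.size(); ++i) out[i] = i + 1;
    return out;
  }
  const double m2 = minsep * minsep;
  std::unordered_map<int64_t, std::vector<int> > grid;
  grid.reserve((size_t)target * 2);
  std::vector<int> kept;
  kept.reserve(target);

  for (int i = 0; i < n && (int)kept.size() < target; ++i) {
    const double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    const int ix = (int)std::floor(x / minsep);
    const int iy = (int)std::floor(y / minsep);
    const int iz = (int)std::floor(z / minsep);
    bool ok = true;
    for (int dx = -1; dx <= 1 && ok; ++dx)
      for (int dy = -1; dy <= 1 && ok; ++dy)
        for (int dz = -1; dz <= 1 && ok; ++dz) {
          auto it = grid.find(cell_key(ix + dx, iy + dy, iz + dz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            const double ddx = x - pts(j, 0);
            const double ddy = y - pts(j, 1);
            const double ddz = z - pts(j, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz < m2) { ok = false; break; }
          }
        }
    if (ok) {
      grid[cell_key(ix, iy, iz)].push_back(i);
      kept.push_back(i);
    }
  }
  IntegerVector out(kept.size());
  for (size_t k = 0; k < kept.size(); ++k) out[k] = kept[k] + 1;
  return out;
}
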