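#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Quality-guided region-growing phase unwrapping for one 3D volume.
// Voxels are admitted into the unwrapped region in order of decreasing
// quality, so the less noisy regions are unwrapped first; each voxel is
// unwrapped against the already-unwrapped neighbour through which it was
// reached, by adding the 2*pi multiple that brings the difference into
// (-pi, pi].  Each connected component of the mask gets its own seed, so
// the result is defined up to one global 2*pi*k per component.
// Voxels whose admitted neighbour difference exceeds `suspect_thresh` are
// flagged: a genuine spatial jump above pi cannot be distinguished from a
// wrap and may have been aliased.

struct QItem {
  double q;
  int idx;
  int parent;
  bool operator<(const QItem& o) const { return q < o.q; }
};

// [[Rcpp::export(name = ".unwrap3d_cpp")]]
List unwrap3d_cpp(NumericVector phase, NumericVector quality,
                  LogicalVector mask, IntegerVector dims,
                  double suspect_thresh) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  const double TWOPI = 2.0 * M_PI;
  NumericVector out(n);
  LogicalVector suspect(n);
  std::vector<char> state(n, 0);  // 0 unvisited, 1 queued/done

  std::vector<int> maskidx;
  maskidx.reserve(n);
  for (int i = 0; i < n; ++i) {
    out[i] = phase[i];
    if (mask[i]) maskidx.push_back(i);
  }
  if (maskidx.empty()) stop("empty mask");

  const int strides[3] = {1, nx, nx * ny};
  std::priority_queue<QItem> pq;
  int n_done = 0, n_suspect = 0;

  auto push_neighbours = [&](int i) {
    int cx = i % nx, cy = (i / nx) % ny, cz = i / (nx * ny);
    int coord[3] = {cx, cy, cz};
    int lim[3] = {nx, ny, nz};
    for (int ax = 0; ax < 3; ++ax) {
      for (int s = -1; s <= 1; s += 2) {
        int c = coord[ax] + s;
        if (c < 0 || c >= lim[ax]) continue;
        int j = i + s * strides[ax];
        if (!mask[j] || state[j]) continue;
        pq.push({quality[j], j, i});
      }
    }
  };

  while (n_done < (int)maskidx.size()) {
    if (pq.empty()) {
      // start a new connected component at its best-quality voxel
      int best = -1; double bq = 0.0;
      for (size_t k = 0; k < maskidx.size(); ++k) {
        int i = maskidx[k];
        if (!state[i] && (best < 0 || quality[i] > bq)) {
          bq = quality[i]; best = i;
        }
      }
      if (best < 0) break;
      state[best] = 1;
      out[best] = phase[best];
      ++n_done;
      push_neighbours(best);
      continue;
    }
    QItem it = pq.top(); pq.pop();
    if (state[it.idx]) continue;
    double d = phase[it.idx] - out[it.parent];
    double k = std::floor((d + M_PI) / TWOPI);
    double u = phase[it.idx] - TWOPI * k;
    out[it.idx] = u;
    state[it.idx] = 1;
    ++n_done;
    if (std::fabs(u - out[it.parent]) > suspect_thresh) {
      suspect[it.idx] = true;
      ++n_suspect;
    }
    push_neighbours(it.idx);
  }

  return List::create(_["unwrapped"] = out,
                      _["suspect"] = suspect,
                      _["n_suspect"] = n_suspect);
}

// Count phase residues: 2x2 loops (all three orientations) around which the
// wrapped gradients do not sum to zero.  A nonzero count marks regions where
// path-dependent unwrapping errors are possible.
// [[Rcpp::export(name = ".count_residues_cpp")]]
int count_residues_cpp(NumericVector phase, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double TWOPI = 2.0 * M_PI;
  auto wrapd = [&](double d) {
    double k = std::floor((d + M_PI) / TWOPI);
    return d - TWOPI * k;
  };
  auto at = [&](int x, int y, int z) {
    return phase[x + nx * (y + (long long)ny * z)];
  };
  int count = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        // xy loop
        if (x + 1 < nx && y + 1 < ny) {
          double s = wrapd(at(x + 1, y, z) - at(x, y, z)) +
                     wrapd(at(x + 1, y + 1, z) - at(x + 1, y, z)) +
                     wrapd(at(x, y + 1, z) - at(x + 1, y + 1, z)) +
                     wrapd(at(x, y, z) - at(x, y + 1, z));
          if (std::fabs(s) > M_PI) ++count;
        }
        // xz loop
        if (x + 1 < nx && z + 1 < nz) {
          double s = wrapd(at(x + 1, y, z) - at(x, y, z)) +
                     wrapd(at(x + 1, y, z + 1) - at(x + 1, y, z)) +
                     wrapd(at(x, y, z + 1) - at(x + 1, y, z + 1)) +
                     wrapd(at(x, y, z) - at(x, y, z + 1));
          if (std::fabs(s) > M_PI) ++count;
        }
        // yz loop
        if (y + 1 < ny && z + 1 < nz) {
          double s = wrapd(at(x, y + 1, z) - at(x, y, z)) +
                     wrapd(at(x, y + 1, z + 1) - at(x, y + 1, z)) +
                     wrapd(at(x, y, z + 1) - at(x, y + 1, z + 1)) +
                     wrapd(at(x, y, z) - at(x, y, z + 1));
          if (std::fabs(s) > M_PI) ++count;
        }
      }
  return count;
}
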