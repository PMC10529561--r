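#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a 0/1 mask with 4- or 8-connectivity,
// breadth-first flood fill. Labels are 1..n in raster-scan discovery order;
// background stays 0.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(IntegerMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  IntegerMatrix lab(H, W);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::queue<int> q;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(i + j * H);
      while (!q.empty()) {
        const int p = q.front(); q.pop();
        const int pi = p % H, pj = p / H;
        for (int k = 0; k < nn; ++k) {
          const int qi = pi + dr8[k], qj = pj + dc8[k];
          if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
          if (mask(qi, qj) != 0 && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            q.push(qi + qj * H);
          }
        }
      }
    }
  }
  return lab;
}

// Grayscale geodesic reconstruction by dilation of `marker` under `mask`
// (marker <= mask pointwise), hybrid algorithm: one forward raster sweep, one
// backward sweep that also seeds a FIFO queue, then queue-driven propagation.
// Equivalent to iterating marker <- min(dilate(marker), mask) to convergence.
// [[Rcpp::export]]
NumericMatrix reconstruct_cpp(NumericMatrix mask, NumericMatrix marker,
                              int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  if (marker.nrow() != H || marker.ncol() != W)
    stop("mask and marker must have the same shape");
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  NumericMatrix J = clone(marker);

  const bool c8 = (connectivity == 8);
  // neighbor offsets split into the raster-order "already visited" half (N-)
  // and its mirror (N+)
  std::vector<int> nm_r, nm_c, np_r, np_c;
  nm_r.push_back(-1); nm_c.push_back(0);   // up
  nm_r.push_back(0);  nm_c.push_back(-1);  // left
  if (c8) {
    nm_r.push_back(-1); nm_c.push_back(-1);
    nm_r.push_back(-1); nm_c.push_back(1);
  }
  for (size_t k = 0; k < nm_r.size(); ++k) {
    np_r.push_back(-nm_r[k]);
    np_c.push_back(-nm_c[k]);
  }

  // forward sweep (column-major raster matches the neighbor split above only
  // for row-major order, so sweep row-major explicitly)
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      double v = J(i, j);
      for (size_t k = 0; k < nm_r.size(); ++k) {
        const int qi = i + nm_r[k], qj = j + nm_c[k];
        if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
        if (J(qi, qj) > v) v = J(qi, qj);
      }
      J(i, j) = std::min(v, mask(i, j));
    }
  }
  // backward sweep + queue seeding
  std::queue<int> q;
  for (int i = H - 1; i >= 0; --i) {
    for (int j = W - 1; j >= 0; --j) {
      double v = J(i, j);
      for (size_t k = 0; k < np_r.size(); ++k) {
        const int qi = i + np_r[k], qj = j + np_c[k];
        if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
        if (J(qi, qj) > v) v = J(qi, qj);
      }
      v = std::min(v, mask(i, j));
      J(i, j) = v;
      for (size_t k = 0; k < np_r.size(); ++k) {
        const int qi = i + np_r[k], qj = j + np_c[k];
        if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
        if (J(qi, qj) < v && J(qi, qj) < mask(qi, qj)) {
          q.push(i + j * H);
          break;
        }
      }
    }
  }
  // queue propagation over the full neighborhood
  std::vector<int> all_r(nm_r), all_c(nm_c);
  all_r.insert(all_r.end(), np_r.begin(), np_r.end());
  all_c.insert(all_c.end(), np_c.begin(), np_c.end());
  while (!q.empty()) {
    const int p = q.front(); q.pop();
    const int pi = p % H, pj = p / H;
    const double vp = J(pi, pj);
    for (size_t k = 0; k < all_r.size(); ++k) {
      const int qi = pi + all_r[k], qj = pj + all_c[k];
      if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
      if (J(qi, qj) < vp && J(qi, qj) < mask(qi, qj)) {
        J(qi, qj) = std::min(vp, mask(qi, qj));
        q.push(qi + qj * H);
      }
    }
  }
  return J;
}
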