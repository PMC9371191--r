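#include <Rcpp.h>
using namespace Rcpp;

// Windowed extremum over an arbitrary offset set (the rasterized disk SE).
// Pixels probed outside the image take `pad`, so erosion pads with the
// maximum representable value and dilation with 0, per the border convention.
static NumericMatrix extremum_filter(const NumericMatrix& img,
                                     const IntegerVector& dr,
                                     const IntegerVector& dc,
                                     double pad, bool take_min) {
  const int nr = img.nrow(), nc = img.ncol(), k = dr.size();
  NumericMatrix out(nr, nc);
  const double* p = img.begin();
  double* q = out.begin();
  int rmax = 0, cmax = 0;
  std::vector<long> off(k);
  for (int t = 0; t < k; ++t) {
    if (std::abs(dr[t]) > rmax) rmax = std::abs(dr[t]);
    if (std::abs(dc[t]) > cmax) cmax = std::abs(dc[t]);
    off[t] = (long)dr[t] + (long)dc[t] * nr;
  }
  for (int j = 0; j < nc; ++j) {
    const bool jfast = (j >= cmax && j < nc - cmax);
    const int i_lo = rmax, i_hi = nr - rmax;  // interior rows
    for (int i = 0; i < nr; ++i) {
      const long base = (long)i + (long)j * nr;
      double v;
      if (jfast && i >= i_lo && i < i_hi) {
        // interior: no bounds checks, direct pointer arithmetic
        v = p[base + off[0]];
        if (take_min) {
          for (int t = 1; t < k; ++t) { const double x = p[base + off[t]]; if (x < v) v = x; }
        } else {
          for (int t = 1; t < k; ++t) { const double x = p[base + off[t]]; if (x > v) v = x; }
        }
      } else {
        v = take_min ? R_PosInf : R_NegInf;
        for (int t = 0; t < k; ++t) {
          const int ii = i + dr[t], jj = j + dc[t];
          const double x = (ii < 0 || ii >= nr || jj < 0 || jj >= nc) ? pad : p[(long)ii + (long)jj * nr];
          if (take_min) { if (x < v) v = x; } else { if (x > v) v = x; }
        }
      }
      q[base] = v;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_min_filter(NumericMatrix img, IntegerVector dr,
                             IntegerVector dc, double pad) {
  return extremum_filter(img, dr, dc, pad, true);
}

// [[Rcpp::export]]
NumericMatrix cpp_max_filter(NumericMatrix img, IntegerVector dr,
                             IntegerVector dc, double pad) {
  return extremum_filter(img, dr, dc, pad, false);
}

// Connected-component labeling (4- or 8-connectivity) by BFS flood fill.
// Labels are assigned in raster-scan order of the first pixel met, so the
// label set is contiguous 1..L and deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 8) ? 8 : 4;
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pi = p % nr, pj = p / nr;
        for (int t = 0; t < nnb; ++t) {
          const int ii = pi + dr8[t], jj = pj + dc8[t];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            stack.push_back(ii + jj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Inner 8-connected boundary: foreground pixels with at least one of their
// 8 neighbours in the background (or beyond the image edge).
// [[Rcpp::export]]
LogicalMatrix cpp_inner_boundary(IntegerMatrix lab) {
  const int nr = lab.nrow(), nc = lab.ncol();
  LogicalMatrix out(nr, nc);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (lab(i, j) == 0) { out(i, j) = false; continue; }
      bool b = false;
      for (int t = 0; t < 8 && !b; ++t) {
        const int ii = i + dr8[t], jj = j + dc8[t];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc || lab(ii, jj) == 0) b = true;
      }
      out(i, j) = b;
    }
  }
  return out;
}
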