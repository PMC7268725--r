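#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Joint spatial-range mean-shift filtering of one pyramid layer.
// R,G,B: the layer's channels; R0,G0,B0: initial colour estimate per pixel
// (the layer itself at the coarsest level, the upsampled coarser result
// otherwise). Each pixel's window iterates to its mode; the converged
// window-mean colour is written out.
// [[Rcpp::export]]
List cpp_mean_shift(NumericMatrix R, NumericMatrix G, NumericMatrix B,
                    NumericMatrix R0, NumericMatrix G0, NumericMatrix B0,
                    int sp, double sr, int max_iters, double eps) {
  int H = R.nrow(), W = R.ncol();
  NumericMatrix outR(H, W), outG(H, W), outB(H, W);
  double sr2 = sr * sr;
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      double x = i, y = j;
      double cr = R0(i, j), cg = G0(i, j), cb = B0(i, j);
      double mr = cr, mg = cg, mb = cb;
      for (int it = 0; it < max_iters; ++it) {
        int u0 = std::max(0, (int)std::ceil(x - sp));
        int u1 = std::min(H - 1, (int)std::floor(x + sp));
        int v0 = std::max(0, (int)std::ceil(y - sp));
        int v1 = std::min(W - 1, (int)std::floor(y + sp));
        double sx = 0, sy = 0, srr = 0, sgg = 0, sbb = 0;
        int n = 0;
        for (int u = u0; u <= u1; ++u) {
          for (int v = v0; v <= v1; ++v) {
            double dr = R(u, v) - cr, dg = G(u, v) - cg, db = B(u, v) - cb;
            if (dr * dr + dg * dg + db * db <= sr2) {
              sx += u; sy += v;
              srr += R(u, v); sgg += G(u, v); sbb += B(u, v);
              ++n;
            }
          }
        }
        if (n == 0) { mr = cr; mg = cg; mb = cb; break; }
        double nx = sx / n, ny = sy / n;
        mr = srr / n; mg = sgg / n; mb = sbb / n;
        double dc = std::sqrt((mr - cr) * (mr - cr) + (mg - cg) * (mg - cg) +
                              (mb - cb) * (mb - cb));
        double ds = std::sqrt((nx - x) * (nx - x) + (ny - y) * (ny - y));
        x = nx; y = ny; cr = mr; cg = mg; cb = mb;
        if (dc < eps && ds < 0.5) break;
      }
      outR(i, j) = mr; outG(i, j) = mg; outB(i, j) = mb;
    }
  }
  return List::create(_["r"] = outR, _["g"] = outG, _["b"] = outB);
}

// Connected-component labelling of non-zero pixels (connectivity 4 or 8).
// [[Rcpp::export]]
IntegerMatrix cpp_label(IntegerMatrix mask, int connectivity) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  const int dx8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dy8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dx4[] = {-1, 1, 0, 0};
  const int dy4[] = {0, 0, -1, 1};
  const int *dx = (connectivity == 8) ? dx8 : dx4;
  const int *dy = (connectivity == 8) ? dy8 : dy4;
  int nd = (connectivity == 8) ? 8 : 4;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * H);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % H, pj = p / H;
        for (int k = 0; k < nd; ++k) {
          int qi = pi + dx[k], qj = pj + dy[k];
          if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
          if (mask(qi, qj) != 0 && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * H);
          }
        }
      }
    }
  }
  return lab;
}

// Block-scan local-maxima candidates: pixel value must be positive, not
// smaller than any value in the LxL block centred on it (truncated at the
// borders), and strictly greater than at least one other block member.
// [[Rcpp::export]]
LogicalMatrix cpp_local_max(NumericMatrix img, int L) {
  int H = img.nrow(), W = img.ncol();
  int r = L / 2;
  LogicalMatrix out(H, W);
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      double v = img(i, j);
      if (v <= 0) continue;
      bool isMax = true, strict = false;
      int u0 = std::max(0, i - r), u1 = std::min(H - 1, i + r);
      int v0 = std::max(0, j - r), v1 = std::min(W - 1, j + r);
      for (int u = u0; u <= u1 && isMax; ++u) {
        for (int w = v0; w <= v1; ++w) {
          double q = img(u, w);
          if (q > v) { isMax = false; break; }
          if (q < v) strict = true;
        }
      }
      out(i, j) = isMax && strict;
    }
  }
  return out;
}
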