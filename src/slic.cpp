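#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Core SLIC assignment loop: k-means in (colour, position) space with a
// spatially windowed search.  Channels are H x W matrices in [0, 1]; step is
// the grid interval S = sqrt(target area); compactness m weights the spatial
// term as (m/S)^2 * d_xy^2 against the squared colour distance.  Returns the
// raw (possibly fragmented) 1-based assignment matrix; connectivity is
// enforced by the caller.
// [[Rcpp::export]]
IntegerMatrix slic_assign(NumericMatrix r, NumericMatrix g, NumericMatrix b,
                          double step, double compactness, int iters) {
  const int H = r.nrow(), W = r.ncol();
  const int ny = std::max(1, (int)std::round(H / step));
  const int nx = std::max(1, (int)std::round(W / step));
  const int K = nx * ny;

  // centers: colour (cr,cg,cb) and position (cy,cx)
  std::vector<double> cr(K), cg(K), cb(K), cy(K), cx(K);
  int k = 0;
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix, ++k) {
      const int y = std::min(H - 1, (int)std::round((iy + 0.5) * H / ny - 0.5));
      const int x = std::min(W - 1, (int)std::round((ix + 0.5) * W / nx - 0.5));
      cy[k] = y; cx[k] = x;
      cr[k] = r(y, x); cg[k] = g(y, x); cb[k] = b(y, x);
    }

  IntegerMatrix lab(H, W);
  NumericMatrix dist(H, W);
  const double ws = compactness * compactness / (step * step);
  const int win = (int)std::ceil(step);

  for (int it = 0; it < iters; ++it) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    for (int c = 0; c < K; ++c) {
      const int y0 = std::max(0, (int)cy[c] - win),
                y1 = std::min(H - 1, (int)cy[c] + win),
                x0 = std::max(0, (int)cx[c] - win),
                x1 = std::min(W - 1, (int)cx[c] + win);
      for (int x = x0; x <= x1; ++x)
        for (int y = y0; y <= y1; ++y) {
          const double dc = (r(y, x) - cr[c]) * (r(y, x) - cr[c]) +
                            (g(y, x) - cg[c]) * (g(y, x) - cg[c]) +
                            (b(y, x) - cb[c]) * (b(y, x) - cb[c]);
          const double ds = (y - cy[c]) * (y - cy[c]) +
                            (x - cx[c]) * (x - cx[c]);
          const double d = dc + ws * ds;
          if (d < dist(y, x)) {
            dist(y, x) = d;
            lab(y, x) = c + 1;
          }
        }
    }
    // update centers
    std::vector<double> sr(K, 0), sg(K, 0), sb(K, 0), sy(K, 0), sx(K, 0);
    std::vector<int> cnt(K, 0);
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        const int c = lab(y, x) - 1;
        if (c < 0) continue; // unreached pixel, claimed below
        sr[c] += r(y, x); sg[c] += g(y, x); sb[c] += b(y, x);
        sy[c] += y; sx[c] += x;
        ++cnt[c];
      }
    for (int c = 0; c < K; ++c)
      if (cnt[c] > 0) {
        cr[c] = sr[c] / cnt[c]; cg[c] = sg[c] / cnt[c]; cb[c] = sb[c] / cnt[c];
        cy[c] = sy[c] / cnt[c]; cx[c] = sx[c] / cnt[c];
      }
  }

  // any pixel outside every search window joins its nearest center spatially
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      if (lab(y, x) == 0) {
        double best = R_PosInf;
        int bc = 1;
        for (int c = 0; c < K; ++c) {
          const double ds = (y - cy[c]) * (y - cy[c]) +
                            (x - cx[c]) * (x - cx[c]);
          if (ds < best) { best = ds; bc = c + 1; }
        }
        lab(y, x) = bc;
      }
  return lab;
}
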