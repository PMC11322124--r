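#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Per-channel median filter over a (2r+1) x (2r+1) window with replicate
// (clamp-to-edge) padding, so the window size is always odd and the median
// is the true middle order statistic of integer samples.
// [[Rcpp::export(name = ".median_filter_cpp")]]
IntegerVector median_filter_cpp(IntegerVector img, int radius) {
  IntegerVector dims = img.attr("dim");
  if (dims.size() != 3 || dims[2] != 3)
    stop("expected an H x W x 3 integer array");
  const int h = dims[0], w = dims[1];
  const int win = 2 * radius + 1;
  const int n = win * win;
  IntegerVector out(img.size());
  out.attr("dim") = dims;
  std::vector<int> buf(n);
  for (int c = 0; c < 3; ++c) {
    const int off = c * h * w;
    for (int x = 0; x < w; ++x) {
      for (int y = 0; y < h; ++y) {
        int k = 0;
        for (int dx = -radius; dx <= radius; ++dx) {
          int xx = std::min(std::max(x + dx, 0), w - 1);
          for (int dy = -radius; dy <= radius; ++dy) {
            int yy = std::min(std::max(y + dy, 0), h - 1);
            buf[k++] = img[off + xx * h + yy];
          }
        }
        std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
        out[off + x * h + y] = buf[n / 2];
      }
    }
  }
  return out;
}
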