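#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a binary raster by breadth-first flood
// fill. connectivity is 4 or 8; labels are assigned in raster-scan order of
// each component's first pixel, starting at 1.
// [[Rcpp::export]]
IntegerMatrix cc_label(const IntegerMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  const int nn = connectivity;
  int next = 0;
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r * nc + c);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pr = p / nc, pc = p % nc;
        for (int k = 0; k < nn; ++k) {
          int qr = pr + dr[k], qc = pc + dc[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (mask(qr, qc) != 0 && lab(qr, qc) == 0) {
            lab(qr, qc) = next;
            stack.push_back(qr * nc + qc);
          }
        }
      }
    }
  }
  return lab;
}

// Moore-neighbour boundary tracing of the outer contour of the component
// with the given label. Returns an ordered (k x 2) matrix of 1-based
// (row, col) boundary pixel coordinates; the first pixel is not repeated at
// the end. Termination by Jacob's criterion (re-entering the start pixel
// with the same backtrack pixel as at the start).
// [[Rcpp::export]]
IntegerMatrix moore_trace(const IntegerMatrix& lab, int id) {
  const int nr = lab.nrow(), nc = lab.ncol();
  // Moore neighbourhood in clockwise (screen) order starting from "west"
  const int dr[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int dc[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  int sr = -1, sc = -1;
  for (int r = 0; r < nr && sr < 0; ++r)
    for (int c = 0; c < nc; ++c)
      if (lab(r, c) == id) { sr = r; sc = c; break; }
  if (sr < 0) stop("label id not present in raster");

  std::vector<int> rows, cols;
  rows.push_back(sr); cols.push_back(sc);
  // start pixel is topmost-leftmost, so its west neighbour is background
  int cr = sr, cc_ = sc;
  int back = 0;                 // direction (index) of the backtrack pixel
  const int back0 = back;
  const int max_steps = 4 * (nr * nc + 4);
  for (int steps = 0; steps < max_steps; ++steps) {
    int found = -1;
    for (int k = 1; k <= 8; ++k) {
      int d = (back + k) % 8;
      int qr = cr + dr[d], qc = cc_ + dc[d];
      if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
      if (lab(qr, qc) == id) { found = d; break; }
    }
    if (found < 0) break;       // isolated single pixel
    // backtrack for the next pixel: the neighbour just before `found` in the
    // clockwise sweep, expressed relative to the new current pixel
    int pr = cr, pc = cc_;
    cr += dr[found]; cc_ += dc[found];
    int prev_d = (found + 7) % 8;  // last background neighbour visited
    int br = pr + dr[prev_d], bc = pc + dc[prev_d];
    // direction index of (br,bc) relative to new (cr,cc)
    back = 0;
    for (int k = 0; k < 8; ++k)
      if (cr + dr[k] == br && cc_ + dc[k] == bc) { back = k; break; }
    if (cr == sr && cc_ == sc && back == back0) break;  // Jacob's criterion
    if (!(cr == sr && cc_ == sc)) {
      rows.push_back(cr); cols.push_back(cc_);
    }
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) {
    out(i, 0) = rows[i] + 1;
    out(i, 1) = cols[i] + 1;
  }
  return out;
}

// Per-pixel coverage of a convex polygon by regular subpixel sampling.
// poly is (m x 2) with columns (x, y) in 0-based pixel-centre coordinates;
// vertices must be in counter-clockwise order (y axis pointing down is
// fine: orientation just flips the sign convention handled below).
// Returns an (nr x nc) matrix of coverage fractions in [0, 1] restricted to
// the polygon's bounding box placed in the full image frame.
// [[Rcpp::export]]
NumericMatrix convex_coverage(const NumericMatrix& poly, int nr, int nc,
                              int samples) {
  const int m = poly.nrow();
  if (m < 3) stop("polygon needs at least 3 vertices");
  // polygon orientation via shoelace
  double a2 = 0.0;
  for (int i = 0; i < m; ++i) {
    int j = (i + 1) % m;
    a2 += poly(i, 0) * poly(j, 1) - poly(j, 0) * poly(i, 1);
  }
  const double orient = (a2 >= 0) ? 1.0 : -1.0;
  double xmin = poly(0, 0), xmax = xmin, ymin = poly(0, 1), ymax = ymin;
  for (int i = 1; i < m; ++i) {
    xmin = std::min(xmin, poly(i, 0)); xmax = std::max(xmax, poly(i, 0));
    ymin = std::min(ymin, poly(i, 1)); ymax = std::max(ymax, poly(i, 1));
  }
  int c0 = std::max(0, (int)std::floor(xmin) - 1);
  int c1 = std::min(nc - 1, (int)std::ceil(xmax) + 1);
  int r0 = std::max(0, (int)std::floor(ymin) - 1);
  int r1 = std::min(nr - 1, (int)std::ceil(ymax) + 1);
  NumericMatrix cov(nr, nc);
  const int s = samples;
  const double inv = 1.0 / s;
  for (int r = r0; r <= r1; ++r) {
    for (int c = c0; c <= c1; ++c) {
      int inside = 0;
      for (int sy = 0; sy < s; ++sy) {
        double y = r - 0.5 + (sy + 0.5) * inv;
        for (int sx = 0; sx < s; ++sx) {
          double x = c - 0.5 + (sx + 0.5) * inv;
          bool in = true;
          for (int i = 0; i < m && in; ++i) {
            int j = (i + 1) % m;
            double cross = (poly(j, 0) - poly(i, 0)) * (y - poly(i, 1)) -
                           (poly(j, 1) - poly(i, 1)) * (x - poly(i, 0));
            if (orient * cross < 0) in = false;
          }
          if (in) ++inside;
        }
      }
      if (inside > 0) cov(r, c) = (double)inside / (s * s);
    }
  }
  return cov;
}
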