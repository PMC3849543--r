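#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// Masks are integer matrices (nrow = height, ncol = width), foreground = 255,
// background = 0. Pixel coordinates exposed to R are 0-based (x = column,
// y = row), origin top-left.

static inline bool in_bounds(int r, int c, int nr, int nc) {
  return r >= 0 && c >= 0 && r < nr && c < nc;
}

// Connected-component labeling by iterative flood fill.
// connectivity: 4 or 8. Returns labels 1..k, 0 for background.
// [[Rcpp::export]]
IntegerMatrix cpp_label(IntegerMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int *dr = connectivity == 8 ? dr8 : dr4;
  const int *dc = connectivity == 8 ? dc8 : dc4;
  const int ndir = connectivity == 8 ? 8 : 4;
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      lab(r, c) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int d = 0; d < ndir; ++d) {
          int rr = p.first + dr[d], cc = p.second + dc[d];
          if (in_bounds(rr, cc, nr, nc) && mask(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// Binary erosion/dilation with a 3x3 square structuring element, iterated.
// Border policy: pixels outside the image are background (0), so erosion
// strips the outermost ring and dilation never reads outside.
// [[Rcpp::export]]
IntegerMatrix cpp_morph(IntegerMatrix mask, bool dilate, int iterations) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix cur = clone(mask);
  for (int it = 0; it < iterations; ++it) {
    IntegerMatrix out(nr, nc);
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        bool hit = dilate ? false : true;
        for (int dr = -1; dr <= 1 && (dilate ? !hit : hit); ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            int rr = r + dr, cc = c + dc;
            int v = in_bounds(rr, cc, nr, nc) ? cur(rr, cc) : 0;
            if (dilate) {
              if (v != 0) { hit = true; break; }
            } else {
              if (v == 0) { hit = false; break; }
            }
          }
        }
        out(r, c) = hit ? 255 : 0;
      }
    }
    cur = out;
  }
  return cur;
}

// Fill enclosed background components (4-connected) of area < max_hole_px.
// Background touching the image border is never a hole.
// [[Rcpp::export]]
IntegerMatrix cpp_fill_holes(IntegerMatrix mask, double max_hole_px) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix inv(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      inv(r, c) = mask(r, c) == 0 ? 255 : 0;
  IntegerMatrix lab = cpp_label(inv, 4);
  int n = lab.attr("n");
  std::vector<double> area(n + 1, 0.0);
  std::vector<bool> border(n + 1, false);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      area[l] += 1.0;
      if (r == 0 || c == 0 || r == nr - 1 || c == nc - 1) border[l] = true;
    }
  }
  IntegerMatrix out = clone(mask);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l != 0 && !border[l] && area[l] < max_hole_px) out(r, c) = 255;
    }
  }
  return out;
}

// Moore-neighbour boundary trace of the component with label `target`,
// starting at its topmost-leftmost pixel. Directions indexed clockwise on
// screen (y down): 0=E,1=SE,2=S,3=SW,4=W,5=NW,6=N,7=NE.
static std::vector<std::pair<int, int> > moore_trace(const IntegerMatrix &lab,
                                                     int target, int r0, int c0) {
  const int nr = lab.nrow(), nc = lab.ncol();
  const int dr[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  const int dc[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  std::vector<std::pair<int, int> > pts;
  pts.push_back(std::make_pair(r0, c0));
  // first move: search W -> NW -> N -> NE -> E ... (clockwise from W)
  int pd = 6; // pretend previous move was northward so search starts at W
  int cr = r0, cc = c0;
  int first_r = -1, first_c = -1, first_d = -1;
  long cap = 4L * nr * nc + 16;
  for (long step = 0; step < cap; ++step) {
    int start = (pd + 6) % 8;
    int found = -1, fr = 0, fc = 0;
    for (int i = 0; i < 8; ++i) {
      int d = (start + i) % 8;
      int rr = cr + dr[d], ccn = cc + dc[d];
      if (in_bounds(rr, ccn, nr, nc) && lab(rr, ccn) == target) {
        found = d; fr = rr; fc = ccn; break;
      }
    }
    if (found < 0) break; // isolated pixel
    if (first_d < 0) { first_r = fr; first_c = fc; first_d = found; }
    else if (cr == r0 && cc == c0 && fr == first_r && fc == first_c && found == first_d)
      break; // back at start, about to repeat the first move (Jacob's criterion)
    pts.push_back(std::make_pair(fr, fc));
    cr = fr; cc = fc; pd = found;
  }
  // the boundary may legitimately revisit the start pixel (1-px spurs); drop
  // a trailing duplicate of the start so the polygon closes implicitly
  while (pts.size() > 1 && pts.back() == pts.front()) pts.pop_back();
  return pts;
}

static double signed_area_rc(const std::vector<std::pair<int, int> > &pts) {
  // shoelace on raw image coordinates (x = col, y = row)
  double a = 0.0;
  size_t n = pts.size();
  for (size_t i = 0; i < n; ++i) {
    size_t j = (i + 1) % n;
    double xi = pts[i].second, yi = pts[i].first;
    double xj = pts[j].second, yj = pts[j].first;
    a += xi * yj - xj * yi;
  }
  return a / 2.0;
}

// Trace all outer boundaries (8-connected foreground components) and
// first-level holes (4-connected enclosed background components).
// Returns a list of contours: points (n x 2 matrix, 0-based x,y), is_hole,
// parent (1-based index into the list, NA for outer contours).
// Orientation: outer contours have positive raw shoelace area (counter-
// clockwise in the Cartesian y-up frame), holes negative.
// [[Rcpp::export]]
List cpp_trace_contours(IntegerMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix fg = cpp_label(mask, 8);
  int nfg = fg.attr("n");
  // topmost-leftmost start pixel per component (row-major scan)
  std::vector<int> sr(nfg + 1, -1), sc(nfg + 1, -1);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      int l = fg(r, c);
      if (l != 0 && sr[l] < 0) { sr[l] = r; sc[l] = c; }
    }
  // enclosed background components = holes
  IntegerMatrix inv(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      inv(r, c) = mask(r, c) == 0 ? 255 : 0;
  IntegerMatrix bg = cpp_label(inv, 4);
  int nbg = bg.attr("n");
  std::vector<bool> border(nbg + 1, false);
  std::vector<int> hr(nbg + 1, -1), hc(nbg + 1, -1);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      int l = bg(r, c);
      if (l == 0) continue;
      if (hr[l] < 0) { hr[l] = r; hc[l] = c; }
      if (r == 0 || c == 0 || r == nr - 1 || c == nc - 1) border[l] = true;
    }

  List out;
  std::vector<int> fg_index(nfg + 1, 0); // position of each fg contour in `out`
  for (int l = 1; l <= nfg; ++l) {
    std::vector<std::pair<int, int> > pts = moore_trace(fg, l, sr[l], sc[l]);
    if (signed_area_rc(pts) < 0) std::reverse(pts.begin() + 1, pts.end());
    IntegerMatrix m(pts.size(), 2);
    for (size_t i = 0; i < pts.size(); ++i) {
      m(i, 0) = pts[i].second; // x
      m(i, 1) = pts[i].first;  // y
    }
    out.push_back(List::create(_["points"] = m, _["is_hole"] = false,
                               _["parent"] = IntegerVector::create(NA_INTEGER)));
    fg_index[l] = out.size(); // 1-based
  }
  for (int l = 1; l <= nbg; ++l) {
    if (border[l]) continue;
    // pixel above the topmost hole pixel belongs to the enclosing component
    int pr = hr[l] - 1, pc = hc[l];
    int parent = (pr >= 0) ? fg(pr, pc) : 0;
    std::vector<std::pair<int, int> > pts = moore_trace(bg, l, hr[l], hc[l]);
    if (signed_area_rc(pts) > 0) std::reverse(pts.begin() + 1, pts.end());
    IntegerMatrix m(pts.size(), 2);
    for (size_t i = 0; i < pts.size(); ++i) {
      m(i, 0) = pts[i].second;
      m(i, 1) = pts[i].first;
    }
    out.push_back(List::create(
        _["points"] = m, _["is_hole"] = true,
        _["parent"] = parent > 0 ? IntegerVector::create(fg_index[parent])
                                 : IntegerVector::create(NA_INTEGER)));
  }
  return out;
}

// Radial membrane probing: for each contour point, step t = tmin..tmax along
// its outward unit normal and test the membrane mask. Returns a logical
// vector of per-point hits. Samples falling outside the image are misses.
// [[Rcpp::export]]
LogicalVector cpp_probe_hits(IntegerMatrix pts, NumericMatrix normals,
                             IntegerMatrix membrane, int tmin, int tmax) {
  const int nr = membrane.nrow(), nc = membrane.ncol();
  const int n = pts.nrow();
  LogicalVector hits(n);
  for (int i = 0; i < n; ++i) {
    double x = pts(i, 0), y = pts(i, 1);
    double nx = normals(i, 0), ny = normals(i, 1);
    bool hit = false;
    for (int t = tmin; t <= tmax && !hit; ++t) {
      int cc = (int)std::floor(x + t * nx + 0.5);
      int rr = (int)std::floor(y + t * ny + 0.5);
      if (in_bounds(rr, cc, nr, nc) && membrane(rr, cc) != 0) hit = true;
    }
    hits[i] = hit;
  }
  return hits;
}
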