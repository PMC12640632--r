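#include <Rcpp.h>
#include <climits>
#include <functional>
#include <set>
#include <utility>
#include <vector>
using namespace Rcpp;

// Matrices are indexed [row, col] = [y, x]; exported point coordinates are
// 0-based (x = col, y = row) to match the repo-wide top-left origin.

// ---- connected-component labelling (8-connectivity, raster discovery order)

// [[Rcpp::export]]
IntegerMatrix cpp_label8(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int y = 0; y < nr; ++y) {
    for (int x = 0; x < nc; ++x) {
      if (mask(y, x) == 0 || lab(y, x) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(y * nc + x);
      lab(y, x) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int py = p / nc, px = p % nc;
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0) continue;
            int qy = py + dy, qx = px + dx;
            if (qy < 0 || qy >= nr || qx < 0 || qx >= nc) continue;
            if (mask(qy, qx) != 0 && lab(qy, qx) == 0) {
              lab(qy, qx) = next;
              stack.push_back(qy * nc + qx);
            }
          }
        }
      }
    }
  }
  return lab;
}

// ---- Moore border following with Jacob's stopping criterion
//
// Traces the outer border of every 8-connected foreground component in
// clockwise order (screen coordinates, y down), starting at the component's
// topmost-then-leftmost pixel. Directions advance clockwise:
// 0 W, 1 NW, 2 N, 3 NE, 4 E, 5 SE, 6 S, 7 SW.

static const int DX8[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int DY8[8] = {0, -1, -1, -1, 0, 1, 1, 1};

// [[Rcpp::export]]
List cpp_trace_contours(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab = cpp_label8(mask);
  int ncomp = 0;
  for (int y = 0; y < nr; ++y)
    for (int x = 0; x < nc; ++x)
      if (lab(y, x) > ncomp) ncomp = lab(y, x);

  // first (topmost, then leftmost) pixel per component
  std::vector<int> sy(ncomp, -1), sx(ncomp, -1);
  for (int y = 0; y < nr; ++y)
    for (int x = 0; x < nc; ++x) {
      int k = lab(y, x);
      if (k > 0 && sy[k - 1] < 0) { sy[k - 1] = y; sx[k - 1] = x; }
    }

  List out(ncomp);
  for (int k = 0; k < ncomp; ++k) {
    const int s0y = sy[k], s0x = sx[k], id = k + 1;
    std::vector<int> cx, cy;
    cx.push_back(s0x); cy.push_back(s0y);
    int py = s0y, px = s0x;
    // the W neighbour of the start pixel is background by construction, so
    // the first clockwise sweep starts there
    int scan = 0;
    int first_dir = -1;
    long long guard = 8LL * nr * nc + 16;
    while (guard-- > 0) {
      int d = -1;
      for (int i = 0; i < 8; ++i) {
        int dd = (scan + i) % 8;
        int qy = py + DY8[dd], qx = px + DX8[dd];
        if (qy >= 0 && qy < nr && qx >= 0 && qx < nc && lab(qy, qx) == id) {
          d = dd;
          break;
        }
      }
      if (d < 0) break;                       // isolated pixel
      if (first_dir < 0) {
        first_dir = d;
      } else if (py == s0y && px == s0x && d == first_dir) {
        break;                                // Jacob's stopping criterion
      }
      py += DY8[d];
      px += DX8[d];
      cx.push_back(px); cy.push_back(py);
      scan = (d + 6) % 8;                     // resume sweep from backtrack
    }
    // drop the final re-entry into the start pixel (closure is implicit)
    if (cx.size() > 1 && cx.back() == s0x && cy.back() == s0y) {
      cx.pop_back(); cy.pop_back();
    }
    IntegerMatrix m((int)cx.size(), 2);
    for (size_t i = 0; i < cx.size(); ++i) { m(i, 0) = cx[i]; m(i, 1) = cy[i]; }
    colnames(m) = CharacterVector::create("x", "y");
    out[k] = m;
  }
  return out;
}

// ---- hysteresis edge tracking (stage 5 of the Canny cascade)
//
// Keeps strong pixels and any weak pixel with an 8-connected path to a
// strong pixel through strong/weak pixels.

// [[Rcpp::export]]
IntegerMatrix cpp_hysteresis(const IntegerMatrix& strong,
                             const IntegerMatrix& weak) {
  const int nr = strong.nrow(), nc = strong.ncol();
  IntegerMatrix keep(nr, nc);
  std::vector<int> stack;
  for (int y = 0; y < nr; ++y)
    for (int x = 0; x < nc; ++x)
      if (strong(y, x) != 0) { keep(y, x) = 255; stack.push_back(y * nc + x); }
  while (!stack.empty()) {
    int p = stack.back(); stack.pop_back();
    int py = p / nc, px = p % nc;
    for (int d = 0; d < 8; ++d) {
      int qy = py + DY8[d], qx = px + DX8[d];
      if (qy < 0 || qy >= nr || qx < 0 || qx >= nc) continue;
      if (keep(qy, qx) == 0 && (weak(qy, qx) != 0 || strong(qy, qx) != 0)) {
        keep(qy, qx) = 255;
        stack.push_back(qy * nc + qx);
      }
    }
  }
  return keep;
}

// ---- quadtree region split-and-merge
//
// Split phase: FIFO queue starting from the whole (power-of-two square)
// image; a block is accepted as a region when its intensity range is at most
// `tol` or its side reaches `minRegion`; otherwise it is divided into four
// equal sub-blocks (NW, NE, SW, SE). Region ids follow acceptance order.
//
// Merge phase: regions are 4-adjacent neighbours; two regions merge when the
// intensity range of their union is at most `tol`. The restart-after-every-
// merge semantics ("scan the region list from the beginning after a merge")
// reduce, because the range of a region only grows under merging, to always
// merging the lexicographically smallest eligible pair of region ids; the
// merged region keeps the smaller id.

struct Block { int x, y, s; };

// [[Rcpp::export]]
List cpp_split_merge(const IntegerMatrix& img, int minRegion, double tol,
                     bool doMerge) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<double> rmin, rmax, rsum;
  std::vector<int> rcount;

  std::vector<Block> queue;
  queue.push_back({0, 0, nc}); // square image: nr == nc
  size_t head = 0;
  while (head < queue.size()) {
    Block b = queue[head++];
    int lo = INT_MAX, hi = INT_MIN;
    long long sum = 0;
    for (int y = b.y; y < b.y + b.s; ++y)
      for (int x = b.x; x < b.x + b.s; ++x) {
        int v = img(y, x);
        if (v < lo) lo = v;
        if (v > hi) hi = v;
        sum += v;
      }
    if ((hi - lo) <= tol || b.s <= minRegion) {
      int id = (int)rmin.size() + 1;
      for (int y = b.y; y < b.y + b.s; ++y)
        for (int x = b.x; x < b.x + b.s; ++x) lab(y, x) = id;
      rmin.push_back(lo); rmax.push_back(hi);
      rsum.push_back((double)sum); rcount.push_back(b.s * b.s);
    } else {
      int h = b.s / 2;
      queue.push_back({b.x, b.y, h});
      queue.push_back({b.x + h, b.y, h});
      queue.push_back({b.x, b.y + h, h});
      queue.push_back({b.x + h, b.y + h, h});
    }
  }

  const int nreg = (int)rmin.size();
  std::vector<int> parent(nreg + 1);
  for (int i = 0; i <= nreg; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
    return i;
  };

  if (doMerge && nreg > 1) {
    std::vector<std::set<int>> nb(nreg + 1);
    for (int y = 0; y < nr; ++y)
      for (int x = 0; x < nc; ++x) {
        int a = lab(y, x);
        if (x + 1 < nc && lab(y, x + 1) != a) {
          nb[a].insert(lab(y, x + 1));
          nb[lab(y, x + 1)].insert(a);
        }
        if (y + 1 < nr && lab(y + 1, x) != a) {
          nb[a].insert(lab(y + 1, x));
          nb[lab(y + 1, x)].insert(a);
        }
      }
    std::set<std::pair<int, int>> cand;
    for (int i = 1; i <= nreg; ++i)
      for (int j : nb[i])
        if (j > i &&
            std::max(rmax[i - 1], rmax[j - 1]) -
                std::min(rmin[i - 1], rmin[j - 1]) <= tol)
          cand.insert({i, j});
    while (!cand.empty()) {
      std::pair<int, int> pr = *cand.begin();
      cand.erase(cand.begin());
      int i = pr.first, j = pr.second;
      if (find(i) != i || find(j) != j) continue;          // stale pair
      if (nb[i].find(j) == nb[i].end()) continue;          // no longer adjacent
      double lo = std::min(rmin[i - 1], rmin[j - 1]);
      double hi = std::max(rmax[i - 1], rmax[j - 1]);
      if (hi - lo > tol) continue;                         // grew apart
      parent[j] = i;
      rmin[i - 1] = lo; rmax[i - 1] = hi;
      rsum[i - 1] += rsum[j - 1];
      rcount[i - 1] += rcount[j - 1];
      nb[i].erase(j);
      for (int m : nb[j]) {
        if (m == i) continue;
        nb[m].erase(j);
        cand.erase({std::min(j, m), std::max(j, m)});
        nb[m].insert(i);
        nb[i].insert(m);
        double l2 = std::min(rmin[i - 1], rmin[m - 1]);
        double h2 = std::max(rmax[i - 1], rmax[m - 1]);
        if (h2 - l2 <= tol) cand.insert({std::min(i, m), std::max(i, m)});
      }
      nb[j].clear();
      // pairs (i, m) that grew past tol are discarded lazily on pop
    }
    for (int y = 0; y < nr; ++y)
      for (int x = 0; x < nc; ++x) lab(y, x) = find(lab(y, x));
  }

  std::vector<int> ids;
  for (int i = 1; i <= nreg; ++i)
    if (find(i) == i) ids.push_back(i);
  NumericMatrix stats((int)ids.size(), 5);
  for (size_t r = 0; r < ids.size(); ++r) {
    int i = ids[r];
    stats(r, 0) = i;
    stats(r, 1) = rmin[i - 1];
    stats(r, 2) = rmax[i - 1];
    stats(r, 3) = rsum[i - 1] / rcount[i - 1];
    stats(r, 4) = rcount[i - 1];
  }
  colnames(stats) = CharacterVector::create("id", "min", "max", "mean", "count");
  return List::create(_["labels"] = lab, _["stats"] = stats);
}
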