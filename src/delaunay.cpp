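// Incremental Bowyer-Watson Delaunay triangulation in 2-D.
//
// Written for the leaf-meshing step: clouds of 1e3-2e4 projected points per
// leaf, where available R triangulators are orders of magnitude too slow.
// Points are normalized to the unit box; predicates run in long double.
// Near-cocircular ties (exact grids) are resolved by a strict epsilon, which
// yields one valid triangulation of the tie; total area is unaffected.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <algorithm>
#include <unordered_map>
using namespace Rcpp;

typedef long double ld;

static inline ld orient2d(ld ax, ld ay, ld bx, ld by, ld cx, ld cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// > 0 iff p strictly inside circumcircle of CCW triangle (a, b, c)
static inline ld incircle(ld ax, ld ay, ld bx, ld by, ld cx, ld cy,
                          ld px, ld py) {
  ld adx = ax - px, ady = ay - py;
  ld bdx = bx - px, bdy = by - py;
  ld cdx = cx - px, cdy = cy - py;
  ld ad = adx * adx + ady * ady;
  ld bd = bdx * bdx + bdy * bdy;
  ld cd = cdx * cdx + cdy * cdy;
  return adx * (bdy * cd - bd * cdy)
       - ady * (bdx * cd - bd * cdx)
       + ad  * (bdx * cdy - bdy * cdx);
}

struct Tri {
  int v[3];   // CCW vertex indices
  int nb[3];  // nb[i]: neighbor across edge opposite vertex i, -1 if none
  bool alive;
  int stamp;  // cavity epoch marker
};

// [[Rcpp::export]]
IntegerMatrix delaunay_cpp(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n < 3) stop("delaunay: need at least 3 points");

  // normalize to [0, 1] (uniform scale keeps orientation and circles)
  double xmin = *std::min_element(x.begin(), x.end());
  double xmax = *std::max_element(x.begin(), x.end());
  double ymin = *std::min_element(y.begin(), y.end());
  double ymax = *std::max_element(y.begin(), y.end());
  double span = std::max(xmax - xmin, ymax - ymin);
  if (span <= 0) stop("delaunay: all points coincide");
  std::vector<ld> px(n + 3), py(n + 3);
  for (int i = 0; i < n; ++i) {
    px[i] = (x[i] - xmin) / span;
    py[i] = (y[i] - ymin) / span;
  }
  // far super-triangle enclosing the unit box
  px[n] = -99.0L;  py[n] = -49.0L;
  px[n + 1] = 101.0L; py[n + 1] = -49.0L;
  px[n + 2] = 1.0L;   py[n + 2] = 151.0L;

  std::vector<Tri> tris;
  tris.reserve(2 * n + 16);
  tris.push_back({{n, n + 1, n + 2}, {-1, -1, -1}, true, 0});

  // spatial insertion order: serpentine grid sweep for walk locality
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  int g = std::max(1, (int)std::ceil(std::sqrt((double)n / 4.0)));
  std::vector<long long> key(n);
  for (int i = 0; i < n; ++i) {
    int cx = std::min(g - 1, (int)((double)px[i] * g));
    int cy = std::min(g - 1, (int)((double)py[i] * g));
    int col = (cy % 2 == 0) ? cx : (g - 1 - cx);
    key[i] = (long long)cy * g + col;
  }
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return key[a] < key[b]; });

  int last = 0;     // a recently created alive triangle, walk start
  int epoch = 0;
  const ld eps_inc = 1e-30L;  // strict-inside threshold for cavity growth
  std::vector<int> cav, stack_;

  for (int oi = 0; oi < n; ++oi) {
    int pi = order[oi];
    ld qx = px[pi], qy = py[pi];

    // locate containing triangle by walking
    int t = last;
    if (!tris[t].alive) {
      for (int k = (int)tris.size() - 1; k >= 0; --k)
        if (tris[k].alive) { t = k; break; }
    }
    int steps = 0, limit = 4 * (int)tris.size() + 64;
    bool found = false;
    while (steps++ < limit) {
      const Tri &T = tris[t];
      int cross = -1;
      for (int j = 0; j < 3; ++j) {
        int a = T.v[j], b = T.v[(j + 1) % 3];
        if (orient2d(px[a], py[a], px[b], py[b], qx, qy) < 0) {
          cross = T.nb[(j + 2) % 3];
          break;
        }
      }
      if (cross == -1) { found = true; break; }
      t = cross;
    }
    if (!found) {  // numerical fallback: exhaustive scan
      found = false;
      for (int k = 0; k < (int)tris.size() && !found; ++k) {
        if (!tris[k].alive) continue;
        const Tri &T = tris[k];
        bool in = true;
        for (int j = 0; j < 3 && in; ++j) {
          int a = T.v[j], b = T.v[(j + 1) % 3];
          if (orient2d(px[a], py[a], px[b], py[b], qx, qy) < -1e-18L)
            in = false;
        }
        if (in) { t = k; found = true; }
      }
      if (!found) stop("delaunay: point location failed");
    }

    // skip exact duplicates (vertex stays isolated)
    bool dup = false;
    for (int j = 0; j < 3; ++j) {
      ld dx = px[tris[t].v[j]] - qx, dy = py[tris[t].v[j]] - qy;
      if (dx * dx + dy * dy < 1e-28L) { dup = true; break; }
    }
    if (dup) continue;

    // grow cavity: BFS over triangles whose circumcircle contains p
    ++epoch;
    cav.clear();
    stack_.clear();
    tris[t].stamp = epoch;
    stack_.push_back(t);
    while (!stack_.empty()) {
      int c = stack_.back();
      stack_.pop_back();
      cav.push_back(c);
      for (int j = 0; j < 3; ++j) {
        int nbj = tris[c].nb[j];
        if (nbj == -1 || tris[nbj].stamp == epoch) continue;
        const Tri &N = tris[nbj];
        if (incircle(px[N.v[0]], py[N.v[0]], px[N.v[1]], py[N.v[1]],
                     px[N.v[2]], py[N.v[2]], qx, qy) > eps_inc) {
          tris[nbj].stamp = epoch;
          stack_.push_back(nbj);
        }
      }
    }

    // boundary edges of the cavity (CCW as seen from inside)
    struct BEdge { int a, b, outer; };
    std::vector<BEdge> bed;
    for (int c : cav) {
      const Tri &T = tris[c];
      for (int j = 0; j < 3; ++j) {
        int outer = T.nb[(j + 2) % 3];
        if (outer == -1 || tris[outer].stamp != epoch) {
          bed.push_back({T.v[j], T.v[(j + 1) % 3], outer});
        }
      }
    }
    for (int c : cav) tris[c].alive = false;

    // fan of new triangles (a, b, p), linked around p
    std::unordered_map<int, int> by_start, by_end;
    by_start.reserve(bed.size() * 2);
    by_end.reserve(bed.size() * 2);
    int base = (int)tris.size();
    for (int k = 0; k < (int)bed.size(); ++k) {
      tris.push_back({{bed[k].a, bed[k].b, pi}, {-1, -1, bed[k].outer},
                      true, 0});
      by_start[bed[k].a] = base + k;
      by_end[bed[k].b] = base + k;
      int outer = bed[k].outer;
      if (outer != -1) {
        // relink the one edge of `outer` matching (a, b)
        for (int j = 0; j < 3; ++j) {
          int ea = tris[outer].v[(j + 1) % 3];
          int eb = tris[outer].v[(j + 2) % 3];
          if ((ea == bed[k].a && eb == bed[k].b) ||
              (ea == bed[k].b && eb == bed[k].a)) {
            tris[outer].nb[j] = base + k;
            break;
          }
        }
      }
    }
    for (int k = 0; k < (int)bed.size(); ++k) {
      tris[base + k].nb[0] = by_start[bed[k].b];  // across edge (b, p)
      tris[base + k].nb[1] = by_end[bed[k].a];    // across edge (p, a)
    }
    last = base;
  }

  std::vector<std::array<int, 3>> faces;
  faces.reserve(2 * n);
  for (const Tri &T : tris) {
    if (T.alive && T.v[0] < n && T.v[1] < n && T.v[2] < n) {
      faces.push_back({T.v[0], T.v[1], T.v[2]});
    }
  }

  // Hull completion. With a finite super-triangle, a near-degenerate hull
  // sliver can be left uncovered (its circumcircle dwarfs the super
  // triangle). Walk the directed boundary cycle of the real triangulation
  // (interior on the left) and convexify it Graham-scan style, filling any
  // sliver pockets so the triangulation covers the convex hull exactly.
  {
    std::unordered_map<int, int> succ;
    succ.reserve(faces.size());
    auto is_real = [&](int t) {
      return t != -1 && tris[t].alive &&
             tris[t].v[0] < n && tris[t].v[1] < n && tris[t].v[2] < n;
    };
    for (const Tri &T : tris) {
      if (!(T.alive && T.v[0] < n && T.v[1] < n && T.v[2] < n)) continue;
      for (int j = 0; j < 3; ++j) {
        if (!is_real(T.nb[(j + 2) % 3])) {
          succ[T.v[j]] = T.v[(j + 1) % 3];
        }
      }
    }
    if (!succ.empty()) {
      int start = succ.begin()->first;
      for (const auto &kv : succ) {
        if (py[kv.first] < py[start] ||
            (py[kv.first] == py[start] && px[kv.first] < px[start])) {
          start = kv.first;
        }
      }
      std::vector<int> cycle;
      int cur = start;
      size_t guard = succ.size() + 2;
      do {
        cycle.push_back(cur);
        auto it = succ.find(cur);
        if (it == succ.end()) { cycle.clear(); break; }
        cur = it->second;
      } while (cur != start && cycle.size() <= guard);
      if (!cycle.empty() && cur == start && cycle.size() >= 3) {
        std::vector<int> st;
        st.push_back(cycle[0]);
        st.push_back(cycle[1]);
        for (size_t i = 2; i <= cycle.size(); ++i) {
          int w = cycle[i % cycle.size()];
          while (st.size() >= 2) {
            int u = st[st.size() - 2], v = st[st.size() - 1];
            ld o = orient2d(px[u], py[u], px[v], py[v], px[w], py[w]);
            if (o < 0) {  // pocket: fill (u, w, v) with interior CCW
              faces.push_back({u, w, v});
              st.pop_back();
            } else {
              break;
            }
          }
          if (i < cycle.size()) st.push_back(w);
        }
      }
    }
  }

  IntegerMatrix out((int)faces.size(), 3);
  for (int r = 0; r < (int)faces.size(); ++r) {
    out(r, 0) = faces[r][0] + 1;
    out(r, 1) = faces[r][1] + 1;
    out(r, 2) = faces[r][2] + 1;
  }
  return out;
}
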