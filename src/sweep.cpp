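#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Exact areas of the n-way intersection and union of a set of planar
// multi-polygons by a vertical slab sweep.
//
// Each polygon is a list of parts; each part is a list of rings (first ring
// the shell, later rings holes, but membership is evaluated by even-odd
// parity over all rings of the part, so orientation and ordering are
// irrelevant).  A point is inside a polygon iff it is inside at least one
// part (parts may overlap).  Coordinates are planar, in metres.
//
// Between two consecutive event abscissae (ring vertices plus proper
// pairwise segment crossings) the vertical cross-section of every boolean
// combination of the polygons has measure linear in x, so evaluating at the
// slab midpoint and multiplying by the slab width integrates exactly.

struct Seg {
  double x1, y1, x2, y2; // x1 < x2
  int poly, part;
};

typedef std::pair<double,double> Iv;

static void merge_union(std::vector<Iv>& ivs) {
  if (ivs.size() <= 1) return;
  std::sort(ivs.begin(), ivs.end());
  std::vector<Iv> out;
  out.push_back(ivs[0]);
  for (size_t i = 1; i < ivs.size(); ++i) {
    if (ivs[i].first <= out.back().second)
      out.back().second = std::max(out.back().second, ivs[i].second);
    else out.push_back(ivs[i]);
  }
  ivs.swap(out);
}

// both inputs sorted & disjoint
static std::vector<Iv> intersect_ivs(const std::vector<Iv>& a,
                                     const std::vector<Iv>& b) {
  std::vector<Iv> out;
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    double lo = std::max(a[i].first, b[j].first);
    double hi = std::min(a[i].second, b[j].second);
    if (lo < hi) out.push_back(Iv(lo, hi));
    if (a[i].second < b[j].second) ++i; else ++j;
  }
  return out;
}

static double measure(const std::vector<Iv>& a) {
  double s = 0.0;
  for (size_t i = 0; i < a.size(); ++i) s += a[i].second - a[i].first;
  return s;
}

// [[Rcpp::export(name = ".region_measures")]]
List region_measures(List polys) {
  int np = polys.size();
  std::vector<Seg> segs;
  std::vector<double> events;

  for (int p = 0; p < np; ++p) {
    List parts(polys[p]);
    for (int q = 0; q < parts.size(); ++q) {
      List rings(parts[q]);
      for (int r = 0; r < rings.size(); ++r) {
        NumericMatrix ring(rings[r]);
        int n = ring.nrow();
        if (n < 3) stop("ring with fewer than 3 vertices");
        // drop a duplicated closing vertex if present
        if (ring(0,0) == ring(n-1,0) && ring(0,1) == ring(n-1,1)) --n;
        for (int i = 0; i < n; ++i) {
          int j = (i + 1) % n;
          double xa = ring(i,0), ya = ring(i,1);
          double xb = ring(j,0), yb = ring(j,1);
          events.push_back(xa);
          if (xa == xb) continue;         // vertical: zero x-extent
          Seg s;
          if (xa < xb) { s.x1 = xa; s.y1 = ya; s.x2 = xb; s.y2 = yb; }
          else         { s.x1 = xb; s.y1 = yb; s.x2 = xa; s.y2 = ya; }
          s.poly = p; s.part = q;
          segs.push_back(s);
        }
      }
    }
  }
  if (segs.empty())
    return List::create(_["intersection"] = 0.0, _["union"] = 0.0,
                        _["areas"] = NumericVector(np));

  // proper pairwise crossings add events
  size_t ns = segs.size();
  for (size_t a = 0; a < ns; ++a) {
    for (size_t b = a + 1; b < ns; ++b) {
      const Seg &s = segs[a], &t = segs[b];
      if (s.x2 <= t.x1 || t.x2 <= s.x1) continue;
      double d1x = s.x2 - s.x1, d1y = s.y2 - s.y1;
      double d2x = t.x2 - t.x1, d2y = t.y2 - t.y1;
      double den = d1x * d2y - d1y * d2x;
      if (den == 0.0) continue;           // parallel/collinear
      double rx = t.x1 - s.x1, ry = t.y1 - s.y1;
      double u = (rx * d2y - ry * d2x) / den;
      double v = (rx * d1y - ry * d1x) / den;
      if (u > 0.0 && u < 1.0 && v > 0.0 && v < 1.0)
        events.push_back(s.x1 + u * d1x);
    }
  }

  std::sort(events.begin(), events.end());
  events.erase(std::unique(events.begin(), events.end()), events.end());
  // merge events closer than a relative tolerance: slivers that thin
  // contribute ~1e-12 of the total extent and midpoints inside them are
  // numerically unreliable
  {
    double span = events.back() - events.front();
    double tol = 1e-12 * (span > 1.0 ? span : 1.0);
    std::vector<double> ev;
    for (size_t i = 0; i < events.size(); ++i)
      if (ev.empty() || events[i] - ev.back() > tol) ev.push_back(events[i]);
    events.swap(ev);
  }

  int nparts_tot = 0;
  std::vector<int> part_off(np + 1, 0);
  for (int p = 0; p < np; ++p) {
    part_off[p] = nparts_tot;
    nparts_tot += List(polys[p]).size();
  }
  part_off[np] = nparts_tot;

  NumericVector areas(np);
  double inter_area = 0.0, union_area = 0.0;
  std::vector< std::vector<Iv> > poly_iv(np);
  std::vector< std::vector<double> > ys(nparts_tot);
  const double fracs[4] = {0.5, 0.382, 0.618, 0.271};

  for (size_t e = 0; e + 1 < events.size(); ++e) {
    double x1 = events[e], x2 = events[e + 1];
    double w = x2 - x1;
    if (w <= 0.0) continue;

    // evaluate the cross-section at a point interior to the slab; if a
    // midpoint coincides numerically with a vertex (odd parity), retry at
    // other interior fractions
    bool ok = false;
    for (int attempt = 0; attempt < 4 && !ok; ++attempt) {
      double xm = x1 + fracs[attempt] * w;
      if (!(x1 < xm && xm < x2)) continue;
      for (int g = 0; g < nparts_tot; ++g) ys[g].clear();
      for (size_t si = 0; si < ns; ++si) {
        const Seg& s = segs[si];
        if (s.x1 < xm && xm < s.x2) {
          double t = (xm - s.x1) / (s.x2 - s.x1);
          ys[part_off[s.poly] + s.part].push_back(s.y1 + t * (s.y2 - s.y1));
        }
      }
      ok = true;
      for (int g = 0; g < nparts_tot && ok; ++g)
        if (ys[g].size() % 2 != 0) ok = false;
    }
    if (!ok)
      stop("odd crossing parity: unclosed or degenerate ring");

    // per polygon: even-odd intervals per part, then union of parts
    for (int p = 0; p < np; ++p) {
      std::vector<Iv> ivs;
      for (int q = part_off[p]; q < part_off[p + 1]; ++q) {
        if (ys[q].empty()) continue;
        std::sort(ys[q].begin(), ys[q].end());
        for (size_t k = 0; k + 1 < ys[q].size(); k += 2)
          if (ys[q][k] < ys[q][k+1]) ivs.push_back(Iv(ys[q][k], ys[q][k+1]));
      }
      merge_union(ivs);
      areas[p] += measure(ivs) * w;
      poly_iv[p].swap(ivs);
    }

    // union across polygons
    std::vector<Iv> uni;
    for (int p = 0; p < np; ++p)
      uni.insert(uni.end(), poly_iv[p].begin(), poly_iv[p].end());
    merge_union(uni);
    union_area += measure(uni) * w;

    // intersection across polygons
    std::vector<Iv> inter = poly_iv[0];
    for (int p = 1; p < np && !inter.empty(); ++p)
      inter = intersect_ivs(inter, poly_iv[p]);
    inter_area += measure(inter) * w;
  }

  return List::create(_["intersection"] = inter_area,
                      _["union"] = union_area,
                      _["areas"] = areas);
}
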