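// Compiled core: Bowyer-Watson Delaunay triangulation, neighborhood-string
// encoding, random sequential adsorption packing, and inverted-index
// shared-string counting. All randomness is drawn from R's global RNG
// (unif_rand), so set.seed() at the R level controls every simulation.
#include <Rcpp.h>

#include <algorithm>
#include <array>
#include <cmath>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <utility>
#include <vector>

using namespace Rcpp;

namespace {

inline double orient2d(double ax, double ay, double bx, double by, double cx,
                       double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// d strictly inside the circumcircle of triangle (a,b,c); (a,b,c) must be in
// positive (counterclockwise in the coordinate frame) orientation.
inline bool in_circumcircle(double ax, double ay, double bx, double by,
                            double cx, double cy, double dx, double dy) {
  const double adx = ax - dx, ady = ay - dy;
  const double bdx = bx - dx, bdy = by - dy;
  const double cdx = cx - dx, cdy = cy - dy;
  const double ad2 = adx * adx + ady * ady;
  const double bd2 = bdx * bdx + bdy * bdy;
  const double cd2 = cdx * cdx + cdy * cdy;
  const double det = adx * (bdy * cd2 - bd2 * cdy) -
                     ady * (bdx * cd2 - bd2 * cdx) +
                     ad2 * (bdx * cdy - bdy * cdx);
  return det > 0.0;
}

struct Tri {
  int a, b, c;
};

// Incremental Bowyer-Watson triangulation. Points are inserted into a large
// enclosing super-triangle; triangles touching its vertices are dropped at the
// end. Cocircular point sets get an implementation-defined (but valid)
// triangulation because the in-circle test is strict.
std::vector<Tri> triangulate(const std::vector<double>& px,
                             const std::vector<double>& py) {
  const int n = static_cast<int>(px.size());
  if (n < 3) stop("degenerate geometry: need at least 3 particles");
  std::vector<double> x(px), y(py);
  double minx = x[0], maxx = x[0], miny = y[0], maxy = y[0];
  for (int i = 1; i < n; ++i) {
    minx = std::min(minx, x[i]);
    maxx = std::max(maxx, x[i]);
    miny = std::min(miny, y[i]);
    maxy = std::max(maxy, y[i]);
  }
  double d = std::max(maxx - minx, maxy - miny);
  if (d <= 0.0) d = 1.0;
  // The super vertices sit ~1e9 spans away: circumcircles through them are
  // then indistinguishable from half-planes over the data region, which is
  // the correct "vertex at infinity" semantics for the hull.
  const double far = 1e9 * d;
  const double cx = 0.5 * (minx + maxx), cy = 0.5 * (miny + maxy);
  x.push_back(cx - 2.0 * far);
  y.push_back(cy - far);
  x.push_back(cx + 2.0 * far);
  y.push_back(cy - far);
  x.push_back(cx);
  y.push_back(cy + 2.0 * far);

  std::vector<Tri> tris;
  {
    Tri t{n, n + 1, n + 2};
    if (orient2d(x[t.a], y[t.a], x[t.b], y[t.b], x[t.c], y[t.c]) < 0.0)
      std::swap(t.b, t.c);
    tris.push_back(t);
  }

  const std::int64_t m = n + 3;
  std::vector<char> bad;
  std::unordered_set<std::int64_t> cavity;  // directed edges of bad triangles
  for (int i = 0; i < n; ++i) {
    bad.assign(tris.size(), 0);
    cavity.clear();
    for (std::size_t t = 0; t < tris.size(); ++t) {
      const Tri& T = tris[t];
      if (in_circumcircle(x[T.a], y[T.a], x[T.b], y[T.b], x[T.c], y[T.c], x[i],
                          y[i])) {
        bad[t] = 1;
        cavity.insert(static_cast<std::int64_t>(T.a) * m + T.b);
        cavity.insert(static_cast<std::int64_t>(T.b) * m + T.c);
        cavity.insert(static_cast<std::int64_t>(T.c) * m + T.a);
      }
    }
    std::vector<Tri> next;
    next.reserve(tris.size() + 4);
    for (std::size_t t = 0; t < tris.size(); ++t)
      if (!bad[t]) next.push_back(tris[t]);
    for (std::int64_t e : cavity) {
      const int a = static_cast<int>(e / m), b = static_cast<int>(e % m);
      // edges whose reverse is also in the cavity are interior to it
      if (cavity.count(static_cast<std::int64_t>(b) * m + a)) continue;
      next.push_back(Tri{a, b, i});
    }
    tris.swap(next);
  }

  std::vector<Tri> out;
  out.reserve(tris.size());
  for (const Tri& T : tris)
    if (T.a < n && T.b < n && T.c < n) out.push_back(T);
  if (out.empty()) stop("degenerate geometry: all particles are collinear");
  return out;
}

struct Graph {
  std::vector<std::vector<int>> adj;  // sorted neighbor lists
  std::vector<char> hull;             // on the triangulation boundary?
};

Graph build_graph(const std::vector<double>& px, const std::vector<double>& py) {
  const int n = static_cast<int>(px.size());
  const std::vector<Tri> tris = triangulate(px, py);
  const std::int64_t m = n;
  std::unordered_map<std::int64_t, int> ecount;
  ecount.reserve(tris.size() * 3);
  for (const Tri& T : tris) {
    const int v[3] = {T.a, T.b, T.c};
    for (int k = 0; k < 3; ++k) {
      int a = v[k], b = v[(k + 1) % 3];
      if (a > b) std::swap(a, b);
      ++ecount[static_cast<std::int64_t>(a) * m + b];
    }
  }
  Graph g;
  g.adj.assign(n, {});
  g.hull.assign(n, 0);
  for (const auto& kv : ecount) {
    const int a = static_cast<int>(kv.first / m);
    const int b = static_cast<int>(kv.first % m);
    g.adj[a].push_back(b);
    g.adj[b].push_back(a);
    if (kv.second == 1) {  // boundary edge: belongs to a single triangle
      g.hull[a] = 1;
      g.hull[b] = 1;
    }
  }
  for (auto& v : g.adj) std::sort(v.begin(), v.end());
  return g;
}

// Lexicographically smallest rotation of a cyclic letter sequence, read in the
// fixed (clockwise) direction. Brute force: neighborhoods have <= ~10 letters.
std::string canonical_rotation_str(const std::string& s) {
  std::string best = s;
  const std::size_t k = s.size();
  for (std::size_t i = 1; i < k; ++i) {
    std::string rot = s.substr(i) + s.substr(0, i);
    if (rot < best) best = rot;
  }
  return best;
}

std::vector<std::string> encode_points(const std::vector<double>& px,
                                       const std::vector<double>& py,
                                       const std::vector<char>& col,
                                       bool discard_hull, int min_distinct,
                                       int min_neighbors) {
  const int n = static_cast<int>(px.size());
  const Graph g = build_graph(px, py);
  std::vector<std::string> out;
  out.reserve(n);
  std::vector<std::pair<double, int>> ang;
  for (int v = 0; v < n; ++v) {
    if (discard_hull && g.hull[v]) continue;
    const std::vector<int>& nb = g.adj[v];
    if (static_cast<int>(nb.size()) < min_neighbors) continue;
    ang.clear();
    for (int u : nb)
      ang.emplace_back(std::atan2(py[u] - py[v], px[u] - px[v]), u);
    // increasing atan2 in the y-down image frame is clockwise on screen
    std::sort(ang.begin(), ang.end());
    std::string cyc;
    cyc.reserve(ang.size());
    for (const auto& a : ang) cyc += col[a.second];
    std::string s(1, col[v]);
    s += canonical_rotation_str(cyc);
    bool seen[256] = {false};
    int distinct = 0;
    for (unsigned char ch : s)
      if (!seen[ch]) {
        seen[ch] = true;
        ++distinct;
      }
    if (distinct < min_distinct) continue;
    out.push_back(std::move(s));
  }
  std::sort(out.begin(), out.end());
  return out;
}

// Random sequential adsorption of n disks of radius r inside a pill of radius
// R: uniform proposals over the allowed disk, rejected on overlap. One attempt
// = one uniform-in-disk proposal.
void rsa_pack(int n, double R, double r, int max_attempts,
              std::vector<double>& xs, std::vector<double>& ys) {
  xs.clear();
  ys.clear();
  xs.reserve(n);
  ys.reserve(n);
  const double a = R - r;
  const double a2 = a * a;
  const double min2 = 4.0 * r * r;
  for (int i = 0; i < n; ++i) {
    bool placed = false;
    for (int att = 0; att < max_attempts && !placed; ++att) {
      double u, v;
      do {
        u = (2.0 * unif_rand() - 1.0) * a;
        v = (2.0 * unif_rand() - 1.0) * a;
      } while (u * u + v * v > a2);
      bool ok = true;
      for (std::size_t j = 0; j < xs.size(); ++j) {
        const double dx = xs[j] - u, dy = ys[j] - v;
        if (dx * dx + dy * dy < min2) {
          ok = false;
          break;
        }
      }
      if (ok) {
        xs.push_back(u);
        ys.push_back(v);
        placed = true;
      }
    }
    if (!placed)
      stop("packing failed: placed %d of %d particles before exhausting "
           "max_attempts; reduce the packing density",
           i, n);
  }
}

inline int sample_idx(const std::vector<double>& cum) {
  const double u = unif_rand();
  int k = 0;
  const int K = static_cast<int>(cum.size());
  while (k + 1 < K && u > cum[k]) ++k;
  return k;
}

std::vector<double> cumulate(const NumericVector& probs) {
  std::vector<double> cum(probs.size());
  double s = 0.0;
  for (int i = 0; i < probs.size(); ++i) {
    s += probs[i];
    cum[i] = s;
  }
  return cum;
}

std::vector<char> first_chars(const CharacterVector& color) {
  std::vector<char> col(color.size());
  for (int i = 0; i < color.size(); ++i) col[i] = CHAR(STRING_ELT(color, i))[0];
  return col;
}

// sorted (string, multiplicity) runs of one code
std::vector<std::pair<std::string, int>> rle_strings(const CharacterVector& sv) {
  std::vector<std::string> ss = as<std::vector<std::string>>(sv);
  std::sort(ss.begin(), ss.end());
  std::vector<std::pair<std::string, int>> runs;
  for (std::size_t i = 0; i < ss.size();) {
    std::size_t j = i;
    while (j < ss.size() && ss[j] == ss[i]) ++j;
    runs.emplace_back(ss[i], static_cast<int>(j - i));
    i = j;
  }
  return runs;
}

}  // namespace

// [[Rcpp::export(.cpp_delaunay)]]
List cpp_delaunay(NumericVector x, NumericVector y) {
  const std::vector<double> px(x.begin(), x.end()), py(y.begin(), y.end());
  const Graph g = build_graph(px, py);
  int ne = 0;
  for (std::size_t v = 0; v < g.adj.size(); ++v)
    for (int u : g.adj[v])
      if (u > static_cast<int>(v)) ++ne;
  IntegerMatrix edges(ne, 2);
  int row = 0;
  for (std::size_t v = 0; v < g.adj.size(); ++v)
    for (int u : g.adj[v])
      if (u > static_cast<int>(v)) {
        edges(row, 0) = static_cast<int>(v) + 1;
        edges(row, 1) = u + 1;
        ++row;
      }
  List adj(g.adj.size());
  IntegerVector hull;
  for (std::size_t v = 0; v < g.adj.size(); ++v) {
    IntegerVector nb(g.adj[v].size());
    for (std::size_t k = 0; k < g.adj[v].size(); ++k) nb[k] = g.adj[v][k] + 1;
    adj[v] = nb;
    if (g.hull[v]) hull.push_back(static_cast<int>(v) + 1);
  }
  return List::create(_["edges"] = edges, _["adjacency"] = adj,
                      _["hull"] = hull);
}

// [[Rcpp::export(.cpp_encode)]]
CharacterVector cpp_encode(NumericVector x, NumericVector y,
                           CharacterVector color, bool discard_hull,
                           int min_distinct, int min_neighbors) {
  const std::vector<double> px(x.begin(), x.end()), py(y.begin(), y.end());
  const std::vector<char> col = first_chars(color);
  return wrap(encode_points(px, py, col, discard_hull, min_distinct,
                            min_neighbors));
}

// [[Rcpp::export(.cpp_sim_code)]]
List cpp_sim_code(int n_particles, double pill_radius, double particle_radius,
                  int max_attempts, NumericVector probs) {
  std::vector<double> xs, ys;
  rsa_pack(n_particles, pill_radius, particle_radius, max_attempts, xs, ys);
  const std::vector<double> cum = cumulate(probs);
  IntegerVector color(n_particles);
  for (int i = 0; i < n_particles; ++i) color[i] = sample_idx(cum) + 1;
  return List::create(_["x"] = wrap(xs), _["y"] = wrap(ys),
                      _["color"] = color);
}

// [[Rcpp::export(.cpp_simulate_library)]]
List cpp_simulate_library(int size, int n_particles, double pill_radius,
                          double particle_radius, int max_attempts,
                          NumericVector probs, CharacterVector letters,
                          bool discard_hull, int min_distinct,
                          int min_neighbors) {
  const std::vector<double> cum = cumulate(probs);
  const std::vector<char> alpha = first_chars(letters);
  List out(size);
  std::vector<double> xs, ys;
  std::vector<char> col(n_particles);
  for (int s = 0; s < size; ++s) {
    rsa_pack(n_particles, pill_radius, particle_radius, max_attempts, xs, ys);
    for (int i = 0; i < n_particles; ++i) col[i] = alpha[sample_idx(cum)];
    out[s] = wrap(encode_points(xs, ys, col, discard_hull, min_distinct,
                                min_neighbors));
    if ((s & 255) == 0) checkUserInterrupt();
  }
  return out;
}

// Maximum multiset-intersection count over all unordered pairs of codes,
// computed with an inverted index (string -> postings of earlier codes) and a
// sparse accumulator, so memory stays linear in the library size.
// [[Rcpp::export(.cpp_max_shared)]]
IntegerVector cpp_max_shared(List lib) {
  const int nc = lib.size();
  std::unordered_map<std::string, int> sid;
  std::vector<std::vector<std::pair<int, int>>> postings;  // (code, count)
  std::vector<int> acc(nc, 0), touched;
  int best = 0, bi = 0, bj = 0;
  for (int i = 0; i < nc; ++i) {
    const CharacterVector sv = lib[i];
    const auto runs = rle_strings(sv);
    std::vector<std::pair<int, int>> mine;
    mine.reserve(runs.size());
    for (const auto& rc : runs) {
      auto it = sid.find(rc.first);
      int id;
      if (it == sid.end()) {
        id = static_cast<int>(postings.size());
        sid.emplace(rc.first, id);
        postings.emplace_back();
      } else {
        id = it->second;
      }
      mine.emplace_back(id, rc.second);
    }
    touched.clear();
    for (const auto& sc : mine)
      for (const auto& pc : postings[sc.first]) {
        if (acc[pc.first] == 0) touched.push_back(pc.first);
        acc[pc.first] += std::min(sc.second, pc.second);
      }
    for (int j : touched) {
      if (acc[j] > best) {
        best = acc[j];
        bi = j + 1;
        bj = i + 1;
      }
      acc[j] = 0;
    }
    for (const auto& sc : mine) postings[sc.first].emplace_back(i, sc.second);
    if ((i & 1023) == 0) checkUserInterrupt();
  }
  return IntegerVector::create(best, bi, bj);
}

// Histogram of shared-string counts over all unordered pairs; element k+1 is
// the number of pairs sharing exactly k strings. Counts are doubles because
// the zero bin can exceed .Machine$integer.max for large libraries.
// [[Rcpp::export(.cpp_pair_hist)]]
NumericVector cpp_pair_hist(List lib) {
  const int nc = lib.size();
  std::unordered_map<std::string, int> sid;
  std::vector<std::vector<std::pair<int, int>>> postings;
  std::vector<int> acc(nc, 0), touched;
  std::vector<double> hist(1, 0.0);
  double nonzero = 0.0;
  for (int i = 0; i < nc; ++i) {
    const CharacterVector sv = lib[i];
    const auto runs = rle_strings(sv);
    std::vector<std::pair<int, int>> mine;
    mine.reserve(runs.size());
    for (const auto& rc : runs) {
      auto it = sid.find(rc.first);
      int id;
      if (it == sid.end()) {
        id = static_cast<int>(postings.size());
        sid.emplace(rc.first, id);
        postings.emplace_back();
      } else {
        id = it->second;
      }
      mine.emplace_back(id, rc.second);
    }
    touched.clear();
    for (const auto& sc : mine)
      for (const auto& pc : postings[sc.first]) {
        if (acc[pc.first] == 0) touched.push_back(pc.first);
        acc[pc.first] += std::min(sc.second, pc.second);
      }
    for (int j : touched) {
      const int v = acc[j];
      if (v >= static_cast<int>(hist.size())) hist.resize(v + 1, 0.0);
      hist[v] += 1.0;
      nonzero += 1.0;
      acc[j] = 0;
    }
    for (const auto& sc : mine) postings[sc.first].emplace_back(i, sc.second);
    if ((i & 1023) == 0) checkUserInterrupt();
  }
  hist[0] = 0.5 * static_cast<double>(nc) * (nc - 1) - nonzero;
  return wrap(hist);
}

// Shared-string count of one suspect against every code in the database.
// [[Rcpp::export(.cpp_query)]]
IntegerVector cpp_query(List db, CharacterVector suspect) {
  std::unordered_map<std::string, int> sus;
  for (int i = 0; i < suspect.size(); ++i)
    ++sus[std::string(CHAR(STRING_ELT(suspect, i)))];
  const int nc = db.size();
  IntegerVector out(nc);
  for (int i = 0; i < nc; ++i) {
    const CharacterVector sv = db[i];
    const auto runs = rle_strings(sv);
    int sh = 0;
    for (const auto& rc : runs) {
      auto it = sus.find(rc.first);
      if (it != sus.end()) sh += std::min(rc.second, it->second);
    }
    out[i] = sh;
  }
  return out;
}
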