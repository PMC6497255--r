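#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <queue>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Pixel-level core: thinning, distance transform, crossing numbers, branch
// tracing, connected-component labelling, and the stochastic tree grower.
// Matrices are H x W, row = y, col = x, 1-based on the R side.
// ---------------------------------------------------------------------------

static inline int at(const IntegerMatrix &m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return 0;
  return m(r, c) != 0 ? 1 : 0;
}

// 8-neighborhood in the cyclic order N, NE, E, SE, S, SW, W, NW
static const int NBR[8][2] = {
  {-1, 0}, {-1, 1}, {0, 1}, {1, 1}, {1, 0}, {1, -1}, {0, -1}, {-1, -1}
};

// [[Rcpp::export(name = ".cpp_thin")]]
IntegerMatrix cpp_thin(IntegerMatrix mask) {
  // Zhang-Suen thinning: topology-preserving 1-px medial skeleton.
  // Works on a 1-px zero-padded buffer and only revisits pixels that are
  // still foreground, so cost is proportional to the vessel area.
  int H = mask.nrow(), W = mask.ncol();
  int HP = H + 2, WP = W + 2;
  std::vector<char> m((size_t)HP * WP, 0);
  std::vector<int> fg;
  fg.reserve((size_t)H * W / 4);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (mask(r, c)) {
        int idx = (c + 1) * HP + (r + 1);  // column-major with pad
        m[idx] = 1;
        fg.push_back(idx);
      }
  // neighbor offsets in cyclic order N, NE, E, SE, S, SW, W, NW
  const int off[8] = {-1, HP - 1, HP, HP + 1, 1, -HP + 1, -HP, -HP - 1};
  std::vector<int> del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (size_t i = 0; i < fg.size(); ++i) {
        int idx = fg[i];
        if (!m[idx]) continue;
        int p[8], B = 0;
        for (int k = 0; k < 8; ++k) {
          p[k] = m[idx + off[k]];
          B += p[k];
        }
        if (B < 2 || B > 6) continue;
        int A = 0;
        for (int k = 0; k < 8; ++k)
          if (p[k] == 0 && p[(k + 1) & 7] == 1) ++A;
        if (A != 1) continue;
        // p[0]=N(P2) p[2]=E(P4) p[4]=S(P6) p[6]=W(P8)
        if (pass == 0) {
          if (p[0] * p[2] * p[4] != 0) continue;
          if (p[2] * p[4] * p[6] != 0) continue;
        } else {
          if (p[0] * p[2] * p[6] != 0) continue;
          if (p[0] * p[4] * p[6] != 0) continue;
        }
        del.push_back(idx);
      }
      if (!del.empty()) changed = true;
      for (size_t i = 0; i < del.size(); ++i) m[del[i]] = 0;
    }
    // compact the foreground list
    size_t keep = 0;
    for (size_t i = 0; i < fg.size(); ++i)
      if (m[fg[i]]) fg[keep++] = fg[i];
    fg.resize(keep);
  }
  IntegerMatrix out(H, W);
  for (size_t i = 0; i < fg.size(); ++i) {
    int idx = fg[i];
    out(idx % HP - 1, idx / HP - 1) = 1;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_dilate8")]]
IntegerMatrix cpp_dilate8(IntegerMatrix mask, int radius) {
  // Chebyshev (8-connected square) dilation by `radius` pixels.
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c)) continue;
      for (int dr = -radius; dr <= radius; ++dr)
        for (int dc = -radius; dc <= radius; ++dc) {
          int rr = r + dr, cc = c + dc;
          if (rr >= 0 && cc >= 0 && rr < H && cc < W) out(rr, cc) = 1;
        }
    }
  return out;
}

// [[Rcpp::export(name = ".cpp_crossing_numbers")]]
IntegerMatrix cpp_crossing_numbers(IntegerMatrix skel) {
  // Crossing number per foreground pixel: half the number of binary
  // transitions around the 8-neighborhood taken in cyclic order.
  int H = skel.nrow(), W = skel.ncol();
  IntegerMatrix cn(H, W);
  std::fill(cn.begin(), cn.end(), NA_INTEGER);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!skel(r, c)) continue;
      int p[8], s = 0;
      for (int k = 0; k < 8; ++k)
        p[k] = at(skel, r + NBR[k][0], c + NBR[k][1]);
      for (int k = 0; k < 8; ++k)
        s += std::abs(p[k] - p[(k + 1) % 8]);
      cn(r, c) = s / 2;
    }
  }
  return cn;
}

// ---- Euclidean distance transform (Felzenszwalb-Huttenlocher) -------------

static const double EDT_INF = 1e20;

static void dt1d(const std::vector<double> &f, int n,
                 std::vector<double> &d, std::vector<int> &arg) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -EDT_INF;
  z[1] = EDT_INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = EDT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = dq * dq + f[v[k]];
    arg[q] = v[k];
  }
}

// [[Rcpp::export(name = ".cpp_edt")]]
List cpp_edt(IntegerMatrix seeds) {
  // seeds: integer label matrix, 0 = non-seed. Returns, per pixel, the
  // Euclidean distance to the nearest seed pixel and that seed's label.
  int H = seeds.nrow(), W = seeds.ncol();
  NumericMatrix dist(H, W);
  IntegerMatrix label(H, W);
  // phase 1: per column, nearest seed row (squared vertical distance)
  std::vector<double> d1(H * W);
  std::vector<int> row1(H * W);
  std::vector<double> f(std::max(H, W));
  std::vector<double> d(std::max(H, W));
  std::vector<int> arg(std::max(H, W));
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) f[r] = seeds(r, c) ? 0.0 : EDT_INF;
    dt1d(f, H, d, arg);
    for (int r = 0; r < H; ++r) {
      d1[(size_t)c * H + r] = d[r];
      row1[(size_t)c * H + r] = arg[r];
    }
  }
  // phase 2: per row, envelope over columns
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) f[c] = d1[(size_t)c * H + r];
    dt1d(f, W, d, arg);
    for (int c = 0; c < W; ++c) {
      int cs = arg[c];
      int rs = row1[(size_t)cs * H + r];
      if (d[c] >= EDT_INF) {
        dist(r, c) = NA_REAL;
        label(r, c) = 0;
      } else {
        dist(r, c) = std::sqrt(d[c]);
        label(r, c) = seeds(rs, cs);
      }
    }
  }
  return List::create(_["dist"] = dist, _["label"] = label);
}

// [[Rcpp::export(name = ".cpp_label8")]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  // 8-connected component labelling (BFS), labels 1..n in scan order.
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int k = 0; k < 8; ++k) {
          int rr = p.first + NBR[k][0], cc = p.second + NBR[k][1];
          if (rr < 0 || cc < 0 || rr >= H || cc >= W) continue;
          if (mask(rr, cc) && !lab(rr, cc)) {
            lab(rr, cc) = next;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}

// ---- branch tracing -------------------------------------------------------

// [[Rcpp::export(name = ".cpp_trace_branches")]]
List cpp_trace_branches(IntegerMatrix skel, IntegerMatrix junction) {
  // Remove junction pixels, label the remaining skeleton 8-connectedly and
  // walk each component into ordered pixel paths. Components without an
  // endpoint are cycles and come back flagged closed.
  int H = skel.nrow(), W = skel.ncol();
  IntegerMatrix rem(H, W);
  for (int i = 0; i < H * W; ++i) rem[i] = (skel[i] != 0 && junction[i] == 0);
  IntegerMatrix lab = cpp_label8(rem);
  int ncomp = 0;
  for (int i = 0; i < H * W; ++i) ncomp = std::max(ncomp, lab[i]);
  std::vector<std::vector<std::pair<int, int> > > comp(ncomp);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (lab(r, c)) comp[lab(r, c) - 1].push_back(std::make_pair(r, c));

  IntegerMatrix branch_id(H, W);
  std::vector<std::vector<std::pair<int, int> > > paths;
  std::vector<bool> closed_flags;
  int bid = 0;
  IntegerMatrix visited(H, W);
  for (int ci = 0; ci < ncomp; ++ci) {
    std::vector<std::pair<int, int> > &px = comp[ci];
    size_t nvis = 0;
    while (nvis < px.size()) {
      // pick an unvisited pixel with the fewest unvisited neighbors
      int best = -1, bestdeg = 9;
      for (size_t i = 0; i < px.size(); ++i) {
        int r = px[i].first, c = px[i].second;
        if (visited(r, c)) continue;
        int deg = 0;
        for (int k = 0; k < 8; ++k) {
          int rr = r + NBR[k][0], cc = c + NBR[k][1];
          if (rr < 0 || cc < 0 || rr >= H || cc >= W) continue;
          if (lab(rr, cc) == ci + 1 && !visited(rr, cc)) ++deg;
        }
        if (deg < bestdeg) {
          bestdeg = deg;
          best = (int)i;
        }
      }
      if (best < 0) break;
      bool cycle = (bestdeg >= 2);
      // walk
      std::vector<std::pair<int, int> > path;
      int r = px[best].first, c = px[best].second;
      visited(r, c) = 1;
      path.push_back(std::make_pair(r, c));
      while (true) {
        int nr = -1, nc = -1;
        // prefer 4-adjacent continuation to avoid corner cutting
        static const int ORD[8] = {0, 2, 4, 6, 1, 3, 5, 7};
        for (int kk = 0; kk < 8; ++kk) {
          int k = ORD[kk];
          int rr = r + NBR[k][0], cc = c + NBR[k][1];
          if (rr < 0 || cc < 0 || rr >= H || cc >= W) continue;
          if (lab(rr, cc) == ci + 1 && !visited(rr, cc)) {
            nr = rr;
            nc = cc;
            break;
          }
        }
        if (nr < 0) break;
        r = nr;
        c = nc;
        visited(r, c) = 1;
        path.push_back(std::make_pair(r, c));
      }
      ++bid;
      for (size_t i = 0; i < path.size(); ++i)
        branch_id(path[i].first, path[i].second) = bid;
      nvis += path.size();
      bool closed = false;
      if (cycle && path.size() >= 3) {
        int dr = std::abs(path.front().first - path.back().first);
        int dc = std::abs(path.front().second - path.back().second);
        closed = (dr <= 1 && dc <= 1);
      }
      paths.push_back(path);
      closed_flags.push_back(closed);
    }
  }
  List out((int)paths.size());
  for (size_t b = 0; b < paths.size(); ++b) {
    IntegerMatrix pts((int)paths[b].size(), 2);
    for (size_t i = 0; i < paths[b].size(); ++i) {
      pts(i, 0) = paths[b][i].first + 1;  // 1-based for R
      pts(i, 1) = paths[b][i].second + 1;
    }
    out[b] = List::create(_["points"] = pts,
                          _["closed"] = (bool)closed_flags[b]);
  }
  return List::create(_["branches"] = out, _["branch_id"] = branch_id);
}

// ---- synthetic vascular tree ----------------------------------------------

struct Tip {
  double r, c, theta, w;
  int depth;
};

static void stamp_disc(IntegerMatrix &m, double r, double c, double rad) {
  int H = m.nrow(), W = m.ncol();
  int R = (int)std::ceil(rad);
  int r0 = (int)std::lround(r), c0 = (int)std::lround(c);
  double rad2 = rad * rad;
  for (int dr = -R; dr <= R; ++dr) {
    for (int dc = -R; dc <= R; ++dc) {
      int rr = r0 + dr, cc = c0 + dc;
      if (rr < 0 || cc < 0 || rr >= H || cc >= W) continue;
      double dy = rr - r, dx = cc - c;
      if (dy * dy + dx * dx <= rad2 + 0.25) m(rr, cc) = 1;
    }
  }
}

// [[Rcpp::export(name = ".cpp_grow_tree")]]
List cpp_grow_tree(int H, int W, int n_roots, double w0, double p_bif,
                   double tau, int max_steps, double step_len,
                   double ang_min, double ang_max, double murray_exp,
                   int max_tips) {
  // Discrete random-walk growth from border roots. Uses R's RNG so results
  // are reproducible under set.seed(). Headings are rounded to 1e-6 rad so
  // the rendered lattice is stable across platforms.
  IntegerMatrix mask(H, W);
  int n_bif = 0, n_end = 0, n_spawned = 0;
  std::vector<double> gt_w, gt_arc, gt_chord;
  std::vector<int> gt_depth;
  double shrink = std::pow(2.0, -1.0 / murray_exp);
  std::vector<Tip> stack;
  // roots fan out from a disc-like origin on one border, like vessels
  // radiating from the optic nerve head
  int side = (int)std::floor(R::unif_rand() * 4.0);
  if (side > 3) side = 3;
  double u0 = 0.2 + 0.6 * R::unif_rand();
  double spread = 30.0;
  for (int i = 0; i < n_roots; ++i) {
    Tip t;
    double du = (R::unif_rand() - 0.5) * 2.0 * spread;
    // fan angle: roots spaced across +/- 55 degrees around the inward normal
    double fan = (n_roots > 1)
      ? (-0.96 + 1.92 * i / (n_roots - 1.0)) + (R::unif_rand() - 0.5) * 0.3
      : (R::unif_rand() - 0.5) * 0.6;
    if (side == 0) { t.r = 0; t.c = u0 * (W - 1) + du; t.theta = M_PI / 2 + fan; }
    else if (side == 1) { t.r = H - 1; t.c = u0 * (W - 1) + du; t.theta = -M_PI / 2 + fan; }
    else if (side == 2) { t.r = u0 * (H - 1) + du; t.c = 0; t.theta = 0 + fan; }
    else { t.r = u0 * (H - 1) + du; t.c = W - 1; t.theta = M_PI + fan; }
    t.r = std::min((double)(H - 1), std::max(0.0, t.r));
    t.c = std::min((double)(W - 1), std::max(0.0, t.c));
    t.w = w0;
    t.depth = 0;
    stack.push_back(t);
    ++n_spawned;
  }
  long total_guard = 0;
  while (!stack.empty()) {
    Tip t = stack.back();
    stack.pop_back();
    double br = t.r, bc = t.c;  // branch start
    double arc = 0.0;
    bool alive = true;
    stamp_disc(mask, t.r, t.c, std::max(t.w / 2.0, 0.5));
    while (alive) {
      if (++total_guard > 2000000L) { alive = false; ++n_end; break; }
      if (t.depth >= max_steps || t.w < 1.0) { alive = false; ++n_end; break; }
      t.theta += R::norm_rand() * tau;
      t.theta = std::round(t.theta * 1e6) / 1e6;
      t.r += step_len * std::sin(t.theta);
      t.c += step_len * std::cos(t.theta);
      t.depth += 1;
      arc += step_len;
      if (t.r < 0 || t.c < 0 || t.r > H - 1 || t.c > W - 1) {
        alive = false;
        ++n_end;
        break;
      }
      stamp_disc(mask, t.r, t.c, std::max(t.w / 2.0, 0.5));
      double cw = t.w * shrink;
      if (cw >= 1.0 && n_spawned + 2 <= max_tips &&
          R::unif_rand() < p_bif) {
        ++n_bif;
        double a1 = ang_min + R::unif_rand() * (ang_max - ang_min);
        double a2 = ang_min + R::unif_rand() * (ang_max - ang_min);
        Tip c1 = t, c2 = t;
        c1.theta = t.theta + a1;
        c1.w = cw;
        c2.theta = t.theta - a2;
        c2.w = cw;
        stack.push_back(c2);
        stack.push_back(c1);
        n_spawned += 2;
        alive = false;  // parent branch ends at the fork
      }
    }
    double dr = t.r - br, dc = t.c - bc;
    gt_w.push_back(t.w);
    gt_arc.push_back(arc);
    gt_chord.push_back(std::sqrt(dr * dr + dc * dc));
    gt_depth.push_back(t.depth);
  }
  return List::create(
      _["mask"] = mask, _["n_bifurcations"] = n_bif, _["n_endpoints"] = n_end,
      _["branch_width"] = wrap(gt_w), _["branch_arc"] = wrap(gt_arc),
      _["branch_chord"] = wrap(gt_chord), _["branch_depth"] = wrap(gt_depth));
}
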