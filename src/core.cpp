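// Simulation core: polarity-modulated pair interactions, line-of-sight
// neighborhoods, and overdamped Euler integration. All randomness comes from
// R's RNG (unif_rand / norm_rand) so set.seed() controls every draw.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

// ---------------------------------------------------------------------------
// Pairwise interaction
//
// V = Rep(r) - S * Att(r), with S = l1*S1 + l2*S2 + l3*S3 and
//   S1 = p_i.p_j - (rhat.p_i)(rhat.p_j)   (quadruple product identity)
//   S2 = (p_i.p_j)(q_i.q_j) - (p_i.q_j)(q_i.p_j)
//   S3 = q_i.q_j - (rhat.q_i)(rhat.q_j)
// Polarity gradients are the gradients of V with each polarity normalized
// inside, i.e. projected orthogonal to the polarity itself; for unit input
// this is (I - p p^T) dV/dp.
// ---------------------------------------------------------------------------
struct PairOut {
  double V, S, S1, S2, S3, r;
  double dVdri[3], dVdrj[3], dVdpi[3], dVdpj[3], dVdqi[3], dVdqj[3];
};

static void pair_interaction(const double* xi, const double* xj,
                             const double* pi, const double* pj,
                             const double* qi, const double* qj,
                             const double* li, const double* lj,
                             double beta, int expo, bool angle_gate,
                             bool inplane_i, bool inplane_j, double s_const,
                             PairOut& out) {
  double d[3] = { xj[0] - xi[0], xj[1] - xi[1], xj[2] - xi[2] };
  double r = norm3(d);
  if (r <= 0.0) stop("coincident cell positions (r_ij = 0)");
  double rhat[3] = { d[0] / r, d[1] / r, d[2] / r };
  out.r = r;

  double l1 = 0.5 * (li[0] + lj[0]);
  double l2 = 0.5 * (li[1] + lj[1]);
  double l3 = 0.5 * (li[2] + lj[2]);

  double pipj = dot3(pi, pj), rpi = dot3(rhat, pi), rpj = dot3(rhat, pj);
  double qiqj = dot3(qi, qj), rqi = dot3(rhat, qi), rqj = dot3(rhat, qj);
  double piqj = dot3(pi, qj), qipj = dot3(qi, pj);

  double S1 = pipj - rpi * rpj;
  double S2 = pipj * qiqj - piqj * qipj;
  double S3 = qiqj - rqi * rqj;
  // AB attraction gated off when polarities point more than pi/2 apart
  double l1e = (angle_gate && pipj < 0.0) ? 0.0 : l1;

  bool fixedS = (s_const >= 0.0);
  double S = fixedS ? s_const : (l1e * S1 + l2 * S2 + l3 * S3);

  double Rep, Att, c_r; // c_r: coefficient of rhat in dV/dri
  if (expo == 1) {
    Rep = std::exp(-r);
    Att = std::exp(-r / beta);
    c_r = Rep - (S / beta) * Att;
  } else {
    double r3 = r * r * r, b4 = beta * beta * beta * beta;
    Rep = std::exp(-r3 * r);
    Att = std::exp(-r3 * r / b4);
    c_r = 4.0 * r3 * (Rep - (S / b4) * Att);
  }
  out.V = Rep - S * Att;
  out.S = S; out.S1 = S1; out.S2 = S2; out.S3 = S3;

  if (fixedS) {
    for (int a = 0; a < 3; ++a) {
      out.dVdri[a] = c_r * rhat[a];
      out.dVdrj[a] = -out.dVdri[a];
      out.dVdpi[a] = out.dVdpj[a] = out.dVdqi[a] = out.dVdqj[a] = 0.0;
    }
    return;
  }

  // dS1/dri = (1/r)[(rhat.pj) pi + (rhat.pi) pj - 2 (rhat.pi)(rhat.pj) rhat]
  // (dS3/dri analogous with q); dV/drj = -dV/dri.
  double l2pi = inplane_i ? 0.0 : l2; // PCP confined to apical plane: no
  double l2pj = inplane_j ? 0.0 : l2; // back-action on AB polarity
  for (int a = 0; a < 3; ++a) {
    double dS1ri = (rpj * pi[a] + rpi * pj[a] - 2.0 * rpi * rpj * rhat[a]) / r;
    double dS3ri = (rqj * qi[a] + rqi * qj[a] - 2.0 * rqi * rqj * rhat[a]) / r;
    out.dVdri[a] = c_r * rhat[a] - Att * (l1e * dS1ri + l3 * dS3ri);
    out.dVdrj[a] = -out.dVdri[a];

    double dS1pi = pj[a] - rpj * rhat[a] - S1 * pi[a];
    double dS2pi = qiqj * pj[a] - qipj * qj[a] - S2 * pi[a];
    out.dVdpi[a] = -Att * (l1e * dS1pi + l2pi * dS2pi);

    double dS1pj = pi[a] - rpi * rhat[a] - S1 * pj[a];
    double dS2pj = qiqj * pi[a] - piqj * qi[a] - S2 * pj[a];
    out.dVdpj[a] = -Att * (l1e * dS1pj + l2pj * dS2pj);

    double dS2qi = pipj * qj[a] - piqj * pj[a] - S2 * qi[a];
    double dS3qi = qj[a] - rqj * rhat[a] - S3 * qi[a];
    out.dVdqi[a] = -Att * (l2 * dS2qi + l3 * dS3qi);

    double dS2qj = pipj * qi[a] - qipj * pi[a] - S2 * qj[a];
    double dS3qj = qi[a] - rqi * rhat[a] - S3 * qj[a];
    out.dVdqj[a] = -Att * (l2 * dS2qj + l3 * dS3qj);
  }
}

// [[Rcpp::export]]
List pair_interaction_cpp(NumericVector xi, NumericVector xj,
                          NumericVector pi, NumericVector pj,
                          NumericVector qi, NumericVector qj,
                          NumericVector li, NumericVector lj,
                          double beta, int exponent, bool angle_gate,
                          bool inplane_i, bool inplane_j,
                          double s_const = -1.0) {
  PairOut o;
  pair_interaction(xi.begin(), xj.begin(), pi.begin(), pj.begin(),
                   qi.begin(), qj.begin(), li.begin(), lj.begin(),
                   beta, exponent, angle_gate, inplane_i, inplane_j, s_const, o);
  return List::create(
    _["V"] = o.V, _["S"] = o.S, _["S1"] = o.S1, _["S2"] = o.S2,
    _["S3"] = o.S3, _["r"] = o.r,
    _["dV_dri"] = NumericVector(o.dVdri, o.dVdri + 3),
    _["dV_drj"] = NumericVector(o.dVdrj, o.dVdrj + 3),
    _["dV_dpi"] = NumericVector(o.dVdpi, o.dVdpi + 3),
    _["dV_dpj"] = NumericVector(o.dVdpj, o.dVdpj + 3),
    _["dV_dqi"] = NumericVector(o.dVdqi, o.dVdqi + 3),
    _["dV_dqj"] = NumericVector(o.dVdqj, o.dVdqj + 3));
}

// ---------------------------------------------------------------------------
// Neighborhoods
// ---------------------------------------------------------------------------

// k nearest candidates per cell, sorted by distance, flattened to N x k.
// Uses a cell-list grid with expanding-ring search (O(N k) in homogeneous
// systems); errors on coincident positions.
static void knn_candidates(const std::vector<double>& x, int N, int k,
                           std::vector<int>& idx, std::vector<double>& d2s,
                           int& kk) {
  kk = std::min(k, N - 1);
  idx.assign((size_t)N * kk, -1);
  d2s.assign((size_t)N * kk, 0.0);
  if (kk < 1) return;

  if (N <= 128) { // brute force: no grid pathologies for tiny or degenerate sets
    std::vector<std::pair<double, int> > buf(N - 1);
    for (int i = 0; i < N; ++i) {
      int m = 0;
      const double* xi = &x[3 * i];
      for (int j = 0; j < N; ++j) {
        if (j == i) continue;
        double dx = x[3 * j] - xi[0], dy = x[3 * j + 1] - xi[1],
               dz = x[3 * j + 2] - xi[2];
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 <= 0.0) stop("coincident cell positions");
        buf[m++] = std::make_pair(d2, j);
      }
      std::partial_sort(buf.begin(), buf.begin() + kk, buf.end());
      for (int a = 0; a < kk; ++a) {
        idx[(size_t)i * kk + a] = buf[a].second;
        d2s[(size_t)i * kk + a] = buf[a].first;
      }
    }
    return;
  }

  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) { lo[a] = hi[a] = x[a]; }
  for (int i = 1; i < N; ++i)
    for (int a = 0; a < 3; ++a) {
      lo[a] = std::min(lo[a], x[3 * i + a]);
      hi[a] = std::max(hi[a], x[3 * i + a]);
    }
  double ext[3], maxext = 0.0, vol = 1.0;
  for (int a = 0; a < 3; ++a) {
    ext[a] = hi[a] - lo[a];
    maxext = std::max(maxext, ext[a]);
    vol *= std::max(ext[a], 1e-12);
  }
  // bucket edge from mean density, but never more than 64 buckets per axis
  // so degenerate (near-planar or near-collinear) clouds stay cheap
  double h = std::max(1e-8, 2.0 * std::cbrt(vol / N));
  h = std::max(h, maxext / 64.0);
  int ng[3];
  for (int a = 0; a < 3; ++a)
    ng[a] = std::max(1, (int)std::floor(ext[a] / h) + 1);
  long nb = (long)ng[0] * ng[1] * ng[2];
  std::vector<int> bucket_of(N), count(nb + 1, 0);
  for (int i = 0; i < N; ++i) {
    int b[3];
    for (int a = 0; a < 3; ++a) {
      b[a] = std::min(ng[a] - 1, (int)((x[3 * i + a] - lo[a]) / h));
    }
    bucket_of[i] = (b[0] * ng[1] + b[1]) * ng[2] + b[2];
    ++count[bucket_of[i] + 1];
  }
  for (long b = 0; b < nb; ++b) count[b + 1] += count[b];
  std::vector<int> members(N), fill(count.begin(), count.end() - 1);
  for (int i = 0; i < N; ++i) members[fill[bucket_of[i]]++] = i;

  std::vector<std::pair<double, int> > cand;
  cand.reserve(4 * kk);
  int max_ring = ng[0] + ng[1] + ng[2];
  for (int i = 0; i < N; ++i) {
    const double* xi = &x[3 * i];
    int bi[3];
    for (int a = 0; a < 3; ++a)
      bi[a] = std::min(ng[a] - 1, (int)((xi[a] - lo[a]) / h));
    cand.clear();
    for (int ring = 0; ring <= max_ring; ++ring) {
      // visit buckets at Chebyshev distance == ring
      int x0 = std::max(0, bi[0] - ring), x1 = std::min(ng[0] - 1, bi[0] + ring);
      for (int bx = x0; bx <= x1; ++bx) {
        int rx = std::abs(bx - bi[0]);
        int ry_lo = (rx == ring) ? 0 : ring;
        int y0 = std::max(0, bi[1] - ring), y1 = std::min(ng[1] - 1, bi[1] + ring);
        for (int by = y0; by <= y1; ++by) {
          int ry = std::abs(by - bi[1]);
          if (rx != ring && ry != ring) {
            // interior in x and y: z must be at +/- ring
            for (int s = -1; s <= 1; s += 2) {
              int bz = bi[2] + s * ring;
              if (ring == 0 && s == 1) continue;
              if (bz < 0 || bz >= ng[2]) continue;
              long b = ((long)bx * ng[1] + by) * ng[2] + bz;
              for (int t = count[b]; t < count[b + 1]; ++t) {
                int j = members[t];
                if (j == i) continue;
                double dx = x[3 * j] - xi[0], dy = x[3 * j + 1] - xi[1],
                       dz = x[3 * j + 2] - xi[2];
                double d2 = dx * dx + dy * dy + dz * dz;
                if (d2 <= 0.0) stop("coincident cell positions");
                cand.push_back(std::make_pair(d2, j));
              }
            }
          } else {
            int z0 = std::max(0, bi[2] - ring), z1 = std::min(ng[2] - 1, bi[2] + ring);
            for (int bz = z0; bz <= z1; ++bz) {
              long b = ((long)bx * ng[1] + by) * ng[2] + bz;
              for (int t = count[b]; t < count[b + 1]; ++t) {
                int j = members[t];
                if (j == i) continue;
                double dx = x[3 * j] - xi[0], dy = x[3 * j + 1] - xi[1],
                       dz = x[3 * j + 2] - xi[2];
                double d2 = dx * dx + dy * dy + dz * dz;
                if (d2 <= 0.0) stop("coincident cell positions");
                cand.push_back(std::make_pair(d2, j));
              }
            }
          }
          (void)ry_lo;
        }
      }
      // points in unvisited buckets are at distance >= ring*h from x_i
      if ((int)cand.size() >= kk) {
        std::nth_element(cand.begin(), cand.begin() + (kk - 1), cand.end());
        double dk = cand[kk - 1].first;
        double safe = (double)ring * h;
        if (dk <= safe * safe) break;
      }
    }
    std::partial_sort(cand.begin(), cand.begin() + kk, cand.end());
    for (int a = 0; a < kk; ++a) {
      idx[(size_t)i * kk + a] = cand[a].second;
      d2s[(size_t)i * kk + a] = cand[a].first;
    }
  }
}

// Line-of-sight rule: edge (i,j) kept iff every other cell k is strictly
// farther than r_ij/2 from the midpoint of i and j (ties block). Candidate
// pairs and blockers come from the prefilter set; a blocker lies within
// r_ij of cell i and r_ij <= the prefilter radius of i for every candidate
// j, so scanning i's candidate list is exact (and the whole rule is exact
// relative to brute force whenever prefilter_k >= N-1).
static void los_edges(const std::vector<double>& x, int N, int prefilter_k,
                      std::vector<std::pair<int, int> >& edges) {
  edges.clear();
  if (N < 2) return;
  std::vector<int> knn;
  std::vector<double> kd2;
  int kk;
  knn_candidates(x, N, prefilter_k, knn, kd2, kk);

  for (int i = 0; i < N; ++i) {
    const double* xi = &x[3 * i];
    const int* lst = &knn[(size_t)i * kk];
    const double* ld2 = &kd2[(size_t)i * kk];
    for (int a = 0; a < kk; ++a) {
      int j = lst[a];
      const double* xj = &x[3 * j];
      double m[3] = { 0.5 * (xi[0] + xj[0]), 0.5 * (xi[1] + xj[1]),
                      0.5 * (xi[2] + xj[2]) };
      double r2 = ld2[a];
      double thr = 0.25 * r2;
      bool blocked = false;
      for (int b = 0; b < kk; ++b) {
        if (ld2[b] > r2) break; // sorted: no further blockers possible
        int k = lst[b];
        if (k == j) continue;
        const double* xk = &x[3 * k];
        double ux = xk[0] - m[0], uy = xk[1] - m[1], uz = xk[2] - m[2];
        if (ux * ux + uy * uy + uz * uz <= thr) { blocked = true; break; }
      }
      if (!blocked)
        edges.push_back(std::make_pair(std::min(i, j), std::max(i, j)));
    }
  }
  std::sort(edges.begin(), edges.end());
  edges.erase(std::unique(edges.begin(), edges.end()), edges.end());
}

// [[Rcpp::export]]
IntegerMatrix find_neighbors_cpp(NumericMatrix pos, int prefilter_k) {
  int N = pos.nrow();
  std::vector<double> x(3 * N);
  for (int i = 0; i < N; ++i)
    for (int a = 0; a < 3; ++a) x[3 * i + a] = pos(i, a);
  std::vector<std::pair<int, int> > edges;
  los_edges(x, N, prefilter_k, edges);
  IntegerMatrix out(edges.size(), 2);
  for (size_t e = 0; e < edges.size(); ++e) {
    out(e, 0) = edges[e].first + 1;
    out(e, 1) = edges[e].second + 1;
  }
  return out;
}

// Voronoi-facet adjacency with a distance cutoff. Two cells are adjacent iff
// their bisector plane carries a region closer to them than to every other
// cell; tested by clipping a large square on the bisector plane by the
// half-plane constraints from all other cells (exact 2D polygon clipping).
static bool facet_nonempty(const std::vector<double>& x, int N, int i, int j,
                           const std::vector<int>& others, double box) {
  const double* xi = &x[3 * i];
  const double* xj = &x[3 * j];
  double n[3] = { xj[0] - xi[0], xj[1] - xi[1], xj[2] - xi[2] };
  double nn = norm3(n);
  if (nn <= 0.0) stop("coincident cell positions");
  for (int a = 0; a < 3; ++a) n[a] /= nn;
  double m[3] = { 0.5 * (xi[0] + xj[0]), 0.5 * (xi[1] + xj[1]),
                  0.5 * (xi[2] + xj[2]) };
  // orthonormal basis of the bisector plane
  double e1[3];
  if (std::fabs(n[0]) < 0.9) { e1[0] = 0; e1[1] = -n[2]; e1[2] = n[1]; }
  else { e1[0] = -n[2]; e1[1] = 0; e1[2] = n[0]; }
  double l1 = norm3(e1);
  for (int a = 0; a < 3; ++a) e1[a] /= l1;
  double e2[3] = { n[1] * e1[2] - n[2] * e1[1], n[2] * e1[0] - n[0] * e1[2],
                   n[0] * e1[1] - n[1] * e1[0] };
  // initial polygon: big square
  std::vector<double> pu, pv, qu, qv;
  pu.push_back(-box); pv.push_back(-box);
  pu.push_back(box);  pv.push_back(-box);
  pu.push_back(box);  pv.push_back(box);
  pu.push_back(-box); pv.push_back(box);
  for (size_t t = 0; t < others.size(); ++t) {
    int k = others[t];
    if (k == i || k == j) continue;
    const double* xk = &x[3 * k];
    double w[3] = { xk[0] - xi[0], xk[1] - xi[1], xk[2] - xi[2] };
    // |y - xi|^2 <= |y - xk|^2  <=>  2 w . y <= |xk|^2 - |xi|^2 (rel. to m)
    double a = 2.0 * dot3(w, e1), b = 2.0 * dot3(w, e2);
    double rhs = dot3(w, w) + 2.0 * (w[0] * (xi[0] - m[0]) +
               w[1] * (xi[1] - m[1]) + w[2] * (xi[2] - m[2]));
    // constraint: a*u + b*v <= rhs
    qu.clear(); qv.clear();
    int nv = (int)pu.size();
    if (nv == 0) return false;
    for (int s = 0; s < nv; ++s) {
      int s2 = (s + 1) % nv;
      double f1 = a * pu[s] + b * pv[s] - rhs;
      double f2 = a * pu[s2] + b * pv[s2] - rhs;
      if (f1 <= 0) { qu.push_back(pu[s]); qv.push_back(pv[s]); }
      if ((f1 < 0 && f2 > 0) || (f1 > 0 && f2 < 0)) {
        double tt = f1 / (f1 - f2);
        qu.push_back(pu[s] + tt * (pu[s2] - pu[s]));
        qv.push_back(pv[s] + tt * (pv[s2] - pv[s]));
      }
    }
    pu = qu; pv = qv;
    if (pu.size() < 3) return false;
  }
  // non-degenerate area?
  double area = 0.0;
  int nv = (int)pu.size();
  for (int s = 0; s < nv; ++s) {
    int s2 = (s + 1) % nv;
    area += pu[s] * pv[s2] - pu[s2] * pv[s];
  }
  return std::fabs(0.5 * area) > 1e-9;
}

// [[Rcpp::export]]
IntegerMatrix voronoi_cutoff_cpp(NumericMatrix pos, double cutoff,
                                 int prefilter_k) {
  int N = pos.nrow();
  std::vector<double> x(3 * N);
  double ext = 0.0;
  for (int i = 0; i < N; ++i)
    for (int a = 0; a < 3; ++a) {
      x[3 * i + a] = pos(i, a);
      ext = std::max(ext, std::fabs(pos(i, a)));
    }
  double box = 100.0 * (ext + 1.0);
  std::vector<std::pair<int, int> > edges;
  if (N >= 2) {
    std::vector<int> knn;
    std::vector<double> kd2;
    int kk;
    knn_candidates(x, N, prefilter_k, knn, kd2, kk);
    bool exact = (kk == N - 1);
    std::vector<std::pair<int, int> > cand;
    double c2 = cutoff * cutoff;
    for (int i = 0; i < N; ++i)
      for (int a = 0; a < kk; ++a)
        if (kd2[(size_t)i * kk + a] <= c2) {
          int j = knn[(size_t)i * kk + a];
          cand.push_back(std::make_pair(std::min(i, j), std::max(i, j)));
        }
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
    std::vector<int> all;
    if (exact) { all.resize(N); for (int i = 0; i < N; ++i) all[i] = i; }
    for (size_t e = 0; e < cand.size(); ++e) {
      int i = cand[e].first, j = cand[e].second;
      std::vector<int> others;
      if (exact) others = all;
      else {
        others.assign(knn.begin() + (size_t)i * kk,
                      knn.begin() + (size_t)(i + 1) * kk);
        others.insert(others.end(), knn.begin() + (size_t)j * kk,
                      knn.begin() + (size_t)(j + 1) * kk);
      }
      if (facet_nonempty(x, N, i, j, others, box)) edges.push_back(cand[e]);
    }
  }
  IntegerMatrix out(edges.size(), 2);
  for (size_t e = 0; e < edges.size(); ++e) {
    out(e, 0) = edges[e].first + 1;
    out(e, 1) = edges[e].second + 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Random sequential packing of n points in a ball of radius R with a minimum
// pairwise distance, grid-accelerated. Uses R's RNG.
// [[Rcpp::export]]
NumericMatrix pack_ball_cpp(int n, double R, double min_dist, int max_tries) {
  RNGScope scope;
  NumericMatrix out(n, 3);
  double cell = min_dist;
  int ng = std::max(1, (int)std::ceil(2.0 * R / cell));
  std::vector<std::vector<int> > grid(ng * ng * ng);
  std::vector<double> pts;
  pts.reserve(3 * n);
  int placed = 0;
  long tries = 0;
  double md2 = min_dist * min_dist;
  while (placed < n) {
    if (++tries > (long)max_tries) stop("ball packing failed; increase radius");
    double u = unif_rand(), v = unif_rand(), w = unif_rand();
    double px = (2.0 * u - 1.0) * R, py = (2.0 * v - 1.0) * R,
           pz = (2.0 * w - 1.0) * R;
    if (px * px + py * py + pz * pz > R * R) continue;
    int gx = std::min(ng - 1, (int)((px + R) / cell));
    int gy = std::min(ng - 1, (int)((py + R) / cell));
    int gz = std::min(ng - 1, (int)((pz + R) / cell));
    bool ok = true;
    for (int ax = std::max(0, gx - 1); ax <= std::min(ng - 1, gx + 1) && ok; ++ax)
      for (int ay = std::max(0, gy - 1); ay <= std::min(ng - 1, gy + 1) && ok; ++ay)
        for (int az = std::max(0, gz - 1); az <= std::min(ng - 1, gz + 1) && ok; ++az) {
          const std::vector<int>& cellv = grid[(ax * ng + ay) * ng + az];
          for (size_t t = 0; t < cellv.size(); ++t) {
            int o = cellv[t];
            double dx = pts[3 * o] - px, dy = pts[3 * o + 1] - py,
                   dz = pts[3 * o + 2] - pz;
            if (dx * dx + dy * dy + dz * dz < md2) { ok = false; break; }
          }
        }
    if (!ok) continue;
    pts.push_back(px); pts.push_back(py); pts.push_back(pz);
    grid[(gx * ng + gy) * ng + gz].push_back(placed);
    out(placed, 0) = px; out(placed, 1) = py; out(placed, 2) = pz;
    ++placed;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Overdamped Euler driver.
//
// Per step: recompute neighbors (every neighbor_stride steps), accumulate
// pair forces (negative gradients) and per-cell energies, add external
// fields, then update positions and polarities; polarities are renormalized
// after every step, PCP of in-plane cells is re-projected orthogonal to the
// updated AB polarity. Noise enters as eta * xi added to the deterministic
// rate (plain Euler kicks, no sqrt(dt) scaling).
// [[Rcpp::export]]
List simulate_cpp(NumericMatrix pos0, NumericMatrix p0, NumericMatrix q0,
                  NumericMatrix lam0, LogicalVector fixed0,
                  LogicalVector inplane0, int n_steps, double dt, double beta,
                  int exponent, double eta_pos, double eta_p, double eta_q,
                  bool angle_gate, double s_const, int neighbor_mode,
                  double cutoff, int prefilter_k, int neighbor_stride,
                  double pressure_P, double force_k, double force_sigma,
                  LogicalVector force_mask0, double t0, int sample_every,
                  bool save_frames) {
  RNGScope scope;
  int N = pos0.nrow();
  std::vector<double> x(3 * N), p(3 * N), q(3 * N), lam(3 * N);
  std::vector<int> fixed(N), inplane(N), fmask(N);
  for (int i = 0; i < N; ++i) {
    for (int a = 0; a < 3; ++a) {
      x[3 * i + a] = pos0(i, a);
      p[3 * i + a] = p0(i, a);
      q[3 * i + a] = q0(i, a);
      lam[3 * i + a] = lam0(i, a);
    }
    fixed[i] = fixed0[i] ? 1 : 0;
    inplane[i] = inplane0[i] ? 1 : 0;
    fmask[i] = force_mask0.size() == N ? (force_mask0[i] ? 1 : 0) : 0;
  }
  if (dt <= 0) stop("dt must be positive");

  std::vector<double> Fx(3 * N), Fp(3 * N), Fq(3 * N), E(N);
  std::vector<int> deg(N);
  std::vector<std::pair<int, int> > edges;

  std::vector<double> m_t, m_emean, m_esd, m_nmean, m_nsd;
  List frames;
  double t = t0;
  PairOut o;

  // one force evaluation over current configuration
  // (lambda: local function via C++11 not assumed; use a loop block instead)
  for (int step = 0; step <= n_steps; ++step) {
    bool last = (step == n_steps);
    if (step % neighbor_stride == 0 || last) {
      if (neighbor_mode == 0) los_edges(x, N, prefilter_k, edges);
      else {
        NumericMatrix pm(N, 3);
        for (int i = 0; i < N; ++i)
          for (int a = 0; a < 3; ++a) pm(i, a) = x[3 * i + a];
        IntegerMatrix em = voronoi_cutoff_cpp(pm, cutoff, prefilter_k);
        edges.assign(em.nrow(), std::make_pair(0, 0));
        for (int e = 0; e < em.nrow(); ++e)
          edges[e] = std::make_pair(em(e, 0) - 1, em(e, 1) - 1);
      }
    }
    std::fill(Fx.begin(), Fx.end(), 0.0);
    std::fill(Fp.begin(), Fp.end(), 0.0);
    std::fill(Fq.begin(), Fq.end(), 0.0);
    std::fill(E.begin(), E.end(), 0.0);
    std::fill(deg.begin(), deg.end(), 0);
    for (size_t e = 0; e < edges.size(); ++e) {
      int i = edges[e].first, j = edges[e].second;
      pair_interaction(&x[3 * i], &x[3 * j], &p[3 * i], &p[3 * j], &q[3 * i],
                       &q[3 * j], &lam[3 * i], &lam[3 * j], beta, exponent,
                       angle_gate, inplane[i] != 0, inplane[j] != 0, s_const, o);
      E[i] += o.V; E[j] += o.V;
      ++deg[i]; ++deg[j];
      for (int a = 0; a < 3; ++a) {
        Fx[3 * i + a] -= o.dVdri[a];
        Fx[3 * j + a] -= o.dVdrj[a];
        Fp[3 * i + a] -= o.dVdpi[a];
        Fp[3 * j + a] -= o.dVdpj[a];
        Fq[3 * i + a] -= o.dVdqi[a];
        Fq[3 * j + a] -= o.dVdqj[a];
      }
    }
    if (pressure_P > 0.0) {
      double com[3] = { 0, 0, 0 };
      for (int i = 0; i < N; ++i)
        for (int a = 0; a < 3; ++a) com[a] += x[3 * i + a];
      for (int a = 0; a < 3; ++a) com[a] /= N;
      double rmax2 = 0.0;
      for (int i = 0; i < N; ++i) {
        double dx = x[3 * i] - com[0], dy = x[3 * i + 1] - com[1],
               dz = x[3 * i + 2] - com[2];
        rmax2 = std::max(rmax2, dx * dx + dy * dy + dz * dz);
      }
      double rmax = std::sqrt(rmax2);
      if (rmax > 0) {
        double c = pressure_P / rmax;
        for (int i = 0; i < N; ++i)
          for (int a = 0; a < 3; ++a)
            Fx[3 * i + a] -= c * (x[3 * i + a] - com[a]);
      }
    }
    if (force_k != 0.0) {
      double s2 = force_sigma * force_sigma;
      for (int i = 0; i < N; ++i) {
        if (!fmask[i]) continue;
        double px_ = x[3 * i], py_ = x[3 * i + 1];
        double rho2 = px_ * px_ + py_ * py_;
        double rho = std::sqrt(rho2);
        if (rho < 1e-12) continue; // on the axis: direction undefined
        double g = force_k * std::exp(-rho2 / s2) / rho;
        Fp[3 * i] -= g * px_;
        Fp[3 * i + 1] -= g * py_;
      }
    }

    bool sample = (step % sample_every == 0) || last;
    if (sample) {
      double se = 0, sse = 0, sn = 0, ssn = 0;
      for (int i = 0; i < N; ++i) {
        se += E[i]; sse += E[i] * E[i];
        sn += deg[i]; ssn += (double)deg[i] * deg[i];
      }
      double em = se / N, nm = sn / N;
      m_t.push_back(t);
      m_emean.push_back(em);
      m_esd.push_back(N > 1 ? std::sqrt(std::max(0.0, (sse - N * em * em) / (N - 1))) : 0.0);
      m_nmean.push_back(nm);
      m_nsd.push_back(N > 1 ? std::sqrt(std::max(0.0, (ssn - N * nm * nm) / (N - 1))) : 0.0);
      if (save_frames) {
        NumericMatrix fx(N, 3), fp(N, 3), fq(N, 3);
        for (int i = 0; i < N; ++i)
          for (int a = 0; a < 3; ++a) {
            fx(i, a) = x[3 * i + a];
            fp(i, a) = p[3 * i + a];
            fq(i, a) = q[3 * i + a];
          }
        frames.push_back(List::create(_["time"] = t, _["positions"] = fx,
                                      _["ab"] = fp, _["pcp"] = fq));
      }
    }
    if (last) break;

    for (int i = 0; i < N; ++i) {
      for (int a = 0; a < 3; ++a) {
        double xi_ = eta_pos > 0 ? eta_pos * norm_rand() : 0.0;
        x[3 * i + a] += dt * (Fx[3 * i + a] + xi_);
      }
      if (!fixed[i]) {
        for (int a = 0; a < 3; ++a) {
          double xi_ = eta_p > 0 ? eta_p * norm_rand() : 0.0;
          p[3 * i + a] += dt * (Fp[3 * i + a] + xi_);
        }
        double np = norm3(&p[3 * i]);
        if (np < 1e-12)
          stop("polarity collapse: |p| < 1e-12 for cell %d at t = %g", i + 1, t);
        for (int a = 0; a < 3; ++a) p[3 * i + a] /= np;
        for (int a = 0; a < 3; ++a) {
          double xi_ = eta_q > 0 ? eta_q * norm_rand() : 0.0;
          q[3 * i + a] += dt * (Fq[3 * i + a] + xi_);
        }
        double nq = norm3(&q[3 * i]);
        if (nq < 1e-12)
          stop("polarity collapse: |q| < 1e-12 for cell %d at t = %g", i + 1, t);
        for (int a = 0; a < 3; ++a) q[3 * i + a] /= nq;
        if (inplane[i]) {
          double qp = dot3(&q[3 * i], &p[3 * i]);
          for (int a = 0; a < 3; ++a) q[3 * i + a] -= qp * p[3 * i + a];
          double n2 = norm3(&q[3 * i]);
          if (n2 < 1e-12)
            stop("polarity collapse: PCP parallel to AB for cell %d at t = %g",
                 i + 1, t);
          for (int a = 0; a < 3; ++a) q[3 * i + a] /= n2;
        }
      }
    }
    t += dt;
  }

  NumericMatrix ox(N, 3), op(N, 3), oq(N, 3);
  for (int i = 0; i < N; ++i)
    for (int a = 0; a < 3; ++a) {
      ox(i, a) = x[3 * i + a];
      op(i, a) = p[3 * i + a];
      oq(i, a) = q[3 * i + a];
    }
  IntegerMatrix em(edges.size(), 2);
  for (size_t e = 0; e < edges.size(); ++e) {
    em(e, 0) = edges[e].first + 1;
    em(e, 1) = edges[e].second + 1;
  }
  return List::create(
    _["positions"] = ox, _["ab"] = op, _["pcp"] = oq, _["time"] = t,
    _["edges"] = em,
    _["metrics"] = DataFrame::create(
      _["time"] = m_t, _["energy_mean"] = m_emean, _["energy_sd"] = m_esd,
      _["neighbors_mean"] = m_nmean, _["neighbors_sd"] = m_nsd),
    _["frames"] = frames);
}
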