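#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Edge graph in CSR form: off has n+1 entries (0-based), adj/w hold the
// neighbor indices (0-based) and edge lengths in mm.

struct QNode {
  double d;
  int v;
  bool operator<(const QNode& o) const { return d > o.d; }
};

static void dijkstra_from(const IntegerVector& off, const IntegerVector& adj,
                          const NumericVector& w, const std::vector<int>& sources,
                          double radius, std::vector<double>& dist,
                          std::vector<int>& touched) {
  std::priority_queue<QNode> pq;
  for (int s : sources) {
    if (dist[s] > 0.0) {
      dist[s] = 0.0;
      touched.push_back(s);
      pq.push({0.0, s});
    }
  }
  while (!pq.empty()) {
    QNode top = pq.top();
    pq.pop();
    if (top.d > dist[top.v]) continue;
    for (int k = off[top.v]; k < off[top.v + 1]; ++k) {
      int u = adj[k];
      double nd = top.d + w[k];
      if (radius >= 0 && nd > radius) continue;
      if (nd < dist[u]) {
        if (dist[u] == R_PosInf) touched.push_back(u);
        dist[u] = nd;
        pq.push({nd, u});
      }
    }
  }
}

// Single-source Dijkstra limited to `radius` (radius < 0 means unlimited).
// Returns 1-based vertex indices and their distances.
// [[Rcpp::export(name = ".cpp_geodesic_disc")]]
List cpp_geodesic_disc(int n, IntegerVector off, IntegerVector adj,
                       NumericVector w, int source, double radius) {
  std::vector<double> dist(n, R_PosInf);
  std::vector<int> touched;
  std::vector<int> src(1, source);
  dijkstra_from(off, adj, w, src, radius, dist, touched);
  std::sort(touched.begin(), touched.end());
  int m = touched.size();
  IntegerVector vi(m);
  NumericVector vd(m);
  for (int i = 0; i < m; ++i) {
    vi[i] = touched[i] + 1;
    vd[i] = dist[touched[i]];
  }
  return List::create(_["vertex"] = vi, _["distance"] = vd);
}

// Multi-source Dijkstra: distance from every vertex to its nearest source.
// [[Rcpp::export(name = ".cpp_geodesic_multisource")]]
NumericVector cpp_geodesic_multisource(int n, IntegerVector off, IntegerVector adj,
                                       NumericVector w, IntegerVector sources) {
  std::vector<double> dist(n, R_PosInf);
  std::vector<int> touched;
  std::vector<int> src(sources.begin(), sources.end());
  dijkstra_from(off, adj, w, src, -1.0, dist, touched);
  return NumericVector(dist.begin(), dist.end());
}

// For every vertex: area-weighted means of each column of `vals` over the
// geodesic disc (d <= r1) and annulus (r1 < d <= r2), skipping NA values.
// Returns disc/annulus mean matrices plus valid-vertex counts.
// [[Rcpp::export(name = ".cpp_disc_annulus_stats")]]
List cpp_disc_annulus_stats(int n, IntegerVector off, IntegerVector adj,
                            NumericVector w, NumericMatrix vals,
                            NumericVector area, double r1, double r2) {
  int p = vals.ncol();
  NumericMatrix disc(n, p), ann(n, p);
  IntegerVector nd(n), na_(n);
  std::vector<double> dist(n, R_PosInf);
  std::vector<int> touched;
  std::vector<double> sd(p), sa(p), wd(p), wa(p);
  for (int v = 0; v < n; ++v) {
    touched.clear();
    std::vector<int> src(1, v);
    dijkstra_from(off, adj, w, src, r2, dist, touched);
    std::fill(sd.begin(), sd.end(), 0.0);
    std::fill(sa.begin(), sa.end(), 0.0);
    std::fill(wd.begin(), wd.end(), 0.0);
    std::fill(wa.begin(), wa.end(), 0.0);
    int cd = 0, ca = 0;
    for (int u : touched) {
      bool in_disc = dist[u] <= r1;
      if (in_disc) ++cd; else ++ca;
      for (int j = 0; j < p; ++j) {
        double x = vals(u, j);
        if (ISNAN(x)) continue;
        if (in_disc) { sd[j] += area[u] * x; wd[j] += area[u]; }
        else         { sa[j] += area[u] * x; wa[j] += area[u]; }
      }
      dist[u] = R_PosInf;  // reset for next source
    }
    nd[v] = cd;
    na_[v] = ca;
    for (int j = 0; j < p; ++j) {
      disc(v, j) = wd[j] > 0 ? sd[j] / wd[j] : NA_REAL;
      ann(v, j)  = wa[j] > 0 ? sa[j] / wa[j] : NA_REAL;
    }
  }
  return List::create(_["disc"] = disc, _["annulus"] = ann,
                      _["n_disc"] = nd, _["n_annulus"] = na_);
}

// Distance from point p to triangle (a, b, c); Ericson's closest-point method.
static double point_tri_dist2(const double* p, const double* a,
                              const double* b, const double* c) {
  double ab[3], ac[3], ap[3], bp[3], cp[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  double cl[3];
  if (d1 <= 0 && d2 <= 0) { for (int i = 0; i < 3; ++i) cl[i] = a[i]; goto done; }
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  {
    double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
    double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
    if (d3 >= 0 && d4 <= d3) { for (int i = 0; i < 3; ++i) cl[i] = b[i]; goto done; }
    double vc = d1*d4 - d3*d2;
    if (vc <= 0 && d1 >= 0 && d3 <= 0) {
      double t = d1 / (d1 - d3);
      for (int i = 0; i < 3; ++i) cl[i] = a[i] + t*ab[i];
      goto done;
    }
    for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
    double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
    double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
    if (d6 >= 0 && d5 <= d6) { for (int i = 0; i < 3; ++i) cl[i] = c[i]; goto done; }
    double vb = d5*d2 - d1*d6;
    if (vb <= 0 && d2 >= 0 && d6 <= 0) {
      double t = d2 / (d2 - d6);
      for (int i = 0; i < 3; ++i) cl[i] = a[i] + t*ac[i];
      goto done;
    }
    double va = d3*d6 - d5*d4;
    if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
      double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
      for (int i = 0; i < 3; ++i) cl[i] = b[i] + t*(c[i] - b[i]);
      goto done;
    }
    {
      double denom = 1.0 / (va + vb + vc);
      double v = vb * denom, ww = vc * denom;
      for (int i = 0; i < 3; ++i) cl[i] = a[i] + ab[i]*v + ac[i]*ww;
    }
  }
done:
  double dx = p[0]-cl[0], dy = p[1]-cl[1], dz = p[2]-cl[2];
  return dx*dx + dy*dy + dz*dz;
}

// Minimum distance from each query point to a triangle surface (brute force).
// verts: K x 3, faces: M x 3 (1-based), pts: N x 3.
// [[Rcpp::export(name = ".cpp_point_surface_dist")]]
NumericVector cpp_point_surface_dist(NumericMatrix pts, NumericMatrix verts,
                                     IntegerMatrix faces) {
  int n = pts.nrow(), m = faces.nrow();
  NumericVector out(n);
  std::vector<double> V(verts.nrow() * 3);
  for (int i = 0; i < verts.nrow(); ++i)
    for (int j = 0; j < 3; ++j) V[3*i + j] = verts(i, j);
  for (int i = 0; i < n; ++i) {
    double p[3] = { pts(i, 0), pts(i, 1), pts(i, 2) };
    double best = R_PosInf;
    for (int f = 0; f < m; ++f) {
      const double* a = &V[3 * (faces(f, 0) - 1)];
      const double* b = &V[3 * (faces(f, 1) - 1)];
      const double* c = &V[3 * (faces(f, 2) - 1)];
      double d2 = point_tri_dist2(p, a, b, c);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
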