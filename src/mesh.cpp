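// Isosurface area by marching tetrahedra and geodesic diameter of a voxel
// object.  Both operate on (n1, n2, n3) column-major arrays with physical
// spacing per dimension.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline long idx3m(int i, int j, int k, int n1, int n2) {
  return (long)i + (long)n1 * ((long)j + (long)n2 * (long)k);
}

struct P3 { double x, y, z; };

static inline P3 lerp(const P3 &a, const P3 &b, double fa, double fb, double level) {
  double t = (level - fa) / (fb - fa);
  P3 p = { a.x + t * (b.x - a.x), a.y + t * (b.y - a.y), a.z + t * (b.z - a.z) };
  return p;
}

static inline double tri_area(const P3 &a, const P3 &b, const P3 &c) {
  double ux = b.x - a.x, uy = b.y - a.y, uz = b.z - a.z;
  double vx = c.x - a.x, vy = c.y - a.y, vz = c.z - a.z;
  double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// Area contributed by one tetrahedron with corner positions p[] / values f[].
static double tet_area(const P3 p[4], const double f[4], double level) {
  int below[4], nb = 0, above[4], na = 0;
  for (int i = 0; i < 4; ++i) {
    if (f[i] < level) below[nb++] = i; else above[na++] = i;
  }
  if (nb == 0 || nb == 4) return 0.0;
  if (nb == 1 || nb == 3) {
    int apex = (nb == 1) ? below[0] : above[0];
    int *rest = (nb == 1) ? above : below;
    P3 q0 = lerp(p[apex], p[rest[0]], f[apex], f[rest[0]], level);
    P3 q1 = lerp(p[apex], p[rest[1]], f[apex], f[rest[1]], level);
    P3 q2 = lerp(p[apex], p[rest[2]], f[apex], f[rest[2]], level);
    return tri_area(q0, q1, q2);
  }
  // 2 below / 2 above: quad split into two triangles
  int a0 = below[0], a1 = below[1], b0 = above[0], b1 = above[1];
  P3 p00 = lerp(p[a0], p[b0], f[a0], f[b0], level);
  P3 p01 = lerp(p[a0], p[b1], f[a0], f[b1], level);
  P3 p11 = lerp(p[a1], p[b1], f[a1], f[b1], level);
  P3 p10 = lerp(p[a1], p[b0], f[a1], f[b0], level);
  return tri_area(p00, p01, p11) + tri_area(p00, p11, p10);
}

// six tetrahedra sharing the main diagonal corner0 -> corner7,
// corners indexed bitwise c = di + 2*dj + 4*dk
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
  {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
};

// [[Rcpp::export]]
double mt_surface_area_cpp(NumericVector field, IntegerVector dim,
                           NumericVector spacing, double level) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const double s1 = spacing[0], s2 = spacing[1], s3 = spacing[2];
  double area = 0.0;
  double fv[8];
  P3 pv[8];
  for (int k = 0; k + 1 < n3; ++k)
    for (int j = 0; j + 1 < n2; ++j)
      for (int i = 0; i + 1 < n1; ++i) {
        bool anyb = false, anya = false;
        for (int c = 0; c < 8; ++c) {
          int di = c & 1, dj = (c >> 1) & 1, dk = (c >> 2) & 1;
          double f = field[idx3m(i + di, j + dj, k + dk, n1, n2)];
          fv[c] = f;
          pv[c].x = (i + di) * s1; pv[c].y = (j + dj) * s2; pv[c].z = (k + dk) * s3;
          if (f < level) anyb = true; else anya = true;
        }
        if (!anyb || !anya) continue;
        for (int t = 0; t < 6; ++t) {
          P3 tp[4]; double tf[4];
          for (int v = 0; v < 4; ++v) { tp[v] = pv[TETS[t][v]]; tf[v] = fv[TETS[t][v]]; }
          area += tet_area(tp, tf, level);
        }
      }
  return area;
}

// Dijkstra over the 26-connected voxel graph with physical edge lengths.
// Returns, for a given source (compact id), distances and predecessors.
static void dijkstra(const std::vector<long> &vox, const std::vector<int> &id,
                     int n1, int n2, int n3,
                     const double s1, const double s2, const double s3,
                     int src, std::vector<double> &dist, std::vector<int> &pred) {
  const int nv = (int)vox.size();
  const double INF = std::numeric_limits<double>::infinity();
  dist.assign(nv, INF);
  pred.assign(nv, -1);
  typedef std::pair<double, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node>> pq;
  dist[src] = 0.0;
  pq.push(Node(0.0, src));
  while (!pq.empty()) {
    double d = pq.top().first; int u = pq.top().second; pq.pop();
    if (d > dist[u]) continue;
    long p = vox[u];
    int i = (int)(p % n1);
    int j = (int)((p / n1) % n2);
    int k = (int)(p / ((long)n1 * n2));
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (!di && !dj && !dk) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3) continue;
          int v = id[idx3m(ii, jj, kk, n1, n2)];
          if (v < 0) continue;
          double w = std::sqrt(di * di * s1 * s1 + dj * dj * s2 * s2 + dk * dk * s3 * s3);
          if (dist[u] + w < dist[v]) {
            dist[v] = dist[u] + w;
            pred[v] = u;
            pq.push(Node(dist[v], v));
          }
        }
  }
}

// Geodesic diameter (pseudo-diameter, two Dijkstra sweeps) of a voxel object.
// The extracted path is straightened into chords of roughly `chord_len`
// physical length to suppress grid metrication error (26-neighbour paths
// overestimate Euclidean length by up to ~10% otherwise).
// [[Rcpp::export]]
double geodesic_diameter_cpp(LogicalVector mask, IntegerVector dim,
                             NumericVector spacing, double chord_len) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const long n = (long)n1 * n2 * n3;
  std::vector<long> vox;
  std::vector<int> id(n, -1);
  for (long p = 0; p < n; ++p)
    if (mask[p]) { id[p] = (int)vox.size(); vox.push_back(p); }
  if (vox.empty()) return 0.0;
  if (vox.size() == 1) return 0.0;

  std::vector<double> dist;
  std::vector<int> pred;
  // sweep 1: arbitrary start -> farthest u (within the same component)
  dijkstra(vox, id, n1, n2, n3, spacing[0], spacing[1], spacing[2], 0, dist, pred);
  int u = 0; double best = -1;
  for (int v = 0; v < (int)vox.size(); ++v)
    if (std::isfinite(dist[v]) && dist[v] > best) { best = dist[v]; u = v; }
  // sweep 2: u -> farthest v, keep path
  dijkstra(vox, id, n1, n2, n3, spacing[0], spacing[1], spacing[2], u, dist, pred);
  int vend = u; best = -1;
  for (int v = 0; v < (int)vox.size(); ++v)
    if (std::isfinite(dist[v]) && dist[v] > best) { best = dist[v]; vend = v; }

  // extract path vend -> u
  std::vector<int> path;
  for (int v = vend; v != -1; v = pred[v]) path.push_back(v);
  if (path.size() < 2) return 0.0;

  // straighten: average path voxels into blocks of ~chord_len arc length and
  // sum chords between block centroids (plus the two end segments); the
  // averaging cancels the transverse zig-zag of grid-constrained paths
  double minsp = std::min(spacing[0], std::min(spacing[1], spacing[2]));
  if (chord_len < 2 * minsp) chord_len = 2 * minsp;
  auto coord = [&](int v, double &x, double &y, double &z) {
    long p = vox[v];
    x = (double)(p % n1) * spacing[0];
    y = (double)((p / n1) % n2) * spacing[1];
    z = (double)(p / ((long)n1 * n2)) * spacing[2];
  };
  std::vector<P3> nodes;
  double px, py, pz, x, y, z;
  coord(path[0], px, py, pz);
  nodes.push_back(P3{px, py, pz});
  double acc = 0.0, sx = 0, sy = 0, sz = 0;
  int cnt = 0;
  for (size_t t = 1; t < path.size(); ++t) {
    coord(path[t], x, y, z);
    acc += std::sqrt((x - px) * (x - px) + (y - py) * (y - py) + (z - pz) * (z - pz));
    px = x; py = y; pz = z;
    sx += x; sy += y; sz += z; ++cnt;
    if (acc >= chord_len) {
      nodes.push_back(P3{sx / cnt, sy / cnt, sz / cnt});
      acc = 0.0; sx = sy = sz = 0.0; cnt = 0;
    }
  }
  coord(path.back(), x, y, z);
  nodes.push_back(P3{x, y, z});
  double len = 0.0;
  for (size_t i = 1; i < nodes.size(); ++i) {
    double dx = nodes[i].x - nodes[i - 1].x;
    double dy = nodes[i].y - nodes[i - 1].y;
    double dz = nodes[i].z - nodes[i - 1].z;
    len += std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  return len;
}
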