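#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Geometry kernels for open-curve topology: exact Gauss linking integral and
// writhe via per-segment-pair solid angles, projection crossing diagrams, and
// the diagram-level second Vassiliev measure. All curves are vertex matrices
// (n x 3); an edge i runs from vertex i to vertex i+1 (wrapping when closed).

static inline void sub3(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

static inline double clamp1(double x) {
  return x > 1.0 ? 1.0 : (x < -1.0 ? -1.0 : x);
}

// Signed solid-angle contribution of one ordered segment pair to the Gauss
// integral (Banchoff's formula in the Klenin--Langowski arrangement).
// Returns Omega/(4*pi); degenerate pairs (collinear supports) contribute 0.
static double seg_pair_gauss(const double* p1, const double* p2,
                             const double* p3, const double* p4) {
  double r12[3], r34[3], r13[3], r14[3], r23[3], r24[3];
  sub3(p2, p1, r12); sub3(p4, p3, r34);
  sub3(p3, p1, r13); sub3(p4, p1, r14);
  sub3(p3, p2, r23); sub3(p4, p2, r24);

  double n1[3], n2[3], n3[3], n4[3];
  cross3(r13, r14, n1); cross3(r14, r24, n2);
  cross3(r24, r23, n3); cross3(r23, r13, n4);
  double l1 = norm3(n1), l2 = norm3(n2), l3 = norm3(n3), l4 = norm3(n4);
  if (l1 == 0.0 || l2 == 0.0 || l3 == 0.0 || l4 == 0.0) return 0.0;
  for (int k = 0; k < 3; ++k) {
    n1[k] /= l1; n2[k] /= l2; n3[k] /= l3; n4[k] /= l4;
  }
  double omega = std::asin(clamp1(dot3(n1, n2))) + std::asin(clamp1(dot3(n2, n3)))
               + std::asin(clamp1(dot3(n3, n4))) + std::asin(clamp1(dot3(n4, n1)));
  double cr[3];
  cross3(r34, r12, cr);
  double s = dot3(cr, r13);
  double sgn = (s > 0.0) - (s < 0.0);
  return omega * sgn / (4.0 * M_PI);
}

static inline const double* row_ptr(const NumericMatrix& V, int i,
                                    std::vector<double>& buf) {
  buf[3 * i + 0] = V(i, 0); buf[3 * i + 1] = V(i, 1); buf[3 * i + 2] = V(i, 2);
  return &buf[3 * i];
}

// Copy an n x 3 matrix into contiguous row-major storage.
static std::vector<double> flatten(const NumericMatrix& V) {
  int n = V.nrow();
  std::vector<double> buf(3 * n);
  for (int i = 0; i < n; ++i) {
    buf[3 * i] = V(i, 0); buf[3 * i + 1] = V(i, 1); buf[3 * i + 2] = V(i, 2);
  }
  return buf;
}

// [[Rcpp::export]]
double cpp_gauss_linking(NumericMatrix A, NumericMatrix B,
                         bool closedA, bool closedB) {
  std::vector<double> a = flatten(A), b = flatten(B);
  int na = A.nrow(), nb = B.nrow();
  int ea = closedA ? na : na - 1, eb = closedB ? nb : nb - 1;
  double lk = 0.0;
  for (int i = 0; i < ea; ++i) {
    const double* p1 = &a[3 * i];
    const double* p2 = &a[3 * ((i + 1) % na)];
    for (int j = 0; j < eb; ++j) {
      const double* p3 = &b[3 * j];
      const double* p4 = &b[3 * ((j + 1) % nb)];
      lk += seg_pair_gauss(p1, p2, p3, p4);
    }
  }
  return lk;
}

// [[Rcpp::export]]
double cpp_writhe(NumericMatrix A, bool closed) {
  std::vector<double> a = flatten(A);
  int n = A.nrow();
  int e = closed ? n : n - 1;
  double wr = 0.0;
  for (int i = 0; i < e; ++i) {
    const double* p1 = &a[3 * i];
    const double* p2 = &a[3 * ((i + 1) % n)];
    for (int j = i + 2; j < e; ++j) {
      if (closed && i == 0 && j == e - 1) continue; // wrap-around adjacency
      const double* p3 = &a[3 * j];
      const double* p4 = &a[3 * ((j + 1) % n)];
      wr += 2.0 * seg_pair_gauss(p1, p2, p3, p4);
    }
  }
  return wr;
}

// ---- projection diagrams -------------------------------------------------

struct Crossing {
  double pos1, pos2;  // along-curve positions (edge index + parameter), pos1 < pos2
  bool over1;         // is the passage at pos1 the over-strand?
  double sign;        // +1 right-handed, -1 left-handed
  int edge1, edge2;
  double depth1, depth2;
};

// Orthonormal frame (e1, e2, dir) for projection onto the plane normal to dir.
static void make_frame(const double* dir, double* e1, double* e2) {
  double ax = std::fabs(dir[0]), ay = std::fabs(dir[1]), az = std::fabs(dir[2]);
  double up[3] = {0.0, 0.0, 0.0};
  if (ax <= ay && ax <= az) up[0] = 1.0;
  else if (ay <= az) up[1] = 1.0;
  else up[2] = 1.0;
  cross3(dir, up, e1);
  double l = norm3(e1);
  e1[0] /= l; e1[1] /= l; e1[2] /= l;
  cross3(dir, e1, e2);
}

// Build the self-crossing diagram of one curve projected along dir.
// Returns false when the projection is non-generic (parallel projected edges
// at a near-contact, endpoint-grazing crossings, or depth ties).
static bool build_self_crossings(const std::vector<double>& a, int n, bool closed,
                                 const double* dir, double eps,
                                 std::vector<Crossing>& out) {
  out.clear();
  int e = closed ? n : n - 1;
  double e1[3], e2[3];
  make_frame(dir, e1, e2);
  std::vector<double> u(e + 1), v(e + 1), d(e + 1);
  for (int i = 0; i < n; ++i) {
    const double* p = &a[3 * i];
    u[i] = dot3(p, e1); v[i] = dot3(p, e2); d[i] = dot3(p, dir);
  }
  if (closed) { u[n] = u[0]; v[n] = v[0]; d[n] = d[0]; }
  for (int i = 0; i < e; ++i) {
    double rx = u[i + 1] - u[i], ry = v[i + 1] - v[i];
    double li = std::sqrt(rx * rx + ry * ry);
    for (int j = i + 2; j < e; ++j) {
      if (closed && i == 0 && j == e - 1) continue;
      double sx = u[j + 1] - u[j], sy = v[j + 1] - v[j];
      double lj = std::sqrt(sx * sx + sy * sy);
      double denom = rx * sy - ry * sx;
      double qx = u[j] - u[i], qy = v[j] - v[i];
      if (std::fabs(denom) <= eps * li * lj) {
        // parallel in projection: only a problem if the supports overlap
        double dist = std::fabs(qx * ry - qy * rx) / (li > 0 ? li : 1.0);
        if (dist <= eps * (li + lj)) return false;
        continue;
      }
      double t = (qx * sy - qy * sx) / denom;
      double s = (qx * ry - qy * rx) / denom;
      if (t <= 0.0 || t >= 1.0 || s <= 0.0 || s >= 1.0) continue;
      double tol = 1e-9;
      if (t < tol || t > 1.0 - tol || s < tol || s > 1.0 - tol) return false;
      double di = d[i] + t * (d[i + 1] - d[i]);
      double dj = d[j] + s * (d[j + 1] - d[j]);
      double scale = std::fabs(di) + std::fabs(dj) + 1.0;
      if (std::fabs(di - dj) <= 1e-9 * scale) return false;
      Crossing c;
      c.pos1 = i + t; c.pos2 = j + s;
      c.edge1 = i; c.edge2 = j;
      c.depth1 = di; c.depth2 = dj;
      c.over1 = di > dj;
      // sign from projected (over x under) . dir == cross2(over2d, under2d)
      double cr = c.over1 ? (rx * sy - ry * sx) : (sx * ry - sy * rx);
      c.sign = cr > 0 ? 1.0 : -1.0;
      out.push_back(c);
    }
  }
  return true;
}

// Inter-curve crossings only (for two-curve diagrams / linking estimates).
static bool build_pair_crossings(const std::vector<double>& a, int na, bool clA,
                                 const std::vector<double>& b, int nb, bool clB,
                                 const double* dir, double eps,
                                 std::vector<Crossing>& out) {
  out.clear();
  int ea = clA ? na : na - 1, eb = clB ? nb : nb - 1;
  double e1[3], e2[3];
  make_frame(dir, e1, e2);
  std::vector<double> ua(ea + 1), va(ea + 1), da(ea + 1);
  std::vector<double> ub(eb + 1), vb(eb + 1), db(eb + 1);
  for (int i = 0; i <= ea; ++i) {
    const double* p = &a[3 * (i % na)];
    ua[i] = dot3(p, e1); va[i] = dot3(p, e2); da[i] = dot3(p, dir);
  }
  for (int j = 0; j <= eb; ++j) {
    const double* p = &b[3 * (j % nb)];
    ub[j] = dot3(p, e1); vb[j] = dot3(p, e2); db[j] = dot3(p, dir);
  }
  for (int i = 0; i < ea; ++i) {
    double rx = ua[i + 1] - ua[i], ry = va[i + 1] - va[i];
    double li = std::sqrt(rx * rx + ry * ry);
    for (int j = 0; j < eb; ++j) {
      double sx = ub[j + 1] - ub[j], sy = vb[j + 1] - vb[j];
      double lj = std::sqrt(sx * sx + sy * sy);
      double denom = rx * sy - ry * sx;
      double qx = ub[j] - ua[i], qy = vb[j] - va[i];
      if (std::fabs(denom) <= eps * li * lj) {
        double dist = std::fabs(qx * ry - qy * rx) / (li > 0 ? li : 1.0);
        if (dist <= eps * (li + lj)) return false;
        continue;
      }
      double t = (qx * sy - qy * sx) / denom;
      double s = (qx * ry - qy * rx) / denom;
      if (t <= 0.0 || t >= 1.0 || s <= 0.0 || s >= 1.0) continue;
      double tol = 1e-9;
      if (t < tol || t > 1.0 - tol || s < tol || s > 1.0 - tol) return false;
      double di = da[i] + t * (da[i + 1] - da[i]);
      double dj = db[j] + s * (db[j + 1] - db[j]);
      double scale = std::fabs(di) + std::fabs(dj) + 1.0;
      if (std::fabs(di - dj) <= 1e-9 * scale) return false;
      Crossing c;
      c.pos1 = i + t; c.pos2 = j + s;
      c.edge1 = i; c.edge2 = j;
      c.depth1 = di; c.depth2 = dj;
      c.over1 = di > dj;
      double cr = c.over1 ? (rx * sy - ry * sx) : (sx * ry - sy * rx);
      c.sign = cr > 0 ? 1.0 : -1.0;
      out.push_back(c);
    }
  }
  return true;
}

// Half the sum over alternating interleaved crossing pairs of the product of
// signs (the per-diagram second Vassiliev value).
static double v2_of_diagram(const std::vector<Crossing>& cs) {
  double total = 0.0;
  size_t m = cs.size();
  for (size_t i = 0; i + 1 < m; ++i) {
    double a1 = cs[i].pos1, a2 = cs[i].pos2;
    for (size_t j = i + 1; j < m; ++j) {
      double b1 = cs[j].pos1, b2 = cs[j].pos2;
      bool inter = (a1 < b1 && b1 < a2 && a2 < b2) ||
                   (b1 < a1 && a1 < b2 && b2 < a2);
      if (!inter) continue;
      bool j1_over, j2_over;
      if (a1 < b1) { j1_over = cs[i].over1; j2_over = cs[j].over1; }
      else         { j1_over = cs[j].over1; j2_over = cs[i].over1; }
      if (j1_over != j2_over) total += cs[i].sign * cs[j].sign;
    }
  }
  return 0.5 * total;
}

static NumericMatrix crossings_to_matrix(const std::vector<Crossing>& cs) {
  int m = (int)cs.size();
  NumericMatrix out(m, 7);
  for (int k = 0; k < m; ++k) {
    const Crossing& c = cs[k];
    bool o1 = c.over1;
    out(k, 0) = o1 ? c.edge1 + 1 : c.edge2 + 1;                 // over_edge (1-based)
    out(k, 1) = o1 ? c.edge2 + 1 : c.edge1 + 1;                 // under_edge
    out(k, 2) = c.sign;
    out(k, 3) = o1 ? c.pos1 - c.edge1 : c.pos2 - c.edge2;       // over_param
    out(k, 4) = o1 ? c.pos2 - c.edge2 : c.pos1 - c.edge1;       // under_param
    out(k, 5) = c.pos1;                                         // along-curve pos 1
    out(k, 6) = c.pos2;                                         // along-curve pos 2
  }
  colnames(out) = CharacterVector::create("over_edge", "under_edge", "sign",
                                          "over_param", "under_param",
                                          "pos1", "pos2");
  return out;
}

// [[Rcpp::export]]
List cpp_project_self(NumericMatrix A, bool closed, NumericVector dir, double eps) {
  std::vector<double> a = flatten(A);
  double d[3] = {dir[0], dir[1], dir[2]};
  std::vector<Crossing> cs;
  bool ok = build_self_crossings(a, A.nrow(), closed, d, eps, cs);
  return List::create(_["ok"] = ok, _["crossings"] = crossings_to_matrix(cs),
                      _["v2"] = ok ? v2_of_diagram(cs) : NA_REAL);
}

// [[Rcpp::export]]
List cpp_project_pair(NumericMatrix A, bool closedA, NumericMatrix B, bool closedB,
                      NumericVector dir, double eps) {
  std::vector<double> a = flatten(A), b = flatten(B);
  double d[3] = {dir[0], dir[1], dir[2]};
  std::vector<Crossing> cs;
  bool ok = build_pair_crossings(a, A.nrow(), closedA, b, B.nrow(), closedB,
                                 d, eps, cs);
  double half_sum = 0.0;
  for (size_t k = 0; k < cs.size(); ++k) half_sum += cs[k].sign;
  return List::create(_["ok"] = ok, _["crossings"] = crossings_to_matrix(cs),
                      _["half_signed_sum"] = ok ? 0.5 * half_sum : NA_REAL);
}

static void random_direction(double* d) {
  // uniform on S^2 via normalized Gaussian triple (R's RNG, seedable from R)
  do {
    d[0] = norm_rand(); d[1] = norm_rand(); d[2] = norm_rand();
  } while (norm3(d) < 1e-8);
  double l = norm3(d);
  d[0] /= l; d[1] /= l; d[2] /= l;
}

// [[Rcpp::export]]
List cpp_vassiliev2(NumericMatrix A, bool closed, int n_projections, double eps,
                    bool keep_values) {
  std::vector<double> a = flatten(A);
  int n = A.nrow();
  RNGScope scope;
  std::vector<Crossing> cs;
  NumericVector vals(keep_values ? n_projections : 0);
  NumericMatrix dirs(keep_values ? n_projections : 0, 3);
  double sum = 0.0, sumsq = 0.0;
  int degenerate = 0;
  for (int k = 0; k < n_projections; ++k) {
    double d[3];
    bool ok = false;
    int attempts = 0;
    while (!ok && attempts < 200) {
      random_direction(d);
      ok = build_self_crossings(a, n, closed, d, eps, cs);
      if (!ok) { ++degenerate; ++attempts; }
    }
    if (!ok) stop("could not find a generic projection direction");
    double v = v2_of_diagram(cs);
    sum += v; sumsq += v * v;
    if (keep_values) {
      vals[k] = v;
      dirs(k, 0) = d[0]; dirs(k, 1) = d[1]; dirs(k, 2) = d[2];
    }
  }
  double mean = sum / n_projections;
  double var = n_projections > 1
    ? (sumsq - n_projections * mean * mean) / (n_projections - 1.0) : 0.0;
  if (var < 0) var = 0;
  double se = std::sqrt(var / n_projections);
  List out = List::create(_["estimate"] = mean, _["se"] = se,
                          _["n_projections"] = n_projections,
                          _["n_degenerate"] = degenerate);
  if (keep_values) { out["values"] = vals; out["directions"] = dirs; }
  return out;
}

// Monte-Carlo projection estimate of Lk: average over directions of half the
// signed inter-crossing sum. Serves as the independent sampling-based route
// against the exact segment-pair integral.
// [[Rcpp::export]]
List cpp_linking_mc(NumericMatrix A, bool closedA, NumericMatrix B, bool closedB,
                    int n_projections, double eps) {
  std::vector<double> a = flatten(A), b = flatten(B);
  RNGScope scope;
  std::vector<Crossing> cs;
  double sum = 0.0, sumsq = 0.0;
  int degenerate = 0;
  for (int k = 0; k < n_projections; ++k) {
    double d[3];
    bool ok = false;
    int attempts = 0;
    while (!ok && attempts < 200) {
      random_direction(d);
      ok = build_pair_crossings(a, A.nrow(), closedA, b, B.nrow(), closedB,
                                d, eps, cs);
      if (!ok) { ++degenerate; ++attempts; }
    }
    if (!ok) stop("could not find a generic projection direction");
    double v = 0.0;
    for (size_t q = 0; q < cs.size(); ++q) v += cs[q].sign;
    v *= 0.5;
    sum += v; sumsq += v * v;
  }
  double mean = sum / n_projections;
  double var = n_projections > 1
    ? (sumsq - n_projections * mean * mean) / (n_projections - 1.0) : 0.0;
  if (var < 0) var = 0;
  return List::create(_["estimate"] = mean,
                      _["se"] = std::sqrt(var / n_projections),
                      _["n_projections"] = n_projections,
                      _["n_degenerate"] = degenerate);
}

// Monte-Carlo projection estimate of Wr: average signed self-crossing sum.
// [[Rcpp::export]]
List cpp_writhe_mc(NumericMatrix A, bool closed, int n_projections, double eps) {
  std::vector<double> a = flatten(A);
  int n = A.nrow();
  RNGScope scope;
  std::vector<Crossing> cs;
  double sum = 0.0, sumsq = 0.0;
  int degenerate = 0;
  for (int k = 0; k < n_projections; ++k) {
    double d[3];
    bool ok = false;
    int attempts = 0;
    while (!ok && attempts < 200) {
      random_direction(d);
      ok = build_self_crossings(a, n, closed, d, eps, cs);
      if (!ok) { ++degenerate; ++attempts; }
    }
    if (!ok) stop("could not find a generic projection direction");
    double v = 0.0;
    for (size_t q = 0; q < cs.size(); ++q) v += cs[q].sign;
    sum += v; sumsq += v * v;
  }
  double mean = sum / n_projections;
  double var = n_projections > 1
    ? (sumsq - n_projections * mean * mean) / (n_projections - 1.0) : 0.0;
  if (var < 0) var = 0;
  return List::create(_["estimate"] = mean,
                      _["se"] = std::sqrt(var / n_projections),
                      _["n_projections"] = n_projections,
                      _["n_degenerate"] = degenerate);
}
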