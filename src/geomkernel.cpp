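#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Moller-Trumbore ray/triangle intersection.
// Returns t (distance along unit dir) or +Inf if no hit; writes the
// barycentric coordinates (u, v) of the hit when `bary` is non-null.
static inline double ray_tri_uv(const double *o, const double *d,
                                const double *v0, const double *v1,
                                const double *v2, double *bary) {
  const double eps = 1e-12;
  double e1[3], e2[3], p[3], q[3], s[3];
  for (int i = 0; i < 3; ++i) { e1[i] = v1[i] - v0[i]; e2[i] = v2[i] - v0[i]; }
  p[0] = d[1]*e2[2] - d[2]*e2[1];
  p[1] = d[2]*e2[0] - d[0]*e2[2];
  p[2] = d[0]*e2[1] - d[1]*e2[0];
  double det = e1[0]*p[0] + e1[1]*p[1] + e1[2]*p[2];
  if (std::fabs(det) < eps) return std::numeric_limits<double>::infinity();
  double inv = 1.0 / det;
  for (int i = 0; i < 3; ++i) s[i] = o[i] - v0[i];
  double u = (s[0]*p[0] + s[1]*p[1] + s[2]*p[2]) * inv;
  if (u < -1e-9 || u > 1.0 + 1e-9) return std::numeric_limits<double>::infinity();
  q[0] = s[1]*e1[2] - s[2]*e1[1];
  q[1] = s[2]*e1[0] - s[0]*e1[2];
  q[2] = s[0]*e1[1] - s[1]*e1[0];
  double v = (d[0]*q[0] + d[1]*q[1] + d[2]*q[2]) * inv;
  if (v < -1e-9 || u + v > 1.0 + 1e-9) return std::numeric_limits<double>::infinity();
  double t = (e2[0]*q[0] + e2[1]*q[1] + e2[2]*q[2]) * inv;
  if (bary) { bary[0] = u; bary[1] = v; }
  return t;
}

static inline double ray_tri(const double *o, const double *d,
                             const double *v0, const double *v1,
                             const double *v2) {
  return ray_tri_uv(o, d, v0, v1, v2, 0);
}

// For each query point (px, pz), cast a vertical line (direction +y) and find
// the lowest intersection with the mesh surface. Returns an n x 4 matrix:
// columns y_min, nx, ny, nz -- the unit surface normal at the hit,
// barycentrically interpolated from area-weighted vertex normals so the
// normal field is continuous across facets (oriented with ny <= 0, facing
// down onto the tibia). y_min is NA when no hit.
// [[Rcpp::export]]
NumericMatrix mesh_lower_surface(NumericMatrix V, IntegerMatrix F,
                                 NumericVector px, NumericVector pz) {
  int n = px.size(), nf = F.nrow(), nv = V.nrow();
  NumericMatrix out(n, 4);
  const double dir[3] = {0.0, 1.0, 0.0};
  // per-triangle (x, z) bounding boxes for pruning + vertex normals
  std::vector<double> bxlo(nf), bxhi(nf), bzlo(nf), bzhi(nf);
  std::vector<double> vn(3 * nv, 0.0);
  for (int f = 0; f < nf; ++f) {
    int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    bxlo[f] = std::min(V(a, 0), std::min(V(b, 0), V(c, 0)));
    bxhi[f] = std::max(V(a, 0), std::max(V(b, 0), V(c, 0)));
    bzlo[f] = std::min(V(a, 2), std::min(V(b, 2), V(c, 2)));
    bzhi[f] = std::max(V(a, 2), std::max(V(b, 2), V(c, 2)));
    double e1[3], e2[3], fn[3];
    for (int k = 0; k < 3; ++k) {
      e1[k] = V(b, k) - V(a, k);
      e2[k] = V(c, k) - V(a, k);
    }
    fn[0] = e1[1]*e2[2] - e1[2]*e2[1];
    fn[1] = e1[2]*e2[0] - e1[0]*e2[2];
    fn[2] = e1[0]*e2[1] - e1[1]*e2[0];   // area-weighted
    for (int k = 0; k < 3; ++k) {
      vn[3*a + k] += fn[k]; vn[3*b + k] += fn[k]; vn[3*c + k] += fn[k];
    }
  }
  for (int v = 0; v < nv; ++v) {
    double nrm = std::sqrt(vn[3*v]*vn[3*v] + vn[3*v+1]*vn[3*v+1] + vn[3*v+2]*vn[3*v+2]);
    if (nrm > 0) for (int k = 0; k < 3; ++k) vn[3*v + k] /= nrm;
  }
  for (int i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    double bn[3] = {0, 0, 0};
    double o[3] = {px[i], -1e6, pz[i]};
    for (int f = 0; f < nf; ++f) {
      if (px[i] < bxlo[f] || px[i] > bxhi[f] ||
          pz[i] < bzlo[f] || pz[i] > bzhi[f]) continue;
      double v0[3], v1[3], v2[3], uv[2];
      int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
      for (int k = 0; k < 3; ++k) { v0[k] = V(a, k); v1[k] = V(b, k); v2[k] = V(c, k); }
      double t = ray_tri_uv(o, dir, v0, v1, v2, uv);
      if (std::isfinite(t) && t < best) {
        best = t;
        double w0 = 1.0 - uv[0] - uv[1];
        for (int k = 0; k < 3; ++k)
          bn[k] = w0 * vn[3*a + k] + uv[0] * vn[3*b + k] + uv[1] * vn[3*c + k];
      }
    }
    if (std::isfinite(best)) {
      double nrm = std::sqrt(bn[0]*bn[0] + bn[1]*bn[1] + bn[2]*bn[2]);
      if (nrm > 0) { bn[0] /= nrm; bn[1] /= nrm; bn[2] /= nrm; }
      if (bn[1] > 0) { bn[0] = -bn[0]; bn[1] = -bn[1]; bn[2] = -bn[2]; }
      out(i, 0) = -1e6 + best;
      out(i, 1) = bn[0]; out(i, 2) = bn[1]; out(i, 3) = bn[2];
    } else {
      out(i, 0) = NA_REAL;
      out(i, 1) = NA_REAL; out(i, 2) = NA_REAL; out(i, 3) = NA_REAL;
    }
  }
  return out;
}

// Intersections of segment a->b with the mesh. Returns sorted parameters
// t in (tol, 1 - tol); duplicates within 1e-9 collapsed (shared edges).
// [[Rcpp::export]]
NumericVector segment_mesh_hits(NumericMatrix V, IntegerMatrix F,
                                NumericVector a, NumericVector b,
                                double tol = 1e-7) {
  int nf = F.nrow();
  double d[3], o[3];
  double len = 0;
  for (int k = 0; k < 3; ++k) { o[k] = a[k]; d[k] = b[k] - a[k]; len += d[k]*d[k]; }
  len = std::sqrt(len);
  if (len == 0) return NumericVector(0);
  for (int k = 0; k < 3; ++k) d[k] /= len;
  std::vector<double> hits;
  for (int f = 0; f < nf; ++f) {
    double v0[3], v1[3], v2[3];
    int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
    for (int k = 0; k < 3; ++k) { v0[k] = V(ia, k); v1[k] = V(ib, k); v2[k] = V(ic, k); }
    double t = ray_tri(o, d, v0, v1, v2);
    if (std::isfinite(t)) {
      double s = t / len;
      if (s > tol && s < 1.0 - tol) hits.push_back(s);
    }
  }
  std::sort(hits.begin(), hits.end());
  std::vector<double> uniq;
  for (size_t i = 0; i < hits.size(); ++i)
    if (uniq.empty() || hits[i] - uniq.back() > 1e-9) uniq.push_back(hits[i]);
  return wrap(uniq);
}

static inline void closest_on_tri(const double *p, const double *a,
                                  const double *b, const double *c, double *out) {
  // Ericson, Real-Time Collision Detection, closest point on triangle.
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) { ab[k] = b[k]-a[k]; ac[k] = c[k]-a[k]; ap[k] = p[k]-a[k]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int k=0;k<3;++k) out[k]=a[k]; return; }
  double bp[3]; for (int k = 0; k < 3; ++k) bp[k] = p[k]-b[k];
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int k=0;k<3;++k) out[k]=b[k]; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int k=0;k<3;++k) out[k] = a[k] + v*ab[k];
    return;
  }
  double cp[3]; for (int k = 0; k < 3; ++k) cp[k] = p[k]-c[k];
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int k=0;k<3;++k) out[k]=c[k]; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int k=0;k<3;++k) out[k] = a[k] + w*ac[k];
    return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k=0;k<3;++k) out[k] = b[k] + w*(c[k]-b[k]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k=0;k<3;++k) out[k] = a[k] + ab[k]*v + ac[k]*w;
}

// Closest point on the mesh surface to p. Returns c(x, y, z, distance).
// [[Rcpp::export]]
NumericVector mesh_closest_point(NumericMatrix V, IntegerMatrix F, NumericVector p) {
  int nf = F.nrow();
  double best = std::numeric_limits<double>::infinity();
  double bq[3] = {0, 0, 0};
  double pp[3] = {p[0], p[1], p[2]};
  for (int f = 0; f < nf; ++f) {
    double v0[3], v1[3], v2[3], q[3];
    int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
    for (int k = 0; k < 3; ++k) { v0[k] = V(ia, k); v1[k] = V(ib, k); v2[k] = V(ic, k); }
    closest_on_tri(pp, v0, v1, v2, q);
    double d2 = 0;
    for (int k = 0; k < 3; ++k) { double e = q[k]-pp[k]; d2 += e*e; }
    if (d2 < best) { best = d2; bq[0]=q[0]; bq[1]=q[1]; bq[2]=q[2]; }
  }
  return NumericVector::create(bq[0], bq[1], bq[2], std::sqrt(best));
}
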