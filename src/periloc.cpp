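#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Physical convention shared with the R code: voxel (i, j, k) (1-based in R)
// has its center at ((i - 0.5) * dx, (j - 0.5) * dy, (k - 0.5) * dz) in um.

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Trilinear interpolation of a 3D array at physical point p (um).
// Points outside the voxel-center lattice hull contribute value 0, gradient 0.
static void trilinear(const double *a, int nx, int ny, int nz,
                      double dx, double dy, double dz,
                      double px, double py, double pz,
                      double *val, double *grad) {
  // continuous 0-based voxel coordinates
  double u = px / dx - 0.5, v = py / dy - 0.5, w = pz / dz - 0.5;
  val[0] = 0.0;
  if (grad) grad[0] = grad[1] = grad[2] = 0.0;
  if (u < 0 || v < 0 || w < 0 || u > nx - 1 || v > ny - 1 || w > nz - 1)
    return;
  int i0 = (int)std::floor(u), j0 = (int)std::floor(v), k0 = (int)std::floor(w);
  if (i0 > nx - 2) i0 = nx - 2;
  if (j0 > ny - 2) j0 = ny - 2;
  if (k0 > nz - 2) k0 = nz - 2;
  if (nx == 1) i0 = 0;
  if (ny == 1) j0 = 0;
  if (nz == 1) k0 = 0;
  double fu = clampd(u - i0, 0.0, 1.0);
  double fv = clampd(v - j0, 0.0, 1.0);
  double fw = clampd(w - k0, 0.0, 1.0);
  int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
      k1 = std::min(k0 + 1, nz - 1);
#define AT(I, J, K) a[(I) + nx * ((J) + (size_t)ny * (K))]
  double c000 = AT(i0, j0, k0), c100 = AT(i1, j0, k0);
  double c010 = AT(i0, j1, k0), c110 = AT(i1, j1, k0);
  double c001 = AT(i0, j0, k1), c101 = AT(i1, j0, k1);
  double c011 = AT(i0, j1, k1), c111 = AT(i1, j1, k1);
#undef AT
  double c00 = c000 * (1 - fu) + c100 * fu;
  double c10 = c010 * (1 - fu) + c110 * fu;
  double c01 = c001 * (1 - fu) + c101 * fu;
  double c11 = c011 * (1 - fu) + c111 * fu;
  double c0 = c00 * (1 - fv) + c10 * fv;
  double c1 = c01 * (1 - fv) + c11 * fv;
  val[0] = c0 * (1 - fw) + c1 * fw;
  if (grad) {
    // d/du then chain rule to physical um
    double du = ((c100 - c000) * (1 - fv) + (c110 - c010) * fv) * (1 - fw) +
                ((c101 - c001) * (1 - fv) + (c111 - c011) * fv) * fw;
    double dv = ((c10 - c00) * (1 - fw) + (c11 - c01) * fw);
    double dw = (c1 - c0);
    grad[0] = du / dx;
    grad[1] = dv / dy;
    grad[2] = dw / dz;
  }
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericMatrix pts, NumericVector arr,
                            IntegerVector dim, NumericVector voxel) {
  int n = pts.nrow();
  NumericVector out(n);
  double val;
  for (int i = 0; i < n; i++) {
    trilinear(REAL(arr), dim[0], dim[1], dim[2], voxel[0], voxel[1], voxel[2],
              pts(i, 0), pts(i, 1), pts(i, 2), &val, NULL);
    out[i] = val;
  }
  return out;
}

struct MeshCtx {
  const int *off;   // CSR offsets, length n+1 (0-based)
  const int *idx;   // CSR neighbor indices (0-based)
  const int *edges; // 2 * ne vertex pairs (0-based), each undirected edge once
  int n, ne;
  const double *img;
  int nx, ny, nz;
  double dx, dy, dz;
  double lb, li;
};

// Total energy E = lb * E_bend + li * E_img and (optionally) its gradient.
// E_bend = sum_v ||v - mean(nbrs)||^2 / h^2, h = mean edge length.
// E_img  = -(1/n) * sum_v I(v), I trilinearly interpolated (0 outside).
// The gradient includes the dependence of h on the vertices: without it the
// bending gradient carries a spurious net inward radial component (E_bend
// itself is scale-invariant, its fixed-h part is not) that slowly shrinks
// the mesh off the membrane.
static double energy_grad(const MeshCtx &c, const double *V, double *G) {
  int n = c.n;
  // mean edge length
  double hsum = 0.0;
  for (int e = 0; e < c.ne; e++) {
    int a = c.edges[2 * e], b = c.edges[2 * e + 1];
    double ex = V[a] - V[b], ey = V[a + n] - V[b + n],
           ez = V[a + 2 * n] - V[b + 2 * n];
    hsum += std::sqrt(ex * ex + ey * ey + ez * ez);
  }
  double h = hsum / c.ne;
  double h2 = h * h;

  std::vector<double> U(3 * (size_t)n); // umbrella vectors v - mean(nbrs)
  double Ebend = 0.0;
  for (int i = 0; i < n; i++) {
    double mx = 0, my = 0, mz = 0;
    int deg = c.off[i + 1] - c.off[i];
    for (int t = c.off[i]; t < c.off[i + 1]; t++) {
      int j = c.idx[t];
      mx += V[j]; my += V[j + n]; mz += V[j + 2 * n];
    }
    double ux = V[i] - mx / deg, uy = V[i + n] - my / deg,
           uz = V[i + 2 * n] - mz / deg;
    U[i] = ux; U[i + n] = uy; U[i + 2 * n] = uz;
    Ebend += ux * ux + uy * uy + uz * uz;
  }
  Ebend /= h2;

  double Eimg = 0.0;
  double val, gr[3];
  if (G) std::fill(G, G + 3 * (size_t)n, 0.0);
  for (int i = 0; i < n; i++) {
    trilinear(c.img, c.nx, c.ny, c.nz, c.dx, c.dy, c.dz,
              V[i], V[i + n], V[i + 2 * n], &val, G ? gr : NULL);
    Eimg -= val;
    if (G) {
      G[i]         -= c.li * gr[0] / n;
      G[i + n]     -= c.li * gr[1] / n;
      G[i + 2 * n] -= c.li * gr[2] / n;
    }
  }
  Eimg /= n;

  if (G) {
    // d(S/h^2)/dh = -2 S / h^3, dh/dv_a = unit(v_a - v_b) / ne per edge
    double dEdh = -2.0 * Ebend / h; // Ebend already = S/h^2
    for (int e = 0; e < c.ne; e++) {
      int a = c.edges[2 * e], b = c.edges[2 * e + 1];
      double ex = V[a] - V[b], ey = V[a + n] - V[b + n],
             ez = V[a + 2 * n] - V[b + 2 * n];
      double len = std::sqrt(ex * ex + ey * ey + ez * ez);
      if (len < 1e-300) continue;
      double s = c.lb * dEdh / (c.ne * len);
      G[a]         += s * ex; G[b]         -= s * ex;
      G[a + n]     += s * ey; G[b + n]     -= s * ey;
      G[a + 2 * n] += s * ez; G[b + 2 * n] -= s * ez;
    }
    // grad of E_bend: 2/h^2 * (I - A)^T U, A row-stochastic adjacency average
    for (int i = 0; i < n; i++) {
      G[i]         += c.lb * 2.0 / h2 * U[i];
      G[i + n]     += c.lb * 2.0 / h2 * U[i + n];
      G[i + 2 * n] += c.lb * 2.0 / h2 * U[i + 2 * n];
    }
    for (int i = 0; i < n; i++) {
      int deg = c.off[i + 1] - c.off[i];
      double sx = 2.0 / h2 * U[i] / deg, sy = 2.0 / h2 * U[i + n] / deg,
             sz = 2.0 / h2 * U[i + 2 * n] / deg;
      for (int t = c.off[i]; t < c.off[i + 1]; t++) {
        int j = c.idx[t];
        G[j]         -= c.lb * sx;
        G[j + n]     -= c.lb * sy;
        G[j + 2 * n] -= c.lb * sz;
      }
    }
  }
  return c.lb * Ebend + c.li * Eimg;
}

static MeshCtx make_ctx(IntegerVector off, IntegerVector idx,
                        IntegerMatrix edges, int n, NumericVector img,
                        IntegerVector dim, NumericVector voxel,
                        double lb, double li,
                        std::vector<int> &ebuf) {
  MeshCtx c;
  c.off = INTEGER(off);
  c.idx = INTEGER(idx);
  c.n = n;
  c.ne = edges.nrow();
  ebuf.resize(2 * (size_t)c.ne);
  for (int e = 0; e < c.ne; e++) {
    ebuf[2 * e] = edges(e, 0);
    ebuf[2 * e + 1] = edges(e, 1);
  }
  c.edges = ebuf.data();
  c.img = REAL(img);
  c.nx = dim[0]; c.ny = dim[1]; c.nz = dim[2];
  c.dx = voxel[0]; c.dy = voxel[1]; c.dz = voxel[2];
  c.lb = lb; c.li = li;
  return c;
}

// [[Rcpp::export]]
double cpp_mesh_energy(NumericMatrix verts, IntegerVector off, IntegerVector idx,
                       IntegerMatrix edges, NumericVector img, IntegerVector dim,
                       NumericVector voxel, double lambda_bend, double lambda_image) {
  std::vector<int> ebuf;
  MeshCtx c = make_ctx(off, idx, edges, verts.nrow(), img, dim, voxel,
                       lambda_bend, lambda_image, ebuf);
  return energy_grad(c, REAL(verts), NULL);
}

// Gradient descent with backtracking line search; deterministic.
// step_size (um) sets the initial largest per-vertex displacement.
// [[Rcpp::export]]
List cpp_mesh_descend(NumericMatrix verts, IntegerVector off, IntegerVector idx,
                      IntegerMatrix edges, NumericVector img, IntegerVector dim,
                      NumericVector voxel, double lambda_bend, double lambda_image,
                      double step_size, int max_iterations, double tol) {
  int n = verts.nrow();
  std::vector<int> ebuf;
  MeshCtx c = make_ctx(off, idx, edges, n, img, dim, voxel,
                       lambda_bend, lambda_image, ebuf);
  std::vector<double> V(REAL(verts), REAL(verts) + 3 * (size_t)n);
  std::vector<double> G(3 * (size_t)n), Vtry(3 * (size_t)n);
  std::vector<double> path;

  double E = energy_grad(c, V.data(), G.data());
  path.push_back(E);

  // scale the first step so the fastest vertex moves step_size um
  double gmax = 0.0;
  for (int i = 0; i < n; i++) {
    double g = std::sqrt(G[i] * G[i] + G[i + n] * G[i + n] +
                         G[i + 2 * n] * G[i + 2 * n]);
    gmax = std::max(gmax, g);
  }
  if (gmax == 0.0)
    return List::create(_["vertices"] = verts, _["energy"] = E,
                        _["iterations"] = 0, _["converged"] = true,
                        _["energy_path"] = NumericVector(path.begin(), path.end()));
  double alpha = step_size / gmax;
  double alpha_max = alpha * 64.0;

  // Gradient descent with heavy-ball momentum; a trial step is accepted only
  // if the exact energy does not increase, otherwise momentum is reset and
  // the step halved, so the accepted energy path is non-increasing. Momentum
  // accelerates the shallow tangential relaxation of the umbrella term,
  // whose plain-descent relaxation time scales as (mesh diameter / h)^2.
  const double beta = 0.9;
  std::vector<double> W(3 * (size_t)n, 0.0); // velocity
  std::vector<double> Gtry(3 * (size_t)n);
  bool converged = false;
  int it = 0;
  for (it = 1; it <= max_iterations; it++) {
    bool accepted = false;
    bool backtracked = false;
    bool grad_fresh = false;
    double Enew = E;
    for (int bt = 0; bt < 40; bt++) {
      for (size_t q = 0; q < V.size(); q++)
        Vtry[q] = V[q] - alpha * G[q] + beta * W[q];
      // the first trial is usually accepted: evaluate its gradient alongside
      // the energy; later (backtracked) trials skip the gradient work
      grad_fresh = (bt == 0);
      Enew = energy_grad(c, Vtry.data(), grad_fresh ? Gtry.data() : NULL);
      if (Enew <= E) { accepted = true; break; }
      std::fill(W.begin(), W.end(), 0.0); // restart momentum
      alpha *= 0.5;
      backtracked = true;
    }
    if (!accepted) { converged = true; break; } // no descent step exists
    double rel = std::fabs(E - Enew) / (std::fabs(E) + 1e-300);
    for (size_t q = 0; q < V.size(); q++) W[q] = Vtry[q] - V[q];
    V.swap(Vtry);
    if (!grad_fresh) energy_grad(c, V.data(), Gtry.data());
    G.swap(Gtry);
    E = Enew;
    path.push_back(E);
    // a restart step is small by construction; only a full-speed step with a
    // sub-tol decrease signals a stationary point
    if (rel < tol && !backtracked) { converged = true; break; }
    alpha = std::min(alpha * 1.1, alpha_max);
  }

  NumericMatrix out(n, 3);
  for (int i = 0; i < n; i++) {
    out(i, 0) = V[i]; out(i, 1) = V[i + n]; out(i, 2) = V[i + 2 * n];
  }
  return List::create(_["vertices"] = out, _["energy"] = E,
                      _["iterations"] = it, _["converged"] = converged,
                      _["energy_path"] = NumericVector(path.begin(), path.end()));
}

// --- exact point-to-triangle distance (Ericson, Real-Time Collision
// Detection, ch. 5): handles vertex / edge / face regions. ---
static double pt_tri_dist2(const double p[3], const double a[3],
                           const double b[3], const double cc[3]) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; i++) {
    ab[i] = b[i] - a[i]; ac[i] = cc[i] - a[i]; ap[i] = p[i] - a[i];
  }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  auto dist2 = [&](const double q[3]) {
    double dx = p[0]-q[0], dy = p[1]-q[1], dz = p[2]-q[2];
    return dx*dx+dy*dy+dz*dz;
  };
  if (d1 <= 0 && d2 <= 0) return dist2(a);
  double bp[3] = {p[0]-b[0], p[1]-b[1], p[2]-b[2]};
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) return dist2(b);
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    double q[3] = {a[0]+v*ab[0], a[1]+v*ab[1], a[2]+v*ab[2]};
    return dist2(q);
  }
  double cp[3] = {p[0]-cc[0], p[1]-cc[1], p[2]-cc[2]};
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) return dist2(cc);
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    double q[3] = {a[0]+w*ac[0], a[1]+w*ac[1], a[2]+w*ac[2]};
    return dist2(q);
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    double q[3] = {b[0]+w*(cc[0]-b[0]), b[1]+w*(cc[1]-b[1]), b[2]+w*(cc[2]-b[2])};
    return dist2(q);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  double q[3] = {a[0]+ab[0]*v+ac[0]*w, a[1]+ab[1]*v+ac[1]*w, a[2]+ab[2]*v+ac[2]*w};
  return dist2(q);
}

// [[Rcpp::export]]
NumericVector cpp_point_mesh_distance(NumericMatrix pts, NumericMatrix verts,
                                      IntegerMatrix faces) {
  int np = pts.nrow(), nf = faces.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; i++) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double best = R_PosInf;
    for (int f = 0; f < nf; f++) {
      int ia = faces(f, 0), ib = faces(f, 1), ic = faces(f, 2);
      double a[3] = {verts(ia,0), verts(ia,1), verts(ia,2)};
      double b[3] = {verts(ib,0), verts(ib,1), verts(ib,2)};
      double cc[3] = {verts(ic,0), verts(ic,1), verts(ic,2)};
      double d2 = pt_tri_dist2(p, a, b, cc);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Generalized winding number via the van Oosterom--Strackee signed solid
// angle; ~4*pi for interior points of a closed outward-oriented mesh.
// [[Rcpp::export]]
NumericVector cpp_winding_number(NumericMatrix pts, NumericMatrix verts,
                                 IntegerMatrix faces) {
  int np = pts.nrow(), nf = faces.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; i++) {
    double px = pts(i,0), py = pts(i,1), pz = pts(i,2);
    double omega = 0.0;
    for (int f = 0; f < nf; f++) {
      int ia = faces(f,0), ib = faces(f,1), ic = faces(f,2);
      double ax = verts(ia,0)-px, ay = verts(ia,1)-py, az = verts(ia,2)-pz;
      double bx = verts(ib,0)-px, by = verts(ib,1)-py, bz = verts(ib,2)-pz;
      double cx = verts(ic,0)-px, cy = verts(ic,1)-py, cz = verts(ic,2)-pz;
      double la = std::sqrt(ax*ax+ay*ay+az*az);
      double lb = std::sqrt(bx*bx+by*by+bz*bz);
      double lc = std::sqrt(cx*cx+cy*cy+cz*cz);
      double det = ax*(by*cz-bz*cy) - ay*(bx*cz-bz*cx) + az*(bx*cy-by*cx);
      double den = la*lb*lc + (ax*bx+ay*by+az*bz)*lc +
                   (ax*cx+ay*cy+az*cz)*lb + (bx*cx+by*cy+bz*cz)*la;
      omega += 2.0 * std::atan2(det, den);
    }
    out[i] = omega / (4.0 * M_PI);
  }
  return out;
}

// segment-triangle intersection (Moller-Trumbore restricted to t in [0,1])
static bool seg_tri_intersect(const double p[3], const double q[3],
                              const double a[3], const double b[3],
                              const double c[3]) {
  const double EPS = 1e-12;
  double dir[3] = {q[0]-p[0], q[1]-p[1], q[2]-p[2]};
  double e1[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
  double e2[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
  double h[3] = {dir[1]*e2[2]-dir[2]*e2[1], dir[2]*e2[0]-dir[0]*e2[2],
                 dir[0]*e2[1]-dir[1]*e2[0]};
  double det = e1[0]*h[0]+e1[1]*h[1]+e1[2]*h[2];
  if (std::fabs(det) < EPS) return false;
  double inv = 1.0/det;
  double s[3] = {p[0]-a[0], p[1]-a[1], p[2]-a[2]};
  double u = (s[0]*h[0]+s[1]*h[1]+s[2]*h[2]) * inv;
  if (u < 0 || u > 1) return false;
  double qv[3] = {s[1]*e1[2]-s[2]*e1[1], s[2]*e1[0]-s[0]*e1[2],
                  s[0]*e1[1]-s[1]*e1[0]};
  double v = (dir[0]*qv[0]+dir[1]*qv[1]+dir[2]*qv[2]) * inv;
  if (v < 0 || u + v > 1) return false;
  double t = (e2[0]*qv[0]+e2[1]*qv[1]+e2[2]*qv[2]) * inv;
  return t > EPS && t < 1 - EPS;
}

// Self-intersection check: any edge of a face crossing a non-adjacent face.
// Axis-aligned bounding boxes prefilter the face pairs.
// [[Rcpp::export]]
bool cpp_mesh_self_intersects(NumericMatrix verts, IntegerMatrix faces) {
  int nf = faces.nrow();
  std::vector<double> lo(3 * (size_t)nf), hi(3 * (size_t)nf);
  for (int f = 0; f < nf; f++) {
    for (int d = 0; d < 3; d++) {
      double v0 = verts(faces(f,0), d), v1 = verts(faces(f,1), d),
             v2 = verts(faces(f,2), d);
      lo[3*f+d] = std::min(v0, std::min(v1, v2));
      hi[3*f+d] = std::max(v0, std::max(v1, v2));
    }
  }
  for (int f = 0; f < nf; f++) {
    for (int g = f + 1; g < nf; g++) {
      bool sep = false;
      for (int d = 0; d < 3; d++)
        if (lo[3*f+d] > hi[3*g+d] || lo[3*g+d] > hi[3*f+d]) { sep = true; break; }
      if (sep) continue;
      bool adjacent = false;
      for (int u = 0; u < 3 && !adjacent; u++)
        for (int v = 0; v < 3; v++)
          if (faces(f,u) == faces(g,v)) { adjacent = true; break; }
      if (adjacent) continue;
      double tf[3][3], tg[3][3];
      for (int u = 0; u < 3; u++)
        for (int d = 0; d < 3; d++) {
          tf[u][d] = verts(faces(f,u), d);
          tg[u][d] = verts(faces(g,u), d);
        }
      for (int u = 0; u < 3; u++) {
        if (seg_tri_intersect(tf[u], tf[(u+1)%3], tg[0], tg[1], tg[2])) return true;
        if (seg_tri_intersect(tg[u], tg[(u+1)%3], tf[0], tf[1], tf[2])) return true;
      }
    }
  }
  return false;
}
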