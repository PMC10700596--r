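#include <Rcpp.h>
using namespace Rcpp;

// Successive over-relaxation for the variable-dielectric Poisson equation
// div(eps grad phi) = -4*pi*k*rho on a regular node lattice.
//
// Discretisation (DelPhi-style, node centred): for an interior node c,
//   sum_f eps_f (phi_nb - phi_c) = -4*pi*k*q_c / h
// with face dielectric eps_f the arithmetic mean of the node values and q_c
// the point charge (e) spread onto node c. Boundary nodes are Dirichlet and
// never updated. k is the electrostatic conversion constant so that phi is
// in kcal/(mol e) when q is in e and h in Angstrom.
//
// [[Rcpp::export]]
List poisson_sor_cpp(NumericVector eps, NumericVector q, NumericVector phi0,
                     IntegerVector dims, double h, double fourpik,
                     double tol, int maxiter, double omega) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (eps.size() != n || q.size() != n || phi0.size() != n)
    stop("field size mismatch");
  NumericVector phi = clone(phi0);
  const double *e = eps.begin();
  const double *qq = q.begin();
  double *p = phi.begin();

  // source norm for the relative residual; fall back to 1 for zero charge
  double qnorm = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) qnorm += std::fabs(qq[i]);
  double src_scale = fourpik * qnorm / h;
  if (src_scale <= 0.0) src_scale = 1.0;

  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  double resid = R_PosInf;
  int it = 0;
  for (it = 1; it <= maxiter; ++it) {
    // red-black Gauss-Seidel sweep with over-relaxation
    for (int colour = 0; colour < 2; ++colour) {
      for (int k = 1; k < nz - 1; ++k)
        for (int j = 1; j < ny - 1; ++j)
          for (int i = 1; i < nx - 1; ++i) {
            if (((i + j + k) & 1) != colour) continue;
            R_xlen_t c = i * sx + (R_xlen_t)j * sy + (R_xlen_t)k * sz;
            double ec = e[c];
            double exm = 0.5 * (ec + e[c - sx]), exp_ = 0.5 * (ec + e[c + sx]);
            double eym = 0.5 * (ec + e[c - sy]), eyp = 0.5 * (ec + e[c + sy]);
            double ezm = 0.5 * (ec + e[c - sz]), ezp = 0.5 * (ec + e[c + sz]);
            double esum = exm + exp_ + eym + eyp + ezm + ezp;
            double num = exm * p[c - sx] + exp_ * p[c + sx] +
                         eym * p[c - sy] + eyp * p[c + sy] +
                         ezm * p[c - sz] + ezp * p[c + sz] +
                         fourpik * qq[c] / h;
            double gs = num / esum;
            p[c] += omega * (gs - p[c]);
          }
    }
    // residual every few sweeps (it is O(n) like a sweep)
    if (it % 5 == 0 || it == maxiter) {
      double rsum = 0.0;
      for (int k = 1; k < nz - 1; ++k)
        for (int j = 1; j < ny - 1; ++j)
          for (int i = 1; i < nx - 1; ++i) {
            R_xlen_t c = i * sx + (R_xlen_t)j * sy + (R_xlen_t)k * sz;
            double ec = e[c];
            double exm = 0.5 * (ec + e[c - sx]), exp_ = 0.5 * (ec + e[c + sx]);
            double eym = 0.5 * (ec + e[c - sy]), eyp = 0.5 * (ec + e[c + sy]);
            double ezm = 0.5 * (ec + e[c - sz]), ezp = 0.5 * (ec + e[c + sz]);
            double r = exm * (p[c - sx] - p[c]) + exp_ * (p[c + sx] - p[c]) +
                       eym * (p[c - sy] - p[c]) + eyp * (p[c + sy] - p[c]) +
                       ezm * (p[c - sz] - p[c]) + ezp * (p[c + sz] - p[c]) +
                       fourpik * qq[c] / h;
            rsum += std::fabs(r);
          }
      resid = rsum / src_scale;
      if (resid < tol) break;
    }
  }
  phi.attr("dim") = dims;
  return List::create(_["phi"] = phi, _["residual"] = resid,
                      _["iterations"] = std::min(it, maxiter));
}

// Occlusion grid: for every lattice node, the fraction of ball sample
// points (offsets, m x 3) that fall inside any inflated sphere. Atoms are
// culled per node by a bounding-distance test before the sample loop.
//
// [[Rcpp::export]]
NumericVector occlusion_grid_cpp(NumericVector origin, double h,
                                 IntegerVector dims, NumericMatrix ball,
                                 NumericMatrix pts, NumericVector radii) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int na = pts.nrow(), m = ball.nrow();
  NumericVector occ(n, 0.0);
  if (na == 0 || m == 0) { occ.attr("dim") = dims; return occ; }
  double ball_r = 0.0;
  for (int s = 0; s < m; ++s) {
    double r2 = ball(s, 0) * ball(s, 0) + ball(s, 1) * ball(s, 1) +
                ball(s, 2) * ball(s, 2);
    if (r2 > ball_r) ball_r = r2;
  }
  ball_r = std::sqrt(ball_r);
  std::vector<int> cand(na);
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    double gz = origin[2] + k * h;
    for (int j = 0; j < ny; ++j) {
      double gy = origin[1] + j * h;
      for (int i = 0; i < nx; ++i, ++idx) {
        double gx = origin[0] + i * h;
        int nc = 0;
        for (int a = 0; a < na; ++a) {
          double dx = pts(a, 0) - gx, dy = pts(a, 1) - gy,
                 dz = pts(a, 2) - gz;
          double lim = radii[a] + ball_r;
          if (dx * dx + dy * dy + dz * dz <= lim * lim) cand[nc++] = a;
        }
        if (nc == 0) continue;
        int hit = 0;
        for (int s = 0; s < m; ++s) {
          double sx = gx + ball(s, 0), sy = gy + ball(s, 1),
                 sz = gz + ball(s, 2);
          for (int c = 0; c < nc; ++c) {
            int a = cand[c];
            double dx = pts(a, 0) - sx, dy = pts(a, 1) - sy,
                   dz = pts(a, 2) - sz;
            if (dx * dx + dy * dy + dz * dz <= radii[a] * radii[a]) {
              ++hit;
              break;
            }
          }
        }
        occ[idx] = (double)hit / m;
      }
    }
  }
  occ.attr("dim") = dims;
  return occ;
}

// Minimum distance from each lattice node to any of a set of points, capped:
// returns for every node whether it lies within (radius_i + extension) of any
// point i. Used by the dielectric and desolvation volume builders.
//
// [[Rcpp::export]]
LogicalVector lattice_inside_cpp(NumericVector origin, double h,
                                 IntegerVector dims, NumericMatrix pts,
                                 NumericVector radii, double extension) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector inside(n, false);
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  for (int a = 0; a < pts.nrow(); ++a) {
    double r = radii[a] + extension;
    double r2 = r * r;
    double px = pts(a, 0), py = pts(a, 1), pz = pts(a, 2);
    int i0 = (int)std::ceil((px - r - origin[0]) / h);
    int i1 = (int)std::floor((px + r - origin[0]) / h);
    int j0 = (int)std::ceil((py - r - origin[1]) / h);
    int j1 = (int)std::floor((py + r - origin[1]) / h);
    int k0 = (int)std::ceil((pz - r - origin[2]) / h);
    int k1 = (int)std::floor((pz + r - origin[2]) / h);
    if (i0 < 0) i0 = 0;
    if (i1 > nx - 1) i1 = nx - 1;
    if (j0 < 0) j0 = 0;
    if (j1 > ny - 1) j1 = ny - 1;
    if (k0 < 0) k0 = 0;
    if (k1 > nz - 1) k1 = nz - 1;
    for (int k = k0; k <= k1; ++k) {
      double dz = origin[2] + k * h - pz;
      for (int j = j0; j <= j1; ++j) {
        double dy = origin[1] + j * h - py;
        double dyz = dy * dy + dz * dz;
        if (dyz > r2) continue;
        for (int i = i0; i <= i1; ++i) {
          double dx = origin[0] + i * h - px;
          if (dx * dx + dyz <= r2)
            inside[i + (R_xlen_t)j * sy + (R_xlen_t)k * sz] = true;
        }
      }
    }
  }
  inside.attr("dim") = dims;
  return inside;
}
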