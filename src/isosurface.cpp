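// Smooth-union molecular envelope: Gaussian density on a regular grid and
// marching-tetrahedra isosurface extraction.
//
// Density: F(x) = sum_i exp(-(||x - x_i||^2 - R_i^2) / (2 sigma^2)), so a
// single atom gives F = 1 exactly at distance R_i; the iso = 1 level set is a
// smooth union of the inflated atom spheres.
//
// Each grid cube is split into six tetrahedra sharing the 0-7 main diagonal;
// crossing vertices are welded on global grid edges, so the result is a
// closed edge-manifold mesh for well-resolved fields. Triangles are oriented
// with normals pointing down-gradient (outward for a density field).

#include <RcppArmadillo.h>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
arma::vec gaussian_density_grid_cpp(const arma::mat& atoms, const arma::vec& radii,
                                    const double sigma, const arma::vec& origin,
                                    const double spacing, const arma::ivec& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  arma::vec field(static_cast<size_t>(nx) * ny * nz, arma::fill::zeros);
  const double s2 = 2.0 * sigma * sigma;
  // exponent cutoff: contributions below exp(-30) are dropped
  for (arma::uword a = 0; a < atoms.n_rows; ++a) {
    const double R2 = radii[a] * radii[a];
    const double dmax = std::sqrt(R2 + 30.0 * s2);
    const double ax = atoms(a, 0), ay = atoms(a, 1), az = atoms(a, 2);
    int i0 = std::max(0, (int)std::floor((ax - dmax - origin[0]) / spacing));
    int i1 = std::min(nx - 1, (int)std::ceil((ax + dmax - origin[0]) / spacing));
    int j0 = std::max(0, (int)std::floor((ay - dmax - origin[1]) / spacing));
    int j1 = std::min(ny - 1, (int)std::ceil((ay + dmax - origin[1]) / spacing));
    int k0 = std::max(0, (int)std::floor((az - dmax - origin[2]) / spacing));
    int k1 = std::min(nz - 1, (int)std::ceil((az + dmax - origin[2]) / spacing));
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + k * spacing - az;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + j * spacing - ay;
        const double dyz = dy * dy + dz * dz;
        const size_t base = (size_t)nx * (j + (size_t)ny * k);
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + i * spacing - ax;
          const double ex = (dx * dx + dyz - R2) / s2;
          if (ex < 30.0) field[base + i] += std::exp(-ex);
        }
      }
    }
  }
  return field;
}

struct EdgeHash {
  size_t operator()(const std::pair<size_t, size_t>& p) const {
    return std::hash<size_t>()(p.first * 1000003u ^ p.second);
  }
};

// [[Rcpp::export]]
List marching_tetrahedra_cpp(const arma::vec& field, const arma::ivec& dims,
                             const arma::vec& origin, const double spacing,
                             const double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto gid = [&](int i, int j, int k) -> size_t {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
  };
  // perturb exact hits so every tetra case is generic
  auto fval = [&](size_t g) {
    double f = field[g] - iso;
    return f == 0.0 ? 1e-12 : f;
  };

  std::vector<double> VX, VY, VZ;
  std::vector<int> TI;
  std::unordered_map<std::pair<size_t, size_t>, int, EdgeHash> edge_vertex;

  auto edge_point = [&](size_t ga, size_t gb) -> int {
    if (ga > gb) std::swap(ga, gb);
    auto key = std::make_pair(ga, gb);
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    const double fa = fval(ga), fb = fval(gb);
    double t = fa / (fa - fb);
    if (t < 1e-6) t = 1e-6;
    if (t > 1.0 - 1e-6) t = 1.0 - 1e-6;
    const int ia = ga % nx, ja = (ga / nx) % ny, ka = ga / ((size_t)nx * ny);
    const int ib = gb % nx, jb = (gb / nx) % ny, kb = gb / ((size_t)nx * ny);
    VX.push_back(origin[0] + spacing * (ia + t * (ib - ia)));
    VY.push_back(origin[1] + spacing * (ja + t * (jb - ja)));
    VZ.push_back(origin[2] + spacing * (ka + t * (kb - ka)));
    const int id = (int)VX.size() - 1;
    edge_vertex[key] = id;
    return id;
  };

  // six tetrahedra per cube, all containing the 0-7 diagonal
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
    {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        size_t corner[8];
        for (int c = 0; c < 8; ++c)
          corner[c] = gid(i + (c & 1), j + ((c >> 1) & 1), k + ((c >> 2) & 1));
        for (int t = 0; t < 6; ++t) {
          size_t g[4];
          double f[4];
          int inside = 0, nin = 0;
          for (int m = 0; m < 4; ++m) {
            g[m] = corner[tets[t][m]];
            f[m] = fval(g[m]);
            if (f[m] > 0.0) { inside |= (1 << m); ++nin; }
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            // single vertex on one side: one triangle
            int lone = -1;
            for (int m = 0; m < 4; ++m) {
              const bool in = (inside >> m) & 1;
              if ((nin == 1 && in) || (nin == 3 && !in)) lone = m;
            }
            int o[3], p = 0;
            for (int m = 0; m < 4; ++m) if (m != lone) o[p++] = m;
            const int a = edge_point(g[lone], g[o[0]]);
            const int b = edge_point(g[lone], g[o[1]]);
            const int c = edge_point(g[lone], g[o[2]]);
            TI.push_back(a); TI.push_back(b); TI.push_back(c);
          } else {
            // two-two split: quad cut across four edges
            int in[2], out[2], pi = 0, po = 0;
            for (int m = 0; m < 4; ++m) {
              if ((inside >> m) & 1) in[pi++] = m; else out[po++] = m;
            }
            const int a = edge_point(g[in[0]], g[out[0]]);
            const int b = edge_point(g[in[0]], g[out[1]]);
            const int c = edge_point(g[in[1]], g[out[1]]);
            const int d = edge_point(g[in[1]], g[out[0]]);
            TI.push_back(a); TI.push_back(b); TI.push_back(c);
            TI.push_back(a); TI.push_back(c); TI.push_back(d);
          }
        }
      }

  const int nv = VX.size();
  const int nf = TI.size() / 3;
  arma::mat Vm(nv, 3);
  for (int v = 0; v < nv; ++v) { Vm(v, 0) = VX[v]; Vm(v, 1) = VY[v]; Vm(v, 2) = VZ[v]; }
  arma::imat Fm(nf, 3);
  for (int f = 0; f < nf; ++f) {
    Fm(f, 0) = TI[3 * f]; Fm(f, 1) = TI[3 * f + 1]; Fm(f, 2) = TI[3 * f + 2];
  }

  // orient each face down-gradient (outward): central differences at the
  // grid point nearest the face centroid
  auto grad_at = [&](double x, double y, double z, double* gr) {
    int ii = std::min(nx - 2, std::max(1, (int)std::lround((x - origin[0]) / spacing)));
    int jj = std::min(ny - 2, std::max(1, (int)std::lround((y - origin[1]) / spacing)));
    int kk = std::min(nz - 2, std::max(1, (int)std::lround((z - origin[2]) / spacing)));
    gr[0] = field[gid(ii + 1, jj, kk)] - field[gid(ii - 1, jj, kk)];
    gr[1] = field[gid(ii, jj + 1, kk)] - field[gid(ii, jj - 1, kk)];
    gr[2] = field[gid(ii, jj, kk + 1)] - field[gid(ii, jj, kk - 1)];
  };
  for (int f = 0; f < nf; ++f) {
    const arma::rowvec a = Vm.row(Fm(f, 0)), b = Vm.row(Fm(f, 1)), c = Vm.row(Fm(f, 2));
    const arma::rowvec n = arma::cross(b - a, c - a);
    double gr[3];
    const arma::rowvec cen = (a + b + c) / 3.0;
    grad_at(cen[0], cen[1], cen[2], gr);
    if (n[0] * gr[0] + n[1] * gr[1] + n[2] * gr[2] > 0.0) {
      const int tmp = Fm(f, 1); Fm(f, 1) = Fm(f, 2); Fm(f, 2) = tmp;
    }
  }

  return List::create(_["vertices"] = Vm, _["faces"] = Fm);
}
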