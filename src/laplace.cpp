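#include <Rcpp.h>
using namespace Rcpp;

// Red-black successive over-relaxation for the discrete Laplace equation
// on a uniform grid (homogeneous conductivity: del.(sigma grad V) = 0
// reduces to del^2 V = 0). Dirichlet nodes are frozen; all other boundary
// nodes get zero-normal-derivative (mirror) closure. v is stored x-fastest:
// idx = i + nx*(j + ny*k).

static inline double neighbor_avg(const double* v, int i, int j, int k,
                                  int nx, int ny, int nz) {
  const int im = (i > 0) ? i - 1 : i + 1;
  const int ip = (i < nx - 1) ? i + 1 : i - 1;
  const int jm = (j > 0) ? j - 1 : j + 1;
  const int jp = (j < ny - 1) ? j + 1 : j - 1;
  const int km = (k > 0) ? k - 1 : k + 1;
  const int kp = (k < nz - 1) ? k + 1 : k - 1;
  const double s =
    v[im + nx * (j + ny * k)] + v[ip + nx * (j + ny * k)] +
    v[i + nx * (jm + ny * k)] + v[i + nx * (jp + ny * k)] +
    v[i + nx * (j + ny * km)] + v[i + nx * (j + ny * kp)];
  return s / 6.0;
}

// [[Rcpp::export(rng = false)]]
List sor_laplace(NumericVector v0, LogicalVector dirichlet,
                 int nx, int ny, int nz,
                 double omega, double tol, int max_iter) {
  NumericVector v = clone(v0);
  double* pv = v.begin();
  const int* pd = dirichlet.begin();

  double scale = 0.0;
  for (int n = 0; n < v.size(); ++n)
    if (pd[n] && std::abs(pv[n]) > scale) scale = std::abs(pv[n]);
  if (scale == 0.0) scale = 1.0;

  int iter = 0;
  double max_delta = 0.0;
  bool converged = false;
  for (iter = 1; iter <= max_iter; ++iter) {
    max_delta = 0.0;
    for (int color = 0; color < 2; ++color) {
      for (int k = 0; k < nz; ++k) {
        for (int j = 0; j < ny; ++j) {
          for (int i = 0; i < nx; ++i) {
            if (((i + j + k) & 1) != color) continue;
            const int n = i + nx * (j + ny * k);
            if (pd[n]) continue;
            const double target = neighbor_avg(pv, i, j, k, nx, ny, nz);
            const double delta = omega * (target - pv[n]);
            pv[n] += delta;
            const double ad = std::abs(delta);
            if (ad > max_delta) max_delta = ad;
          }
        }
      }
    }
    if (max_delta / scale < tol) { converged = true; break; }
  }

  // residual of the plain (unrelaxed) discrete Laplacian at free nodes
  double resid = 0.0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int n = i + nx * (j + ny * k);
        if (pd[n]) continue;
        const double r = std::abs(neighbor_avg(pv, i, j, k, nx, ny, nz) - pv[n]);
        if (r > resid) resid = r;
      }

  return List::create(_["v"] = v, _["iterations"] = iter,
                      _["converged"] = converged,
                      _["max_delta"] = max_delta,
                      _["residual"] = resid / scale);
}
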