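// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// |x|^k matrix with the convention 0^0 = 1 (columns indexed by k).
static arma::mat abs_pow_matrix(const arma::vec& x, const arma::vec& k) {
  const arma::uword n = x.n_elem, m = k.n_elem;
  arma::vec lx(n);
  for (arma::uword i = 0; i < n; ++i) {
    double a = std::fabs(x[i]);
    lx[i] = (a > 0.0) ? std::log(a) : -std::numeric_limits<double>::infinity();
  }
  arma::mat out(n, m);
  for (arma::uword j = 0; j < m; ++j) {
    if (k[j] == 0.0) {
      out.col(j).ones();
    } else {
      for (arma::uword i = 0; i < n; ++i) {
        double e = k[j] * lx[i];
        out(i, j) = std::isinf(e) ? 0.0 : std::exp(e);
      }
    }
  }
  return out;
}

// Antisymmetric map C[k,l] = mean_i (x_i^k y_i^l - x_i^l y_i^k) with the
// principal-branch convention x^k = |x|^k exp(i*pi*k) for x < 0.
// Samples are partitioned by the sign pattern of (x, y); within each group
// the phase factor exp(i*pi*(k*a + l*b)) is constant, so each group reduces
// to a real crossproduct of |x|^k and |y|^l power matrices (BLAS dgemm).
// [[Rcpp::export(name = ".cumulant_map_cpp")]]
List cumulant_map_cpp(const arma::vec& x, const arma::vec& y,
                      const arma::vec& k) {
  if (x.n_elem != y.n_elem) stop("x and y must have equal length");
  const arma::uword n = x.n_elem, m = k.n_elem;
  arma::mat U = abs_pow_matrix(x, k);
  arma::mat V = abs_pow_matrix(y, k);

  arma::uvec xneg = arma::conv_to<arma::uvec>::from(x < 0.0);
  arma::uvec yneg = arma::conv_to<arma::uvec>::from(y < 0.0);

  arma::cx_vec d(m);  // exp(i*pi*k)
  for (arma::uword j = 0; j < m; ++j)
    d[j] = std::polar(1.0, M_PI * k[j]);

  arma::cx_mat T(m, m, arma::fill::zeros);
  for (int a = 0; a <= 1; ++a) {
    for (int b = 0; b <= 1; ++b) {
      arma::uvec idx = arma::find(xneg == (arma::uword)a &&
                                  yneg == (arma::uword)b);
      if (idx.n_elem == 0) continue;
      arma::mat G = U.rows(idx).t() * V.rows(idx);
      arma::cx_mat Gc(G, arma::mat(m, m, arma::fill::zeros));
      if (a == 1) Gc.each_col() %= d;          // row phase: exp(i*pi*k)
      if (b == 1) Gc.each_row() %= d.st();     // column phase: exp(i*pi*l)
      T += Gc;
    }
  }
  arma::cx_mat C = (T - T.st()) / (double)n;
  return List::create(_["Cr"] = arma::mat(arma::real(C)),
                      _["Ci"] = arma::mat(arma::imag(C)));
}

// Euler integration of bilinear neuronal dynamics plus the canonical
// Balloon-Windkessel hemodynamic model, one state set per node.
//   zdot = A z + drive(t)
//   sdot = z - kappa s - gamma (f - 1)
//   fdot = s
//   vdot = (f - v^(1/alpha)) / tau
//   qdot = (f E(f,E0)/E0 - v^(1/alpha) q / v) / tau
//   BOLD = V0 (k1 (1-q) + k2 (1 - q/v) + k3 (1 - v)),
//   k1 = 7 E0, k2 = 2, k3 = 2 E0 - 0.2
// drive: (steps x nodes) exogenous input plus neuronal noise.
// [[Rcpp::export(name = ".dcm_integrate_cpp")]]
List dcm_integrate_cpp(const arma::mat& A, const arma::mat& drive, double dt,
                       const arma::vec& kappa, const arma::vec& gam,
                       const arma::vec& tau, const arma::vec& alpha,
                       const arma::vec& e0, const arma::vec& v0) {
  const arma::uword nT = drive.n_rows, n = drive.n_cols;
  if (A.n_rows != n || A.n_cols != n) stop("adjacency does not match drive");
  arma::vec z(n, arma::fill::zeros), s(n, arma::fill::zeros);
  arma::vec f(n, arma::fill::ones), v(n, arma::fill::ones),
            q(n, arma::fill::ones);
  arma::mat bold(nT, n), neuronal(nT, n);
  const double floor_ = 1e-8;

  for (arma::uword t = 0; t < nT; ++t) {
    arma::vec dz = A * z + drive.row(t).t();
    arma::vec ds = z - kappa % s - gam % (f - 1.0);
    arma::vec df = s;
    arma::vec fv(n), dv(n), dq(n);
    for (arma::uword i = 0; i < n; ++i) {
      fv[i] = std::pow(v[i], 1.0 / alpha[i]);
      double E = 1.0 - std::pow(1.0 - e0[i], 1.0 / f[i]);
      dv[i] = (f[i] - fv[i]) / tau[i];
      dq[i] = (f[i] * E / e0[i] - fv[i] * q[i] / v[i]) / tau[i];
    }
    z += dt * dz;
    s += dt * ds;
    f += dt * df;
    v += dt * dv;
    q += dt * dq;
    for (arma::uword i = 0; i < n; ++i) {
      if (f[i] < floor_) f[i] = floor_;
      if (v[i] < floor_) v[i] = floor_;
      if (q[i] < floor_) q[i] = floor_;
      if (!std::isfinite(z[i]) || !std::isfinite(s[i]) ||
          !std::isfinite(v[i]) || !std::isfinite(q[i]))
        stop("simulation diverged (non-finite state) at step %d", (int)(t + 1));
      double k1 = 7.0 * e0[i], k2 = 2.0, k3 = 2.0 * e0[i] - 0.2;
      bold(t, i) = v0[i] * (k1 * (1.0 - q[i]) + k2 * (1.0 - q[i] / v[i]) +
                            k3 * (1.0 - v[i]));
      neuronal(t, i) = z[i];
    }
  }
  return List::create(_["bold"] = bold, _["neuronal"] = neuronal);
}
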