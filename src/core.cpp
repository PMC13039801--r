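// Compiled core: ALF featurization with exact Cartesian Jacobians (B-matrix),
// composite periodic kernel, analytic force assembly, and the MD inner loop.
// All geometry is in Angstrom; model energies in Hartree. Unit conversion
// constants are passed in from R so they are defined in exactly one place.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double FRAME_TOL = 1e-8; // collinearity tolerance (rad) for ALF frames

// skew-symmetric cross-product matrix: skew(a) * b == a x b
static arma::mat33 skew(const arma::vec3 &a) {
  arma::mat33 s(arma::fill::zeros);
  s(0, 1) = -a(2); s(0, 2) = a(1);
  s(1, 0) = a(2);  s(1, 2) = -a(0);
  s(2, 0) = -a(1); s(2, 1) = a(0);
  return s;
}

// Indices of the "other" atoms (not the centre, not the two frame atoms),
// ascending. All indices 0-based here.
static arma::uvec other_atoms(int n, int a, int ax, int ay) {
  arma::uvec out(n - 3);
  int k = 0;
  for (int i = 0; i < n; ++i)
    if (i != a && i != ax && i != ay) out(k++) = i;
  return out;
}

// ALF feature vector of one atom: d1, d2, valence angle, then (r, theta, phi)
// spherical coordinates of every other atom in the right-handed local frame
// (x along centre->x-axis atom, z along u x w, y = z x x).
static arma::vec features_one(const arma::mat &coords, int a, int ax, int ay) {
  const int n = coords.n_rows;
  arma::vec3 pa = coords.row(a).t();
  arma::vec3 u = coords.row(ax).t() - pa;
  arma::vec3 w = coords.row(ay).t() - pa;
  double d1 = arma::norm(u), d2 = arma::norm(w);
  if (d1 <= 0 || d2 <= 0) stop("coincident ALF frame atoms");
  arma::vec3 e1 = u / d1;
  arma::vec3 zv = arma::cross(u, w);
  double nz = arma::norm(zv);
  double cosx = arma::dot(e1, w / d2);
  if (nz / (d1 * d2) < FRAME_TOL || std::abs(cosx) > 1.0 - FRAME_TOL * FRAME_TOL / 2)
    stop("degenerate ALF frame: frame atoms are collinear with the centre");
  arma::vec3 e3 = zv / nz;
  arma::vec3 e2 = arma::cross(e3, e1);

  arma::vec f(3 * n - 6);
  f(0) = d1;
  f(1) = d2;
  f(2) = std::acos(std::max(-1.0, std::min(1.0, cosx)));
  arma::uvec oth = other_atoms(n, a, ax, ay);
  for (arma::uword k = 0; k < oth.n_elem; ++k) {
    arma::vec3 v = coords.row(oth(k)).t() - pa;
    double r = arma::norm(v);
    double a1 = arma::dot(v, e1), a2 = arma::dot(v, e2), a3 = arma::dot(v, e3);
    f(3 + 3 * k) = r;
    f(4 + 3 * k) = std::acos(std::max(-1.0, std::min(1.0, a3 / r)));
    f(5 + 3 * k) = std::atan2(a2, a1);
  }
  return f;
}

// Exact Jacobian of the feature vector w.r.t. all Cartesian coordinates,
// (3N-6) x 3N, column order x1,y1,z1,x2,... (Angstrom denominator).
static arma::mat jacobian_one(const arma::mat &coords, int a, int ax, int ay) {
  const int n = coords.n_rows;
  arma::vec3 pa = coords.row(a).t();
  arma::vec3 u = coords.row(ax).t() - pa;
  arma::vec3 w = coords.row(ay).t() - pa;
  double d1 = arma::norm(u), d2 = arma::norm(w);
  arma::vec3 e1 = u / d1, what = w / d2;
  arma::vec3 zv = arma::cross(u, w);
  double nz = arma::norm(zv);
  if (nz / (d1 * d2) < FRAME_TOL)
    stop("degenerate ALF frame: frame atoms are collinear with the centre");
  arma::vec3 e3 = zv / nz;
  arma::vec3 e2 = arma::cross(e3, e1);

  arma::mat B(3 * n - 6, 3 * n, arma::fill::zeros);
  auto put = [&](int row, int atom, const arma::vec3 &g) {
    B(row, 3 * atom) += g(0);
    B(row, 3 * atom + 1) += g(1);
    B(row, 3 * atom + 2) += g(2);
  };

  // d1 = |u|, u = x_X - x_a
  put(0, ax, e1); put(0, a, -e1);
  // d2 = |w|
  put(1, ay, what); put(1, a, -what);
  // valence angle chi = acos(e1 . what)
  double c = arma::dot(e1, what);
  double s = std::sqrt(std::max(1.0 - c * c, 1e-20));
  arma::vec3 dchi_du = -(what - c * e1) / (s * d1);
  arma::vec3 dchi_dw = -(e1 - c * what) / (s * d2);
  put(2, ax, dchi_du); put(2, ay, dchi_dw); put(2, a, -(dchi_du + dchi_dw));

  // axis Jacobians (3x3, d axis / d u and d axis / d w)
  arma::mat33 I = arma::eye(3, 3);
  arma::mat33 P1 = (I - e1 * e1.t()) / d1;              // de1/du
  arma::mat33 Pz = (I - e3 * e3.t()) / nz;
  arma::mat33 de3_du = -Pz * skew(w);                   // d(u x w)/du = -skew(w)
  arma::mat33 de3_dw = Pz * skew(u);
  arma::mat33 de2_du = -skew(e1) * de3_du + skew(e3) * P1;
  arma::mat33 de2_dw = -skew(e1) * de3_dw;

  arma::uvec oth = other_atoms(n, a, ax, ay);
  for (arma::uword k = 0; k < oth.n_elem; ++k) {
    int nn = oth(k);
    arma::vec3 v = coords.row(nn).t() - pa;
    double r = arma::norm(v);
    double a1 = arma::dot(v, e1), a2 = arma::dot(v, e2), a3 = arma::dot(v, e3);

    // local-coordinate gradients: da_i = e_i . dv + v . (de_i/du) du + v . (de_i/dw) dw
    arma::vec3 da1_dv = e1, da2_dv = e2, da3_dv = e3;
    arma::vec3 da1_du = P1.t() * v;          // v^T (de1/du) as a column vector
    arma::vec3 da2_du = de2_du.t() * v;
    arma::vec3 da2_dw = de2_dw.t() * v;
    arma::vec3 da3_du = de3_du.t() * v;
    arma::vec3 da3_dw = de3_dw.t() * v;

    // r
    arma::vec3 dr_dv = v / r;
    int row = 3 + 3 * k;
    put(row, nn, dr_dv); put(row, a, -dr_dv);

    // theta = acos(a3 / r)
    double q = a3 / r;
    double sq = std::sqrt(std::max(1.0 - q * q, 1e-20));
    // dtheta = -(da3 - q dr)/ (r * sq)
    arma::vec3 dth_dv = -(da3_dv - q * dr_dv) / (r * sq);
    arma::vec3 dth_du = -(da3_du) / (r * sq);
    arma::vec3 dth_dw = -(da3_dw) / (r * sq);
    row = 4 + 3 * k;
    put(row, nn, dth_dv); put(row, ax, dth_du); put(row, ay, dth_dw);
    put(row, a, -(dth_dv + dth_du + dth_dw));

    // phi = atan2(a2, a1)
    double den = a1 * a1 + a2 * a2;
    if (den < 1e-20) den = 1e-20;
    arma::vec3 dph_dv = (a1 * da2_dv - a2 * da1_dv) / den;
    arma::vec3 dph_du = (a1 * da2_du - a2 * da1_du) / den;
    arma::vec3 dph_dw = (a1 * da2_dw) / den;           // a1 depends on u only via e1
    row = 5 + 3 * k;
    put(row, nn, dph_dv); put(row, ax, dph_du); put(row, ay, dph_dw);
    put(row, a, -(dph_dv + dph_du + dph_dw));
  }
  return B;
}

// [[Rcpp::export]]
arma::vec cpp_features(const arma::mat &coords, int atom, int ax, int ay) {
  return features_one(coords, atom - 1, ax - 1, ay - 1);
}

// [[Rcpp::export]]
arma::mat cpp_features_all(const arma::mat &coords, const arma::ivec &alfx,
                           const arma::ivec &alfy) {
  const int n = coords.n_rows;
  arma::mat out(n, 3 * n - 6);
  for (int a = 0; a < n; ++a)
    out.row(a) = features_one(coords, a, alfx(a) - 1, alfy(a) - 1).t();
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_feature_jacobian(const arma::mat &coords, int atom, int ax, int ay) {
  return jacobian_one(coords, atom - 1, ax - 1, ay - 1);
}

// Composite kernel matrix between rows of X and rows of Y:
// k = sigma_f * exp(-sum_d theta_d * Phi_d), Phi_d = sin^2(0.5 delta) on
// periodic features and delta^2 otherwise.
// [[Rcpp::export]]
arma::mat cpp_kernel_matrix(const arma::mat &X, const arma::mat &Y,
                            const arma::vec &theta, double sigma_f,
                            const arma::uvec &periodic) {
  const arma::uword nx = X.n_rows, ny = Y.n_rows, f = X.n_cols;
  arma::mat S(nx, ny, arma::fill::zeros);
  for (arma::uword d = 0; d < f; ++d) {
    if (theta(d) == 0) continue;
    arma::vec xd = X.col(d), yd = Y.col(d);
    for (arma::uword j = 0; j < ny; ++j) {
      arma::vec delta = xd - yd(j);
      arma::vec phi;
      if (periodic(d)) phi = arma::square(arma::sin(0.5 * delta));
      else phi = arma::square(delta);
      S.col(j) += theta(d) * phi;
    }
  }
  return sigma_f * arma::exp(-S);
}

// Kabsch superposition RMSD between two conformations (rows = atoms).
// [[Rcpp::export]]
double cpp_rmsd(const arma::mat &A, const arma::mat &B) {
  arma::mat P = A.each_row() - arma::mean(A, 0);
  arma::mat Q = B.each_row() - arma::mean(B, 0);
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, P.t() * Q)) stop("SVD failed in RMSD superposition");
  arma::vec d = {1.0, 1.0, arma::det(V * U.t()) < 0 ? -1.0 : 1.0};
  arma::mat R = V * arma::diagmat(d) * U.t();
  return std::sqrt(arma::accu(arma::square(Q - P * R.t())) / A.n_rows);
}

// ---- molecular model plumbing -------------------------------------------

struct CModel {
  int n_atoms, n_feats;
  arma::ivec alfx, alfy;        // 0-based
  arma::uvec periodic;
  arma::vec mean, sigma_f;
  std::vector<arma::mat> X;     // training features per atom model
  std::vector<arma::vec> w;     // regression weights
  std::vector<arma::vec> theta;
};

static CModel unpack_model(const List &m) {
  CModel cm;
  cm.n_atoms = as<int>(m["n_atoms"]);
  cm.n_feats = as<int>(m["n_feats"]);
  cm.alfx = as<arma::ivec>(m["alfx"]) - 1;
  cm.alfy = as<arma::ivec>(m["alfy"]) - 1;
  cm.periodic = as<arma::uvec>(m["periodic"]);
  cm.mean = as<arma::vec>(m["mean"]);
  cm.sigma_f = as<arma::vec>(m["sigma_f"]);
  List X = m["X"], w = m["w"], th = m["theta"];
  for (int a = 0; a < cm.n_atoms; ++a) {
    cm.X.push_back(as<arma::mat>(X[a]));
    cm.w.push_back(as<arma::vec>(w[a]));
    cm.theta.push_back(as<arma::vec>(th[a]));
  }
  return cm;
}

// energy (Ha) and Cartesian energy gradient (Ha/Angstrom, N x 3)
static double energy_gradient(const CModel &cm, const arma::mat &coords,
                              arma::mat &grad, bool want_grad) {
  const int n = cm.n_atoms;
  double energy = arma::sum(cm.mean);
  if (want_grad) grad.zeros(n, 3);
  for (int a = 0; a < n; ++a) {
    arma::vec R = features_one(coords, a, cm.alfx(a), cm.alfy(a));
    const arma::mat &X = cm.X[a];
    const arma::vec &th = cm.theta[a];
    arma::mat D = X.each_row() - R.t();              // N_train x f, R^i - R^j
    arma::vec expo(X.n_rows, arma::fill::zeros);
    for (int d = 0; d < cm.n_feats; ++d) {
      if (th(d) == 0) continue;
      arma::vec dd = D.col(d);
      if (cm.periodic(d))
        expo += th(d) * arma::square(arma::sin(0.5 * dd));
      else
        expo += th(d) * arma::square(dd);
    }
    arma::vec k = cm.sigma_f(a) * arma::exp(-expo);
    energy += arma::dot(cm.w[a], k);
    if (!want_grad) continue;
    arma::vec wk = cm.w[a] % k;
    arma::vec g(cm.n_feats);                         // dE_A / dR_d (test point)
    for (int d = 0; d < cm.n_feats; ++d) {
      if (th(d) == 0) { g(d) = 0; continue; }
      g(d) = cm.periodic(d)
                 ? 0.5 * th(d) * arma::dot(wk, arma::sin(D.col(d)))
                 : 2.0 * th(d) * arma::dot(wk, D.col(d));
    }
    arma::mat B = jacobian_one(coords, a, cm.alfx(a), cm.alfy(a));
    arma::vec gc = B.t() * g;                        // 3N vector
    for (int i = 0; i < n; ++i)
      for (int kk = 0; kk < 3; ++kk) grad(i, kk) += gc(3 * i + kk);
  }
  return energy;
}

// [[Rcpp::export]]
List cpp_energy_gradient(const arma::mat &coords, const List &model,
                         bool gradient = true) {
  CModel cm = unpack_model(model);
  arma::mat grad;
  double e = energy_gradient(cm, coords, grad, gradient);
  if (!gradient) return List::create(_["energy"] = e);
  return List::create(_["energy"] = e, _["gradient"] = grad);
}

// ---- MD loop -------------------------------------------------------------

// mode: 0 = NVE, 1 = Nose-Hoover NVT, 2 = Langevin (BAOAB) NVT
// [[Rcpp::export]]
List cpp_run_md(const arma::mat &coords0, const arma::mat &vel0,
                const arma::vec &mass, const List &model, double dt, int nsteps,
                int mode, double t_target, double tau_nh, double gamma,
                double kb, double ha2mdu, const arma::imat &bonds,
                const arma::vec &b0, double ratio_limit, int sample_every,
                bool record_frames) {
  CModel cm = unpack_model(model);
  const int n = coords0.n_rows, nb = bonds.n_rows;
  arma::mat x = coords0, v = vel0, grad(n, 3);
  // Langevin noise thermalizes all 3N degrees of freedom (no conserved
  // momentum); NVE/Nose-Hoover preserve the zeroed total momentum.
  double g_dof = (mode == 2) ? 3.0 * n : 3.0 * n - 3.0;
  double q_nh = g_dof * kb * t_target * tau_nh * tau_nh;
  double xi = 0.0;

  double epot = energy_gradient(cm, x, grad, true);
  arma::mat acc = -grad * ha2mdu;
  acc.each_col() /= mass;

  int max_samples = nsteps / (sample_every > 0 ? sample_every : nsteps + 1) + 4;
  arma::vec s_epot(max_samples), s_ekin(max_samples), s_temp(max_samples);
  arma::ivec s_step(max_samples);
  arma::cube frames;
  if (record_frames) frames.set_size(n, 3, max_samples);
  arma::vec max_ratio(nsteps + 1);
  int ns = 0, crash_step = -1, crash_kind = 0;

  auto bond_check = [&](int step) {
    double worst = 1.0;
    bool bad = false;
    for (int b = 0; b < nb; ++b) {
      double r = arma::norm(x.row(bonds(b, 0) - 1) - x.row(bonds(b, 1) - 1));
      double ratio = r / b0(b);
      double dev = std::max(ratio, 1.0 / ratio);
      if (dev > worst) worst = dev;
      if (ratio > ratio_limit || ratio < 1.0 / ratio_limit) bad = true;
    }
    max_ratio(step) = worst;
    return bad;
  };
  auto sample = [&](int step, double ep) {
    double ke = 0.5 * arma::accu((arma::square(v).eval().each_col() % mass));
    s_step(ns) = step;
    s_epot(ns) = ep;
    s_ekin(ns) = ke / ha2mdu; // report in Hartree, like epot
    s_temp(ns) = 2.0 * ke / (g_dof * kb);
    if (record_frames) frames.slice(ns) = x;
    ++ns;
  };

  bond_check(0);
  sample(0, epot);

  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  int step = 0;
  for (step = 1; step <= nsteps; ++step) {
    if (mode == 1) { // Nose-Hoover half kick of the thermostat
      double ke = 0.5 * arma::accu((arma::square(v).eval().each_col() % mass));
      xi += 0.5 * dt * (2.0 * ke - g_dof * kb * t_target) / q_nh;
      v *= std::exp(-xi * 0.5 * dt);
    }
    v += 0.5 * dt * acc;
    if (mode == 2) {
      x += 0.5 * dt * v;
      for (int i = 0; i < n; ++i) {
        double sd = std::sqrt(kb * t_target / mass(i));
        for (int kk = 0; kk < 3; ++kk)
          v(i, kk) = c1 * v(i, kk) + c2 * sd * R::norm_rand();
      }
      x += 0.5 * dt * v;
    } else {
      x += dt * v;
    }
    epot = energy_gradient(cm, x, grad, true);
    if (!std::isfinite(epot) || !grad.is_finite()) {
      crash_step = step; crash_kind = 2;
      max_ratio(step) = max_ratio(step - 1);
      break;
    }
    acc = -grad * ha2mdu;
    acc.each_col() /= mass;
    v += 0.5 * dt * acc;
    if (mode == 1) {
      v *= std::exp(-xi * 0.5 * dt);
      double ke = 0.5 * arma::accu((arma::square(v).eval().each_col() % mass));
      xi += 0.5 * dt * (2.0 * ke - g_dof * kb * t_target) / q_nh;
    }
    bool crashed = bond_check(step);
    if (sample_every > 0 && (step % sample_every == 0 || step == nsteps ||
                             crashed))
      sample(step, epot);
    if (crashed) { crash_step = step; crash_kind = 1; break; }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  int done = (crash_step > 0) ? crash_step : nsteps;
  return List::create(
      _["crash_step"] = crash_step, _["crash_kind"] = crash_kind,
      _["steps_done"] = done,
      _["max_ratio"] = max_ratio.head(done + 1),
      _["sample_step"] = s_step.head(ns), _["epot"] = s_epot.head(ns),
      _["ekin"] = s_ekin.head(ns), _["temp"] = s_temp.head(ns),
      _["frames"] = record_frames ? wrap(arma::cube(frames.head_slices(ns)))
                                  : R_NilValue,
      _["coords"] = x, _["vel"] = v, _["xi"] = xi);
}
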