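// Compiled trajectory engine: mirrors the pure-R reference loop in
// run_trajectory_reference() step for step, including the order in which
// uniform random numbers are drawn (two per nuclear step, one per hop check),
// so that a given seed produces the same trajectory on either engine.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct ModelParams {
  double W1, W2, E2, c1, delta;
  double mu_trans_y, mu_perm_z1, mu_perm_z2, mu_perm_x1, mu_perm_x2;
  imat bonds;        // B x 2 (1-based)
  vec kb, r0;
  imat angles;       // A x 3 (1-based)
  vec ka, th0;
  ivec dih;          // 4 atoms (1-based)
  vec masses;        // per atom
};

struct CavityParams {
  double omega, g_c, lambda, gamma;
  vec eps;
  int n_fock;
  bool include_dse;
};

vec cross3(const vec& a, const vec& b) {
  vec c(3);
  c(0) = a(1) * b(2) - a(2) * b(1);
  c(1) = a(2) * b(0) - a(0) * b(2);
  c(2) = a(0) * b(1) - a(1) * b(0);
  return c;
}

double dihedral(const mat& R, const ivec& idx) {
  vec b1 = R.row(idx(1) - 1).t() - R.row(idx(0) - 1).t();
  vec b2 = R.row(idx(2) - 1).t() - R.row(idx(1) - 1).t();
  vec b3 = R.row(idx(3) - 1).t() - R.row(idx(2) - 1).t();
  vec n1 = cross3(b1, b2), n2 = cross3(b2, b3);
  vec b2n = b2 / norm(b2);
  double x = dot(n1, n2);
  double y = dot(cross3(n1, n2), b2n);
  return std::atan2(y, x);
}

// gradient of the dihedral wrt all atoms (N x 3), nonzero on the four centers
mat dihedral_grad(const mat& R, const ivec& idx) {
  vec b1 = R.row(idx(1) - 1).t() - R.row(idx(0) - 1).t();
  vec b2 = R.row(idx(2) - 1).t() - R.row(idx(1) - 1).t();
  vec b3 = R.row(idx(3) - 1).t() - R.row(idx(2) - 1).t();
  vec n1 = cross3(b1, b2), n2 = cross3(b2, b3);
  double b2l = norm(b2);
  vec gA = -b2l / dot(n1, n1) * n1;
  vec gD = b2l / dot(n2, n2) * n2;
  double f1 = dot(b1, b2) / dot(b2, b2);
  double f2 = dot(b3, b2) / dot(b2, b2);
  vec gB = -(1.0 + f1) * gA + f2 * gD;
  vec gC = -(gA + gB + gD);
  mat g(R.n_rows, 3, fill::zeros);
  g.row(idx(0) - 1) = gA.t();
  g.row(idx(1) - 1) = gB.t();
  g.row(idx(2) - 1) = gC.t();
  g.row(idx(3) - 1) = gD.t();
  return g;
}

// state-independent harmonic scaffold
void scaffold(const ModelParams& mp, const mat& R, double& e, mat& g) {
  e = 0.0;
  g.zeros(R.n_rows, 3);
  for (uword b = 0; b < mp.bonds.n_rows; ++b) {
    int i = mp.bonds(b, 0) - 1, j = mp.bonds(b, 1) - 1;
    vec dv = R.row(i).t() - R.row(j).t();
    double r = norm(dv);
    e += 0.5 * mp.kb(b) * std::pow(r - mp.r0(b), 2);
    vec gv = mp.kb(b) * (r - mp.r0(b)) * dv / r;
    g.row(i) += gv.t();
    g.row(j) -= gv.t();
  }
  for (uword a = 0; a < mp.angles.n_rows; ++a) {
    int i = mp.angles(a, 0) - 1, j = mp.angles(a, 1) - 1, k = mp.angles(a, 2) - 1;
    vec u = R.row(i).t() - R.row(j).t();
    vec v = R.row(k).t() - R.row(j).t();
    double lu = norm(u), lv = norm(v);
    double cth = std::max(-1.0, std::min(1.0, dot(u, v) / (lu * lv)));
    double sth = std::sqrt(std::max(1e-14, 1.0 - cth * cth));
    double th = std::acos(cth);
    e += 0.5 * mp.ka(a) * std::pow(th - mp.th0(a), 2);
    double pref = mp.ka(a) * (th - mp.th0(a));
    vec gi = (cth * u / lu - v / lv) / (lu * sth);
    vec gk = (cth * v / lv - u / lu) / (lv * sth);
    vec gj = -(gi + gk);
    g.row(i) += pref * gi.t();
    g.row(j) += pref * gj.t();
    g.row(k) += pref * gk.t();
  }
}

struct Frame {
  vec energies;      // 2
  mat grads;         // 2 x 3N (atom-major flat)
  vec nac_ge;        // 3N, <g|grad e>
  cube dip;          // 2 x 2 x 3
  cube dmu;          // slices: per lab component, 2x2 d mu / d phi
  vec dphi;          // 3N
  double phi;
};

Frame eval_frame(const ModelParams& mp, const mat& R) {
  Frame f;
  f.phi = dihedral(R, mp.dih);
  mat dphi_m = dihedral_grad(R, mp.dih);
  int ndof = 3 * R.n_rows;
  f.dphi.set_size(ndof);
  for (uword a = 0; a < R.n_rows; ++a)
    for (int l = 0; l < 3; ++l) f.dphi(3 * a + l) = dphi_m(a, l);

  double s2 = std::sin(f.phi) * std::sin(f.phi);
  double V1 = mp.W1 * s2 + mp.c1 * std::cos(f.phi);
  double V2 = mp.E2 - mp.W2 * s2 + mp.c1 * std::cos(f.phi);
  double dV1 = mp.W1 * std::sin(2 * f.phi) - mp.c1 * std::sin(f.phi);
  double dV2 = -mp.W2 * std::sin(2 * f.phi) - mp.c1 * std::sin(f.phi);
  double gap = V2 - V1, dgap = dV2 - dV1;
  double s = 0.5 * std::sqrt(gap * gap + 4 * mp.delta * mp.delta);
  double ds = gap * dgap / (4 * s);
  double m = 0.5 * (V1 + V2), dm = 0.5 * (dV1 + dV2);
  double theta = 0.5 * std::atan2(2 * mp.delta, gap);
  double dtheta = -mp.delta * dgap / (gap * gap + 4 * mp.delta * mp.delta);

  double esc;
  mat gsc;
  scaffold(mp, R, esc, gsc);
  vec gsc_flat(ndof);
  for (uword a = 0; a < R.n_rows; ++a)
    for (int l = 0; l < 3; ++l) gsc_flat(3 * a + l) = gsc(a, l);

  f.energies = {m - s + esc, m + s + esc};
  f.grads.set_size(2, ndof);
  f.grads.row(0) = ((dm - ds) * f.dphi + gsc_flat).t();
  f.grads.row(1) = ((dm + ds) * f.dphi + gsc_flat).t();
  f.nac_ge = -dtheta * f.dphi;

  // diabatic dipoles and phi-derivatives
  double shape = 0.5 * (1 + std::cos(f.phi)), dshape = -0.5 * std::sin(f.phi);
  double ds2 = std::sin(2 * f.phi);
  cube M(2, 2, 3, fill::zeros), dM(2, 2, 3, fill::zeros);
  M(0, 0, 0) = mp.mu_perm_x1 * s2;  dM(0, 0, 0) = mp.mu_perm_x1 * ds2;
  M(1, 1, 0) = mp.mu_perm_x2 * s2;  dM(1, 1, 0) = mp.mu_perm_x2 * ds2;
  M(0, 1, 1) = M(1, 0, 1) = mp.mu_trans_y * shape;
  dM(0, 1, 1) = dM(1, 0, 1) = mp.mu_trans_y * dshape;
  M(0, 0, 2) = mp.mu_perm_z1 * shape;  dM(0, 0, 2) = mp.mu_perm_z1 * dshape;
  M(1, 1, 2) = mp.mu_perm_z2 * shape;  dM(1, 1, 2) = mp.mu_perm_z2 * dshape;

  mat G = {{std::cos(theta), -std::sin(theta)},
           {std::sin(theta),  std::cos(theta)}};
  mat J = {{0.0, -1.0}, {1.0, 0.0}};
  f.dip.set_size(2, 2, 3);
  f.dmu.set_size(2, 2, 3);
  for (int l = 0; l < 3; ++l) {
    mat A = G.t() * M.slice(l) * G;
    A = 0.5 * (A + A.t());
    f.dip.slice(l) = A;
    mat dA = G.t() * dM.slice(l) * G + dtheta * (A * J - J * A);
    f.dmu.slice(l) = 0.5 * (dA + dA.t());
  }
  return f;
}

mat fock_annihilation(int nf) {
  mat a(nf, nf, fill::zeros);
  for (int n = 1; n < nf; ++n) a(n - 1, n) = std::sqrt((double)n);
  return a;
}

// V in the adiabatic-Fock basis (electronic-major), 2 electronic states
mat build_V(const Frame& f, const CavityParams& cp) {
  int nf = cp.n_fock, K = 2 * nf;
  mat emu(2, 2);
  emu = cp.eps(0) * f.dip.slice(0) + cp.eps(1) * f.dip.slice(1) +
        cp.eps(2) * f.dip.slice(2);
  mat a = fock_annihilation(nf);
  mat x = a + a.t();
  mat V(K, K, fill::zeros);
  for (int al = 0; al < 2; ++al)
    for (int n = 0; n < nf; ++n)
      V(al * nf + n, al * nf + n) = f.energies(al) + cp.omega * (n + 0.5);
  mat dse;
  if (cp.include_dse) dse = 0.5 * cp.lambda * cp.lambda * emu * emu;
  for (int al = 0; al < 2; ++al)
    for (int ga = 0; ga < 2; ++ga)
      for (int n = 0; n < nf; ++n)
        for (int mph = 0; mph < nf; ++mph) {
          V(al * nf + n, ga * nf + mph) += cp.g_c * emu(al, ga) * x(n, mph);
          if (cp.include_dse && n == mph)
            V(al * nf + n, ga * nf + mph) += dse(al, ga);
        }
  return 0.5 * (V + V.t());
}

// The bare derivative of V decomposes as
//   dV/dR_d = diag(dE_alpha/dR_d) + S_phi * dphi/dR_d
// with one K x K torsional slice S_phi (the phi-derivative of the coupling
// and DSE blocks). Forces and polariton NACs then reduce to O(ndof) scalar
// contractions with eigenvectors (the NAC-commutator part of the full
// gradient matrix contributes nothing on the diagonal and a closed-form
// scalar off the diagonal, since V u_J = E_J u_J).
mat build_slice_phi(const Frame& f, const CavityParams& cp) {
  int nf = cp.n_fock, K = 2 * nf;
  mat emu = cp.eps(0) * f.dip.slice(0) + cp.eps(1) * f.dip.slice(1) +
            cp.eps(2) * f.dip.slice(2);
  mat demu_dphi = cp.eps(0) * f.dmu.slice(0) + cp.eps(1) * f.dmu.slice(1) +
                  cp.eps(2) * f.dmu.slice(2);
  mat a = fock_annihilation(nf);
  mat x = a + a.t();
  mat slice_phi(K, K, fill::zeros);
  for (int al = 0; al < 2; ++al)
    for (int ga = 0; ga < 2; ++ga)
      for (int n = 0; n < nf; ++n)
        for (int mph = 0; mph < nf; ++mph)
          slice_phi(al * nf + n, ga * nf + mph) =
              cp.g_c * demu_dphi(al, ga) * x(n, mph);
  if (cp.include_dse) {
    mat ddse = 0.5 * cp.lambda * cp.lambda *
               (demu_dphi * emu + emu * demu_dphi);
    for (int al = 0; al < 2; ++al)
      for (int ga = 0; ga < 2; ++ga)
        for (int n = 0; n < nf; ++n)
          slice_phi(al * nf + n, ga * nf + n) += ddse(al, ga);
  }
  return slice_phi;
}

// photon-number operator (PZW-displaced)
mat photon_operator(const Frame& f, const CavityParams& cp) {
  int nf = cp.n_fock, K = 2 * nf;
  mat emu = cp.eps(0) * f.dip.slice(0) + cp.eps(1) * f.dip.slice(1) +
            cp.eps(2) * f.dip.slice(2);
  mat g = (cp.g_c / cp.omega) * emu;
  mat a = fock_annihilation(nf);
  mat ada = a.t() * a, x = a + a.t();
  mat g2 = g * g;
  mat N(K, K, fill::zeros);
  for (int al = 0; al < 2; ++al)
    for (int ga = 0; ga < 2; ++ga)
      for (int n = 0; n < nf; ++n)
        for (int mph = 0; mph < nf; ++mph) {
          double v = 0.0;
          if (al == ga) v += ada(n, mph);
          v += g(al, ga) * x(n, mph);
          if (n == mph) v += g2(al, ga);
          N(al * nf + n, ga * nf + mph) = v;
        }
  return N;
}

cx_mat cplx(const mat& A) { return cx_mat(A, mat(size(A), fill::zeros)); }

// Preallocated workspace for the quantum substeps: avoids per-substep BLAS
// dispatch and heap churn on these small (K <= ~10) matrices.
struct QWork {
  cx_mat k1, k2, k3, k4, r2;
  explicit QWork(int K)
      : k1(K, K), k2(K, K), k3(K, K), k4(K, K), r2(K, K) {}
};

// out = r*M - M*r  (the commutator form of -i[V,rho] - [D,rho], M = D + iV)
inline void commut(const cx_mat& r, const cx_mat& M, cx_mat& out) {
  const int K = r.n_rows;
  for (int j = 0; j < K; ++j)
    for (int i = 0; i < K; ++i) {
      cx_double s(0, 0);
      for (int k = 0; k < K; ++k)
        s += r.at(i, k) * M.at(k, j) - M.at(i, k) * r.at(k, j);
      out.at(i, j) = s;
    }
}

// one RK4 step of drho/dt = [rho, M], in place
void rk4_ham(cx_mat& rho, const cx_mat& M, double dt, QWork& w) {
  const int n = rho.n_elem;
  commut(rho, M, w.k1);
  for (int i = 0; i < n; ++i) w.r2[i] = rho[i] + 0.5 * dt * w.k1[i];
  commut(w.r2, M, w.k2);
  for (int i = 0; i < n; ++i) w.r2[i] = rho[i] + 0.5 * dt * w.k2[i];
  commut(w.r2, M, w.k3);
  for (int i = 0; i < n; ++i) w.r2[i] = rho[i] + dt * w.k3[i];
  commut(w.r2, M, w.k4);
  for (int i = 0; i < n; ++i)
    rho[i] += dt / 6.0 * (w.k1[i] + 2.0 * w.k2[i] + 2.0 * w.k3[i] + w.k4[i]);
}

// Lindblad dissipator for L = I_el (x) a, written elementwise:
//   rhs_ij = gamma [ sqrt((n_i+1)(n_j+1)) rho_{i+1,j+1} - (n_i+n_j)/2 rho_ij ]
// where n_i is the photon number of basis index i (electronic-major).
inline void lind_rhs(const cx_mat& r, int nf, double gamma, cx_mat& out) {
  const int K = r.n_rows;
  for (int j = 0; j < K; ++j) {
    int njf = j % nf;
    for (int i = 0; i < K; ++i) {
      int nif = i % nf;
      cx_double s = -0.5 * (nif + njf) * r.at(i, j);
      if (nif + 1 < nf && njf + 1 < nf)
        s += std::sqrt(double((nif + 1) * (njf + 1))) * r.at(i + 1, j + 1);
      out.at(i, j) = gamma * s;
    }
  }
}

void rk4_lind(cx_mat& rho, int nf, double gamma, double dt, QWork& w) {
  const int n = rho.n_elem;
  lind_rhs(rho, nf, gamma, w.k1);
  for (int i = 0; i < n; ++i) w.r2[i] = rho[i] + 0.5 * dt * w.k1[i];
  lind_rhs(w.r2, nf, gamma, w.k2);
  for (int i = 0; i < n; ++i) w.r2[i] = rho[i] + 0.5 * dt * w.k2[i];
  lind_rhs(w.r2, nf, gamma, w.k3);
  for (int i = 0; i < n; ++i) w.r2[i] = rho[i] + dt * w.k3[i];
  lind_rhs(w.r2, nf, gamma, w.k4);
  for (int i = 0; i < n; ++i)
    rho[i] += dt / 6.0 * (w.k1[i] + 2.0 * w.k2[i] + 2.0 * w.k3[i] + w.k4[i]);
}

// ascending eigen decomposition with continuity: match new columns to prev
// columns by greedy maximal |overlap|, fix signs, return match (1-based)
void diag_cont(const mat& V, const mat* prevU, vec& evals, mat& U,
               ivec& match) {
  eig_sym(evals, U, 0.5 * (V + V.t()));
  int K = V.n_rows;
  match.set_size(K);
  if (prevU) {
    mat O = prevU->t() * U;
    mat absO = abs(O);
    for (int s = 0; s < K; ++s) {
      uword lin = absO.index_max();
      int i = lin % K, j = lin / K;
      match(j) = i + 1;
      if (O(i, j) < 0) U.col(j) *= -1.0;
      absO.row(i).fill(-datum::inf);
      absO.col(j).fill(-datum::inf);
    }
  } else {
    for (int j = 0; j < K; ++j) {
      match(j) = j + 1;
      uword i = index_max(abs(U.col(j)));
      if (U(i, j) < 0) U.col(j) *= -1.0;
    }
  }
}

vec gfsh_probs(const vec& p_prev, const vec& p_now, int active) {
  int K = p_prev.n_elem;
  vec probs(K, fill::zeros);
  vec delta = p_now - p_prev;
  if (delta(active) >= 0) return probs;
  double rho_ii = p_prev(active);
  if (rho_ii <= 0) return probs;
  double lossA = 0.0;
  for (int k = 0; k < K; ++k) if (delta(k) < 0) lossA -= delta(k);
  for (int k = 0; k < K; ++k) {
    if (delta(k) > 0) {
      double p = (delta(k) / rho_ii) * (-delta(active) / lossA);
      probs(k) = std::min(1.0, std::max(0.0, p));
    }
  }
  return probs;
}

int attempt_hop_cpp(const vec& probs) {
  double zeta = R::runif(0, 1);
  double s = accu(probs);
  vec p = probs;
  if (s > 1 + 1e-12) p /= s;
  double acc = 0.0;
  for (uword j = 0; j < p.n_elem; ++j) {
    acc += p(j);
    if (zeta <= acc && p(j) > 0) return (int)j;
  }
  return -1;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List run_trajectory_cpp(Rcpp::List model, Rcpp::List cavity,
                              Rcpp::List run, arma::mat R0, arma::vec P0) {
  ModelParams mp;
  mp.W1 = model["W1"]; mp.W2 = model["W2"]; mp.E2 = model["E2"];
  mp.c1 = model["c1"]; mp.delta = model["delta"];
  mp.mu_trans_y = model["mu_trans_y"];
  mp.mu_perm_z1 = model["mu_perm_z1"]; mp.mu_perm_z2 = model["mu_perm_z2"];
  mp.mu_perm_x1 = model["mu_perm_x1"]; mp.mu_perm_x2 = model["mu_perm_x2"];
  mp.bonds = Rcpp::as<imat>(model["bonds"]);
  mp.kb = Rcpp::as<vec>(model["kb"]); mp.r0 = Rcpp::as<vec>(model["r0"]);
  mp.angles = Rcpp::as<imat>(model["angles"]);
  mp.ka = Rcpp::as<vec>(model["ka"]); mp.th0 = Rcpp::as<vec>(model["th0"]);
  mp.dih = Rcpp::as<ivec>(model["dih"]);
  mp.masses = Rcpp::as<vec>(model["masses"]);

  CavityParams cp;
  cp.omega = cavity["omega"]; cp.g_c = cavity["g_c"];
  cp.lambda = cavity["lambda"]; cp.gamma = cavity["gamma"];
  cp.eps = Rcpp::as<vec>(cavity["eps"]);
  cp.n_fock = cavity["n_fock"];
  cp.include_dse = cavity["include_dse"];

  double dt = run["dt"];
  int n_steps = run["n_steps"], n_sub = run["n_sub"];
  double alpha = run["alpha"];
  int init_state = run["init_state"];   // 1-based; -1 => dominant |e,0>
  bool store_geometry = run["store_geometry"];

  int n_atoms = R0.n_rows, ndof = 3 * n_atoms, nf = cp.n_fock, K = 2 * nf;
  vec m3(ndof);
  for (int a = 0; a < n_atoms; ++a)
    for (int l = 0; l < 3; ++l) m3(3 * a + l) = mp.masses(a);

  QWork qw(K);

  mat Rc = R0;
  vec P = P0;
  Frame fr = eval_frame(mp, Rc);
  mat V = build_V(fr, cp);
  vec evals; mat U; ivec match;
  diag_cont(V, nullptr, evals, U, match);
  int active;
  if (init_state > 0) active = init_state - 1;
  else {
    int e0 = 1 * nf + 0;  // |e,0> linear index (0-based)
    active = (int)index_max(square(U.row(e0).t()));
  }
  cx_mat rho_af = cx_mat(U.col(active) * U.col(active).t(),
                         mat(K, K, fill::zeros));

  // NAC in adiabatic-Fock basis contracted with velocities, and force
  auto contract_D = [&](const Frame& f, const vec& Rdot) {
    double c = dot(f.nac_ge, Rdot);
    mat D(K, K, fill::zeros);
    for (int n = 0; n < nf; ++n) {
      D(0 * nf + n, 1 * nf + n) = c;      // <g|d/dt|e>
      D(1 * nf + n, 0 * nf + n) = -c;
    }
    return D;
  };
  // F_d = -u_J' dV_d u_J (the NAC commutator has zero diagonal in the
  // eigenbasis): contract the electronic-state weights with the energy
  // gradients plus the torsional slice along dphi/dR.
  auto force_on = [&](const Frame& f, const mat& Sphi, const mat& Uc, int J) {
    vec u = Uc.col(J);
    vec wst(2);
    for (int al = 0; al < 2; ++al) {
      double s = 0;
      for (int n = 0; n < nf; ++n) s += u(al * nf + n) * u(al * nf + n);
      wst(al) = s;
    }
    double q = as_scalar(u.t() * Sphi * u);
    return vec(-(f.grads.t() * wst + q * f.dphi));
  };
  // d_IK = (u_I' [gradV] u_K)/(E_K - E_I); with V u = E u the commutator part
  // collapses to (u_I' D u_K) so d_IK = u_I' dV u_K / dE + S * nac_ge.
  auto nac_pl = [&](const Frame& f, const mat& Sphi, const mat& Uc,
                    const vec& ev, int I, int Kd, bool& ok) {
    double dE = ev(Kd) - ev(I);
    vec out(ndof, fill::zeros);
    if (std::abs(dE) <= 1e-8) { ok = false; return out; }
    ok = true;
    vec uI = Uc.col(I), uK = Uc.col(Kd);
    vec wst(2);
    double S = 0;
    for (int al = 0; al < 2; ++al) {
      double s = 0;
      for (int n = 0; n < nf; ++n) s += uI(al * nf + n) * uK(al * nf + n);
      wst(al) = s;
    }
    for (int n = 0; n < nf; ++n)
      S += uI(0 * nf + n) * uK(1 * nf + n) - uI(1 * nf + n) * uK(0 * nf + n);
    double q = as_scalar(uI.t() * Sphi * uK);
    out = (f.grads.t() * wst + q * f.dphi) / dE + S * f.nac_ge;
    return out;
  };
  mat Sphi = build_slice_phi(fr, cp);
  vec Fc = force_on(fr, Sphi, U, active);
  mat D_now = contract_D(fr, P / m3);
  mat Nop = photon_operator(fr, cp);

  int nt = n_steps + 1;
  ivec rec_active(nt);
  mat rec_energies(nt, K), rec_pop_af(nt, K), rec_pop_pl(nt, K);
  vec rec_photon(nt), rec_dihedral(nt), rec_ekin(nt), rec_etot(nt);
  cube rec_geom;
  if (store_geometry) rec_geom.set_size(n_atoms, 3, nt);
  std::vector<int> hop_step, hop_from, hop_to;
  std::vector<std::string> hop_type;
  std::vector<double> hop_dE;
  int n_frustrated = 0;
  double dissipated = 0.0;

  auto record = [&](int i) {
    cx_mat Uc = cplx(U);
    cx_mat rho_pl = Uc.t() * rho_af * Uc;
    cx_mat mixed = rho_pl;
    mixed.diag().zeros();
    mixed(active, active) = 1.0;
    cx_mat back = Uc * mixed * Uc.t();
    rec_active(i) = active + 1;
    rec_energies.row(i) = evals.t();
    rec_pop_af.row(i) = real(diagvec(back)).t();
    rec_pop_pl.row(i) = real(diagvec(rho_pl)).t();
    rec_photon(i) = std::real(trace(rho_af * cplx(Nop)));
    rec_dihedral(i) = fr.phi;
    double ke = accu(square(P) / (2 * m3));
    rec_ekin(i) = ke;
    rec_etot(i) = ke + evals(active);
    if (store_geometry) rec_geom.slice(i) = Rc;
  };
  record(0);

  double dt_sub = dt / n_sub;
  for (int step = 1; step <= n_steps; ++step) {
    vec P_half = P + 0.5 * dt * Fc;
    vec drift = dt * P_half / m3;
    for (int a = 0; a < n_atoms; ++a)
      for (int l = 0; l < 3; ++l) Rc(a, l) += drift(3 * a + l);

    Frame fr_new = eval_frame(mp, Rc);
    mat V_new = build_V(fr_new, cp);
    vec evals_new; mat U_new; ivec match_new;
    diag_cont(V_new, &U, evals_new, U_new, match_new);
    // active follows the matched column
    for (int j = 0; j < K; ++j)
      if (match_new(j) == active + 1) { active = j; break; }
    mat Sphi_new = build_slice_phi(fr_new, cp);
    vec F_new = force_on(fr_new, Sphi_new, U_new, active);
    if (!F_new.is_finite()) Rcpp::stop("non-finite force: trajectory aborted");
    P = P_half + 0.5 * dt * F_new;

    // phase A: Hamiltonian/NAC propagation with linear interpolation
    mat D_new = contract_D(fr_new, P / m3);
    cx_mat M0(D_now, V);        // M = D + iV
    cx_mat M1(D_new, V_new);
    cx_mat rho = rho_af;
    cx_mat Mk(K, K);
    for (int k = 1; k <= n_sub; ++k) {
      double w = (k - 0.5) / n_sub;
      for (int q = 0; q < K * K; ++q) Mk[q] = (1 - w) * M0[q] + w * M1[q];
      rk4_ham(rho, Mk, dt_sub, qw);
    }
    cx_mat rho_A = rho;

    // hop check 1 (rescaled)
    cx_mat Uc_new = cplx(U_new);
    vec p_prev = real(diagvec(cx_mat(Uc_new.t() * rho_af * Uc_new)));
    vec p_A = real(diagvec(cx_mat(Uc_new.t() * rho_A * Uc_new)));
    vec probs = gfsh_probs(p_prev, p_A, active);
    int dest = attempt_hop_cpp(probs);
    if (dest >= 0) {
      double dE = evals_new(dest) - evals_new(active);
      bool ok;
      vec dvec = nac_pl(fr_new, Sphi_new, U_new, evals_new, active, dest, ok);
      if (!ok) dvec = P;
      double nrm = norm(dvec);
      if (nrm < 1e-14) { dvec = P; nrm = norm(dvec); }
      bool frustrated = true;
      if (nrm >= 1e-14) {
        vec u = dvec / nrm;
        double aq = accu(m3 % square(u)) / 2.0;
        double bq = dot(u, P);
        double disc = bq * bq - 4 * aq * dE;
        if (disc >= 0) {
          double r1 = (-bq + std::sqrt(disc)) / (2 * aq);
          double r2 = (-bq - std::sqrt(disc)) / (2 * aq);
          double kappa = (std::abs(r1) <= std::abs(r2)) ? r1 : r2;
          P += kappa * (m3 % u);
          frustrated = false;
        }
      }
      if (frustrated) {
        ++n_frustrated;
      } else {
        hop_step.push_back(step); hop_type.push_back("rescaled");
        hop_from.push_back(active + 1); hop_to.push_back(dest + 1);
        hop_dE.push_back(dE);
        active = dest;
        F_new = force_on(fr_new, Sphi_new, U_new, active);
      }
    }

    // phase B: Lindblad loss
    cx_mat rho_B = rho_A;
    if (cp.gamma > 0) {
      for (int k = 0; k < n_sub; ++k)
        rk4_lind(rho_B, nf, cp.gamma, dt_sub, qw);
    }

    // hop check 2 (loss channel, never rescaled)
    vec p_A2 = real(diagvec(cx_mat(Uc_new.t() * rho_A * Uc_new)));
    vec p_B = real(diagvec(cx_mat(Uc_new.t() * rho_B * Uc_new)));
    vec probs2 = gfsh_probs(p_A2, p_B, active);
    int dest2 = attempt_hop_cpp(probs2);
    if (dest2 >= 0) {
      double dE = evals_new(dest2) - evals_new(active);
      hop_step.push_back(step); hop_type.push_back("loss");
      hop_from.push_back(active + 1); hop_to.push_back(dest2 + 1);
      hop_dE.push_back(dE);
      dissipated += -dE;
      active = dest2;
      F_new = force_on(fr_new, Sphi_new, U_new, active);
    }

    // decoherence correction
    cx_mat rho_pl = Uc_new.t() * rho_B * Uc_new;
    double ekin = accu(square(P) / (2 * m3));
    if (ekin > 1e-12) {
      vec fdamp(K, fill::zeros);
      for (int J = 0; J < K; ++J) {
        if (J == active) continue;
        double gap = std::abs(evals_new(J) - evals_new(active));
        if (gap < 1e-14) { fdamp(J) = 1.0; continue; }
        double tau = (1.0 / gap) * (1.0 + alpha / ekin);
        fdamp(J) = std::exp(-dt / tau);
      }
      double pII = std::real(rho_pl(active, active));
      double others = 0.0;
      for (int J = 0; J < K; ++J)
        if (J != active)
          others += std::real(rho_pl(J, J)) * fdamp(J) * fdamp(J);
      fdamp(active) =
          (pII > 1e-14) ? std::sqrt(std::max(0.0, 1.0 - others) / pII) : 1.0;
      for (int i = 0; i < K; ++i)
        for (int j = 0; j < K; ++j) rho_pl(i, j) *= fdamp(i) * fdamp(j);
      double tr = std::real(trace(rho_pl));
      if (tr > 1e-14) rho_pl /= tr;
    }
    rho_af = Uc_new * rho_pl * Uc_new.t();
    rho_af = 0.5 * (rho_af + rho_af.t());

    fr = fr_new; V = V_new; U = U_new; evals = evals_new;
    Fc = F_new; D_now = D_new; Sphi = Sphi_new;
    Nop = photon_operator(fr, cp);
    record(step);
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("active") = rec_active,
      Rcpp::Named("energies") = rec_energies,
      Rcpp::Named("pop_af") = rec_pop_af,
      Rcpp::Named("pop_pl") = rec_pop_pl,
      Rcpp::Named("photon") = rec_photon,
      Rcpp::Named("dihedral") = rec_dihedral,
      Rcpp::Named("ekin") = rec_ekin,
      Rcpp::Named("etot") = rec_etot,
      Rcpp::Named("hop_step") = hop_step,
      Rcpp::Named("hop_type") = hop_type,
      Rcpp::Named("hop_from") = hop_from,
      Rcpp::Named("hop_to") = hop_to,
      Rcpp::Named("hop_dE") = hop_dE,
      Rcpp::Named("n_frustrated") = n_frustrated,
      Rcpp::Named("dissipated") = dissipated,
      Rcpp::Named("final_coords") = Rc,
      Rcpp::Named("final_momenta") = P);
  if (store_geometry) out["geometry"] = rec_geom;
  return out;
}
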