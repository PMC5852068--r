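// Core integrators for the Epileptor neural field model.
//
// The field equations are integrated with a classical fixed-step RK4 scheme;
// all spatial convolutions against the periodic grid are evaluated by FFT.
// The temporal convolution g(u1) is represented throughout by the auxiliary
// variable q3 (exact ODE recast), so the state per site is
// (u1, u2, v, q1, q2, q3).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// Circular convolution with the periodised Laplacian kernel e^{-|x|}/2,
// normalised to preserve constants.  The geometric decay of the kernel makes
// the convolution an O(N) pair of recursive sweeps: with rho = e^{-dx},
//   F_i = sum_{k>=0} rho^k s_{i-k},  B_i = sum_{k>=0} rho^k s_{i+k}
// (periodic, infinite image sum), and
//   conv_i = (F_i + B_i - s_i) * (1-rho)/(1+rho).
// This equals the FFT evaluation of the periodised, mass-normalised kernel
// to machine precision.
struct ExpConv {
  double rho, rhoN, scale;
  explicit ExpConv(int N = 0, double dx = 1.0) {
    rho = std::exp(-dx);
    rhoN = std::pow(rho, N);
    scale = (1.0 - rho) / (1.0 + rho);
  }
  void apply(const double* s, double* out, double* Bbuf, int N) const {
    // forward windowed sums T_i = sum_{k=0}^{N-1} rho^k s_{(i-k) mod N},
    // seeded directly at i = 0, then T_i = s_i (1 - rho^N) + rho T_{i-1};
    // out[] temporarily holds T
    double acc = s[0], r = rho;
    for (int k = N - 1; k >= 1; --k) { acc += r * s[k]; r *= rho; }
    out[0] = acc;
    const double m = 1.0 - rhoN;
    for (int i = 1; i < N; ++i) out[i] = s[i] * m + rho * out[i - 1];
    // backward windowed sums B_i = sum_{k=0}^{N-1} rho^k s_{(i+k) mod N}
    acc = s[N - 1]; r = rho;
    for (int k = 0; k < N - 1; ++k) { acc += r * s[k]; r *= rho; }
    Bbuf[N - 1] = acc;
    for (int i = N - 2; i >= 0; --i) Bbuf[i] = s[i] * m + rho * Bbuf[i + 1];
    const double g = 1.0 / m;
    for (int i = 0; i < N; ++i)
      out[i] = ((out[i] + Bbuf[i]) * g - s[i]) * scale;
  }
  void apply(const arma::vec& s, arma::vec& out) const {
    arma::vec B(s.n_elem);
    apply(s.memptr(), out.memptr(), B.memptr(), (int)s.n_elem);
  }
};

inline void heavi_into(const double* u, int n, double theta, double* out) {
  for (int i = 0; i < n; ++i) out[i] = (u[i] >= theta) ? 1.0 : 0.0;
}

struct FieldPars {
  double I1, I2, tau0, tau2, tau12;
  double th11, th22, th12, th_het;
  double g11, g22, g12, a12;
  bool freeze_v;
};

struct HetConn {
  int src, tgt;            // 0-based field indices
  arma::vec wsrc;          // w_het(y - xs) * dx  (quadrature weights at source)
  arma::vec wtgt;          // w_het(x - xt)       (injection profile at target)
  double gamma;
};

struct Stim {
  double onset, offset;
  int field;
  arma::vec profile;   // amplitude within the spatial boxcar, per site
};

std::vector<Stim> parse_stimuli(const List& stimuli, const arma::vec& x,
                                double L) {
  std::vector<Stim> out;
  for (int s = 0; s < stimuli.size(); ++s) {
    List st = stimuli[s];
    Stim sp;
    sp.onset = as<double>(st["onset"]);
    sp.offset = sp.onset + as<double>(st["duration"]);
    sp.field = as<int>(st["field"]) - 1;
    double amp = as<double>(st["amplitude"]);
    double ctr = as<double>(st["center"]), wid = as<double>(st["width"]);
    sp.profile.zeros(x.n_elem);
    for (arma::uword i = 0; i < x.n_elem; ++i) {
      double d = std::fabs(x(i) - ctr);
      d = std::min(d, L - d);              // periodic distance
      if (d <= wid / 2.0) sp.profile(i) = amp;
    }
    out.push_back(sp);
  }
  return out;
}

// scratch buffers reused across rhs evaluations
struct RhsWork {
  arma::vec ind, c11, c22, c12, bbuf;
  arma::mat hdrive;
  RhsWork(int N, int nf)
    : ind(N), c11(N), c22(N), c12(N), bbuf(N), hdrive(N, nf) {}
};

// derivative of the full 6-variable field; state vars are N x nf matrices
void field_rhs(const FieldPars& p,
               const arma::mat& u0,
               const ExpConv& conv,
               const std::vector<HetConn>& het,
               const std::vector<Stim>& stims, double t,
               const arma::mat& u1, const arma::mat& u2, const arma::mat& v,
               const arma::mat& q1, const arma::mat& q2, const arma::mat& q3,
               RhsWork& w,
               arma::mat& du1, arma::mat& du2, arma::mat& dv,
               arma::mat& dq1, arma::mat& dq2, arma::mat& dq3) {
  const int nf = (int)u1.n_cols, N = (int)u1.n_rows;
  // long-range (heterogeneous) drive, Gaussian sampled at source / injected at target
  arma::mat& hdrive = w.hdrive;
  hdrive.zeros();
  for (const HetConn& hc : het) {
    heavi_into(u1.colptr(hc.src), N, p.th_het, w.ind.memptr());
    double act = arma::dot(hc.wsrc, w.ind);
    hdrive.col(hc.tgt) += hc.gamma * act * hc.wtgt;
  }
  for (const Stim& s : stims)
    if (t >= s.onset && t < s.offset) hdrive.col(s.field) += s.profile;

  for (int f = 0; f < nf; ++f) {
    const double* u1f = u1.colptr(f); const double* u2f = u2.colptr(f);
    const double* vf = v.colptr(f);   const double* q1f = q1.colptr(f);
    const double* q2f = q2.colptr(f); const double* q3f = q3.colptr(f);
    double* bb = w.bbuf.memptr(); double* ind = w.ind.memptr();
    heavi_into(u1f, N, p.th11, ind); conv.apply(ind, w.c11.memptr(), bb, N);
    heavi_into(q1f, N, p.th22, ind); conv.apply(ind, w.c22.memptr(), bb, N);
    heavi_into(u1f, N, p.th12, ind); conv.apply(ind, w.c12.memptr(), bb, N);
    double* d1 = du1.colptr(f); double* d2 = du2.colptr(f);
    double* d3 = dv.colptr(f);  double* d4 = dq1.colptr(f);
    double* d5 = dq2.colptr(f); double* d6 = dq3.colptr(f);
    const double* hd = hdrive.colptr(f);
    const double* u0f = u0.colptr(f);
    const double* c11 = w.c11.memptr(); const double* c22 = w.c22.memptr();
    const double* c12 = w.c12.memptr();
    for (int i = 0; i < N; ++i) {
      double a = u1f[i], b = u2f[i], vv = vf[i];
      double qa = q1f[i], qb = q2f[i], qc = q3f[i];
      double f1v = (a < 0.0) ? a * a * (a - 3.0)
                             : (qa - 0.6 * (vv - 4.0) * (vv - 4.0)) * a;
      double f2v = (qa < -0.25) ? 0.0 : 6.0 * (qa + 0.25);
      d1[i] = b - f1v - vv + p.I1 + p.g11 * c11[i] + hd[i];
      d2[i] = 1.0 - 5.0 * a * a - b;
      d3[i] = p.freeze_v ? 0.0 : (4.0 * (a - u0f[i]) - vv) / p.tau0;
      d4[i] = -qb + qa - qa * qa * qa + p.I2 + 2.0 * qc
              - 0.3 * (vv - 3.5) + p.g22 * c22[i];
      d5[i] = (-qb + f2v) / p.tau2;
      d6[i] = -qc / p.tau12 + 0.001 * (p.a12 * a + p.g12 * c12[i]);
    }
  }
}

std::vector<HetConn> parse_het(const List& het_list) {
  std::vector<HetConn> out;
  for (int j = 0; j < het_list.size(); ++j) {
    List h = het_list[j];
    HetConn hc;
    hc.src = as<int>(h["source_field"]) - 1;
    hc.tgt = as<int>(h["target_field"]) - 1;
    hc.wsrc = as<arma::vec>(h["wsrc"]);
    hc.wtgt = as<arma::vec>(h["wtgt"]);
    hc.gamma = as<double>(h["gamma"]);
    out.push_back(hc);
  }
  return out;
}

} // namespace

// [[Rcpp::export]]
List simulate_field_cpp(List pars, arma::mat u0, arma::vec x, double L,
                        List het_list, List stimuli,
                        arma::mat state0,   // 6 rows x (N*nf): u1,u2,v,q1,q2,q3
                        double dt, int nsteps, int stride,
                        double noise_sigma2, bool freeze_v) {
  FieldPars p;
  p.I1 = as<double>(pars["I1"]);   p.I2 = as<double>(pars["I2"]);
  p.tau0 = as<double>(pars["tau0"]); p.tau2 = as<double>(pars["tau2"]);
  p.tau12 = as<double>(pars["tau12"]);
  p.th11 = as<double>(pars["theta11"]); p.th22 = as<double>(pars["theta22"]);
  p.th12 = as<double>(pars["theta12"]); p.th_het = as<double>(pars["theta_het"]);
  p.g11 = as<double>(pars["gamma11"]); p.g22 = as<double>(pars["gamma22"]);
  p.g12 = as<double>(pars["gamma12"]); p.a12 = as<double>(pars["a12"]);
  p.freeze_v = freeze_v;

  const arma::uword N = x.n_elem, nf = u0.n_cols;
  std::vector<HetConn> het = parse_het(het_list);
  std::vector<Stim> stims = parse_stimuli(stimuli, x, L);
  ExpConv conv((int)N, L / (double)N);
  RhsWork work((int)N, (int)nf);

  arma::mat u1(N, nf), u2(N, nf), v(N, nf), q1(N, nf), q2(N, nf), q3(N, nf);
  for (arma::uword f = 0; f < nf; ++f) {
    u1.col(f) = state0.row(0).subvec(f * N, (f + 1) * N - 1).t();
    u2.col(f) = state0.row(1).subvec(f * N, (f + 1) * N - 1).t();
    v.col(f)  = state0.row(2).subvec(f * N, (f + 1) * N - 1).t();
    q1.col(f) = state0.row(3).subvec(f * N, (f + 1) * N - 1).t();
    q2.col(f) = state0.row(4).subvec(f * N, (f + 1) * N - 1).t();
    q3.col(f) = state0.row(5).subvec(f * N, (f + 1) * N - 1).t();
  }

  const int nrec = nsteps / stride + 1;
  std::vector<arma::cube> rec(6, arma::cube(nrec, N, nf));
  arma::vec trec(nrec);
  auto record = [&](int idx, double t) {
    trec(idx) = t;
    for (arma::uword f = 0; f < nf; ++f) {
      rec[0].slice(f).row(idx) = u1.col(f).t();
      rec[1].slice(f).row(idx) = u2.col(f).t();
      rec[2].slice(f).row(idx) = v.col(f).t();
      rec[3].slice(f).row(idx) = q1.col(f).t();
      rec[4].slice(f).row(idx) = q2.col(f).t();
      rec[5].slice(f).row(idx) = q3.col(f).t();
    }
  };
  record(0, 0.0);

  arma::mat k1u1(N, nf), k1u2(N, nf), k1v(N, nf), k1q1(N, nf), k1q2(N, nf), k1q3(N, nf);
  arma::mat k2u1(N, nf), k2u2(N, nf), k2v(N, nf), k2q1(N, nf), k2q2(N, nf), k2q3(N, nf);
  arma::mat k3u1(N, nf), k3u2(N, nf), k3v(N, nf), k3q1(N, nf), k3q2(N, nf), k3q3(N, nf);
  arma::mat k4u1(N, nf), k4u2(N, nf), k4v(N, nf), k4q1(N, nf), k4q2(N, nf), k4q3(N, nf);
  arma::mat tu1(N, nf), tu2(N, nf), tv(N, nf), tq1(N, nf), tq2(N, nf), tq3(N, nf);

  const double sdq = std::sqrt(noise_sigma2 * dt);
  RNGScope scope;
  int ridx = 1;
  for (int step = 0; step < nsteps; ++step) {
    double t = step * dt;
    field_rhs(p, u0, conv, het, stims, t,
              u1, u2, v, q1, q2, q3, work,
              k1u1, k1u2, k1v, k1q1, k1q2, k1q3);
    tu1 = u1 + 0.5 * dt * k1u1; tu2 = u2 + 0.5 * dt * k1u2;
    tv = v + 0.5 * dt * k1v;    tq1 = q1 + 0.5 * dt * k1q1;
    tq2 = q2 + 0.5 * dt * k1q2; tq3 = q3 + 0.5 * dt * k1q3;
    field_rhs(p, u0, conv, het, stims, t + dt / 2.0,
              tu1, tu2, tv, tq1, tq2, tq3,
              work, k2u1, k2u2, k2v, k2q1, k2q2, k2q3);
    tu1 = u1 + 0.5 * dt * k2u1; tu2 = u2 + 0.5 * dt * k2u2;
    tv = v + 0.5 * dt * k2v;    tq1 = q1 + 0.5 * dt * k2q1;
    tq2 = q2 + 0.5 * dt * k2q2; tq3 = q3 + 0.5 * dt * k2q3;
    field_rhs(p, u0, conv, het, stims, t + dt / 2.0,
              tu1, tu2, tv, tq1, tq2, tq3,
              work, k3u1, k3u2, k3v, k3q1, k3q2, k3q3);
    tu1 = u1 + dt * k3u1; tu2 = u2 + dt * k3u2;
    tv = v + dt * k3v;    tq1 = q1 + dt * k3q1;
    tq2 = q2 + dt * k3q2; tq3 = q3 + dt * k3q3;
    field_rhs(p, u0, conv, het, stims, t + dt,
              tu1, tu2, tv, tq1, tq2, tq3,
              work, k4u1, k4u2, k4v, k4q1, k4q2, k4q3);

    u1 += dt / 6.0 * (k1u1 + 2.0 * k2u1 + 2.0 * k3u1 + k4u1);
    u2 += dt / 6.0 * (k1u2 + 2.0 * k2u2 + 2.0 * k3u2 + k4u2);
    v  += dt / 6.0 * (k1v  + 2.0 * k2v  + 2.0 * k3v  + k4v);
    q1 += dt / 6.0 * (k1q1 + 2.0 * k2q1 + 2.0 * k3q1 + k4q1);
    q2 += dt / 6.0 * (k1q2 + 2.0 * k2q2 + 2.0 * k3q2 + k4q2);
    q3 += dt / 6.0 * (k1q3 + 2.0 * k2q3 + 2.0 * k3q3 + k4q3);

    if (sdq > 0.0) {
      for (arma::uword f = 0; f < nf; ++f)
        for (arma::uword i = 0; i < N; ++i) {
          q1(i, f) += sdq * norm_rand();
          q2(i, f) += sdq * norm_rand();
        }
    }

    if (!u1.is_finite() || !q1.is_finite()) {
      arma::uword bad = arma::abs(u1).index_max();
      stop("state became non-finite at t=%f (site %d)", t + dt, (int)(bad % N) + 1);
    }
    if ((step + 1) % stride == 0 && ridx < nrec) record(ridx++, (step + 1) * dt);
    if (step % 2048 == 0) Rcpp::checkUserInterrupt();
  }

  CharacterVector nms = CharacterVector::create("u1", "u2", "v", "q1", "q2", "q3");
  List fields(nf);
  for (arma::uword f = 0; f < nf; ++f) {
    List vars(6);
    for (int k = 0; k < 6; ++k) vars[k] = wrap(arma::mat(rec[k].slice(f)));
    vars.attr("names") = nms;
    fields[f] = vars;
  }
  return List::create(_["time"] = trec, _["fields"] = fields);
}

// Frozen-permittivity fast subsystem on a periodic grid.
// variant 1 (full):    du1 = u2 - u1^3 + 3 u1^2 - Vbar + I1 + g11 w*S(u1)
//                      du2 = 1 - 5 u1^2 - u2
// variant 2 (reduced): du1 = -u1^3 - 2 u1^2 + 1 + I1 - Vbar + g11 w*S(u1)
// [[Rcpp::export]]
List simulate_fast_subsystem_cpp(arma::vec u1_0, arma::vec u2_0,
                                 double Vbar, double I1, double gamma11,
                                 double theta11, double L,
                                 double dt, int nsteps, int stride, int variant) {
  const arma::uword N = u1_0.n_elem;
  ExpConv conv((int)N, L / (double)N);
  arma::vec u1 = u1_0, u2 = u2_0, cbuf(N), ibuf(N);
  const int nrec = nsteps / stride + 1;
  arma::mat rec_u1(nrec, N);
  arma::vec trec(nrec);
  rec_u1.row(0) = u1.t(); trec(0) = 0.0;

  auto rhs = [&](const arma::vec& a, const arma::vec& b,
                 arma::vec& da, arma::vec& db) {
    heavi_into(a.memptr(), (int)N, theta11, ibuf.memptr());
    conv.apply(ibuf, cbuf);
    arma::vec c = gamma11 * cbuf;
    if (variant == 1) {
      da = b - arma::pow(a, 3) + 3.0 * arma::square(a) - Vbar + I1 + c;
      db = 1.0 - 5.0 * arma::square(a) - b;
    } else {
      da = -arma::pow(a, 3) - 2.0 * arma::square(a) + 1.0 + I1 - Vbar + c;
      db.zeros(a.n_elem);
    }
  };

  arma::vec k1a(N), k1b(N), k2a(N), k2b(N), k3a(N), k3b(N), k4a(N), k4b(N);
  int ridx = 1;
  for (int step = 0; step < nsteps; ++step) {
    rhs(u1, u2, k1a, k1b);
    rhs(u1 + 0.5 * dt * k1a, u2 + 0.5 * dt * k1b, k2a, k2b);
    rhs(u1 + 0.5 * dt * k2a, u2 + 0.5 * dt * k2b, k3a, k3b);
    rhs(u1 + dt * k3a, u2 + dt * k3b, k4a, k4b);
    u1 += dt / 6.0 * (k1a + 2.0 * k2a + 2.0 * k3a + k4a);
    u2 += dt / 6.0 * (k1b + 2.0 * k2b + 2.0 * k3b + k4b);
    if (!u1.is_finite()) stop("fast subsystem became non-finite at t=%f", (step + 1) * dt);
    if ((step + 1) % stride == 0 && ridx < nrec) {
      rec_u1.row(ridx) = u1.t();
      trec(ridx++) = (step + 1) * dt;
    }
    if (step % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["time"] = trec, _["u1"] = rec_u1);
}

// Co-moving-frame ODEs for the traveling ictal wavefront, integrated with a
// fixed-step Euler scheme in the frame coordinate xi.  variant 1 = full
// 5-variable system (U1,E1,H1,U2,E2); variant 2 = reduced averaged 3-variable
// system (U1,E1,H1).  Integration stops early when |U1| exceeds `bound`
// (escape from the physical range; frame derivatives are legitimately large
// at small c1 and are not bounded); the trajectory up to that point is
// returned.
// [[Rcpp::export]]
List integrate_frame_cpp(arma::vec y0, double c1, double Vbar, double I1,
                         double gamma11, double theta11,
                         double h, int nsteps, double bound, int variant,
                         int stride) {
  const int d = y0.n_elem;
  arma::vec y = y0;
  const int nrec = nsteps / stride + 1;
  arma::mat out(nrec, d);
  out.row(0) = y.t();
  int ridx = 1, laststep = 0;
  arma::vec dy(d);
  for (int step = 0; step < nsteps; ++step) {
    double U1 = y(0), E1 = y(1), H1 = y(2);
    double S = (U1 >= theta11) ? 1.0 : 0.0;
    if (variant == 1) {
      double U2 = y(3), E2 = y(4);
      dy(0) = E1;
      dy(1) = H1;
      dy(2) = -(1.0 / c1) * (U1 * H1 * (3.0 * U1 - 6.0)
               + E1 * (6.0 * E1 * (U1 - 1.0) - c1 + 10.0 * U1 / c1)
               + U2 + E2 / c1 - U1 * U1 * U1 + 3.0 * U1 * U1
               + I1 - Vbar + gamma11 * S);
      dy(3) = E2;
      dy(4) = (1.0 / c1) * (-10.0 * E1 * U1 - E2);
    } else {
      dy(0) = E1;
      dy(1) = H1;
      dy(2) = -(1.0 / c1) * (U1 * H1 * (3.0 * U1 + 4.0)
               + E1 * (E1 * (6.0 * U1 + 4.0) - c1)
               - U1 * U1 * U1 - 2.0 * U1 * U1 + 4.1 - Vbar + gamma11 * S);
    }
    y += h * dy;
    laststep = step + 1;
    if ((step + 1) % stride == 0 && ridx < nrec) out.row(ridx++) = y.t();
    if (!y.is_finite() || std::fabs(y(0)) > bound) break;
  }
  return List::create(_["traj"] = out.rows(0, std::max(ridx - 1, 0)),
                      _["nsteps_done"] = laststep,
                      _["escaped"] = (laststep < nsteps));
}
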