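#include <Rcpp.h>
#include <cmath>
#include <functional>
#include <algorithm>
using namespace Rcpp;

// Unit system: Angstrom, fs, amu, eV.
// 1 eV = EV_AA amu*A^2/fs^2 — the single force->acceleration conversion constant.
static const double EV_AA = 9.648533215665e-3;
static const double KB_EV = 8.617333e-5; // eV / K

struct PesParams {
  int nb, na, nat;
  // bonds: i, j (0-based), De (eV), r0 (A), a (1/A)
  std::vector<int> bi, bj;
  std::vector<double> De, r0, am;
  // angles: p, c, q (c central), k (eV/rad^2), th0 (rad),
  // switch centers for the two flanking bonds (A), shared width w (A)
  std::vector<int> ai, ac, ak;
  std::vector<double> kth, th0, rc1, rc2;
  double sw_w;
  double shift; // constant surface offset (eV)
};

static PesParams unpack(const List& par, int nat) {
  PesParams p;
  NumericMatrix B = par["bonds"];   // cols: i j De r0 a (i,j 1-based)
  NumericMatrix A = par["angles"];  // cols: p c q k th0 rc1 rc2
  p.nat = nat;
  p.nb = B.nrow();
  p.na = A.nrow();
  p.sw_w = as<double>(par["switch_width"]);
  p.shift = as<double>(par["shift"]);
  for (int b = 0; b < p.nb; ++b) {
    p.bi.push_back((int)B(b, 0) - 1);
    p.bj.push_back((int)B(b, 1) - 1);
    p.De.push_back(B(b, 2));
    p.r0.push_back(B(b, 3));
    p.am.push_back(B(b, 4));
  }
  for (int a = 0; a < p.na; ++a) {
    p.ai.push_back((int)A(a, 0) - 1);
    p.ac.push_back((int)A(a, 1) - 1);
    p.ak.push_back((int)A(a, 2) - 1);
    p.kth.push_back(A(a, 3));
    p.th0.push_back(A(a, 4));
    p.rc1.push_back(A(a, 5));
    p.rc2.push_back(A(a, 6));
  }
  return p;
}

// energy + gradient (dE/dx, eV/A) of the Morse + switched-angle surface
static double eval_pes(const PesParams& p, const double* x, double* g) {
  const int n = p.nat;
  for (int i = 0; i < 3 * n; ++i) g[i] = 0.0;
  double E = p.shift;

  for (int b = 0; b < p.nb; ++b) {
    const int i = p.bi[b], j = p.bj[b];
    double d[3];
    double r2 = 0.0;
    for (int k = 0; k < 3; ++k) { d[k] = x[3*i+k] - x[3*j+k]; r2 += d[k]*d[k]; }
    const double r = std::sqrt(r2);
    const double ex = std::exp(-p.am[b] * (r - p.r0[b]));
    const double om = 1.0 - ex;
    E += p.De[b] * om * om;
    const double dEdr = 2.0 * p.am[b] * p.De[b] * om * ex;
    for (int k = 0; k < 3; ++k) {
      const double gk = dEdr * d[k] / r;
      g[3*i+k] += gk;
      g[3*j+k] -= gk;
    }
  }

  for (int a = 0; a < p.na; ++a) {
    const int ip = p.ai[a], ic = p.ac[a], iq = p.ak[a];
    double u[3], v[3];
    double ru2 = 0.0, rv2 = 0.0, uv = 0.0;
    for (int k = 0; k < 3; ++k) {
      u[k] = x[3*ip+k] - x[3*ic+k];
      v[k] = x[3*iq+k] - x[3*ic+k];
      ru2 += u[k]*u[k]; rv2 += v[k]*v[k]; uv += u[k]*v[k];
    }
    const double ru = std::sqrt(ru2), rv = std::sqrt(rv2);
    double ct = uv / (ru * rv);
    if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
    const double th = std::acos(ct);
    double st = std::sqrt(1.0 - ct * ct);
    if (st < 1e-8) st = 1e-8;

    // smooth switch on each flanking bond: S(r) = (1 - tanh((r - rc)/w)) / 2
    const double t1 = std::tanh((ru - p.rc1[a]) / p.sw_w);
    const double t2 = std::tanh((rv - p.rc2[a]) / p.sw_w);
    const double s1 = 0.5 * (1.0 - t1), s2 = 0.5 * (1.0 - t2);
    const double ds1 = -0.5 * (1.0 - t1 * t1) / p.sw_w;
    const double ds2 = -0.5 * (1.0 - t2 * t2) / p.sw_w;

    const double dth = th - p.th0[a];
    const double eang = 0.5 * p.kth[a] * dth * dth;
    E += eang * s1 * s2;

    // d(theta)/d(atom) via d(cos theta)
    const double pref = -1.0 / st;                 // dtheta/dcos
    const double fac = p.kth[a] * dth * s1 * s2;   // dE/dtheta (switched)
    for (int k = 0; k < 3; ++k) {
      const double dcp = (v[k] / rv - ct * u[k] / ru) / ru; // dcos/du_k
      const double dcq = (u[k] / ru - ct * v[k] / rv) / rv;
      const double gp = fac * pref * dcp;
      const double gq = fac * pref * dcq;
      g[3*ip+k] += gp;
      g[3*iq+k] += gq;
      g[3*ic+k] -= gp + gq;
      // switch derivatives act along the bond vectors
      const double w1 = eang * ds1 * s2 * u[k] / ru;
      const double w2 = eang * s1 * ds2 * v[k] / rv;
      g[3*ip+k] += w1;
      g[3*ic+k] -= w1;
      g[3*iq+k] += w2;
      g[3*ic+k] -= w2;
    }
  }
  return E;
}

// [[Rcpp::export]]
List toy_eval_cpp(NumericMatrix pos, List params) {
  const int n = pos.nrow();
  PesParams p = unpack(params, n);
  std::vector<double> x(3 * n), g(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3*i+k] = pos(i, k);
  const double E = eval_pes(p, x.data(), g.data());
  NumericMatrix grad(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) grad(i, k) = g[3*i+k];
  return List::create(_["energy"] = E, _["gradient"] = grad);
}

// Velocity-Verlet propagation on the toy surface.
// thermo_stride = 0 -> NVE; > 0 -> velocity rescaling to T_target every
// thermo_stride steps using dof degrees of freedom.
// [[Rcpp::export]]
List toy_propagate_cpp(NumericMatrix pos, NumericMatrix vel, NumericVector masses,
                       List params, double dt, int n_steps, int sample_stride,
                       int thermo_stride, double T_target, double dof, double t0) {
  const int n = pos.nrow();
  PesParams p = unpack(params, n);
  std::vector<double> x(3 * n), v(3 * n), g(3 * n), m(n);
  for (int i = 0; i < n; ++i) {
    m[i] = masses[i];
    for (int k = 0; k < 3; ++k) { x[3*i+k] = pos(i, k); v[3*i+k] = vel(i, k); }
  }
  const int n_frames = n_steps / sample_stride + 1;
  NumericVector out_pos(Dimension(n, 3, n_frames));
  NumericVector out_vel(Dimension(n, 3, n_frames));
  NumericVector times(n_frames), energies(n_frames);
  bool ok = true;

  double pe = eval_pes(p, x.data(), g.data());
  int frame = 0;
  auto store = [&](int step) {
    double ke = 0.0;
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) ke += 0.5 * m[i] * v[3*i+k] * v[3*i+k];
    ke /= EV_AA;
    times[frame] = t0 + step * dt;
    energies[frame] = pe + ke;
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) {
        out_pos[i + n * k + 3 * n * frame] = x[3*i+k];
        out_vel[i + n * k + 3 * n * frame] = v[3*i+k];
      }
    ++frame;
  };
  store(0);

  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i) {
      const double c = -0.5 * dt * EV_AA / m[i];
      for (int k = 0; k < 3; ++k) {
        v[3*i+k] += c * g[3*i+k];
        x[3*i+k] += dt * v[3*i+k];
      }
    }
    pe = eval_pes(p, x.data(), g.data());
    if (!std::isfinite(pe)) { ok = false; break; }
    for (int i = 0; i < n; ++i) {
      const double c = -0.5 * dt * EV_AA / m[i];
      for (int k = 0; k < 3; ++k) v[3*i+k] += c * g[3*i+k];
    }
    if (thermo_stride > 0 && step % thermo_stride == 0) {
      double ke = 0.0;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) ke += 0.5 * m[i] * v[3*i+k] * v[3*i+k];
      ke /= EV_AA;
      const double T_inst = 2.0 * ke / (dof * KB_EV);
      if (T_inst > 0.0) {
        const double s = std::sqrt(T_target / T_inst);
        for (int i = 0; i < 3 * n; ++i) v[i] *= s;
      }
    }
    if (step % sample_stride == 0) store(step);
  }

  if (frame < n_frames) { // aborted: truncate
    times = times[Range(0, frame - 1)];
    energies = energies[Range(0, frame - 1)];
    NumericVector tp(Dimension(n, 3, frame)), tv(Dimension(n, 3, frame));
    for (int q = 0; q < n * 3 * frame; ++q) { tp[q] = out_pos[q]; tv[q] = out_vel[q]; }
    out_pos = tp; out_vel = tv;
  }
  return List::create(_["times"] = times, _["positions"] = out_pos,
                      _["velocities"] = out_vel, _["energies"] = energies,
                      _["ok"] = ok);
}

// Connected components of the graph with edges d(i,j) <= cutoff (union-find).
// Labels are 1-based, numbered in order of each component's smallest member.
// [[Rcpp::export]]
IntegerVector fragment_labels_cpp(NumericMatrix pos, double cutoff) {
  const int n = pos.nrow();
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
    return i;
  };
  const double c2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        const double d = pos(i, k) - pos(j, k);
        d2 += d * d;
      }
      if (d2 <= c2) {
        const int ri = find(i), rj = find(j);
        if (ri != rj) parent[std::max(ri, rj)] = std::min(ri, rj);
      }
    }
  IntegerVector lab(n);
  std::vector<int> relabel(n, 0);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    const int r = find(i);
    if (relabel[r] == 0) relabel[r] = ++next;
    lab[i] = relabel[r];
  }
  return lab;
}
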