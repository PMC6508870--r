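// Newton-Euler forward dynamics of a rigid-body vertebral chain coupled by
// 6-DoF Kelvin-Voigt bushing elements, integrated with fixed-step RK4.
//
// Conventions (shared with the R side):
//  * world frame: x anterior, y superior, z = x cross y (right-handed);
//  * per-body generalized coordinates are deviations from the build (rest)
//    pose: 3 world translations of the COM and a body X-Y-Z Euler-angle
//    triplet applied in the world frame, R_body = Rx(a)Ry(b)Rz(c) * R_rest;
//  * rotations stay well below 1 rad over the few-ms impact windows this
//    package simulates, so Euler-angle rates are identified with the world
//    angular velocity (error is O(angle^2));
//  * constrained DoF are masked out of the state entirely.
//
// The hot path uses fixed-size Armadillo types and preallocated workspaces:
// the system is tiny (<= 40 states) and is evaluated ~2e4 times per
// simulated window inside optimisation loops.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;
typedef arma::mat33 mat33;
typedef arma::vec3 vec3;

static mat33 rot_x(double a) {
  mat33 R;
  R.eye();
  R(1, 1) = std::cos(a); R(1, 2) = -std::sin(a);
  R(2, 1) = std::sin(a); R(2, 2) =  std::cos(a);
  return R;
}
static mat33 rot_y(double a) {
  mat33 R;
  R.eye();
  R(0, 0) =  std::cos(a); R(0, 2) = std::sin(a);
  R(2, 0) = -std::sin(a); R(2, 2) = std::cos(a);
  return R;
}
static mat33 rot_z(double a) {
  mat33 R;
  R.eye();
  R(0, 0) = std::cos(a); R(0, 1) = -std::sin(a);
  R(1, 0) = std::sin(a); R(1, 1) =  std::cos(a);
  return R;
}
static mat33 euler_xyz(const vec3& ang) {
  return rot_x(ang(0)) * rot_y(ang(1)) * rot_z(ang(2));
}
// Inverse of euler_xyz: R = Rx(a) Ry(b) Rz(c).
static vec3 euler_from_R(const mat33& R) {
  vec3 ang;
  ang(1) = std::asin(std::max(-1.0, std::min(1.0, R(0, 2))));
  ang(0) = std::atan2(-R(1, 2), R(2, 2));
  ang(2) = std::atan2(-R(0, 1), R(0, 0));
  return ang;
}
static inline vec3 cross3(const vec3& a, const vec3& b) {
  vec3 c;
  c(0) = a(1) * b(2) - a(2) * b(1);
  c(1) = a(2) * b(0) - a(0) * b(2);
  c(2) = a(0) * b(1) - a(1) * b(0);
  return c;
}
// Solve the symmetric positive-definite 3x3 system I x = t (Cramer's rule;
// the inertia tensors are SPD by construction).
static inline vec3 solve33(const mat33& A, const vec3& t) {
  const double a = A(0,0), b = A(0,1), c = A(0,2);
  const double d = A(1,1), e = A(1,2), f = A(2,2);
  const double A11 = d*f - e*e, A12 = c*e - b*f, A13 = b*e - c*d;
  const double det = a*A11 + b*A12 + c*A13;
  const double A22 = a*f - c*c, A23 = b*c - a*e, A33 = a*d - b*b;
  vec3 x;
  x(0) = (A11*t(0) + A12*t(1) + A13*t(2)) / det;
  x(1) = (A12*t(0) + A22*t(1) + A23*t(2)) / det;
  x(2) = (A13*t(0) + A23*t(1) + A33*t(2)) / det;
  return x;
}

struct Joint {
  int caudal, cranial;          // 0-based body indices
  vec3 o1, o2;                  // frame origins in body frames (rel. COM)
  mat33 A1, A2;                 // body-frame -> joint-frame rotations
  vec3 kt, bt, kr, br;          // stiffness/damping, translational/rotational
};

struct Chain {
  int n_bodies, n_free, n_joints;
  std::vector<double> mass;
  std::vector<mat33> inertia;
  std::vector<vec3> rest_pos;
  std::vector<mat33> rest_rot;
  std::vector<std::array<int, 6> > qidx;  // per body: index into q or -1
  std::vector<vec3> const_force;
  vec3 gravity;
  int load_body;                // 0-based, -1 none
  vec3 load_dir;
  std::vector<Joint> joints;
  // workspaces (resized once per entry call)
  std::vector<vec3> pos, vel, omg;
  std::vector<mat33> R;
  std::vector<vec3> F, T;
};

static Chain parse_chain(const List& model) {
  Chain ch;
  vec mass = as<vec>(model["mass"]);
  ch.n_bodies = mass.n_elem;
  cube inertia = as<cube>(model["inertia"]);
  mat rest_pos = as<mat>(model["rest_pos"]);
  cube rest_rot = as<cube>(model["rest_rot"]);
  arma::imat fm = as<arma::imat>(model["free_mask"]);
  mat cf = as<mat>(model["const_force"]);
  ch.gravity = as<vec>(model["gravity"]);
  ch.load_body = as<int>(model["load_body"]) - 1;
  ch.load_dir = as<vec>(model["load_dir"]);
  int k = 0;
  for (int b = 0; b < ch.n_bodies; ++b) {
    ch.mass.push_back(mass(b));
    ch.inertia.push_back(inertia.slice(b));
    ch.rest_pos.push_back(rest_pos.col(b));
    ch.rest_rot.push_back(rest_rot.slice(b));
    ch.const_force.push_back(cf.col(b));
    std::array<int, 6> qi;
    for (int d = 0; d < 6; ++d) qi[d] = fm(d, b) ? k++ : -1;
    ch.qidx.push_back(qi);
  }
  ch.n_free = k;
  List js = model["joints"];
  ch.n_joints = js.size();
  for (int j = 0; j < ch.n_joints; ++j) {
    List jj = js[j];
    Joint J;
    J.caudal = as<int>(jj["caudal"]) - 1;
    J.cranial = as<int>(jj["cranial"]) - 1;
    J.o1 = as<vec>(jj["o1"]); J.o2 = as<vec>(jj["o2"]);
    J.A1 = as<mat>(jj["A1"]); J.A2 = as<mat>(jj["A2"]);
    vec k6 = as<vec>(jj["k"]), b6 = as<vec>(jj["b"]);
    J.kt = k6.subvec(0, 2); J.kr = k6.subvec(3, 5);
    J.bt = b6.subvec(0, 2); J.br = b6.subvec(3, 5);
    ch.joints.push_back(J);
  }
  ch.pos.resize(ch.n_bodies); ch.vel.resize(ch.n_bodies);
  ch.omg.resize(ch.n_bodies); ch.R.resize(ch.n_bodies);
  ch.F.resize(ch.n_bodies); ch.T.resize(ch.n_bodies);
  return ch;
}

// Fill the pose/velocity workspaces from a packed state.
static void body_kinematics(Chain& ch, const double* q, const double* u) {
  for (int b = 0; b < ch.n_bodies; ++b) {
    vec3 dp, ang, v, w;
    dp.zeros(); ang.zeros(); v.zeros(); w.zeros();
    const std::array<int, 6>& qi = ch.qidx[b];
    for (int d = 0; d < 3; ++d) {
      if (qi[d] >= 0) { dp(d) = q[qi[d]]; v(d) = u[qi[d]]; }
      if (qi[d + 3] >= 0) { ang(d) = q[qi[d + 3]]; w(d) = u[qi[d + 3]]; }
    }
    ch.pos[b] = ch.rest_pos[b] + dp;
    ch.vel[b] = v;
    ch.omg[b] = w;
    if (ang(0) == 0.0 && ang(1) == 0.0 && ang(2) == 0.0) {
      ch.R[b] = ch.rest_rot[b];
    } else {
      ch.R[b] = euler_xyz(ang) * ch.rest_rot[b];
    }
  }
}

// Per-joint state: deflection, rate, and bushing force/torque on the cranial
// body in the joint frame. Requires body_kinematics() to have run.
static void joint_state(const Chain& ch, int j,
                        vec3& dt, vec3& dr, vec3& dtdot, vec3& wrel,
                        vec3& Fj, vec3& Tj, mat33& G1, vec3& x1, vec3& x2) {
  const Joint& J = ch.joints[j];
  const mat33& Rca = ch.R[J.caudal];
  const mat33& Rcr = ch.R[J.cranial];
  G1 = Rca * J.A1;
  mat33 G2 = Rcr * J.A2;
  vec3 r1 = Rca * J.o1, r2 = Rcr * J.o2;
  x1 = ch.pos[J.caudal] + r1;
  x2 = ch.pos[J.cranial] + r2;
  const vec3& wca = ch.omg[J.caudal];
  const vec3& wcr = ch.omg[J.cranial];
  vec3 v1 = ch.vel[J.caudal] + cross3(wca, r1);
  vec3 v2 = ch.vel[J.cranial] + cross3(wcr, r2);
  vec3 sep = x2 - x1;
  dt = G1.t() * sep;
  dr = euler_from_R(mat33(G1.t() * G2));
  dtdot = G1.t() * (v2 - v1 - cross3(wca, sep));
  wrel = G1.t() * (wcr - wca);
  Fj = -(J.kt % dt + J.bt % dtdot);
  Tj = -(J.kr % dr + J.br % wrel);
}

// udot for the current kinematic workspace state.
static void accelerations(Chain& ch, double f_applied, double* udot) {
  for (int b = 0; b < ch.n_bodies; ++b) {
    ch.F[b] = ch.mass[b] * ch.gravity + ch.const_force[b];
    ch.T[b].zeros();
  }
  if (ch.load_body >= 0) ch.F[ch.load_body] += ch.load_dir * f_applied;

  vec3 dt, dr, dtdot, wrel, Fj, Tj, x1, x2;
  mat33 G1;
  for (int j = 0; j < ch.n_joints; ++j) {
    const Joint& J = ch.joints[j];
    joint_state(ch, j, dt, dr, dtdot, wrel, Fj, Tj, G1, x1, x2);
    vec3 Fw = G1 * Fj, Tw = G1 * Tj;
    ch.F[J.cranial] += Fw;
    ch.T[J.cranial] += Tw + cross3(vec3(x2 - ch.pos[J.cranial]), Fw);
    ch.F[J.caudal] -= Fw;
    ch.T[J.caudal] += -Tw - cross3(vec3(x1 - ch.pos[J.caudal]), Fw);
  }

  for (int b = 0; b < ch.n_bodies; ++b) {
    const std::array<int, 6>& qi = ch.qidx[b];
    bool any_rot = qi[3] >= 0 || qi[4] >= 0 || qi[5] >= 0;
    vec3 a = ch.F[b] / ch.mass[b];
    vec3 wdot;
    if (any_rot) {
      mat33 Iw = ch.R[b] * ch.inertia[b] * ch.R[b].t();
      const vec3& w = ch.omg[b];
      wdot = solve33(Iw, vec3(ch.T[b] - cross3(w, vec3(Iw * w))));
    }
    for (int d = 0; d < 3; ++d) {
      if (qi[d] >= 0) udot[qi[d]] = a(d);
      if (qi[d + 3] >= 0) udot[qi[d + 3]] = wdot(d);
    }
  }
}

// [[Rcpp::export]]
arma::vec chain_derivative_cpp(List model, arma::vec q, arma::vec u,
                               double f_applied) {
  Chain ch = parse_chain(model);
  if ((int)q.n_elem != ch.n_free || (int)u.n_elem != ch.n_free)
    stop("state dimension does not match the model's free coordinates");
  body_kinematics(ch, q.memptr(), u.memptr());
  vec udot(ch.n_free);
  accelerations(ch, f_applied, udot.memptr());
  return udot;
}

static void record_joint_row(Chain& ch, int j, double* row18) {
  vec3 dt, dr, dtdot, wrel, Fj, Tj, x1, x2;
  mat33 G1;
  joint_state(ch, j, dt, dr, dtdot, wrel, Fj, Tj, G1, x1, x2);
  for (int d = 0; d < 3; ++d) {
    row18[d] = dt(d);       row18[3 + d] = dr(d);
    row18[6 + d] = dtdot(d); row18[9 + d] = wrel(d);
    row18[12 + d] = Fj(d);  row18[15 + d] = Tj(d);
  }
}

// [[Rcpp::export]]
List joint_states_cpp(List model, arma::vec q, arma::vec u) {
  Chain ch = parse_chain(model);
  if ((int)q.n_elem != ch.n_free)
    stop("state dimension does not match the model's free coordinates");
  body_kinematics(ch, q.memptr(), u.memptr());
  mat out(ch.n_joints, 18);
  std::vector<double> row(18);
  for (int j = 0; j < ch.n_joints; ++j) {
    record_joint_row(ch, j, row.data());
    for (int c = 0; c < 18; ++c) out(j, c) = row[c];
  }
  return List::create(_["joint"] = out);
}

// [[Rcpp::export]]
List body_poses_cpp(List model, arma::vec q) {
  Chain ch = parse_chain(model);
  vec u(ch.n_free, arma::fill::zeros);
  body_kinematics(ch, q.memptr(), u.memptr());
  mat pos(3, ch.n_bodies);
  cube R(3, 3, ch.n_bodies);
  for (int b = 0; b < ch.n_bodies; ++b) {
    pos.col(b) = ch.pos[b];
    R.slice(b) = ch.R[b];
  }
  return List::create(_["pos"] = pos, _["R"] = R);
}

// Fixed-step RK4 over n_steps of size h, with the applied load linearly
// interpolated from `force` sampled at force_fs starting at t = 0.
// Records state and joint series every `record_every` steps (and step 0).
// [[Rcpp::export]]
List chain_simulate_cpp(List model, arma::vec q0, arma::vec u0,
                        arma::vec force, double force_fs,
                        double h, int n_steps, int record_every) {
  Chain ch = parse_chain(model);
  if ((int)q0.n_elem != ch.n_free || (int)u0.n_elem != ch.n_free)
    stop("state dimension does not match the model's free coordinates");
  const int nf = ch.n_free, nj = ch.n_joints;
  const int n_rec = n_steps / record_every + 1;

  std::vector<double> q(q0.begin(), q0.end()), u(u0.begin(), u0.end());
  std::vector<double> q2(nf), u2(nf), q3(nf), u3(nf), q4(nf), u4(nf);
  std::vector<double> a1(nf), a2(nf), a3(nf), a4(nf);
  mat Q(n_rec, nf), U(n_rec, nf);
  vec times(n_rec);
  std::vector<mat> jser(nj, mat(n_rec, 18));
  bool diverged = false;
  int rec = 0;

  const double hf = 1.0 / force_fs;
  const int nF = force.n_elem;
  const double* fp = force.memptr();
  auto fload = [&](double t) -> double {
    if (nF == 0) return 0.0;
    double s = t / hf;
    int i = (int)std::floor(s);
    if (i < 0) return fp[0];
    if (i >= nF - 1) return fp[nF - 1];
    double w = s - i;
    return fp[i] * (1.0 - w) + fp[i + 1] * w;
  };

  std::vector<double> row(18);
  auto record = [&](int step) {
    times(rec) = step * h;
    for (int k = 0; k < nf; ++k) { Q(rec, k) = q[k]; U(rec, k) = u[k]; }
    body_kinematics(ch, q.data(), u.data());
    for (int j = 0; j < nj; ++j) {
      record_joint_row(ch, j, row.data());
      for (int c = 0; c < 18; ++c) jser[j](rec, c) = row[c];
    }
    ++rec;
  };

  record(0);
  for (int step = 0; step < n_steps; ++step) {
    const double t = step * h;
    body_kinematics(ch, q.data(), u.data());
    accelerations(ch, fload(t), a1.data());
    for (int k = 0; k < nf; ++k) {
      q2[k] = q[k] + 0.5 * h * u[k];
      u2[k] = u[k] + 0.5 * h * a1[k];
    }
    body_kinematics(ch, q2.data(), u2.data());
    accelerations(ch, fload(t + 0.5 * h), a2.data());
    for (int k = 0; k < nf; ++k) {
      q3[k] = q[k] + 0.5 * h * u2[k];
      u3[k] = u[k] + 0.5 * h * a2[k];
    }
    body_kinematics(ch, q3.data(), u3.data());
    accelerations(ch, fload(t + 0.5 * h), a3.data());
    for (int k = 0; k < nf; ++k) {
      q4[k] = q[k] + h * u3[k];
      u4[k] = u[k] + h * a3[k];
    }
    body_kinematics(ch, q4.data(), u4.data());
    accelerations(ch, fload(t + h), a4.data());
    bool finite = true;
    for (int k = 0; k < nf; ++k) {
      q[k] += (h / 6.0) * (u[k] + 2.0 * u2[k] + 2.0 * u3[k] + u4[k]);
      u[k] += (h / 6.0) * (a1[k] + 2.0 * a2[k] + 2.0 * a3[k] + a4[k]);
      if (!std::isfinite(q[k]) || !std::isfinite(u[k])) finite = false;
    }
    if (!finite) { diverged = true; break; }
    if ((step + 1) % record_every == 0) record(step + 1);
  }

  if (diverged && rec > 0) {
    Q = Q.rows(0, rec - 1); U = U.rows(0, rec - 1);
    times = times.subvec(0, rec - 1);
    for (int j = 0; j < nj; ++j) jser[j] = jser[j].rows(0, rec - 1);
  }
  List out_j(nj);
  for (int j = 0; j < nj; ++j) out_j[j] = jser[j];
  return List::create(_["times"] = times, _["Q"] = Q, _["U"] = U,
                      _["joints"] = out_j, _["diverged"] = diverged);
}
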