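#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Problem {
  // fixed landmarks
  double fpx, fpy, fd0x, fd0y;
  // moving landmarks (already mirrored if a pre-flip applies)
  double mpx, mpy, mmidx, mmidy;
  // unit fixed diaphysis direction and its normal
  double ifx, ify, nfx, nfy;
  // moving diaphysis difference, pre-divided by its (untransformed) norm
  double vmx, vmy;
  // weights and targets
  double wx, wy, wa, wo, wp, d, w;
  // rotation centre and angle scale
  double cx, cy, r;
};

// energy at internal parameters u = (theta * r, ax, ay); the transform is
// p -> R(theta) * (p - c) + c + (ax, ay)
inline double energy(const Problem &P, const double *u,
                     double *ca_out = nullptr, double *co_out = nullptr,
                     double *cp_out = nullptr) {
  const double th = u[0] / P.r, ax = u[1], ay = u[2];
  const double cs = std::cos(th), sn = std::sin(th);

  const double qpx = cs * (P.mpx - P.cx) - sn * (P.mpy - P.cy) + P.cx + ax;
  const double qpy = sn * (P.mpx - P.cx) + cs * (P.mpy - P.cy) + P.cy + ay;
  const double ca = P.wx * std::fabs(P.fpx - qpx) +
                    P.wy * std::fabs(P.d - P.fpy + qpy);

  const double imx = cs * P.vmx - sn * P.vmy;
  const double imy = sn * P.vmx + cs * P.vmy;
  const double co = std::sqrt((P.ifx - imx) * (P.ifx - imx) +
                              (P.ify - imy) * (P.ify - imy));

  const double qmx = cs * (P.mmidx - P.cx) - sn * (P.mmidy - P.cy) + P.cx + ax;
  const double qmy = sn * (P.mmidx - P.cx) + cs * (P.mmidy - P.cy) + P.cy + ay;
  const double dist = std::fabs((qmx - P.fd0x) * P.nfx + (qmy - P.fd0y) * P.nfy);
  const double cp = std::fabs(dist - P.w);

  if (ca_out) { *ca_out = ca; *co_out = co; *cp_out = cp; }
  return P.wa * ca + P.wo * co + P.wp * cp;
}

} // namespace

// Gradient descent on the three-constraint alignment energy.
// Lf, Lm: 3 x 2 landmark matrices, rows (L_p, L_d0, L_d1), mm.
// weights: (w_x, w_y, w_a, w_o, w_p). ctr: rotation centre. r: angle scale.
// u0: initial (theta_rad, tx, ty) in the centred parameterization.
// Returns the best-seen iterate, its energy, the initial energy and a
// strided trace (iter, E, C_a, C_o, C_p, theta, ax, ay), whose last row is
// the returned iterate.
// [[Rcpp::export]]
List pose_gd_cpp(NumericMatrix Lf, NumericMatrix Lm, NumericVector weights,
                 double d, double w, double lr, int iterations,
                 double fd_step, NumericVector ctr, double r,
                 NumericVector u0, int trace_every) {
  Problem P;
  P.fpx = Lf(0, 0); P.fpy = Lf(0, 1);
  P.fd0x = Lf(1, 0); P.fd0y = Lf(1, 1);
  P.mpx = Lm(0, 0); P.mpy = Lm(0, 1);
  P.mmidx = 0.5 * (Lm(1, 0) + Lm(2, 0));
  P.mmidy = 0.5 * (Lm(1, 1) + Lm(2, 1));

  const double vfx = Lf(1, 0) - Lf(2, 0), vfy = Lf(1, 1) - Lf(2, 1);
  const double nf = std::sqrt(vfx * vfx + vfy * vfy);
  const double vmx0 = Lm(1, 0) - Lm(2, 0), vmy0 = Lm(1, 1) - Lm(2, 1);
  const double nm = std::sqrt(vmx0 * vmx0 + vmy0 * vmy0);
  if (nf == 0.0 || nm == 0.0) stop("zero-length diaphysis segment");
  P.ifx = vfx / nf; P.ify = vfy / nf;
  P.nfx = -P.ify; P.nfy = P.ifx;
  P.vmx = vmx0 / nm; P.vmy = vmy0 / nm;

  P.wx = weights[0]; P.wy = weights[1];
  P.wa = weights[2]; P.wo = weights[3]; P.wp = weights[4];
  P.d = d; P.w = w;
  P.cx = ctr[0]; P.cy = ctr[1]; P.r = r;

  // internal coordinates: scaled angle first
  double u[3] = {u0[0] * r, u0[1], u0[2]};
  double ca, co, cp;
  const double E0 = energy(P, u, &ca, &co, &cp);
  if (!std::isfinite(E0)) stop("non-finite energy at initialization");

  double best[3] = {u[0], u[1], u[2]};
  double Ebest = E0;

  const int nrec = iterations / trace_every + 2;
  NumericMatrix trace(nrec, 8);
  int rec = 0;
  trace(rec, 0) = 0; trace(rec, 1) = E0; trace(rec, 2) = ca;
  trace(rec, 3) = co; trace(rec, 4) = cp;
  trace(rec, 5) = u[0] / r; trace(rec, 6) = u[1]; trace(rec, 7) = u[2];
  ++rec;

  double up[3], um[3], g[3];
  for (int it = 1; it <= iterations; ++it) {
    for (int k = 0; k < 3; ++k) {
      up[0] = u[0]; up[1] = u[1]; up[2] = u[2];
      um[0] = u[0]; um[1] = u[1]; um[2] = u[2];
      up[k] += fd_step; um[k] -= fd_step;
      g[k] = (energy(P, up) - energy(P, um)) / (2.0 * fd_step);
    }
    for (int k = 0; k < 3; ++k) u[k] -= lr * g[k];
    const double E = energy(P, u, &ca, &co, &cp);
    if (!std::isfinite(E))
      stop("non-finite energy at iteration %d", it);
    if (E < Ebest) {
      Ebest = E;
      best[0] = u[0]; best[1] = u[1]; best[2] = u[2];
    }
    if (it % trace_every == 0 && rec < nrec - 1) {
      trace(rec, 0) = it; trace(rec, 1) = E; trace(rec, 2) = ca;
      trace(rec, 3) = co; trace(rec, 4) = cp;
      trace(rec, 5) = u[0] / r; trace(rec, 6) = u[1]; trace(rec, 7) = u[2];
      ++rec;
    }
  }
  // final record: the returned (best-seen) iterate
  energy(P, best, &ca, &co, &cp);
  trace(rec, 0) = iterations; trace(rec, 1) = Ebest; trace(rec, 2) = ca;
  trace(rec, 3) = co; trace(rec, 4) = cp;
  trace(rec, 5) = best[0] / r; trace(rec, 6) = best[1]; trace(rec, 7) = best[2];
  ++rec;

  return List::create(
    _["best"] = NumericVector::create(best[0] / r, best[1], best[2]),
    _["E_best"] = Ebest, _["E0"] = E0,
    _["trace"] = trace(Range(0, rec - 1), Range(0, 7)));
}
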