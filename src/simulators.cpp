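// Simulation cores for the self-activating gene motif under bounded
// extrinsic noise on the deactivation rate b0(t) = b0 * (1 + xi(t)).
//
// All samplers consume R's RNG stream (so set.seed() in R gives
// byte-identical runs) and receive the noise path xi as a vector sampled
// on a uniform grid of step dt_noise; xi(t) is piecewise constant on
// [k*dt_noise, (k+1)*dt_noise).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline double xi_at(const NumericVector& xi, double dt, double t) {
  R_xlen_t k = (R_xlen_t)(t / dt);
  if (k < 0) k = 0;
  if (k >= xi.size()) k = xi.size() - 1;
  return xi[k];
}

// time-weighted occupation statistics of the protein variable, with the
// first `burn_in` time units discarded
struct Acc {
  double burn_in, lo, hi, sum_w, sum_x, sum_x2;
  int nbins;
  std::vector<double> hist;
  Acc(double burn_in_, double lo_, double hi_, int nbins_)
    : burn_in(burn_in_), lo(lo_), hi(hi_),
      sum_w(0), sum_x(0), sum_x2(0), nbins(nbins_), hist(nbins_, 0.0) {}
  void add(double x, double t0, double t1) {
    double w = t1 - std::max(t0, burn_in);
    if (w <= 0) return;
    sum_w += w; sum_x += x * w; sum_x2 += x * x * w;
    int b = (int)std::floor((x - lo) / (hi - lo) * nbins);
    if (b < 0) b = 0;
    if (b >= nbins) b = nbins - 1;
    hist[b] += w;
  }
};

// trajectory recorder on a uniform grid
struct Rec {
  double record_dt, next_t;
  std::vector<double> t, g, x, xiv;
  Rec(double record_dt_) : record_dt(record_dt_), next_t(0.0) {}
  // record all grid times in [t0, t1); state (gv, xv) constant there
  void span(double t1, double gv, double xv,
            const NumericVector& xi, double dt_noise) {
    while (next_t < t1 - 1e-12) {
      t.push_back(next_t); g.push_back(gv); x.push_back(xv);
      xiv.push_back(xi_at(xi, dt_noise, next_t));
      next_t += record_dt;
    }
  }
  void final_point(double t_end, double gv, double xv,
                   const NumericVector& xi, double dt_noise) {
    t.push_back(t_end); g.push_back(gv); x.push_back(xv);
    xiv.push_back(xi_at(xi, dt_noise, t_end));
  }
};

static List pack(const Rec& rec, const Acc& acc) {
  return List::create(
    _["time"] = wrap(rec.t), _["gene"] = wrap(rec.g),
    _["protein"] = wrap(rec.x), _["xi"] = wrap(rec.xiv),
    _["sum_w"] = acc.sum_w, _["sum_x"] = acc.sum_x, _["sum_x2"] = acc.sum_x2,
    _["hist"] = wrap(acc.hist));
}

// Euler-Maruyama path of the Cai-Lin bounded diffusion
//   dxi = -(xi/tau) dt + sqrt((B^2 - xi^2) / (tau (1+z))) dW
// overshoots are clamped back inside (-B, B); the diffusion coefficient
// vanishes at the bound so the exact process never crosses it
// [[Rcpp::export]]
NumericVector cpp_cai_lin_path(double B, double tau, double z,
                               double dt, R_xlen_t n_steps, double xi0) {
  NumericVector out(n_steps + 1);
  double eps = 1e-12 * B;
  double x = xi0;
  if (x >  B - eps) x =  B - eps;
  if (x < -B + eps) x = -B + eps;
  out[0] = x;
  // sub-step the Euler-Maruyama integration: the grid step dt couples the
  // noise to the simulators, but the SDE is integrated 16 times finer to
  // keep the stationary-law discretisation bias well below Monte-Carlo
  // resolution (the diffusion coefficient is stiff near the boundaries)
  const int n_sub = 16;
  double h = dt / n_sub;
  double sdt = std::sqrt(h);
  for (R_xlen_t i = 1; i <= n_steps; ++i) {
    for (int k = 0; k < n_sub; ++k) {
      double diff2 = (B * B - x * x) / (tau * (1.0 + z));
      if (diff2 < 0) diff2 = 0;
      x += -(x / tau) * h + std::sqrt(diff2) * sdt * norm_rand();
      if (x >  B - eps) x =  B - eps;
      if (x < -B + eps) x = -B + eps;
    }
    out[i] = x;
  }
  return out;
}

// Regime 1: exact time-inhomogeneous birth-death process for (G, Y).
// method 0 = quasi-static (xi held constant within each noise-grid cell,
// standard SSA per cell); method 1 = thinning with bound b0*(1+B)*G on the
// deactivation propensity.
// [[Rcpp::export]]
List cpp_sim_regime1(int n, double s, double d, double c0, double c2,
                     double b0, double B, double omega,
                     NumericVector xi, double dt_noise,
                     double t_end, double burn_in,
                     int G0, double Y0, int method,
                     double record_dt, double hist_lo, double hist_hi,
                     int hist_nbins) {
  Acc acc(burn_in, hist_lo, hist_hi, hist_nbins);
  Rec rec(record_dt);
  int G = G0;
  double Y = Y0;
  double t = 0.0;

  if (method == 0) {
    R_xlen_t k = 0;
    while (t < t_end) {
      double seg_end = std::min(((double)k + 1.0) * dt_noise, t_end);
      double xic = xi[std::min(k, xi.size() - 1)];
      double a1 = b0 * (1.0 + xic) * G;
      double a2 = c0 * (n - G);
      double a3 = c2 * Y * Y * (n - G) / (omega * omega);
      double a4 = s * omega * G;
      double a5 = d * Y;
      double tot = a1 + a2 + a3 + a4 + a5;
      double delta = (tot > 0) ? exp_rand() / tot : R_PosInf;
      if (t + delta >= seg_end) {
        rec.span(seg_end, G, Y, xi, dt_noise);
        acc.add(Y, t, seg_end);
        t = seg_end; ++k;
      } else {
        double tn = t + delta;
        rec.span(tn, G, Y, xi, dt_noise);
        acc.add(Y, t, tn);
        t = tn;
        double u = unif_rand() * tot;
        if      (u < a1)                 G -= 1;
        else if (u < a1 + a2)            G += 1;
        else if (u < a1 + a2 + a3)       G += 1;
        else if (u < a1 + a2 + a3 + a4)  Y += 1;
        else                             Y -= 1;
      }
    }
  } else {
    while (t < t_end) {
      double a1b = b0 * (1.0 + B) * G;
      double a2 = c0 * (n - G);
      double a3 = c2 * Y * Y * (n - G) / (omega * omega);
      double a4 = s * omega * G;
      double a5 = d * Y;
      double lam = a1b + a2 + a3 + a4 + a5;
      if (lam <= 0) {          // empty absorbing state cannot occur if c0>0
        rec.span(t_end, G, Y, xi, dt_noise);
        acc.add(Y, t, t_end);
        t = t_end; break;
      }
      double tn = std::min(t + exp_rand() / lam, t_end);
      rec.span(tn, G, Y, xi, dt_noise);
      acc.add(Y, t, tn);
      t = tn;
      if (t >= t_end) break;
      double a1 = b0 * (1.0 + xi_at(xi, dt_noise, t)) * G;
      double u = unif_rand() * lam;
      if      (u < a1)                 G -= 1;
      else if (u < a1 + a2)            G += 1;
      else if (u < a1 + a2 + a3)       G += 1;
      else if (u < a1 + a2 + a3 + a4)  Y += 1;
      else if (u < a1 + a2 + a3 + a4 + a5) Y -= 1;
      // else: thinned candidate, no event
    }
  }
  rec.final_point(t_end, G, Y, xi, dt_noise);
  return pack(rec, acc);
}

// Regime 2: protein birth-death with the fast-switching gene mean.
// gene_mode 0 = quasi-steady state <G> = n c(y) / (c(y) + b0(t));
// gene_mode 1 = finite-h relaxation d<G>/dt = c(y)(n - <G>) - b0(t)<G>,
// integrated piecewise-exactly on the noise grid.
// Birth events sampled by thinning with bound s*omega*n.
// [[Rcpp::export]]
List cpp_sim_regime2(int n, double s, double d, double c0, double c2,
                     double b0, NumericVector xi, double dt_noise,
                     double t_end, double burn_in,
                     double Y0, double Gm0, int gene_mode, double omega,
                     double record_dt, double hist_lo, double hist_hi,
                     int hist_nbins) {
  Acc acc(burn_in, hist_lo, hist_hi, hist_nbins);
  Rec rec(record_dt);
  double Y = Y0, Gm = Gm0, t = 0.0;

  auto qss = [&](double tt) {
    double y = Y / omega;
    double c = c0 + c2 * y * y;
    double b = b0 * (1.0 + xi_at(xi, dt_noise, tt));
    return n * c / (c + b);
  };
  // advance the relaxation ODE for <G> from t0 to t1 (Y constant there)
  auto relax_Gm = [&](double t0, double t1) {
    double y = Y / omega;
    double c = c0 + c2 * y * y;
    double tt = t0;
    while (tt < t1 - 1e-15) {
      R_xlen_t k = (R_xlen_t)(tt / dt_noise);
      double cell_end = std::min(((double)k + 1.0) * dt_noise, t1);
      double b = b0 * (1.0 + xi[std::min(k, xi.size() - 1)]);
      double rate = c + b;
      double ginf = n * c / rate;
      Gm = ginf + (Gm - ginf) * std::exp(-rate * (cell_end - tt));
      tt = cell_end;
    }
  };

  double birth_bound = s * omega * n;
  while (t < t_end) {
    double lam = birth_bound + d * Y;
    double tn = std::min(t + exp_rand() / lam, t_end);
    rec.span(tn, Gm, Y, xi, dt_noise);
    acc.add(Y, t, tn);
    if (gene_mode == 1) relax_Gm(t, tn); else Gm = qss(tn);
    t = tn;
    if (t >= t_end) break;
    double gm = (gene_mode == 1) ? Gm : qss(t);
    double birth = s * omega * gm;
    double death = d * Y;
    double u = unif_rand() * lam;
    if      (u < death)         Y -= 1;
    else if (u < death + birth) Y += 1;
  }
  rec.final_point(t_end, Gm, Y, xi, dt_noise);
  return pack(rec, acc);
}

// Regime 3: piecewise-deterministic process. Between gene jumps the
// protein density follows dy/dt = s*G - d*y (solved exactly); gene jumps
// fire at a1 = b0(t)G, a2 = c0(n-G), a3 = c2 y(t)^2 (n-G).
// method 0 = numerically inverted integrated hazard on the noise grid;
// method 1 = thinning with the flow bound max(y0, sG/d) for a3.
//
// Occupation integrals of y and y^2 along the exponential flow are closed
// form; the histogram is filled by sub-stepping the flow at hist_step.
struct Flow3 {
  double s, d;
  double yinf(double G) const { return s * G / d; }
  double at(double y0, double G, double u) const {
    double yi = yinf(G);
    return yi + (y0 - yi) * std::exp(-d * u);
  }
};

static void acc_flow(Acc& acc, const Flow3& fl, double y0, double G,
                     double t0, double t1, double hist_step) {
  if (t1 <= acc.burn_in) {
    return;
  }
  double a = fl.yinf(G), b = y0 - a, d = fl.d;
  double u0 = std::max(t0, acc.burn_in) - t0, u1 = t1 - t0;
  double e0 = std::exp(-d * u0), e1 = std::exp(-d * u1);
  double w = u1 - u0;
  acc.sum_w += w;
  acc.sum_x += a * w + b * (e0 - e1) / d;
  acc.sum_x2 += a * a * w + 2.0 * a * b * (e0 - e1) / d
              + b * b * (e0 * e0 - e1 * e1) / (2.0 * d);
  // histogram by sub-stepping
  double u = u0;
  while (u < u1) {
    double step = std::min(hist_step, u1 - u);
    double ymid = fl.at(y0, G, u + 0.5 * step);
    int bin = (int)std::floor((ymid - acc.lo) / (acc.hi - acc.lo) * acc.nbins);
    if (bin < 0) bin = 0;
    if (bin >= acc.nbins) bin = acc.nbins - 1;
    acc.hist[bin] += step;
    u += step;
  }
}

static void rec_flow(Rec& rec, const Flow3& fl, double y0, double G,
                     double t0, double t1,
                     const NumericVector& xi, double dt_noise) {
  while (rec.next_t < t1 - 1e-12) {
    rec.t.push_back(rec.next_t);
    rec.g.push_back(G);
    rec.x.push_back(fl.at(y0, G, rec.next_t - t0));
    rec.xiv.push_back(xi_at(xi, dt_noise, rec.next_t));
    rec.next_t += rec.record_dt;
  }
}

// [[Rcpp::export]]
List cpp_sim_regime3(int n, double s, double d, double c0, double c2,
                     double b0, double B, NumericVector xi, double dt_noise,
                     double t_end, double burn_in,
                     int G0, double y0, int method,
                     double record_dt, double hist_lo, double hist_hi,
                     int hist_nbins, double hist_step) {
  Acc acc(burn_in, hist_lo, hist_hi, hist_nbins);
  Rec rec(record_dt);
  Flow3 fl; fl.s = s; fl.d = d;
  int G = G0;
  double y = y0, t = 0.0;

  if (method == 1) {  // thinning
    while (t < t_end) {
      double ymax = std::max(y, fl.yinf(G));
      double lam = b0 * (1.0 + B) * G + c0 * (n - G)
                 + c2 * ymax * ymax * (n - G);
      double tn = (lam > 0) ? std::min(t + exp_rand() / lam, t_end) : t_end;
      rec_flow(rec, fl, y, G, t, tn, xi, dt_noise);
      acc_flow(acc, fl, y, G, t, tn, hist_step);
      double ynew = fl.at(y, G, tn - t);
      y = ynew; t = tn;
      if (t >= t_end) break;
      double a1 = b0 * (1.0 + xi_at(xi, dt_noise, t)) * G;
      double a2 = c0 * (n - G);
      double a3 = c2 * y * y * (n - G);
      double tot = a1 + a2 + a3;
      if (tot > lam * (1.0 + 1e-9))
        stop("thinning bound violated in regime-3 sampler");
      double u = unif_rand() * lam;
      if (u < tot) { if (u < a1) G -= 1; else G += 1; }
    }
  } else {            // integrated-hazard inversion, step = dt_noise
    double E = exp_rand(), H = 0.0;
    while (t < t_end) {
      double tn = std::min(t + dt_noise, t_end);
      double a1 = b0 * (1.0 + xi_at(xi, dt_noise, t)) * G;
      double a2 = c0 * (n - G);
      double a3 = c2 * y * y * (n - G);
      double tot = a1 + a2 + a3;
      double Hinc = tot * (tn - t);
      if (H + Hinc >= E && tot > 0) {
        double tj = t + (E - H) / tot;
        rec_flow(rec, fl, y, G, t, tj, xi, dt_noise);
        acc_flow(acc, fl, y, G, t, tj, hist_step);
        y = fl.at(y, G, tj - t); t = tj;
        double u = unif_rand() * tot;
        if (u < a1) G -= 1; else G += 1;
        E = exp_rand(); H = 0.0;
      } else {
        H += Hinc;
        rec_flow(rec, fl, y, G, t, tn, xi, dt_noise);
        acc_flow(acc, fl, y, G, t, tn, hist_step);
        y = fl.at(y, G, tn - t); t = tn;
      }
    }
  }
  rec.final_point(t_end, G, y, xi, dt_noise);
  return pack(rec, acc);
}

// Regime 4: mean-field ODE dy/dt = s n c(y)/(c(y) + b0(t)) - d y,
// fixed-step RK4 with xi held constant within each step.
// [[Rcpp::export]]
List cpp_sim_regime4(int n, double s, double d, double c0, double c2,
                     double b0, NumericVector xi, double dt_noise,
                     double t_end, double burn_in, double y0,
                     double dt_ode, double record_dt,
                     double hist_lo, double hist_hi, int hist_nbins) {
  Acc acc(burn_in, hist_lo, hist_hi, hist_nbins);
  Rec rec(record_dt);
  double y = y0, t = 0.0;
  auto f = [&](double yy, double b) {
    double c = c0 + c2 * yy * yy;
    return s * n * c / (c + b) - d * yy;
  };
  while (t < t_end - 1e-12) {
    double dt = std::min(dt_ode, t_end - t);
    double b = b0 * (1.0 + xi_at(xi, dt_noise, t));
    rec.span(t + dt, NA_REAL, y, xi, dt_noise);
    double k1 = f(y, b);
    double k2 = f(y + 0.5 * dt * k1, b);
    double k3 = f(y + 0.5 * dt * k2, b);
    double k4 = f(y + dt * k3, b);
    double ynew = y + dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (ynew < 0) ynew = 0;
    if (!std::isfinite(ynew)) stop("non-finite protein density in ODE step");
    acc.add(0.5 * (y + ynew), t, t + dt);
    y = ynew; t += dt;
  }
  rec.final_point(t_end, NA_REAL, y, xi, dt_noise);
  return pack(rec, acc);
}
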