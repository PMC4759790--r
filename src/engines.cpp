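// Event-driven simulation engines for the toggle / three-way switch.
//
// All engines share one propensity function and one packed parameter
// layout (see pack_params() on the R side):
//   [0] B  [1] gamma  [2] gamma0  [3] r  [4] r0  [5] K  [6] n
//   [7] regulation (0 toggle, 1 three-way)
//   [8] q0 [9] r1 [10] r2 [11] n1 [12] n2 [13] K1 [14] K2
//
// Model tags (discrete engines): 0 = GB, 1 = CB, 2 = NB, 3 = FM.
// Randomness comes from R's RNG so that set.seed() on the R side makes
// every trajectory bit-reproducible.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Params {
  double B, gamma, gamma0, r, r0, K, n;
  int reg;
  double q0, r1, r2, n1, n2, K1, K2;
};

static Params unpack(const NumericVector& p) {
  Params P;
  P.B = p[0]; P.gamma = p[1]; P.gamma0 = p[2]; P.r = p[3]; P.r0 = p[4];
  P.K = p[5]; P.n = p[6]; P.reg = (int) p[7];
  P.q0 = p[8]; P.r1 = p[9]; P.r2 = p[10]; P.n1 = p[11]; P.n2 = p[12];
  P.K1 = p[13]; P.K2 = p[14];
  return P;
}

// transcription propensity a(N_other, N_self), events per cell cycle
static inline double trans_rate(const Params& P, double Nother, double Nself) {
  if (P.reg == 0) {
    double f = 1.0 / (1.0 + std::pow(Nother / P.K, P.n));
    return P.K * (P.r0 + P.r * f);
  }
  double h1 = 1.0 / (1.0 + std::pow(Nself / P.K1, P.n1));
  double h2 = 1.0 / (1.0 + std::pow(Nother / P.K2, P.n2));
  return P.q0 * (1.0 + P.r1 * h1) * (1.0 + P.r2 * h2);
}

// exact sup of the propensity over the non-negative quadrant
static inline double rate_sup(const Params& P) {
  if (P.reg == 0) return P.K * (P.r0 + P.r);
  double f1 = std::max(1.0, 1.0 + P.r1), f2 = std::max(1.0, 1.0 + P.r2);
  return P.q0 * f1 * f2;
}

static inline double rgeom_mean(double B) {
  // geometric on {0,1,2,...} with mean B
  return R::rgeom(1.0 / (1.0 + B));
}

// ---------------------------------------------------------------------------
// Discrete-state Gillespie core
// ---------------------------------------------------------------------------

struct DiscreteSim {
  Params P;
  int model;              // 0 GB, 1 CB, 2 NB, 3 FM
  double NX, NY, mX, mY;  // copy numbers (mX,mY used by FM only)
  double t;
  double lastProdX, lastProdY;  // proteins added by the last event

  void init(double nx, double ny, double mx, double my, double t0) {
    NX = nx; NY = ny; mX = mx; mY = my; t = t0;
    lastProdX = lastProdY = 0.0;
  }

  // advance one reaction; returns dt (or -1 when all rates vanish)
  double step() {
    lastProdX = lastProdY = 0.0;
    double aX = trans_rate(P, NY, NX);
    double aY = trans_rate(P, NX, NY);
    double rates[8];
    int nch;
    if (model == 3) {  // FM: transcription, mRNA decay, translation, protein decay
      rates[0] = aX;                 rates[1] = aY;
      rates[2] = P.gamma * mX;       rates[3] = P.gamma * mY;
      rates[4] = P.gamma * P.B * mX; rates[5] = P.gamma * P.B * mY;
      rates[6] = P.gamma0 * NX;      rates[7] = P.gamma0 * NY;
      nch = 8;
    } else {           // protein-only: production, protein decay
      double fac = (model == 2) ? P.B : 1.0;  // NB: B-fold event rate
      rates[0] = fac * aX; rates[1] = fac * aY;
      rates[2] = P.gamma0 * NX; rates[3] = P.gamma0 * NY;
      nch = 4;
    }
    double tot = 0.0;
    for (int i = 0; i < nch; ++i) tot += rates[i];
    if (!(tot > 0.0)) return -1.0;
    double dt = R::exp_rand() / tot;
    t += dt;
    double u = R::unif_rand() * tot;
    int ch = 0;
    for (; ch < nch - 1; ++ch) { if (u < rates[ch]) break; u -= rates[ch]; }
    if (model == 3) {
      switch (ch) {
        case 0: mX += 1; break;
        case 1: mY += 1; break;
        case 2: mX -= 1; break;
        case 3: mY -= 1; break;
        case 4: NX += 1; lastProdX = 1; break;
        case 5: NY += 1; lastProdY = 1; break;
        case 6: NX -= 1; break;
        case 7: NY -= 1; break;
      }
    } else {
      double k;
      switch (ch) {
        case 0:
          k = (model == 0) ? rgeom_mean(P.B) : (model == 1 ? P.B : 1.0);
          NX += k; lastProdX = k; break;
        case 1:
          k = (model == 0) ? rgeom_mean(P.B) : (model == 1 ? P.B : 1.0);
          NY += k; lastProdY = k; break;
        case 2: NX -= 1; break;
        case 3: NY -= 1; break;
      }
    }
    if (NX < 0 || NY < 0 || mX < 0 || mY < 0)
      stop("negative copy number reached (state NX=%f NY=%f mX=%f mY=%f)", NX, NY, mX, mY);
    return dt;
  }
};

// [[Rcpp::export]]
NumericMatrix cpp_ssa_trajectory(int model, NumericVector par,
                                 NumericVector init, double t_end,
                                 int max_events) {
  DiscreteSim S; S.P = unpack(par); S.model = model;
  S.init(init[0], init[1], init.size() > 2 ? init[2] : 0.0,
         init.size() > 3 ? init[3] : 0.0, 0.0);
  std::vector<double> rec;
  rec.reserve(1024);
  int nev = 0;
  rec.push_back(S.t); rec.push_back(S.mX); rec.push_back(S.mY);
  rec.push_back(S.NX); rec.push_back(S.NY);
  while (S.t < t_end) {
    double dt = S.step();
    if (dt < 0) break;
    if (S.t > t_end) break;
    rec.push_back(S.t); rec.push_back(S.mX); rec.push_back(S.mY);
    rec.push_back(S.NX); rec.push_back(S.NY);
    if (++nev >= max_events)
      stop("max_events (%d) exceeded before t_end; raise max_events or shorten the run", max_events);
  }
  int nrow = rec.size() / 5;
  NumericMatrix out(nrow, 5);
  for (int i = 0; i < nrow; ++i)
    for (int j = 0; j < 5; ++j) out(i, j) = rec[5 * i + j];
  colnames(out) = CharacterVector::create("t", "mX", "mY", "NX", "NY");
  return out;
}

// time-weighted stationary accumulation; returns occupancy matrix plus
// production / occupancy integrals for flux-balance checks
// [[Rcpp::export]]
List cpp_ssa_histogram(int model, NumericVector par, NumericVector init,
                       double t_burn, double t_total, int nmax) {
  DiscreteSim S; S.P = unpack(par); S.model = model;
  S.init(init[0], init[1], init.size() > 2 ? init[2] : 0.0,
         init.size() > 3 ? init[3] : 0.0, 0.0);
  NumericMatrix H(nmax + 1, nmax + 1);
  double prodX = 0, prodY = 0, intNX = 0, intNY = 0, intmX = 0, intmY = 0,
         wtot = 0;
  while (S.t < t_total) {
    double nx = S.NX, ny = S.NY, mx = S.mX, my = S.mY, t0 = S.t;
    double dt = S.step();
    double t1 = (dt < 0) ? t_total : std::min(S.t, t_total);
    double w = t1 - std::max(t_burn, t0);
    if (w > 0) {
      int ix = (int) std::min(nx, (double) nmax);
      int iy = (int) std::min(ny, (double) nmax);
      H(ix, iy) += w;
      intNX += nx * w; intNY += ny * w;
      intmX += mx * w; intmY += my * w;
      wtot += w;
      if (S.t <= t_total && dt > 0) { prodX += S.lastProdX; prodY += S.lastProdY; }
    }
    if (dt < 0) break;
  }
  return List::create(_["H"] = H, _["time"] = wtot,
                      _["prodX"] = prodX, _["prodY"] = prodY,
                      _["intNX"] = intNX, _["intNY"] = intNY,
                      _["intmX"] = intmX, _["intmY"] = intmY);
}

// first-passage times to {NY >= NX} from a grid of initial conditions
// [[Rcpp::export]]
List cpp_ssa_fpt(int model, NumericVector par, NumericMatrix inits,
                 int n_rep, double t_cap) {
  DiscreteSim S; S.P = unpack(par); S.model = model;
  int ng = inits.nrow();
  NumericMatrix tsum(ng, 3);  // sum of uncensored times, n_censored, sum of squares
  for (int g = 0; g < ng; ++g) {
    for (int rep = 0; rep < n_rep; ++rep) {
      S.init(inits(g, 0), inits(g, 1),
             inits.ncol() > 2 ? inits(g, 2) : 0.0,
             inits.ncol() > 3 ? inits(g, 3) : 0.0, 0.0);
      bool hit = false;
      while (S.t < t_cap) {
        double dt = S.step();
        if (dt < 0) break;
        if (S.t >= t_cap) break;
        if (S.NY >= S.NX) { hit = true; break; }
      }
      if (hit) { tsum(g, 0) += S.t; tsum(g, 2) += S.t * S.t; }
      else tsum(g, 1) += 1;
    }
  }
  return List::create(_["sums"] = tsum, _["n_rep"] = n_rep);
}

// short-horizon increments for jump-moment (Kramers-Moyal) oracles
// [[Rcpp::export]]
NumericMatrix cpp_ssa_increment(int model, NumericVector par,
                                NumericVector init, double dt, int n_rep) {
  DiscreteSim S; S.P = unpack(par); S.model = model;
  NumericMatrix out(n_rep, 2);
  for (int rep = 0; rep < n_rep; ++rep) {
    S.init(init[0], init[1], init.size() > 2 ? init[2] : 0.0,
           init.size() > 3 ? init[3] : 0.0, 0.0);
    while (true) {
      double nx = S.NX, ny = S.NY;
      double d = S.step();
      if (d < 0 || S.t > dt) { S.NX = nx; S.NY = ny; break; }
    }
    out(rep, 0) = S.NX - init[0];
    out(rep, 1) = S.NY - init[1];
  }
  return out;
}

// number of proteins produced during single mRNA lifecycles: exact SSA of
// the translation (rate gamma*B) vs degradation (rate gamma) race
// [[Rcpp::export]]
NumericVector cpp_mrna_lifecycle(int n, double B, double gamma) {
  NumericVector out(n);
  double ptr = gamma * B / (gamma * B + gamma);
  for (int i = 0; i < n; ++i) {
    double k = 0;
    while (R::unif_rand() < ptr) k += 1;
    out[i] = k;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Euler-Maruyama integration of the diffusion approximation of the GB model
// ---------------------------------------------------------------------------

struct SdeSim {
  Params P;
  double x, y, t, dt;
  double lastProdX, lastProdY;  // production drift contributions (for flux checks)

  void drift_diff(double& vx, double& vy, double& Dx, double& Dy) {
    double aX = trans_rate(P, P.K * y, P.K * x);
    double aY = trans_rate(P, P.K * x, P.K * y);
    double m2 = 2.0 * P.B * P.B + P.B;  // E[k^2] of the geometric burst law
    vx = (P.B * aX - P.gamma0 * P.K * x) / P.K;
    vy = (P.B * aY - P.gamma0 * P.K * y) / P.K;
    Dx = (aX * m2 + P.gamma0 * P.K * x) / (P.K * P.K);
    Dy = (aY * m2 + P.gamma0 * P.K * y) / (P.K * P.K);
  }

  void step() {
    double vx, vy, Dx, Dy;
    drift_diff(vx, vy, Dx, Dy);
    x += vx * dt + std::sqrt(Dx * dt) * R::norm_rand();
    y += vy * dt + std::sqrt(Dy * dt) * R::norm_rand();
    if (x < 0) x = -x;  // reflecting boundary at zero
    if (y < 0) y = -y;
    if (!std::isfinite(x) || !std::isfinite(y))
      stop("SDE step produced a non-finite state at t=%f", t);
    t += dt;
  }
};

// [[Rcpp::export]]
NumericMatrix cpp_sde_trajectory(NumericVector par, NumericVector init,
                                 double t_end, double dt, int thin) {
  SdeSim S; S.P = unpack(par);
  S.x = init[0]; S.y = init[1]; S.t = 0.0; S.dt = dt;
  long nstep = (long) std::ceil(t_end / dt);
  long nrec = nstep / thin + 1;
  NumericMatrix out(nrec, 3);
  long k = 0;
  out(k, 0) = S.t; out(k, 1) = S.x; out(k, 2) = S.y; ++k;
  for (long i = 1; i <= nstep; ++i) {
    S.step();
    if (i % thin == 0 && k < nrec) {
      out(k, 0) = S.t; out(k, 1) = S.x; out(k, 2) = S.y; ++k;
    }
  }
  colnames(out) = CharacterVector::create("t", "x", "y");
  return out;
}

// [[Rcpp::export]]
List cpp_sde_histogram(NumericVector par, NumericVector init, double t_burn,
                       double t_total, double dt, int nmax) {
  SdeSim S; S.P = unpack(par);
  S.x = init[0]; S.y = init[1]; S.t = 0.0; S.dt = dt;
  NumericMatrix H(nmax + 1, nmax + 1);
  double wtot = 0, intx = 0, inty = 0;
  while (S.t < t_total) {
    if (S.t >= t_burn) {
      int ix = (int) std::min(std::max(0.0, std::round(S.P.K * S.x)), (double) nmax);
      int iy = (int) std::min(std::max(0.0, std::round(S.P.K * S.y)), (double) nmax);
      H(ix, iy) += dt; wtot += dt;
      intx += S.x * dt; inty += S.y * dt;
    }
    S.step();
  }
  return List::create(_["H"] = H, _["time"] = wtot,
                      _["intx"] = intx, _["inty"] = inty);
}

// [[Rcpp::export]]
List cpp_sde_fpt(NumericVector par, NumericMatrix inits, int n_rep,
                 double t_cap, double dt) {
  SdeSim S; S.P = unpack(par); S.dt = dt;
  int ng = inits.nrow();
  NumericMatrix tsum(ng, 3);
  for (int g = 0; g < ng; ++g) {
    for (int rep = 0; rep < n_rep; ++rep) {
      S.x = inits(g, 0); S.y = inits(g, 1); S.t = 0.0;
      bool hit = false;
      while (S.t < t_cap) {
        S.step();
        if (S.y >= S.x) { hit = true; break; }
      }
      if (hit) { tsum(g, 0) += S.t; tsum(g, 2) += S.t * S.t; }
      else tsum(g, 1) += 1;
    }
  }
  return List::create(_["sums"] = tsum, _["n_rep"] = n_rep);
}

// ---------------------------------------------------------------------------
// Shot-noise limit of the PDMP: instantaneous exponential bursts
// ---------------------------------------------------------------------------

// decay both concentrations over an interval
static inline void decay2(double& x, double& y, double g0, double dt) {
  double f = std::exp(-g0 * dt);
  x *= f; y *= f;
}

struct ShotSim {
  Params P;
  double x, y, t, b;
  double lastBx, lastBy;  // burst increments (concentration)

  // advance to the next accepted burst (thinning against the exact sup);
  // returns false if t_end reached first
  bool next_event(double t_end) {
    double amax = rate_sup(P), Lam = 2.0 * amax;
    lastBx = lastBy = 0.0;
    while (true) {
      double tau = R::exp_rand() / Lam;
      if (t + tau > t_end) {
        decay2(x, y, P.gamma0, t_end - t);
        t = t_end;
        return false;
      }
      decay2(x, y, P.gamma0, tau);
      t += tau;
      double aX = trans_rate(P, P.K * y, P.K * x);
      double aY = trans_rate(P, P.K * x, P.K * y);
      double u = R::unif_rand() * Lam;
      if (u < aX) { lastBx = R::rexp(b); x += lastBx; return true; }
      if (u < aX + aY) { lastBy = R::rexp(b); y += lastBy; return true; }
      // thinning rejection: keep going
    }
  }
};

// [[Rcpp::export]]
NumericMatrix cpp_shotnoise_trajectory(NumericVector par, NumericVector init,
                                       double t_end, int max_events) {
  ShotSim S; S.P = unpack(par); S.b = S.P.B / S.P.K;
  S.x = init[0]; S.y = init[1]; S.t = 0.0;
  std::vector<double> rec; rec.reserve(1024);
  rec.push_back(S.t); rec.push_back(S.x); rec.push_back(S.y);
  int nev = 0;
  while (S.t < t_end) {
    double x0 = S.x, y0 = S.y;
    if (!S.next_event(t_end)) {
      rec.push_back(S.t); rec.push_back(S.x); rec.push_back(S.y);
      break;
    }
    // pre- and post-burst points share the event time (left-continuous
    // convention for time-weighted statistics)
    rec.push_back(S.t); rec.push_back(S.x - S.lastBx); rec.push_back(S.y - S.lastBy);
    rec.push_back(S.t); rec.push_back(S.x); rec.push_back(S.y);
    (void) x0; (void) y0;
    if (++nev >= max_events)
      stop("max_events (%d) exceeded before t_end", max_events);
  }
  int nrow = rec.size() / 3;
  NumericMatrix out(nrow, 3);
  for (int i = 0; i < nrow; ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = rec[3 * i + j];
  colnames(out) = CharacterVector::create("t", "x", "y");
  return out;
}

// occupancy sampled on a fine grid dt_occ between events
static void accumulate_decay(NumericMatrix& H, double& wtot, double& intx,
                             double& inty, double x0, double y0, double g0,
                             double span, double from_offset, double dt_occ,
                             double K, int nmax) {
  // occupancy of the decaying flow x(t)=x0 e^{-g0 t} over t in
  // [from_offset, span], sampled every dt_occ
  for (double s = from_offset; s < span; s += dt_occ) {
    double w = std::min(dt_occ, span - s);
    double f = std::exp(-g0 * s);
    int ix = (int) std::min(std::max(0.0, std::round(K * x0 * f)), (double) nmax);
    int iy = (int) std::min(std::max(0.0, std::round(K * y0 * f)), (double) nmax);
    H(ix, iy) += w; wtot += w;
    intx += x0 * f * w; inty += y0 * f * w;
  }
}

// [[Rcpp::export]]
List cpp_shotnoise_histogram(NumericVector par, NumericVector init,
                             double t_burn, double t_total, double dt_occ,
                             int nmax) {
  ShotSim S; S.P = unpack(par); S.b = S.P.B / S.P.K;
  S.x = init[0]; S.y = init[1]; S.t = 0.0;
  NumericMatrix H(nmax + 1, nmax + 1);
  double wtot = 0, intx = 0, inty = 0, prodx = 0, prody = 0;
  while (S.t < t_total) {
    double x0 = S.x, y0 = S.y, t0 = S.t;
    bool ev = S.next_event(t_total);
    double span = S.t - t0;
    double from = std::max(0.0, t_burn - t0);
    if (from < span)
      accumulate_decay(H, wtot, intx, inty, x0, y0, S.P.gamma0, span, from,
                       dt_occ, S.P.K, nmax);
    if (ev && S.t >= t_burn) { prodx += S.lastBx; prody += S.lastBy; }
    if (!ev) break;
  }
  return List::create(_["H"] = H, _["time"] = wtot, _["intx"] = intx,
                      _["inty"] = inty, _["prodx"] = prodx, _["prody"] = prody);
}

// [[Rcpp::export]]
List cpp_shotnoise_fpt(NumericVector par, NumericMatrix inits, int n_rep,
                       double t_cap) {
  ShotSim S; S.P = unpack(par); S.b = S.P.B / S.P.K;
  int ng = inits.nrow();
  NumericMatrix tsum(ng, 3);
  for (int g = 0; g < ng; ++g) {
    for (int rep = 0; rep < n_rep; ++rep) {
      S.x = inits(g, 0); S.y = inits(g, 1); S.t = 0.0;
      bool hit = false;
      while (S.t < t_cap) {
        if (!S.next_event(t_cap)) break;
        // decay preserves the x/y ratio and x-bursts move away from the
        // boundary, so crossings happen only at y-bursts
        if (S.y >= S.x) { hit = true; break; }
      }
      if (hit) { tsum(g, 0) += S.t; tsum(g, 2) += S.t * S.t; }
      else tsum(g, 1) += 1;
    }
  }
  return List::create(_["sums"] = tsum, _["n_rep"] = n_rep);
}

// ---------------------------------------------------------------------------
// Finite-gamma PDMP: three mRNA modes (0, X, Y) with deterministic flow
// ---------------------------------------------------------------------------

struct PdmpSim {
  Params P;
  int mode;  // 0, 1 = X, 2 = Y
  double x, y, t, b;

  // flow over dt within the current mode; the production gain uses expm1
  // so that gamma0 -> 0 stays exact (no gb/gamma0 cancellation)
  void flow(double dt) {
    double g0 = P.gamma0, gb = P.gamma * b;
    double f = std::exp(-g0 * dt);
    double gain = (g0 > 0) ? gb * (-std::expm1(-g0 * dt)) / g0 : gb * dt;
    x *= f; y *= f;
    if (mode == 1) x += gain;
    if (mode == 2) y += gain;
    t += dt;
  }

  // next mode switch; returns the sojourn time (capped at t_end - t)
  // and updates mode; sets *capped when t_end was reached first
  double next_switch(double t_end, bool& capped) {
    capped = false;
    if (mode != 0) {
      double tau = R::exp_rand() / P.gamma;
      if (t + tau > t_end) { capped = true; return t_end - t; }
      // flow applied by caller; mode returns to 0
      return tau;
    }
    // 0-state: time-dependent rates handled by thinning
    double amax = rate_sup(P), Lam = 2.0 * amax;
    double x0 = x, y0 = y, acc = 0.0;
    while (true) {
      double tau = R::exp_rand() / Lam;
      acc += tau;
      if (t + acc > t_end) { capped = true; return t_end - t; }
      double f = std::exp(-P.gamma0 * acc);
      double aX = trans_rate(P, P.K * y0 * f, P.K * x0 * f);
      double aY = trans_rate(P, P.K * x0 * f, P.K * y0 * f);
      double u = R::unif_rand() * Lam;
      if (u < aX) { mode = 1; return acc; }
      if (u < aX + aY) { mode = 2; return acc; }
    }
  }
};

// [[Rcpp::export]]
NumericMatrix cpp_pdmp_trajectory(NumericVector par, NumericVector init,
                                  int mode0, double t_end, int max_events) {
  PdmpSim S; S.P = unpack(par); S.b = S.P.B / S.P.K;
  S.x = init[0]; S.y = init[1]; S.mode = mode0; S.t = 0.0;
  std::vector<double> rec; rec.reserve(1024);
  rec.push_back(S.t); rec.push_back(S.mode); rec.push_back(S.x); rec.push_back(S.y);
  int nev = 0;
  while (S.t < t_end) {
    bool capped;
    int old_mode = S.mode;
    double tau = S.next_switch(t_end, capped);
    int new_mode = S.mode;
    S.mode = old_mode;  // flow under the pre-switch mode
    S.flow(tau);
    S.mode = capped ? old_mode : (old_mode == 0 ? new_mode : 0);
    rec.push_back(S.t); rec.push_back(S.mode); rec.push_back(S.x); rec.push_back(S.y);
    if (capped) break;
    if (++nev >= max_events)
      stop("max_events (%d) exceeded before t_end", max_events);
  }
  int nrow = rec.size() / 4;
  NumericMatrix out(nrow, 4);
  for (int i = 0; i < nrow; ++i)
    for (int j = 0; j < 4; ++j) out(i, j) = rec[4 * i + j];
  colnames(out) = CharacterVector::create("t", "mode", "x", "y");
  return out;
}

// [[Rcpp::export]]
List cpp_pdmp_histogram(NumericVector par, NumericVector init, int mode0,
                        double t_burn, double t_total, double dt_occ,
                        int nmax) {
  PdmpSim S; S.P = unpack(par); S.b = S.P.B / S.P.K;
  S.x = init[0]; S.y = init[1]; S.mode = mode0; S.t = 0.0;
  NumericMatrix H(nmax + 1, nmax + 1);
  NumericVector mode_time(3);
  double wtot = 0, intx = 0, inty = 0;
  while (S.t < t_total) {
    bool capped;
    int old_mode = S.mode;
    double tau = S.next_switch(t_total, capped);
    int new_mode = S.mode;
    S.mode = old_mode;
    // sample the within-mode flow
    double t0 = S.t, x0 = S.x, y0 = S.y;
    for (double s = 0.0; s < tau; s += dt_occ) {
      double w = std::min(dt_occ, tau - s);
      double keep_t = S.t; double kx = S.x, ky = S.y;
      S.x = x0; S.y = y0; S.t = t0; S.flow(s);
      if (S.t + 0.5 * w >= t_burn) {
        int ix = (int) std::min(std::max(0.0, std::round(S.P.K * S.x)), (double) nmax);
        int iy = (int) std::min(std::max(0.0, std::round(S.P.K * S.y)), (double) nmax);
        H(ix, iy) += w; wtot += w;
        intx += S.x * w; inty += S.y * w;
        mode_time[old_mode] += w;
      }
      S.t = keep_t; S.x = kx; S.y = ky;
    }
    S.x = x0; S.y = y0; S.t = t0;
    S.flow(tau);
    S.mode = capped ? old_mode : (old_mode == 0 ? new_mode : 0);
    if (capped) break;
  }
  return List::create(_["H"] = H, _["time"] = wtot, _["intx"] = intx,
                      _["inty"] = inty, _["mode_time"] = mode_time);
}

// [[Rcpp::export]]
List cpp_pdmp_fpt(NumericVector par, NumericMatrix inits, int mode0,
                  int n_rep, double t_cap) {
  PdmpSim S; S.P = unpack(par); S.b = S.P.B / S.P.K;
  int ng = inits.nrow();
  NumericMatrix tsum(ng, 3);
  double g0 = S.P.gamma0, gb = S.P.gamma * S.b;
  for (int g = 0; g < ng; ++g) {
    for (int rep = 0; rep < n_rep; ++rep) {
      S.x = inits(g, 0); S.y = inits(g, 1); S.mode = mode0; S.t = 0.0;
      bool hit = false;
      while (S.t < t_cap && !hit) {
        bool capped;
        int old_mode = S.mode;
        double tau = S.next_switch(t_cap, capped);
        int new_mode = S.mode;
        S.mode = old_mode;
        if (old_mode == 2 && S.x > S.y) {
          // only the Y-production mode can drive y across x; closed-form
          // crossing time of y(t) - x(t) = 0 within the sojourn
          double tc;
          if (g0 > 0) {
            tc = std::log1p(g0 * (S.x - S.y) / gb) / g0;
          } else {
            tc = (S.x - S.y) / gb;
          }
          if (tc <= tau) {
            S.flow(tc);
            hit = true;
            break;
          }
        }
        S.flow(tau);
        S.mode = capped ? old_mode : (old_mode == 0 ? new_mode : 0);
        if (S.y >= S.x) hit = true;
        if (capped) break;
      }
      if (hit) { tsum(g, 0) += S.t; tsum(g, 2) += S.t * S.t; }
      else tsum(g, 1) += 1;
    }
  }
  return List::create(_["sums"] = tsum, _["n_rep"] = n_rep);
}
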