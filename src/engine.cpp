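// Brownian-dynamics engine for the recolourable bead-spring chromatin model.
//
// Units: lengths in sigma, energies in k_B T_L, masses = 1, friction gamma in
// LJ units.  With gamma = 1 and T_L = 1 the Brownian time tau_Br =
// sigma^2 gamma / (k_B T_L) equals one LJ time unit, so simulation time is
// reported directly in tau_Br.
//
// Pair channel between beads a,b with colours q_a, q_b:
//   cutoff 1.8 sigma   if q_a == q_b != 0  (attractive, depth epsilon)
//   cutoff 2^(1/6)     otherwise           (WCA, purely repulsive)
// End beads (diameter 5 sigma) interact through the WCA channel with the
// radial shift of additive-radius mixing: x_eff = r - (d_a + d_b)/2 + sigma.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double XC_SAME = 1.8;
static const double XC_WCA  = 1.122462048309373;  // 2^(1/6)

// shift term S = xc^-12 - xc^-6 and normalisation N per channel.
// N is chosen so the attractive channel has depth exactly -epsilon:
// N = 4 * |min of bracket| = 4 * (1/4 - S) for xc > 2^(1/6); the WCA channel
// has zero-depth minimum, for which the conventional N = 1 is used.
struct PairChannel {
  double xc, S, norm;
};

static PairChannel make_channel(double xc) {
  PairChannel ch;
  ch.xc = xc;
  double i6 = std::pow(xc, -6.0);
  ch.S = i6 * i6 - i6;
  if (xc > XC_WCA + 1e-12) {
    ch.norm = 4.0 * (0.25 + ch.S);
  } else {
    ch.norm = 1.0;
  }
  return ch;
}

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded via splitmix64; Gaussians by Box-Muller.
// ---------------------------------------------------------------------------
struct Xoshiro {
  uint64_t s[4];
  bool have_cached;
  double cached;

  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t sd) {
    uint64_t x = sd;
    for (int i = 0; i < 4; i++) s[i] = splitmix(x);
    have_cached = false;
    cached = 0.0;
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  int unif_int(int n) {  // 0 .. n-1
    return (int)(unif() * n) % n;
  }
  double norm() {
    if (have_cached) { have_cached = false; return cached; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586 * u2;
    cached = r * std::sin(a);
    have_cached = true;
    return r * std::cos(a);
  }
};

// ---------------------------------------------------------------------------
// Model parameters gathered from R
// ---------------------------------------------------------------------------
struct Model {
  int n;                    // total beads (incl. end beads)
  double epsilon;           // like-colour affinity [k_B T_L]
  double TL;                // solution temperature
  double kappa, x0, lp;     // bond and bending parameters
  bool attract_on;          // colour channel active?
  bool pairs_on, bonds_on;  // switch off for free-bead ensembles
  double f;                 // terminal stretching force magnitude
  double axis[3];
  std::vector<double> diam;
  std::vector<int> is_end;
  PairChannel ch_same, ch_wca;
};

static inline double pair_delta(const Model &m, int i, int j) {
  return 0.5 * (m.diam[i] + m.diam[j]) - 1.0;
}

// channel for the (i, j) pair given current colours
static inline const PairChannel *channel_for(const Model &m, int i, int j,
                                             const int *col) {
  if (m.attract_on && !m.is_end[i] && !m.is_end[j] &&
      col[i] != 0 && col[i] == col[j])
    return &m.ch_same;
  return &m.ch_wca;
}

// epsilon per channel: the attractive channel carries the free parameter,
// the WCA channel is fixed at 1 k_B T_L
static inline double eps_for(const Model &m, const PairChannel *ch) {
  return (ch == &m.ch_same) ? m.epsilon : 1.0;
}

// pair energy at centre distance r (colour-resolved channel);
// x below 0.3 sigma is clamped to keep catastrophic overlaps finite
static inline double pair_energy(const Model &m, const PairChannel *ch,
                                 double r, double delta) {
  double x = r - delta;
  if (x >= ch->xc) return 0.0;
  if (x < 0.3) x = 0.3;
  double i6 = std::pow(x, -6.0);
  return m.TL * (4.0 * eps_for(m, ch) / ch->norm) * (i6 * i6 - i6 - ch->S);
}

// dU/dr at centre distance r
static inline double pair_dudr(const Model &m, const PairChannel *ch,
                               double r, double delta) {
  double x = r - delta;
  if (x >= ch->xc) return 0.0;
  if (x < 0.3) x = 0.3;
  double inv = 1.0 / x;
  double i6 = std::pow(inv, 6.0);
  return m.TL * (4.0 * eps_for(m, ch) / ch->norm) *
         (-12.0 * i6 * i6 + 6.0 * i6) * inv;
}

// ---------------------------------------------------------------------------
// Neighbour list (Verlet list with skin)
// ---------------------------------------------------------------------------
struct NbrList {
  double skin;
  std::vector<std::vector<int> > nbr;   // full list, per bead
  std::vector<double> ref;              // positions at last build
  void build(const Model &m, const std::vector<double> &pos) {
    int n = m.n;
    nbr.assign(n, std::vector<int>());
    ref = pos;
    for (int i = 0; i < n; i++) {
      for (int j = i + 1; j < n; j++) {
        double dx = pos[3 * i] - pos[3 * j];
        double dy = pos[3 * i + 1] - pos[3 * j + 1];
        double dz = pos[3 * i + 2] - pos[3 * j + 2];
        double rl = XC_SAME + pair_delta(m, i, j) + skin;
        if (dx * dx + dy * dy + dz * dz < rl * rl) {
          nbr[i].push_back(j);
          nbr[j].push_back(i);
        }
      }
    }
  }
  bool stale(const std::vector<double> &pos) const {
    double m1 = 0.0, m2 = 0.0;
    int n = (int)pos.size() / 3;
    for (int i = 0; i < n; i++) {
      double dx = pos[3 * i] - ref[3 * i];
      double dy = pos[3 * i + 1] - ref[3 * i + 1];
      double dz = pos[3 * i + 2] - ref[3 * i + 2];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d > m1) { m2 = m1; m1 = d; }
      else if (d > m2) m2 = d;
    }
    return (m1 + m2) >= skin;
  }
};

// ---------------------------------------------------------------------------
// Energies and forces
// ---------------------------------------------------------------------------
static double total_energy_cpp(const Model &m, const std::vector<double> &pos,
                               const int *col) {
  double U = 0.0;
  int n = m.n;
  if (m.pairs_on) {
    for (int i = 0; i < n; i++) {
      for (int j = i + 1; j < n; j++) {
        double dx = pos[3 * i] - pos[3 * j];
        double dy = pos[3 * i + 1] - pos[3 * j + 1];
        double dz = pos[3 * i + 2] - pos[3 * j + 2];
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        const PairChannel *ch = channel_for(m, i, j, col);
        U += pair_energy(m, ch, r, pair_delta(m, i, j));
      }
    }
  }
  if (m.bonds_on) {
    for (int i = 0; i + 1 < n; i++) {
      double dx = pos[3 * i] - pos[3 * (i + 1)];
      double dy = pos[3 * i + 1] - pos[3 * (i + 1) + 1];
      double dz = pos[3 * i + 2] - pos[3 * (i + 1) + 2];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double x0 = m.x0 + pair_delta(m, i, i + 1);
      U += 0.5 * m.kappa * m.TL * (r - x0) * (r - x0);
    }
    for (int i = 1; i + 1 < n; i++) {
      double t1[3], t2[3];
      double n1 = 0, n2 = 0, dot = 0;
      for (int k = 0; k < 3; k++) {
        t1[k] = pos[3 * i + k] - pos[3 * (i - 1) + k];
        t2[k] = pos[3 * (i + 1) + k] - pos[3 * i + k];
        n1 += t1[k] * t1[k];
        n2 += t2[k] * t2[k];
        dot += t1[k] * t2[k];
      }
      double c = dot / std::sqrt(n1 * n2);
      U += m.TL * m.lp * (1.0 - c);
    }
  }
  return U;
}

static void forces_cpp(const Model &m, const std::vector<double> &pos,
                       const int *col, const NbrList &nl,
                       std::vector<double> &frc) {
  int n = m.n;
  std::fill(frc.begin(), frc.end(), 0.0);
  if (m.pairs_on) {
    for (int i = 0; i < n; i++) {
      for (size_t k = 0; k < nl.nbr[i].size(); k++) {
        int j = nl.nbr[i][k];
        if (j < i) continue;
        double dx = pos[3 * i] - pos[3 * j];
        double dy = pos[3 * i + 1] - pos[3 * j + 1];
        double dz = pos[3 * i + 2] - pos[3 * j + 2];
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (r <= 0) continue;
        const PairChannel *ch = channel_for(m, i, j, col);
        double du = pair_dudr(m, ch, r, pair_delta(m, i, j));
        if (du == 0.0) continue;
        double fac = -du / r;
        frc[3 * i] += fac * dx; frc[3 * i + 1] += fac * dy; frc[3 * i + 2] += fac * dz;
        frc[3 * j] -= fac * dx; frc[3 * j + 1] -= fac * dy; frc[3 * j + 2] -= fac * dz;
      }
    }
  }
  if (m.bonds_on) {
    for (int i = 0; i + 1 < n; i++) {
      double dx = pos[3 * i] - pos[3 * (i + 1)];
      double dy = pos[3 * i + 1] - pos[3 * (i + 1) + 1];
      double dz = pos[3 * i + 2] - pos[3 * (i + 1) + 2];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double x0 = m.x0 + pair_delta(m, i, i + 1);
      double fac = -m.kappa * m.TL * (r - x0) / r;
      frc[3 * i] += fac * dx; frc[3 * i + 1] += fac * dy; frc[3 * i + 2] += fac * dz;
      frc[3 * (i + 1)] -= fac * dx; frc[3 * (i + 1) + 1] -= fac * dy; frc[3 * (i + 1) + 2] -= fac * dz;
    }
    for (int i = 1; i + 1 < n; i++) {
      double t1[3], t2[3];
      double n1 = 0, n2 = 0, dot = 0;
      for (int k = 0; k < 3; k++) {
        t1[k] = pos[3 * i + k] - pos[3 * (i - 1) + k];
        t2[k] = pos[3 * (i + 1) + k] - pos[3 * i + k];
        n1 += t1[k] * t1[k];
        n2 += t2[k] * t2[k];
        dot += t1[k] * t2[k];
      }
      double l1 = std::sqrt(n1), l2 = std::sqrt(n2);
      double c = dot / (l1 * l2);
      double kb = m.TL * m.lp;  // dU/dcos = -kb for U = kb (1 - cos)
      for (int k = 0; k < 3; k++) {
        double g1 = t2[k] / (l1 * l2) - c * t1[k] / n1;
        double g2 = t1[k] / (l1 * l2) - c * t2[k] / n2;
        double fa = -kb * g1;           // force on bead i-1
        double fc = +kb * g2;           // force on bead i+1
        frc[3 * (i - 1) + k] += fa;
        frc[3 * (i + 1) + k] += fc;
        frc[3 * i + k] -= (fa + fc);
      }
    }
  }
  // terminal stretching: -f axis on the first end bead, +f axis on the last
  if (m.f != 0.0) {
    int first = -1, last = -1;
    for (int i = 0; i < n; i++)
      if (m.is_end[i]) { if (first < 0) first = i; last = i; }
    if (first >= 0 && last > first) {
      for (int k = 0; k < 3; k++) {
        frc[3 * first + k] -= m.f * m.axis[k];
        frc[3 * last + k]  += m.f * m.axis[k];
      }
    }
  }
}

// energy of all pair interactions involving a single bead (used by recolouring)
static double bead_pair_energy(const Model &m, const std::vector<double> &pos,
                               const int *col, const NbrList &nl, int a) {
  double U = 0.0;
  for (size_t k = 0; k < nl.nbr[a].size(); k++) {
    int j = nl.nbr[a][k];
    double dx = pos[3 * a] - pos[3 * j];
    double dy = pos[3 * a + 1] - pos[3 * j + 1];
    double dz = pos[3 * a + 2] - pos[3 * j + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    const PairChannel *ch = channel_for(m, a, j, col);
    U += pair_energy(m, ch, r, pair_delta(m, a, j));
  }
  return U;
}

static Model model_from_r(NumericVector diam, IntegerVector is_end, List ff,
                          bool attract_on, bool pairs_on, bool bonds_on,
                          double f, NumericVector axis) {
  Model m;
  m.n = diam.size();
  m.epsilon = as<double>(ff["epsilon"]);
  m.TL = as<double>(ff["T_L"]);
  m.kappa = as<double>(ff["bond_k"]);
  m.x0 = as<double>(ff["bond_x0"]);
  m.lp = as<double>(ff["persistence_lp"]);
  m.attract_on = attract_on;
  m.pairs_on = pairs_on;
  m.bonds_on = bonds_on;
  m.f = f;
  double an = std::sqrt(axis[0] * axis[0] + axis[1] * axis[1] + axis[2] * axis[2]);
  for (int k = 0; k < 3; k++) m.axis[k] = axis[k] / an;
  m.diam.assign(diam.begin(), diam.end());
  m.is_end.assign(is_end.begin(), is_end.end());
  m.ch_same = make_channel(XC_SAME);
  m.ch_wca = make_channel(XC_WCA);
  return m;
}

// [[Rcpp::export]]
double cpp_total_energy(NumericMatrix pos, IntegerVector colours,
                        NumericVector diam, IntegerVector is_end, List ff,
                        bool attract_on, bool pairs_on, bool bonds_on) {
  Model m = model_from_r(diam, is_end, ff, attract_on, pairs_on, bonds_on,
                         0.0, NumericVector::create(0, 0, 1));
  std::vector<double> p(3 * m.n);
  for (int i = 0; i < m.n; i++)
    for (int k = 0; k < 3; k++) p[3 * i + k] = pos(i, k);
  return total_energy_cpp(m, p, &colours[0]);
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix pos, IntegerVector colours,
                         NumericVector diam, IntegerVector is_end, List ff,
                         bool attract_on, bool pairs_on, bool bonds_on,
                         double f, NumericVector axis) {
  Model m = model_from_r(diam, is_end, ff, attract_on, pairs_on, bonds_on,
                         f, axis);
  std::vector<double> p(3 * m.n), frc(3 * m.n);
  for (int i = 0; i < m.n; i++)
    for (int k = 0; k < 3; k++) p[3 * i + k] = pos(i, k);
  NbrList nl;
  nl.skin = 0.4;
  nl.build(m, p);
  forces_cpp(m, p, &colours[0], nl, frc);
  NumericMatrix out(m.n, 3);
  for (int i = 0; i < m.n; i++)
    for (int k = 0; k < 3; k++) out(i, k) = frc[3 * i + k];
  return out;
}

// [[Rcpp::export]]
double cpp_recolour_delta(NumericMatrix pos, IntegerVector colours,
                          NumericVector diam, IntegerVector is_end, List ff,
                          bool attract_on, int bead, int new_colour) {
  Model m = model_from_r(diam, is_end, ff, attract_on, true, true,
                         0.0, NumericVector::create(0, 0, 1));
  std::vector<double> p(3 * m.n);
  for (int i = 0; i < m.n; i++)
    for (int k = 0; k < 3; k++) p[3 * i + k] = pos(i, k);
  NbrList nl;
  nl.skin = 0.4;
  nl.build(m, p);
  std::vector<int> col(colours.begin(), colours.end());
  int a = bead - 1;
  double u_old = bead_pair_energy(m, p, &col[0], nl, a);
  int keep = col[a];
  col[a] = new_colour;
  double u_new = bead_pair_energy(m, p, &col[0], nl, a);
  col[a] = keep;
  return u_new - u_old;
}

// one Metropolis attempt on bead a; returns 1 if accepted
static int attempt_cpp(const Model &m, const std::vector<double> &pos,
                       std::vector<int> &col, const NbrList &nl, int a,
                       double TR, Xoshiro &rng) {
  int cur = col[a];
  // propose one of the two remaining colours with probability 1/2 each
  int other[2], idx = 0;
  for (int c = 0; c < 3; c++)
    if (c != cur) other[idx++] = c;
  int prop = other[rng.unif_int(2)];
  double u_old = bead_pair_energy(m, pos, &col[0], nl, a);
  col[a] = prop;
  double u_new = bead_pair_energy(m, pos, &col[0], nl, a);
  double dU = u_new - u_old;
  if (dU <= 0.0 || rng.unif() < std::exp(-dU / TR)) return 1;
  col[a] = cur;
  return 0;
}

// Recolouring-only run at frozen positions; returns colour trace.
// [[Rcpp::export]]
IntegerMatrix cpp_recolour_run(NumericMatrix pos, IntegerVector colours,
                               NumericVector diam, IntegerVector is_end,
                               List ff, bool attract_on, double TR,
                               int nsweeps, int record_every, int seed) {
  Model m = model_from_r(diam, is_end, ff, attract_on, true, true,
                         0.0, NumericVector::create(0, 0, 1));
  std::vector<double> p(3 * m.n);
  for (int i = 0; i < m.n; i++)
    for (int k = 0; k < 3; k++) p[3 * i + k] = pos(i, k);
  NbrList nl;
  nl.skin = 0.4;
  nl.build(m, p);
  std::vector<int> col(colours.begin(), colours.end());
  std::vector<int> poly;
  for (int i = 0; i < m.n; i++)
    if (!m.is_end[i]) poly.push_back(i);
  int npoly = (int)poly.size();
  Xoshiro rng;
  rng.seed((uint64_t)seed * 2ULL + 1ULL);
  int nrec = nsweeps / record_every;
  IntegerMatrix trace(nrec, m.n);
  int r = 0;
  for (int sw = 1; sw <= nsweeps; sw++) {
    for (int t = 0; t < npoly; t++) {
      int a = poly[rng.unif_int(npoly)];
      attempt_cpp(m, p, col, nl, a, TR, rng);
    }
    if (sw % record_every == 0 && r < nrec) {
      for (int i = 0; i < m.n; i++) trace(r, i) = col[i];
      r++;
    }
  }
  return trace;
}

// ---------------------------------------------------------------------------
// Main integrator: BAOAB Langevin velocity-Verlet with interleaved recolouring
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_run_dynamics(NumericMatrix pos0, NumericMatrix vel0,
                      IntegerVector colours0, NumericVector diam,
                      IntegerVector is_end, List ff, bool attract_on,
                      bool pairs_on, bool bonds_on, double f,
                      NumericVector axis, double dt, double gamma, double TL,
                      int nsteps, int save_every, int tauR_steps,
                      bool recolour_on, double TR, int seed,
                      double time0) {
  Model m = model_from_r(diam, is_end, ff, attract_on, pairs_on, bonds_on,
                         f, axis);
  int n = m.n;
  std::vector<double> pos(3 * n), vel(3 * n), frc(3 * n);
  for (int i = 0; i < n; i++)
    for (int k = 0; k < 3; k++) {
      pos[3 * i + k] = pos0(i, k);
      vel[3 * i + k] = vel0(i, k);
    }
  std::vector<int> col(colours0.begin(), colours0.end());
  std::vector<int> poly;
  for (int i = 0; i < n; i++)
    if (!m.is_end[i]) poly.push_back(i);
  int npoly = (int)poly.size();

  Xoshiro rng_th, rng_rc;
  rng_th.seed((uint64_t)seed * 2ULL);
  rng_rc.seed((uint64_t)seed * 2ULL + 1ULL);

  NbrList nl;
  nl.skin = 0.4;
  nl.build(m, pos);
  forces_cpp(m, pos, &col[0], nl, frc);

  // OU coefficients for the O step
  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt((1.0 - c1 * c1) * TL);

  int nframes = nsteps / save_every + 1;
  NumericVector times(nframes);
  NumericVector traj(nframes * n * 3);
  IntegerMatrix kymo(nframes, n);
  traj.attr("dim") = IntegerVector::create(n, 3, nframes);

  long n_attempt = 0, n_accept = 0;
  int frame = 0;
  // frame 0 = initial state
  times[0] = time0;
  for (int i = 0; i < n; i++) {
    for (int k = 0; k < 3; k++) traj[frame * 3 * n + k * n + i] = pos[3 * i + k];
    kymo(0, i) = col[i];
  }
  frame = 1;

  double half = 0.5 * dt;
  for (int step = 1; step <= nsteps; step++) {
    // B
    for (int i = 0; i < 3 * n; i++) vel[i] += half * frc[i];
    // A
    for (int i = 0; i < 3 * n; i++) pos[i] += half * vel[i];
    // O
    for (int i = 0; i < 3 * n; i++) vel[i] = c1 * vel[i] + c2 * rng_th.norm();
    // A
    for (int i = 0; i < 3 * n; i++) pos[i] += half * vel[i];
    // rebuild neighbour list if needed, then B
    if (m.pairs_on && nl.stale(pos)) nl.build(m, pos);
    forces_cpp(m, pos, &col[0], nl, frc);
    for (int i = 0; i < 3 * n; i++) vel[i] += half * frc[i];

    if (!std::isfinite(pos[0]))
      stop("integrator blow-up at step %d (bead 1 position is not finite); "
           "reduce dt or check the initial configuration", step);

    // recolouring sweep: npoly random single-bead attempts every tau_R
    if (recolour_on && tauR_steps > 0 && step % tauR_steps == 0) {
      if (m.pairs_on && nl.stale(pos)) nl.build(m, pos);
      for (int t = 0; t < npoly; t++) {
        int a = poly[rng_rc.unif_int(npoly)];
        n_attempt++;
        n_accept += attempt_cpp(m, pos, col, nl, a, TR, rng_rc);
      }
    }

    if (step % save_every == 0 && frame < nframes) {
      times[frame] = time0 + step * dt;
      for (int i = 0; i < n; i++) {
        for (int k = 0; k < 3; k++)
          traj[frame * 3 * n + k * n + i] = pos[3 * i + k];
        kymo(frame, i) = col[i];
      }
      frame++;
    }
  }

  NumericMatrix pos_out(n, 3), vel_out(n, 3);
  IntegerVector col_out(n);
  for (int i = 0; i < n; i++) {
    for (int k = 0; k < 3; k++) {
      pos_out(i, k) = pos[3 * i + k];
      vel_out(i, k) = vel[3 * i + k];
    }
    col_out[i] = col[i];
  }
  return List::create(_["positions"] = pos_out, _["velocities"] = vel_out,
                      _["colours"] = col_out, _["times"] = times,
                      _["trajectory"] = traj, _["kymograph"] = kymo,
                      _["time"] = time0 + nsteps * dt,
                      _["recolour_attempts"] = (double)n_attempt,
                      _["recolour_accepts"] = (double)n_accept);
}
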