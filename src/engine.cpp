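// Fixed-step RK4 integrator for the closed-loop lumped-parameter circulation.
//
// State vector (mL): V_LA, V_LV, V_RA, V_RV, V_SA, V_SC, V_SV, V_PA, V_PC, V_PV.
// The same right-hand side is exposed to R (sim_rhs_cpp) so the pure-R
// circulation_rhs() can be property-tested against it.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Double-Hill activation constants, in units of the activation window [0, 1].
static const double ACT_TAU1 = 0.30;
static const double ACT_N1 = 1.32;
static const double ACT_TAU2 = 0.51;
static const double ACT_N2 = 21.9;

// mmHg -> dyn/cm^2 conversion squared into the orifice constant:
// dP[mmHg] = rho/(2 * 1333.22 * A^2) * Q^2 with Q in mL/s, A in cm^2.
static const double MMHG_DYN = 1333.22;

// fractional part in [0, 1); avoids fmod (versioned too recently in glibc
// for the runtime loader of this toolchain)
static inline double wrap1(double x) { return x - std::floor(x); }

// [[Rcpp::export]]
double hill_activation_raw(double x) {
  if (x <= 0.0 || x >= 1.0) return 0.0;
  double r1 = std::pow(x / ACT_TAU1, ACT_N1);
  double r2 = std::pow(x / ACT_TAU2, ACT_N2);
  return (r1 / (1.0 + r1)) / (1.0 + r2);
}

struct Chamber {
  double E_es, E_min, V0, alpha, beta, onset, dur, norm;
};

struct Circuit {
  double R_MV, R_AV, R_TV, R_PAV;
  double R_SZ0, R_SA, R_SC, R_SV;
  double R_PZ0, R_PA, R_PC, R_PV;
  double C_SA, C_SC, C_SV, C_PA, C_PC, C_PV;
  double B_MV, B_AV, B_TV, B_PAV; // Bernoulli orifice coefficients
  double HR;
};

static double getv(const NumericVector& v, const char* nm) {
  if (!v.containsElementNamed(nm)) stop("circuit vector missing element '%s'", nm);
  return v[std::string(nm)];
}

static Circuit parse_circuit(const NumericVector& p) {
  Circuit c;
  c.R_MV = getv(p, "R_MV");   c.R_AV = getv(p, "R_AV");
  c.R_TV = getv(p, "R_TV");   c.R_PAV = getv(p, "R_PAV");
  c.R_SZ0 = getv(p, "R_SZ0"); c.R_SA = getv(p, "R_SA");
  c.R_SC = getv(p, "R_SC");   c.R_SV = getv(p, "R_SV");
  c.R_PZ0 = getv(p, "R_PZ0"); c.R_PA = getv(p, "R_PA");
  c.R_PC = getv(p, "R_PC");   c.R_PV = getv(p, "R_PV");
  c.C_SA = getv(p, "C_SA");   c.C_SC = getv(p, "C_SC");
  c.C_SV = getv(p, "C_SV");   c.C_PA = getv(p, "C_PA");
  c.C_PC = getv(p, "C_PC");   c.C_PV = getv(p, "C_PV");
  c.HR = getv(p, "HR");
  double rho = getv(p, "rho");
  double A_MV = getv(p, "A_MV"), A_AV = getv(p, "A_AV");
  double A_TV = getv(p, "A_TV"), A_PAV = getv(p, "A_PAV");
  c.B_MV = rho / (2.0 * MMHG_DYN * A_MV * A_MV);
  c.B_AV = rho / (2.0 * MMHG_DYN * A_AV * A_AV);
  c.B_TV = rho / (2.0 * MMHG_DYN * A_TV * A_TV);
  c.B_PAV = rho / (2.0 * MMHG_DYN * A_PAV * A_PAV);
  return c;
}

// chambers matrix: rows LA, LV, RA, RV; cols E_es, E_min, V0, alpha, beta,
// onset, dur, norm
static void parse_chambers(const NumericMatrix& m, Chamber ch[4]) {
  if (m.nrow() != 4 || m.ncol() != 8) stop("chambers matrix must be 4 x 8");
  for (int i = 0; i < 4; ++i) {
    ch[i].E_es = m(i, 0); ch[i].E_min = m(i, 1); ch[i].V0 = m(i, 2);
    ch[i].alpha = m(i, 3); ch[i].beta = m(i, 4); ch[i].onset = m(i, 5);
    ch[i].dur = m(i, 6); ch[i].norm = m(i, 7);
  }
}

static inline double activation_at(const Chamber& ch, double phase) {
  double x = phase - ch.onset;
  if (x < 0.0) x += 1.0;
  x /= ch.dur;
  if (x >= 1.0 || x <= 0.0) return 0.0;
  return hill_activation_raw(x) / ch.norm;
}

static inline double chamber_p(const Chamber& ch, double a, double V) {
  return a * ch.E_es * (V - ch.V0) + (1.0 - a) * ch.alpha * std::expm1(ch.beta * V);
}

static inline double valve_q(double dp, double R, double B) {
  if (dp <= 0.0) return 0.0;
  if (B <= 0.0) return dp / R;
  return (-R + std::sqrt(R * R + 4.0 * B * dp)) / (2.0 * B);
}

// outflow throttle near-empty compartments
static inline double floor_f(double V, double vfloor) {
  if (V >= vfloor) return 1.0;
  if (V <= 0.0) return 0.0;
  return V / vfloor;
}

// H-Q quadratic dP = a - b*Q - c*Q^2 (Q in L/min); returns nominal Q (L/min)
static inline double hq_flow(const double* hq_a, const double* hq_b,
                             const double* hq_c, int level, double head) {
  if (level <= 0) return 0.0;
  double a = hq_a[level], b = hq_b[level], cc = hq_c[level];
  if (a <= 0.0) return 0.0;
  double eff = (head <= 0.0) ? a : (a - head); // clamp at zero-head capacity
  if (eff <= 0.0) return 0.0;
  if (cc <= 0.0) return eff / std::max(b, 1e-12);
  return (-b + std::sqrt(b * b + 4.0 * cc * eff)) / (2.0 * cc);
}

struct Aux {
  double P[10];      // LAP LVP RAP RVP SAP SCP SVP PAP PCP PVP
  double q_av;       // trans-aortic-valve flow mL/s
  double q_imp;      // effective Impella flow L/min
  double q_ec;       // effective VA-ECMO flow L/min
  bool suction;      // LAP <= 0
};

// indices in the state vector
enum { iLA, iLV, iRA, iRV, iSA, iSC, iSV, iPA, iPC, iPV };

static void rhs(const Circuit& c, const Chamber ch[4], const double* V,
                double aLA, double aLV, double aRA, double aRV,
                int level, double qec_Lmin,
                const double* hq_a, const double* hq_b, const double* hq_c,
                double limiter_gain, double vfloor,
                double* dV, Aux& aux) {
  double LAP = chamber_p(ch[0], aLA, V[iLA]);
  double LVP = chamber_p(ch[1], aLV, V[iLV]);
  double RAP = chamber_p(ch[2], aRA, V[iRA]);
  double RVP = chamber_p(ch[3], aRV, V[iRV]);
  double SAP = V[iSA] / c.C_SA, SCP = V[iSC] / c.C_SC, SVP = V[iSV] / c.C_SV;
  double PAP = V[iPA] / c.C_PA, PCP = V[iPC] / c.C_PC, PVP = V[iPV] / c.C_PV;

  double q_mv  = floor_f(V[iLA], vfloor) * valve_q(LAP - LVP, c.R_MV, c.B_MV);
  double q_av  = floor_f(V[iLV], vfloor) * valve_q(LVP - SAP, c.R_AV + c.R_SZ0, c.B_AV);
  double q_tv  = floor_f(V[iRA], vfloor) * valve_q(RAP - RVP, c.R_TV, c.B_TV);
  double q_pav = floor_f(V[iRV], vfloor) * valve_q(RVP - PAP, c.R_PAV + c.R_PZ0, c.B_PAV);

  double q_sa_sc = (SAP - SCP) / c.R_SA;
  q_sa_sc *= (q_sa_sc > 0) ? floor_f(V[iSA], vfloor) : floor_f(V[iSC], vfloor);
  double q_sc_sv = (SCP - SVP) / c.R_SC;
  q_sc_sv *= (q_sc_sv > 0) ? floor_f(V[iSC], vfloor) : floor_f(V[iSV], vfloor);
  double q_sv_ra = (SVP - RAP) / c.R_SV;
  q_sv_ra *= (q_sv_ra > 0) ? floor_f(V[iSV], vfloor) : floor_f(V[iRA], vfloor);
  double q_pa_pc = (PAP - PCP) / c.R_PA;
  q_pa_pc *= (q_pa_pc > 0) ? floor_f(V[iPA], vfloor) : floor_f(V[iPC], vfloor);
  double q_pc_pv = (PCP - PVP) / c.R_PC;
  q_pc_pv *= (q_pc_pv > 0) ? floor_f(V[iPC], vfloor) : floor_f(V[iPV], vfloor);
  double q_pv_la = (PVP - LAP) / c.R_PV;
  q_pv_la *= (q_pv_la > 0) ? floor_f(V[iPV], vfloor) : floor_f(V[iLA], vfloor);

  // Impella: head = SAP - LVP; suction limiter throttles below LAP = 0
  double q_imp_nom = hq_flow(hq_a, hq_b, hq_c, level, SAP - LVP);
  if (LAP < 0.0) {
    q_imp_nom -= limiter_gain * (-LAP);
    if (q_imp_nom < 0.0) q_imp_nom = 0.0;
  }
  double q_imp = floor_f(V[iLV], vfloor) * q_imp_nom * (1000.0 / 60.0); // mL/s
  double q_ec = floor_f(V[iSV], vfloor) * qec_Lmin * (1000.0 / 60.0);   // mL/s

  dV[iLA] = q_pv_la - q_mv;
  dV[iLV] = q_mv - q_av - q_imp;
  dV[iSA] = q_av + q_imp + q_ec - q_sa_sc;
  dV[iSC] = q_sa_sc - q_sc_sv;
  dV[iSV] = q_sc_sv - q_sv_ra - q_ec;
  dV[iRA] = q_sv_ra - q_tv;
  dV[iRV] = q_tv - q_pav;
  dV[iPA] = q_pav - q_pa_pc;
  dV[iPC] = q_pa_pc - q_pc_pv;
  dV[iPV] = q_pc_pv - q_pv_la;

  aux.P[0] = LAP; aux.P[1] = LVP; aux.P[2] = RAP; aux.P[3] = RVP;
  aux.P[4] = SAP; aux.P[5] = SCP; aux.P[6] = SVP;
  aux.P[7] = PAP; aux.P[8] = PCP; aux.P[9] = PVP;
  aux.q_av = q_av;
  aux.q_imp = q_imp * (60.0 / 1000.0);
  aux.q_ec = q_ec * (60.0 / 1000.0);
  aux.suction = (LAP <= 0.0);
}

// Single right-hand-side evaluation, exported for cross-checking against the
// pure-R implementation.
// [[Rcpp::export]]
List sim_rhs_cpp(NumericVector state, NumericVector circuit,
                 NumericMatrix chambers, NumericMatrix hq, double t,
                 int impella_level, double vaecmo_flow,
                 double limiter_gain, double v_floor) {
  if (state.size() != 10) stop("state must have 10 volumes");
  Circuit c = parse_circuit(circuit);
  Chamber ch[4];
  parse_chambers(chambers, ch);
  std::vector<double> ha(10), hb(10), hc(10);
  for (int i = 0; i < 10; ++i) { ha[i] = hq(i,0); hb[i] = hq(i,1); hc[i] = hq(i,2); }
  double phase = wrap1(t * c.HR / 60.0);
  double dV[10];
  Aux aux;
  rhs(c, ch, REAL(state),
      activation_at(ch[0], phase), activation_at(ch[1], phase),
      activation_at(ch[2], phase), activation_at(ch[3], phase),
      impella_level, vaecmo_flow, ha.data(), hb.data(), hc.data(),
      limiter_gain, v_floor, dV, aux);
  NumericVector d(10), P(10);
  for (int i = 0; i < 10; ++i) { d[i] = dV[i]; P[i] = aux.P[i]; }
  d.names() = state.names();
  P.names() = CharacterVector::create("LAP","LVP","RAP","RVP","SAP","SCP",
                                      "SVP","PAP","PCP","PVP");
  return List::create(_["dVdt"] = d, _["pressures"] = P,
                      _["q_av"] = aux.q_av, _["q_impella"] = aux.q_imp,
                      _["suction"] = aux.suction);
}

// Full fixed-step RK4 run over a schedule of (duration, impella level,
// VA-ECMO flow) segments. Returns a decimated sample matrix.
// [[Rcpp::export]]
NumericMatrix sim_run_cpp(NumericVector y0, NumericVector circuit,
                          NumericMatrix chambers, NumericMatrix hq,
                          NumericVector seg_duration, IntegerVector seg_level,
                          NumericVector seg_vaecmo, double dt, int decimation,
                          double limiter_gain, double v_floor, double p_max) {
  if (y0.size() != 10) stop("initial state must have 10 volumes");
  if (dt <= 0) stop("dt must be positive");
  if (decimation < 1) stop("decimation must be >= 1");
  Circuit c = parse_circuit(circuit);
  Chamber ch[4];
  parse_chambers(chambers, ch);
  std::vector<double> ha(10), hb(10), hc(10);
  for (int i = 0; i < 10; ++i) { ha[i] = hq(i,0); hb[i] = hq(i,1); hc[i] = hq(i,2); }

  int nseg = seg_duration.size();
  std::vector<long long> seg_steps(nseg);
  long long total_steps = 0;
  for (int s = 0; s < nseg; ++s) {
    if (seg_duration[s] < 0) stop("segment durations must be >= 0");
    seg_steps[s] = (long long)std::llround(seg_duration[s] / dt);
    total_steps += seg_steps[s];
  }

  // Precomputed activation lookup on the RK4 half-step grid when the cardiac
  // period is an integer number of half-steps (true for the default dt).
  double period = 60.0 / c.HR;
  double half_per_cycle = period / (dt / 2.0);
  long long ncyc = (long long)std::llround(half_per_cycle);
  bool use_table = std::fabs(half_per_cycle - (double)ncyc) < 1e-9 && ncyc > 0;
  std::vector<double> actab;
  if (use_table) {
    actab.resize(4 * ncyc);
    for (long long k = 0; k < ncyc; ++k) {
      double phase = (double)k / (double)ncyc;
      for (int j = 0; j < 4; ++j) actab[4 * k + j] = activation_at(ch[j], phase);
    }
  }

  long long nsamp = total_steps / decimation + 1;
  int ncol = 26;
  NumericMatrix out((int)nsamp, ncol);
  CharacterVector cn = CharacterVector::create(
      "t", "LAP", "LVP", "RAP", "RVP", "SAP", "SCP", "SVP", "PAP", "PCP",
      "PVP", "V_LA", "V_LV", "V_RA", "V_RV", "V_SA", "V_SC", "V_SV", "V_PA",
      "V_PC", "V_PV", "Q_av", "Q_impella", "Q_vaecmo", "suction", "impella_level");
  colnames(out) = cn;

  double V[10], k1[10], k2[10], k3[10], k4[10], tmp[10];
  for (int i = 0; i < 10; ++i) V[i] = y0[i];

  const char* pnames[10] = {"LAP","LVP","RAP","RVP","SAP","SCP","SVP","PAP","PCP","PVP"};
  long long gstep = 0; // global step counter, t = gstep * dt
  long long isamp = 0;
  Aux aux;

  #define ACT4(kk, aa)                                                        \
    double aa[4];                                                             \
    if (use_table) {                                                          \
      long long idx = (kk) % ncyc;                                            \
      aa[0] = actab[4*idx]; aa[1] = actab[4*idx+1];                           \
      aa[2] = actab[4*idx+2]; aa[3] = actab[4*idx+3];                         \
    } else {                                                                  \
      double ph = wrap1(((double)(kk)) * (dt / 2.0) / period);                \
      for (int j = 0; j < 4; ++j) aa[j] = activation_at(ch[j], ph);           \
    }

  for (int s = 0; s < nseg; ++s) {
    int level = seg_level[s];
    double qec = seg_vaecmo[s];
    for (long long st = 0; st < seg_steps[s]; ++st) {
      // stage 1 (also the recording point for step gstep)
      ACT4(2 * gstep, a0);
      rhs(c, ch, V, a0[0], a0[1], a0[2], a0[3], level, qec,
          ha.data(), hb.data(), hc.data(), limiter_gain, v_floor, k1, aux);
      if (gstep % decimation == 0) {
        double t = (double)gstep * dt;
        out(isamp, 0) = t;
        for (int i = 0; i < 10; ++i) out(isamp, 1 + i) = aux.P[i];
        for (int i = 0; i < 10; ++i) out(isamp, 11 + i) = V[i];
        out(isamp, 21) = aux.q_av;
        out(isamp, 22) = aux.q_imp;
        out(isamp, 23) = aux.q_ec;
        out(isamp, 24) = aux.suction ? 1.0 : 0.0;
        out(isamp, 25) = (double)level;
        ++isamp;
        for (int i = 0; i < 10; ++i) {
          if (!std::isfinite(aux.P[i]) || std::fabs(aux.P[i]) > p_max)
            stop("numerical blow-up: |%s| = %.1f mmHg > %.0f at t = %.4f s",
                 pnames[i], aux.P[i], p_max, t);
        }
      }
      // stages 2-4
      ACT4(2 * gstep + 1, ah);
      for (int i = 0; i < 10; ++i) tmp[i] = V[i] + 0.5 * dt * k1[i];
      rhs(c, ch, tmp, ah[0], ah[1], ah[2], ah[3], level, qec,
          ha.data(), hb.data(), hc.data(), limiter_gain, v_floor, k2, aux);
      for (int i = 0; i < 10; ++i) tmp[i] = V[i] + 0.5 * dt * k2[i];
      rhs(c, ch, tmp, ah[0], ah[1], ah[2], ah[3], level, qec,
          ha.data(), hb.data(), hc.data(), limiter_gain, v_floor, k3, aux);
      ACT4(2 * gstep + 2, a1);
      for (int i = 0; i < 10; ++i) tmp[i] = V[i] + dt * k3[i];
      rhs(c, ch, tmp, a1[0], a1[1], a1[2], a1[3], level, qec,
          ha.data(), hb.data(), hc.data(), limiter_gain, v_floor, k4, aux);
      for (int i = 0; i < 10; ++i)
        V[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      ++gstep;
      if (gstep % 500000 == 0) Rcpp::checkUserInterrupt();
    }
  }

  // final sample (state at t_end) if it falls on the decimation grid
  if (total_steps % decimation == 0 && isamp < nsamp) {
    int level = nseg > 0 ? seg_level[nseg - 1] : 0;
    double qec = nseg > 0 ? seg_vaecmo[nseg - 1] : 0.0;
    ACT4(2 * gstep, a0);
    rhs(c, ch, V, a0[0], a0[1], a0[2], a0[3], level, qec,
        ha.data(), hb.data(), hc.data(), limiter_gain, v_floor, k1, aux);
    out(isamp, 0) = (double)gstep * dt;
    for (int i = 0; i < 10; ++i) out(isamp, 1 + i) = aux.P[i];
    for (int i = 0; i < 10; ++i) out(isamp, 11 + i) = V[i];
    out(isamp, 21) = aux.q_av;
    out(isamp, 22) = aux.q_imp;
    out(isamp, 23) = aux.q_ec;
    out(isamp, 24) = aux.suction ? 1.0 : 0.0;
    out(isamp, 25) = (double)level;
    ++isamp;
  }
  if (isamp != nsamp)
    stop("internal error: sample count mismatch (%lld vs %lld)",
         (long long)isamp, (long long)nsamp);
  return out;
}
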