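// Event-loop core of the whole-cell simulator.
//
// Couples the DeYoung-Keizer subunit chains of all channels (exact
// stochastic sampling under piecewise-constant local concentrations) to the
// Green's-function field: per-(cluster, mode, root) amplitudes advanced in
// closed form over source-constant intervals, a 4-variable uniform
// component carrying the volume averages and the ER balance, and
// quasi-static cluster currents that switch only at channel open/close
// events. All randomness flows through R's RNG so a set.seed() in R fixes
// the trajectory bit-for-bit.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Kin {
  double a1, a2, a3, a4, a5, b1, b2, b3, b4, b5, ip3;
};

// subunit state s = i*4 + j*2 + k; edge 0 flips the IP3 site, edge 1 the
// activating Ca site, edge 2 the inhibiting Ca site
inline void subunit_rates(int s, double c, const Kin &K, double *r) {
  const int i = (s >> 2) & 1, j = (s >> 1) & 1, k = s & 1;
  r[0] = i == 0 ? (k == 0 ? K.a1 : K.a3) * K.ip3 : (k == 0 ? K.b1 : K.b3);
  r[1] = j == 0 ? K.a5 * c : K.b5;
  r[2] = k == 0 ? (i == 1 ? K.a2 : K.a4) * c : (i == 1 ? K.b2 : K.b4);
}

const int ACTIVE = 6;  // (i,j,k) = (1,1,0)

struct Engine {
  // layout / channels
  int ncl, nchan_total, nsub;
  std::vector<int> cl_of_chan, chan_first_sub;
  std::vector<int> sub_chan;            // channel of each subunit
  std::vector<int> cl_sub_off, cl_sub_cnt;  // subunits grouped per cluster
  std::vector<int> state;               // encoded subunit states
  std::vector<int> n_active;            // active subunits per channel
  std::vector<char> chan_open;
  std::vector<int> n_open;              // per cluster
  std::vector<double> I;                // per-cluster current (uM um^3/s)
  int inh_count = 0, open_total = 0;

  // kinetics / propensities
  Kin K;
  std::vector<double> rate;             // 3 per subunit
  std::vector<double> subprop, clprop;
  double Lam = 0;

  // physical constants
  double c0, E0, gamma, Vcell, Dc, k1, Rs, gdiff;  // gdiff = 1/DE + 1/Dc

  // field modes
  int m;                                // number of spatial modes
  std::vector<double> lambda, invlam, embuf;  // length 3m
  std::vector<double> Rc;               // length 3m (residues for Ca)
  std::vector<double> A;                // ncl * 3m transient amplitudes
  std::vector<double> ac;               // ncl * m collapsed amplitudes
  std::vector<double> geo;              // ncl*ncl*m pair factors
  std::vector<double> geomax;           // m
  std::vector<double> Spair;            // ncl*ncl static pair gains
  std::vector<double> cmode, selfpair, cstat;  // per cluster
  double t_field = 0;
  bool dormant = true;
  double field_tol;

  // uniform component (c,b,h,E deviations)
  double u[4] = {0, 0, 0, 0};
  double Vu[16], Vui[16], lam_u[4];
  double t_unif = 0;
  double Jtot = 0;

  // env cache
  std::vector<double> c_loc;
  double t_env = 0;

  long n_events = 0, n_full_refresh = 0;

  void advance_uniform(double t) {
    const double dt = t - t_unif;
    if (dt <= 0) { t_unif = t; return; }
    // Vu/Vui are stored column-major (R layout): element (i, j) = [j*4+i]
    double w[4], wf[4], f[4] = {Jtot / Vcell, 0, 0, -gamma * Jtot / Vcell};
    for (int i = 0; i < 4; i++) {
      w[i] = wf[i] = 0;
      for (int j = 0; j < 4; j++) {
        w[i] += Vui[j * 4 + i] * u[j];
        wf[i] += Vui[j * 4 + i] * f[j];
      }
    }
    for (int i = 0; i < 4; i++) {
      const double ld = lam_u[i] * dt;
      const double em = std::exp(ld);
      const double ph = std::fabs(ld) < 1e-8 ? dt * (1 + 0.5 * ld)
                                             : std::expm1(ld) / lam_u[i];
      w[i] = em * w[i] + ph * wf[i];
    }
    for (int i = 0; i < 4; i++) {
      u[i] = 0;
      for (int j = 0; j < 4; j++) u[i] += Vu[j * 4 + i] * w[j];
    }
    t_unif = t;
  }

  void advance_amps(double t) {
    if (dormant) { t_field = t; return; }
    const double dt = t - t_field;
    if (dt <= 0) { t_field = t; return; }
    const int m3 = 3 * m;
    for (int i = 0; i < m3; i++) embuf[i] = std::exp(lambda[i] * dt);
    for (int s = 0; s < ncl; s++) {
      double *a = &A[(size_t)s * m3];
      for (int i = 0; i < m3; i++) a[i] *= embuf[i];
    }
    t_field = t;
  }

  // collapse amplitudes with residues; returns an upper bound on any
  // cluster's mode-field magnitude for the dormancy test
  double collapse() {
    double bound = 0;
    for (int mm = 0; mm < m; mm++) {
      double colabs = 0;
      for (int s = 0; s < ncl; s++) {
        const double *a = &A[((size_t)s * m + mm) * 3];
        const double v = Rc[mm * 3] * a[0] + Rc[mm * 3 + 1] * a[1] +
                         Rc[mm * 3 + 2] * a[2];
        ac[(size_t)s * m + mm] = v;
        colabs += std::fabs(v);
      }
      bound += geomax[mm] * colabs;
    }
    return bound;
  }

  void eval_mode_fields() {
    for (int j = 0; j < ncl; j++) {
      double tot = 0;
      for (int s = 0; s < ncl; s++) {
        const double *g = &geo[((size_t)j * ncl + s) * m];
        const double *a = &ac[(size_t)s * m];
        double d = 0;
        for (int mm = 0; mm < m; mm++) d += g[mm] * a[mm];
        tot += d;
        if (s == j) selfpair[j] = d;
      }
      cmode[j] = tot;
    }
  }

  bool any_open() const { return open_total > 0; }

  void refresh_env(double t) {
    advance_uniform(t);
    if (!dormant) {
      advance_amps(t);
      const double bound = collapse();
      if (bound < field_tol && !any_open()) {
        dormant = true;
        std::fill(A.begin(), A.end(), 0.0);
        std::fill(cmode.begin(), cmode.end(), 0.0);
        std::fill(selfpair.begin(), selfpair.end(), 0.0);
      } else {
        eval_mode_fields();
      }
    }
    // static response to the instantaneous currents
    if (Jtot != 0.0 || any_open()) {
      for (int j = 0; j < ncl; j++) {
        double tot = 0;
        for (int s = 0; s < ncl; s++) {
          if (I[s] != 0.0) tot += I[s] * Spair[(size_t)j * ncl + s];
        }
        cstat[j] = tot;
      }
    } else {
      std::fill(cstat.begin(), cstat.end(), 0.0);
    }
    const double base = c0 + u[0];
    for (int kcl = 0; kcl < ncl; kcl++) {
      double cc;
      if (n_open[kcl] > 0) {
        const double Rcl = Rs * std::sqrt((double)n_open[kcl]);
        cc = base + (cstat[kcl] - I[kcl] * Spair[(size_t)kcl * ncl + kcl]) +
             (cmode[kcl] - selfpair[kcl]) +
             I[kcl] / (4 * M_PI * Dc * Rcl);
      } else {
        cc = base + cstat[kcl] + cmode[kcl];
      }
      c_loc[kcl] = cc > 0 ? cc : 0;
    }
    recompute_all_rates();
    t_env = t;
    n_full_refresh++;
  }

  void recompute_all_rates() {
    Lam = 0;
    for (int kcl = 0; kcl < ncl; kcl++) {
      double cp = 0;
      const double cc = c_loc[kcl];
      for (int si = cl_sub_off[kcl]; si < cl_sub_off[kcl] + cl_sub_cnt[kcl];
           si++) {
        double *r = &rate[3 * (size_t)si];
        subunit_rates(state[si], cc, K, r);
        subprop[si] = r[0] + r[1] + r[2];
        cp += subprop[si];
      }
      clprop[kcl] = cp;
      Lam += cp;
    }
  }

  // returns true when the flip changed the cluster's open-channel count
  bool apply_flip(int si, int edge) {
    const int mask = edge == 0 ? 4 : (edge == 1 ? 2 : 1);
    const int snew = state[si] ^ mask;
    const int ch = sub_chan[si];
    if (edge == 2) inh_count += (snew & 1) ? 1 : -1;
    if (state[si] == ACTIVE) n_active[ch]--;
    state[si] = snew;
    if (snew == ACTIVE) n_active[ch]++;
    const bool open_now = n_active[ch] >= 3;
    bool changed = false;
    const int kcl = cl_of_chan[ch];
    if (open_now != (bool)chan_open[ch]) {
      chan_open[ch] = open_now;
      n_open[kcl] += open_now ? 1 : -1;
      open_total += open_now ? 1 : -1;
      changed = true;
    }
    // refresh this subunit's rates at the cached env
    double *r = &rate[3 * (size_t)si];
    const double old = subprop[si];
    subunit_rates(snew, c_loc[kcl], K, r);
    subprop[si] = r[0] + r[1] + r[2];
    clprop[kcl] += subprop[si] - old;
    Lam += subprop[si] - old;
    return changed;
  }

  void set_cluster_current(int kcl, double t) {
    // decay existing transients to the switch time, then jump
    advance_amps(t);
    advance_uniform(t);
    double Inew = 0;
    if (n_open[kcl] > 0) {
      const double dC = (E0 + u[3]) - (c0 + u[0]);
      const double n = (double)n_open[kcl];
      Inew = n * k1 * dC /
             (1 + std::sqrt(n) * k1 * gdiff / (4 * M_PI * Rs));
    }
    const double dI = Inew - I[kcl];
    if (dI != 0.0) {
      dormant = false;
      double *a = &A[(size_t)kcl * 3 * m];
      for (int i = 0; i < 3 * m; i++) a[i] += dI * invlam[i];
    }
    Jtot += dI;
    I[kcl] = Inew;
  }
};

}  // namespace

// [[Rcpp::export(name = ".run_engine")]]
List run_engine(IntegerVector n_channels, NumericVector kin, double ip3,
                List phys, NumericVector lambda, NumericVector res_c,
                NumericVector geo, NumericVector geomax,
                NumericVector s_pair,
                NumericMatrix Vu, NumericMatrix Vui, NumericVector lam_u,
                IntegerVector init_states, double t_end, double dt_record,
                double env_refresh, double refresh_cap, double field_tol,
                bool record_cluster_open) {
  Engine E;
  E.ncl = n_channels.size();
  E.K = {kin[0], kin[1], kin[2], kin[3], kin[4],
         kin[5], kin[6], kin[7], kin[8], kin[9], ip3};
  E.c0 = phys["c0"]; E.E0 = phys["E0"]; E.gamma = phys["gamma"];
  E.Vcell = phys["V_cell"]; E.Dc = phys["D_c"]; E.k1 = phys["channel_flux"];
  E.Rs = phys["channel_radius"];
  E.gdiff = 1.0 / as<double>(phys["D_E"]) + 1.0 / as<double>(phys["D_c"]);
  E.field_tol = field_tol;

  // channels and subunits grouped by cluster
  E.nchan_total = 0;
  for (int kcl = 0; kcl < E.ncl; kcl++) E.nchan_total += n_channels[kcl];
  E.nsub = 4 * E.nchan_total;
  E.cl_of_chan.resize(E.nchan_total);
  E.sub_chan.resize(E.nsub);
  E.cl_sub_off.resize(E.ncl);
  E.cl_sub_cnt.resize(E.ncl);
  {
    int ch = 0, si = 0;
    for (int kcl = 0; kcl < E.ncl; kcl++) {
      E.cl_sub_off[kcl] = si;
      E.cl_sub_cnt[kcl] = 4 * n_channels[kcl];
      for (int c = 0; c < n_channels[kcl]; c++, ch++) {
        E.cl_of_chan[ch] = kcl;
        for (int s = 0; s < 4; s++, si++) E.sub_chan[si] = ch;
      }
    }
  }
  if (init_states.size() != E.nsub) stop("init_states has wrong length");
  E.rate.assign(3 * (size_t)E.nsub, 0.0);
  E.subprop.assign(E.nsub, 0.0);
  E.clprop.assign(E.ncl, 0.0);
  E.state.assign(init_states.begin(), init_states.end());
  E.n_active.assign(E.nchan_total, 0);
  E.chan_open.assign(E.nchan_total, 0);
  E.n_open.assign(E.ncl, 0);
  E.I.assign(E.ncl, 0.0);
  for (int si = 0; si < E.nsub; si++) {
    if (E.state[si] == ACTIVE) E.n_active[E.sub_chan[si]]++;
    if (E.state[si] & 1) E.inh_count++;
  }
  for (int ch = 0; ch < E.nchan_total; ch++) {
    if (E.n_active[ch] >= 3) {
      E.chan_open[ch] = 1;
      E.n_open[E.cl_of_chan[ch]]++;
      E.open_total++;
    }
  }

  // field setup
  E.m = geomax.size();
  const int m3 = 3 * E.m;
  if (lambda.size() != m3 || res_c.size() != m3)
    stop("lambda/res_c must have 3*m entries");
  if (geo.size() != (R_xlen_t)E.ncl * E.ncl * E.m)
    stop("geo has wrong length");
  if (s_pair.size() != (R_xlen_t)E.ncl * E.ncl)
    stop("s_pair has wrong length");
  E.lambda.assign(lambda.begin(), lambda.end());
  E.invlam.resize(m3);
  for (int i = 0; i < m3; i++) E.invlam[i] = 1.0 / E.lambda[i];
  E.Rc.assign(res_c.begin(), res_c.end());
  E.geo.assign(geo.begin(), geo.end());
  E.geomax.assign(geomax.begin(), geomax.end());
  E.Spair.assign(s_pair.begin(), s_pair.end());
  E.A.assign((size_t)E.ncl * m3, 0.0);
  E.ac.assign((size_t)E.ncl * E.m, 0.0);
  E.embuf.resize(m3);
  E.cmode.assign(E.ncl, 0.0);
  E.selfpair.assign(E.ncl, 0.0);
  E.cstat.assign(E.ncl, 0.0);
  E.c_loc.assign(E.ncl, E.c0);
  for (int i = 0; i < 16; i++) { E.Vu[i] = Vu[i]; E.Vui[i] = Vui[i]; }
  for (int i = 0; i < 4; i++) E.lam_u[i] = lam_u[i];

  // event log
  std::vector<double> ev_t, ev_I;
  std::vector<int> ev_cl, ev_nopen;
  auto log_event = [&](double t, int kcl) {
    ev_t.push_back(t); ev_cl.push_back(kcl + 1);
    ev_nopen.push_back(E.n_open[kcl]); ev_I.push_back(E.I[kcl]);
  };

  // initial currents for channels that start open
  for (int kcl = 0; kcl < E.ncl; kcl++) {
    if (E.n_open[kcl] > 0) {
      E.set_cluster_current(kcl, 0.0);
      log_event(0.0, kcl);
    }
  }

  // recording buffers
  const int n_rec = (int)std::floor(t_end / dt_record + 1e-9);
  NumericVector rec_t(n_rec), rec_c(n_rec), rec_E(n_rec);
  IntegerVector rec_open(n_rec), rec_inh(n_rec);
  IntegerMatrix rec_cl_open(record_cluster_open ? n_rec : 0,
                            record_cluster_open ? E.ncl : 0);
  int i_rec = 0;

  RNGScope rng;
  E.refresh_env(0.0);
  double t = 0.0;
  double e_budget = exp_rand();
  double cur_interval = env_refresh > 0 ? env_refresh : R_PosInf;
  const double grow = 1.5;
  double next_refresh = env_refresh > 0 ? cur_interval : R_PosInf;

  while (t < t_end) {
    double next_rec = (i_rec < n_rec) ? dt_record * (i_rec + 1) : R_PosInf;
    double t_b = std::min(std::min(next_rec, next_refresh), t_end);
    bool event_fired = false;
    if (E.Lam > 0) {
      const double dt_ev = e_budget / E.Lam;
      if (t + dt_ev < t_b) {
        t += dt_ev;
        event_fired = true;
      } else {
        e_budget -= E.Lam * (t_b - t);
        if (e_budget < 0) e_budget = 0;
        t = t_b;
      }
    } else {
      t = t_b;
    }

    if (event_fired) {
      // select transition: fixed (cluster, subunit, edge) order
      double v = unif_rand() * E.Lam;
      int kcl = 0;
      while (kcl < E.ncl - 1 && v > E.clprop[kcl]) v -= E.clprop[kcl++];
      int si = E.cl_sub_off[kcl];
      const int si_end = si + E.cl_sub_cnt[kcl] - 1;
      while (si < si_end && v > E.subprop[si]) v -= E.subprop[si++];
      const double *r = &E.rate[3 * (size_t)si];
      int edge = 0;
      if (v > r[0]) { v -= r[0]; edge = (v > r[1]) ? 2 : 1; }
      const bool changed = E.apply_flip(si, edge);
      E.n_events++;
      if (changed) {
        E.set_cluster_current(kcl, t);
        log_event(t, kcl);
        E.refresh_env(t);
        cur_interval = env_refresh > 0 ? env_refresh : R_PosInf;
        next_refresh = env_refresh > 0 ? t + cur_interval : R_PosInf;
      } else if (env_refresh <= 0) {
        E.refresh_env(t);  // spec-strict mode: refresh at every event
      }
      e_budget = exp_rand();
      if (E.n_events % 16384 == 0) Rcpp::checkUserInterrupt();
      continue;
    }

    // boundary reached: record and/or refresh
    if (i_rec < n_rec && t >= dt_record * (i_rec + 1) - 1e-12) {
      E.advance_uniform(t);
      rec_t[i_rec] = t;
      rec_c[i_rec] = E.c0 + E.u[0];
      rec_E[i_rec] = E.E0 + E.u[3];
      rec_open[i_rec] = E.open_total;
      rec_inh[i_rec] = E.inh_count;
      if (record_cluster_open) {
        for (int kcl = 0; kcl < E.ncl; kcl++)
          rec_cl_open(i_rec, kcl) = E.n_open[kcl];
      }
      i_rec++;
    }
    if (t >= next_refresh - 1e-12 || t >= t_end) {
      E.refresh_env(t);
      if (!E.any_open()) {
        // sources silent: the field only relaxes, so the refresh interval
        // may grow geometrically up to a cap without losing accuracy
        cur_interval = std::min(cur_interval * grow,
                                std::max(refresh_cap, env_refresh));
      } else {
        cur_interval = env_refresh > 0 ? env_refresh : R_PosInf;
      }
      next_refresh = env_refresh > 0 ? t + cur_interval : R_PosInf;
    } else {
      // record boundary without full refresh: rates follow the uniform
      // drift cheaply when the mode field is dormant
      if (E.dormant) {
        E.advance_uniform(t);
        const double base = E.c0 + E.u[0];
        for (int kcl = 0; kcl < E.ncl; kcl++)
          E.c_loc[kcl] = base > 0 ? base : 0;
        E.recompute_all_rates();
        E.t_env = t;
      }
    }
    if (t >= t_end) break;
  }

  E.advance_amps(t_end);
  E.advance_uniform(t_end);

  E.refresh_env(t_end);
  List final_state = List::create(
      _["sub_state"] = IntegerVector(E.state.begin(), E.state.end()),
      _["A"] = NumericVector(E.A.begin(), E.A.end()),
      _["u"] = NumericVector(E.u, E.u + 4),
      _["currents"] = NumericVector(E.I.begin(), E.I.end()),
      _["n_open"] = IntegerVector(E.n_open.begin(), E.n_open.end()),
      _["c_loc"] = NumericVector(E.c_loc.begin(), E.c_loc.end()),
      _["t"] = t_end, _["dormant"] = E.dormant);

  List out = List::create(
      _["time"] = rec_t, _["c_avg"] = rec_c, _["E_avg"] = rec_E,
      _["n_open"] = rec_open, _["n_inhibited"] = rec_inh,
      _["events"] = List::create(
          _["time"] = NumericVector(ev_t.begin(), ev_t.end()),
          _["cluster"] = IntegerVector(ev_cl.begin(), ev_cl.end()),
          _["n_open"] = IntegerVector(ev_nopen.begin(), ev_nopen.end()),
          _["current"] = NumericVector(ev_I.begin(), ev_I.end())),
      _["final"] = final_state,
      _["n_events"] = (double)E.n_events,
      _["n_refresh"] = (double)E.n_full_refresh);
  if (record_cluster_open) out["cluster_open"] = rec_cl_open;
  return out;
}
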