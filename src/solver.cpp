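// Compiled core of the branched-cable integrator.
//
// Staggered scheme per step, mirroring the R reference stepper:
//   (1) calcium influx from Ca channels at the current V and gate values
//   (2) exact-exponential updates of gates, Markov occupancies, Ca pools
//   (3) dynamic calcium reversal from the Nernst relation
//   (4) backward-Euler voltage solve on the tree (direct Hines elimination)
//
// Kinetics arrive as tabulated inf/tau (or Markov rate) curves on a uniform
// voltage grid; the solver only interpolates.

#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct Chan {
  int seg;        // 0-based segment
  int kind;       // 0 leak, 1 gated, 2 sk, 3 markov
  double gbar, erev;
  bool dynca, isca;
  std::vector<int> gate_tab;  // 0-based table columns
  std::vector<int> gate_exp;
  double sk_kd, sk_hill;
  // markov
  int nstates = 0;
  std::vector<int> conducting, m_from, m_to, m_tab;  // 0-based
  std::vector<double> x;  // gate values or occupancies
};

inline double lookup(const arma::mat& tab, int col, double v,
                     double vmin, double dv) {
  double x = (v - vmin) / dv;
  int n = tab.n_rows;
  if (x < 0) x = 0;
  if (x > n - 1.000001) x = n - 1.000001;
  int i = (int)x;
  double w = x - i;
  return (1 - w) * tab(i, col) + w * tab(i + 1, col);
}

inline double chan_open(const Chan& c, double ca) {
  switch (c.kind) {
    case 0: return 1.0;
    case 1: {
      double o = 1.0;
      for (size_t k = 0; k < c.x.size(); ++k) {
        double g = c.x[k];
        if (g < 0) g = 0; else if (g > 1) g = 1;
        for (int e = 0; e < c.gate_exp[k]; ++e) o *= g;
      }
      return o;
    }
    case 2: {
      double cc = ca > 1e-12 ? ca : 1e-12;
      return 1.0 / (1.0 + std::pow(c.sk_kd / cc, c.sk_hill));
    }
    default: {
      double o = 0.0;
      for (int s : c.conducting) o += c.x[s];
      return o;
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List simulate_cpp(List compiled, List init_gates, double dt, double settle,
                  double dur, double amp_nA, int stim_seg1, int record_ca) {
  const int nseg = as<int>(compiled["nseg"]);
  const IntegerVector parent1 = compiled["parent"];
  const NumericVector gax = compiled["gax"];
  const NumericVector area = compiled["area_cm2"];
  const NumericVector cm_uF = compiled["cm"];
  const double v_init = as<double>(compiled["v_init"]);
  const double vmin = as<double>(compiled["vmin"]);
  const double dv = as<double>(compiled["dv"]);
  const arma::mat inf_tab = as<arma::mat>(compiled["inf"]);
  const arma::mat tau_tab = as<arma::mat>(compiled["tau"]);
  const arma::mat mrate_tab = as<arma::mat>(compiled["mrate"]);
  const IntegerVector pool_has = compiled["pool_has"];
  const List pool = compiled["pool"];
  const double p_k = as<double>(pool["k"]);
  const double p_tau = as<double>(pool["tau"]);
  const double p_rest = as<double>(pool["rest"]);
  const double p_camin = as<double>(pool["camin"]);
  const double p_caout = as<double>(pool["ca_out"]);
  const double p_ecoef = as<double>(pool["ecoef"]);

  const List chlist = compiled["channels"];
  std::vector<Chan> chans(chlist.size());
  for (int i = 0; i < chlist.size(); ++i) {
    List cl = chlist[i];
    Chan& c = chans[i];
    c.seg = as<int>(cl["seg"]) - 1;
    c.kind = as<int>(cl["kind"]);
    c.gbar = as<double>(cl["gbar"]);
    c.erev = as<double>(cl["erev"]);
    c.dynca = as<int>(cl["dynca"]) != 0;
    c.isca = as<int>(cl["isca"]) != 0;
    if (c.kind == 1) {
      IntegerVector gt = cl["gate_tab"], ge = cl["gate_exp"];
      for (int k = 0; k < gt.size(); ++k) {
        c.gate_tab.push_back(gt[k] - 1);
        c.gate_exp.push_back(ge[k]);
      }
    }
    c.sk_kd = as<double>(cl["sk_kd"]);
    c.sk_hill = as<double>(cl["sk_hill"]);
    if (c.kind == 3) {
      List mk = cl["markov"];
      c.nstates = as<int>(mk["nstates"]);
      IntegerVector cond = mk["conducting"], mf = mk["from"], mt = mk["to"],
                    mtab = mk["tab"];
      for (int s : cond) c.conducting.push_back(s - 1);
      for (int k = 0; k < mf.size(); ++k) {
        c.m_from.push_back(mf[k] - 1);
        c.m_to.push_back(mt[k] - 1);
        c.m_tab.push_back(mtab[k] - 1);
      }
    }
    NumericVector x0 = init_gates[i];
    c.x.assign(x0.begin(), x0.end());
  }

  std::vector<int> parent(nseg);
  for (int j = 0; j < nseg; ++j) parent[j] = parent1[j] - 1;
  const int stim_seg = stim_seg1 - 1;

  arma::vec V(nseg), ca(nseg), eca(nseg), ica(nseg);
  V.fill(v_init);
  ca.fill(p_rest);
  arma::vec d(nseg), b(nseg), offc(nseg), offp(nseg), dd(nseg), bb(nseg);
  for (int j = 0; j < nseg; ++j) {
    offc[j] = parent[j] >= 0 ? -gax[j] / area[j] : 0.0;
  }

  const long n_settle = (long)std::lround(settle / dt);
  const long n_stim = (long)std::lround(dur / dt);
  NumericVector vout(n_stim);
  NumericVector caout(record_ca ? n_stim : 0);

  const double exp_pool = std::exp(-dt / p_tau);

  for (long it = 0; it < n_settle + n_stim; ++it) {
    const double stim = (it >= n_settle) ? amp_nA * 1e-6 : 0.0;

    // calcium reversal at current concentrations
    for (int j = 0; j < nseg; ++j)
      if (pool_has[j]) eca[j] = p_ecoef * std::log(p_caout / std::max(ca[j], p_camin));

    // (1) calcium influx at current V and gates
    ica.zeros();
    for (const Chan& c : chans)
      if (c.isca) {
        double e = c.dynca ? eca[c.seg] : c.erev;
        ica[c.seg] += c.gbar * chan_open(c, ca[c.seg]) * (V[c.seg] - e);
      }

    // (2) state updates at current V
    for (Chan& c : chans) {
      if (c.kind == 1) {
        for (size_t k = 0; k < c.x.size(); ++k) {
          double inf = lookup(inf_tab, c.gate_tab[k], V[c.seg], vmin, dv);
          double tau = lookup(tau_tab, c.gate_tab[k], V[c.seg], vmin, dv);
          c.x[k] = inf + (c.x[k] - inf) * std::exp(-dt / tau);
        }
      } else if (c.kind == 3) {
        arma::mat Q(c.nstates, c.nstates, arma::fill::zeros);
        for (size_t k = 0; k < c.m_from.size(); ++k) {
          double r = lookup(mrate_tab, c.m_tab[k], V[c.seg], vmin, dv);
          Q(c.m_to[k], c.m_from[k]) += r;
          Q(c.m_from[k], c.m_from[k]) -= r;
        }
        arma::vec p(c.x.data(), c.nstates);
        arma::vec pn = arma::expmat(Q * dt) * p;
        for (int s = 0; s < c.nstates; ++s) c.x[s] = pn[s];
      }
    }
    for (int j = 0; j < nseg; ++j)
      if (pool_has[j]) {
        double target = p_rest - p_k * p_tau * ica[j];
        ca[j] = target + (ca[j] - target) * exp_pool;
        if (ca[j] < p_camin) ca[j] = p_camin;
        // (3) updated calcium reversal
        eca[j] = p_ecoef * std::log(p_caout / ca[j]);
      }

    // (4) backward-Euler voltage solve
    for (int j = 0; j < nseg; ++j) {
      double a = cm_uF[j] * 1e-3 / dt;
      d[j] = a;
      b[j] = a * V[j];
      offp[j] = 0.0;
    }
    b[stim_seg] += stim / area[stim_seg];
    for (const Chan& c : chans) {
      double g = c.gbar * chan_open(c, ca[c.seg]);
      double e = c.dynca ? eca[c.seg] : c.erev;
      d[c.seg] += g;
      b[c.seg] += g * e;
    }
    for (int j = 0; j < nseg; ++j) {
      int p = parent[j];
      if (p >= 0) {
        d[j] += gax[j] / area[j];
        d[p] += gax[j] / area[p];
        offp[j] = -gax[j] / area[p];
      }
    }
    dd = d; bb = b;
    for (int j = nseg - 1; j >= 1; --j) {
      int p = parent[j];
      double f = offp[j] / dd[j];
      dd[p] -= f * offc[j];
      bb[p] -= f * bb[j];
    }
    V[0] = bb[0] / dd[0];
    for (int j = 1; j < nseg; ++j) V[j] = (bb[j] - offc[j] * V[parent[j]]) / dd[j];

    if (it >= n_settle) {
      vout[it - n_settle] = V[stim_seg];
      if (record_ca) caout[it - n_settle] = ca[stim_seg];
    }
  }

  List out = List::create(Named("v") = vout);
  if (record_ca) out["ca"] = caout;
  return out;
}
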