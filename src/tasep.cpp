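// Continuous-time kinetic Monte Carlo engine for open-boundary TASEP with
// static slow sites or dynamically binding obstacles.
//
// Lattice sites are 1..L. Particles (Pol II) enter at site 1 with rate alpha
// when the site is free, hop forward under hard-core exclusion, and exit from
// site L with rate beta. Variants:
//   0 slow_sites:          hop rate v_s out of special sites, v elsewhere
//   1 dynamical_obstacles: obstacles bind free special sites with rate
//                          k_u * p * mult and unbind with rate k_u; an
//                          obstacle blocks hops into its site
//   2 slowdown_obstacles:  obstacles do not block; a particle on an
//                          obstacle-bearing site hops out with rate v_s
// Uses R's RNG (unif_rand / exp_rand) so set.seed() governs reproducibility.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct IndexSet {
  std::vector<int> items;
  std::vector<int> slot;
  explicit IndexSet(int n) : slot(n + 2, -1) {}
  bool has(int i) const { return slot[i] >= 0; }
  void add(int i) {
    if (slot[i] >= 0) return;
    slot[i] = (int)items.size();
    items.push_back(i);
  }
  void remove(int i) {
    int s = slot[i];
    if (s < 0) return;
    int last = items.back();
    items[s] = last;
    slot[last] = s;
    items.pop_back();
    slot[i] = -1;
  }
  int size() const { return (int)items.size(); }
  int pick() const {
    int k = (int)(unif_rand() * items.size());
    if (k >= (int)items.size()) k = (int)items.size() - 1;
    return items[k];
  }
};

}  // namespace

// [[Rcpp::export(name = ".tasep_engine")]]
List tasep_engine(int L, double alpha, double beta, double v, double vs,
                  double ku, double p, int variant,
                  IntegerVector special, IntegerVector mult,
                  double burn_in, double measure, int n_batch,
                  int max_particles, double kymo_dt, int init_obs) {
  if (L < 2) stop("L must be at least 2");
  if (alpha < 0 || beta <= 0 || v <= 0 || vs < 0 || ku < 0 || p < 0)
    stop("rates must be non-negative (beta, v positive)");
  const bool blocking = (variant == 1);
  const bool dynamic = (variant == 1 || variant == 2);

  std::vector<char> pol(L + 2, 0), obs(L + 2, 0), isSpec(L + 2, 0);
  std::vector<int> m(L + 2, 0);
  int maxMult = 1;
  for (int k = 0; k < special.size(); ++k) {
    int s = special[k];
    if (s < 1 || s > L) stop("special site index out of range");
    isSpec[s] = 1;
    m[s] = (mult.size() == special.size()) ? mult[k] : 1;
    if (m[s] < 1) stop("mCG multiplicity must be >= 1");
    if (m[s] > maxMult) maxMult = m[s];
  }

  IndexSet fastH(L), slowH(L), freeSp(L), boundO(L);
  long sumMultFree = 0;

  RNGScope rngScope;

  // helper lambdas -----------------------------------------------------------
  auto outSlow = [&](int i) -> bool {
    if (variant == 0) return isSpec[i];
    if (variant == 2) return obs[i];
    return false;
  };
  auto canHop = [&](int i) -> bool {
    return pol[i] && i < L && !pol[i + 1] && !(blocking && obs[i + 1]);
  };
  auto updHop = [&](int i) {
    if (i < 1 || i > L) return;
    fastH.remove(i);
    slowH.remove(i);
    if (canHop(i)) {
      if (outSlow(i)) slowH.add(i); else fastH.add(i);
    }
  };
  auto updFree = [&](int i) {
    if (i < 1 || i > L || !isSpec[i] || !dynamic) return;
    bool eligible = !obs[i] && !pol[i];
    if (eligible && !freeSp.has(i)) { freeSp.add(i); sumMultFree += m[i]; }
    else if (!eligible && freeSp.has(i)) { freeSp.remove(i); sumMultFree -= m[i]; }
  };

  // initial obstacle configuration ------------------------------------------
  std::vector<double> bindTime(L + 2, 0.0);
  if (dynamic && init_obs > 0) {
    for (int i = 1; i <= L; ++i) {
      if (!isSpec[i]) continue;
      double q = p * m[i] / (1.0 + p * m[i]);
      if (init_obs == 2 || unif_rand() < q) {
        obs[i] = 1;
        boundO.add(i);
      }
    }
  }
  if (dynamic) for (int i = 1; i <= L; ++i) updFree(i);

  // bookkeeping --------------------------------------------------------------
  const double t_end = burn_in + measure;
  const double batch_len = measure / n_batch;
  double t = 0.0;
  long entries = 0, exits = 0, exits_meas = 0, hops_meas = 0;
  int n_pol = 0;
  double polInt = 0.0;  // integral of particle count over measurement window
  std::vector<double> batchExits(n_batch, 0.0);
  std::vector<double> occT(L + 2, 0.0), obsT(L + 2, 0.0);
  std::vector<double> occSince(L + 2, 0.0), obsSince(L + 2, 0.0);
  double resSum = 0.0;
  long resN = 0;
  for (int i = 1; i <= L; ++i) if (obs[i]) { bindTime[i] = 0.0; obsSince[i] = 0.0; }

  int n_snap = 0;
  if (kymo_dt > 0) n_snap = (int)(measure / kymo_dt) + 1;
  IntegerMatrix kymoPol(n_snap > 0 ? n_snap : 0, n_snap > 0 ? L : 0);
  IntegerMatrix kymoObs((n_snap > 0 && dynamic) ? n_snap : 0,
                        (n_snap > 0 && dynamic) ? L : 0);
  int snap_i = 0;
  double next_snap = (kymo_dt > 0) ? burn_in : R_PosInf;

  auto measuredDt = [&](double t0, double t1) -> double {
    double lo = t0 > burn_in ? t0 : burn_in;
    double hi = t1 < t_end ? t1 : t_end;
    return hi > lo ? hi - lo : 0.0;
  };

  long guard = 0;
  const long guard_max = 2000000000L;
  while (t < t_end) {
    if (++guard > guard_max) stop("event budget exceeded");
    bool entry_ok = !pol[1] && !(blocking && obs[1]) &&
                    (max_particles <= 0 || n_pol < max_particles);
    double rEntry = entry_ok ? alpha : 0.0;
    double rExit = pol[L] ? beta : 0.0;
    double rFast = v * fastH.size();
    double rSlow = vs * slowH.size();
    double rBind = dynamic ? ku * p * (double)sumMultFree : 0.0;
    double rUnbind = dynamic ? ku * boundO.size() : 0.0;
    double R = rEntry + rExit + rFast + rSlow + rBind + rUnbind;
    if (R <= 0) {  // frozen configuration: jump to end
      polInt += n_pol * measuredDt(t, t_end);
      t = t_end;
      break;
    }
    double dt = exp_rand() / R;
    double t_new = t + dt;

    // snapshots due before this event
    while (next_snap <= t_new && snap_i < n_snap) {
      for (int i = 1; i <= L; ++i) {
        kymoPol(snap_i, i - 1) = pol[i];
        if (dynamic) kymoObs(snap_i, i - 1) = obs[i];
      }
      ++snap_i;
      next_snap += kymo_dt;
    }
    polInt += n_pol * measuredDt(t, t_new);
    t = t_new;
    if (t >= t_end) break;

    double u = unif_rand() * R;
    if (u < rEntry) {
      // entry at site 1
      if (pol[1]) stop("exclusion violated at entry");
      pol[1] = 1;
      occSince[1] = t;
      ++n_pol;
      ++entries;
      updHop(1);
      updFree(1);
    } else if (u < rEntry + rExit) {
      // exit from site L
      pol[L] = 0;
      if (t > burn_in) occT[L] += t - (occSince[L] > burn_in ? occSince[L] : burn_in);
      --n_pol;
      ++exits;
      if (t > burn_in) {
        ++exits_meas;
        int b = (int)((t - burn_in) / batch_len);
        if (b >= n_batch) b = n_batch - 1;
        batchExits[b] += 1.0;
      }
      updHop(L - 1);
      updFree(L);
    } else if (u < rEntry + rExit + rFast + rSlow) {
      // hop
      int i = (u < rEntry + rExit + rFast) ? fastH.pick() : slowH.pick();
      if (pol[i + 1]) stop("exclusion violated in hop");
      if (blocking && obs[i + 1]) stop("obstacle exclusion violated in hop");
      pol[i] = 0;
      pol[i + 1] = 1;
      if (t > burn_in) {
        occT[i] += t - (occSince[i] > burn_in ? occSince[i] : burn_in);
        ++hops_meas;
      }
      occSince[i + 1] = t;
      updHop(i - 1);
      updHop(i);
      updHop(i + 1);
      updFree(i);
      updFree(i + 1);
    } else if (u < rEntry + rExit + rFast + rSlow + rBind) {
      // obstacle binding (weighted by mCG multiplicity via rejection)
      int j = -1;
      for (int tries = 0; tries < 10000; ++tries) {
        int cand = freeSp.pick();
        if (maxMult == 1 || unif_rand() * maxMult < m[cand]) { j = cand; break; }
      }
      if (j < 0) stop("obstacle binding selection failed");
      if (obs[j] || pol[j]) stop("obstacle bound to occupied site");
      obs[j] = 1;
      bindTime[j] = t;
      obsSince[j] = t;
      boundO.add(j);
      updFree(j);
      if (blocking) updHop(j - 1);
    } else {
      // obstacle unbinding
      int j = boundO.pick();
      obs[j] = 0;
      boundO.remove(j);
      resSum += t - bindTime[j];
      ++resN;
      if (t > burn_in) obsT[j] += t - (obsSince[j] > burn_in ? obsSince[j] : burn_in);
      updFree(j);
      if (blocking) updHop(j - 1);
      if (variant == 2 && pol[j]) updHop(j);
    }
  }

  // flush tail snapshots and occupancy integrals
  while (snap_i < n_snap) {
    for (int i = 1; i <= L; ++i) {
      kymoPol(snap_i, i - 1) = pol[i];
      if (dynamic) kymoObs(snap_i, i - 1) = obs[i];
    }
    ++snap_i;
    next_snap += kymo_dt;
  }
  for (int i = 1; i <= L; ++i) {
    if (pol[i]) occT[i] += t_end - (occSince[i] > burn_in ? occSince[i] : burn_in);
    if (obs[i]) obsT[i] += t_end - (obsSince[i] > burn_in ? obsSince[i] : burn_in);
  }

  double J = exits_meas / measure;
  double mean_bj = 0.0, var_bj = 0.0;
  for (int b = 0; b < n_batch; ++b) mean_bj += batchExits[b] / batch_len;
  mean_bj /= n_batch;
  for (int b = 0; b < n_batch; ++b) {
    double d = batchExits[b] / batch_len - mean_bj;
    var_bj += d * d;
  }
  double J_se = n_batch > 1 ? std::sqrt(var_bj / (n_batch - 1) / n_batch) : NA_REAL;

  NumericVector dens(L), odens(L);
  for (int i = 1; i <= L; ++i) {
    dens[i - 1] = occT[i] / measure;
    odens[i - 1] = obsT[i] / measure;
  }

  List out = List::create(
      _["J"] = J, _["J_stderr"] = J_se,
      _["entries"] = (double)entries, _["exits"] = (double)exits,
      _["particles_on_lattice"] = n_pol,
      _["hops"] = (double)hops_meas, _["occupied_time"] = polInt,
      _["density"] = dens, _["obstacle_density"] = odens,
      _["residence_mean"] = resN > 0 ? resSum / resN : NA_REAL,
      _["residence_n"] = (double)resN,
      _["time"] = t_end);
  if (n_snap > 0) {
    out["kymo_pol"] = kymoPol;
    if (dynamic) out["kymo_obs"] = kymoObs;
  }
  return out;
}
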