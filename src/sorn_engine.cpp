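// Discrete-time SORN stepping engine.
//
// One call advances the network n_steps steps with the selected plasticity
// rules, noise model and (optional) letter input, and records the activity
// trace a(t), connection fraction, spike raster and readout features x'(t).
//
// Within-step order (the synaptic-normalization rule must run last):
//   state update -> STDP -> iSTDP -> prune -> structural -> intrinsic -> SN.
//
// Weights are stored as V(i,j) with a per-row scale factor, so the true
// weight is s_i * V(i,j). Synaptic normalization then only updates s_i from
// the incrementally maintained row sums of V; the scale is folded into V by
// a physical renormalization pass every RENORM steps (and before returning),
// which also rebuilds the row sums exactly. This is algebraically identical
// to dividing every row by its sum at every step, at a fraction of the
// memory traffic.
//
// Randomness comes from two named streams (membrane noise, structural
// plasticity) using xoshiro256** seeded through splitmix64, with explicit
// uniform (53-bit) and Marsaglia-polar normal transforms, so draws are
// reproducible everywhere independent of any standard-library details.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct Stream {
  uint64_t s[4];
  bool have_spare;
  double spare;

  explicit Stream(uint64_t seed) : have_spare(false), spare(0.0) {
    // splitmix64 expansion of the seed into the xoshiro256** state
    for (int k = 0; k < 4; ++k) {
      seed += 0x9E3779B97f4A7C15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[k] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on [0, 1) with 53 random bits
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // standard normal, Marsaglia polar method
  double normal() {
    if (have_spare) {
      have_spare = false;
      return spare;
    }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double m = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * m;
    have_spare = true;
    return u * m;
  }
  // integer in [0, n)
  int randint(int n) {
    uint64_t lim = UINT64_MAX - (UINT64_MAX % (uint64_t)n);
    uint64_t x;
    do {
      x = next();
    } while (x >= lim);
    return (int)(x % (uint64_t)n);
  }
};

const double SPIKE_DRIVE = 1e7;  // supra-threshold kick of random-spike noise
const int RENORM = 256;          // steps between physical renormalizations

// fold the row scales into the matrix and rebuild exact row sums
void physical_renorm(double* V, int nrow, int ncol, std::vector<double>& sc,
                     std::vector<double>& rs) {
  std::fill(rs.begin(), rs.end(), 0.0);
  for (int j = 0; j < ncol; ++j) {
    double* col = V + (long long)j * nrow;
    for (int i = 0; i < nrow; ++i) {
      const double v = col[i] * sc[i];
      col[i] = v;
      rs[i] += v;
    }
  }
  std::fill(sc.begin(), sc.end(), 1.0);
}

}  // namespace

// [[Rcpp::export(name = ".sorn_run_cpp")]]
List sorn_run_cpp(NumericMatrix W_EE, NumericMatrix W_EI, NumericMatrix W_IE,
                  IntegerMatrix mask_EI, IntegerVector x0, IntegerVector y0,
                  NumericVector T_E0, NumericVector T_I, NumericVector H_ip,
                  int t0, int n_steps, LogicalVector flags, List rates,
                  List noise, IntegerVector input_letters, List input_subsets,
                  double input_amplitude, double noise_seed, double sp_seed,
                  bool record_raster, bool record_features,
                  bool features_with_noise, int conn_stride,
                  IntegerVector count_units) {
  const int NE = W_EE.nrow();
  const int NI = W_IE.nrow();

  const bool f_stdp = flags[0], f_istdp = flags[1], f_sn = flags[2],
             f_sp = flags[3], f_ip = flags[4];

  const double eta_stdp = as<double>(rates["eta_stdp"]);
  const double eta_inh = as<double>(rates["eta_inh"]);
  const double eta_ip = as<double>(rates["eta_ip"]);
  const double eta_sp = as<double>(rates["eta_sp"]);
  const double p_sp = as<double>(rates["p_sp"]);
  const double mu_ip = as<double>(rates["mu_ip"]);

  // noise model: 0 none, 1 gaussian, 2 random_spike
  const int nkind = as<int>(noise["kind"]);
  const double nsd = as<double>(noise["sd"]);
  const double p_s = as<double>(noise["p_s"]);
  const IntegerVector nsub = noise["subset"];  // 0-based E units; empty = all
  const bool noise_on_I = as<bool>(noise["on_inhibitory"]);

  NumericMatrix V_ee = clone(W_EE);
  NumericMatrix V_ei = clone(W_EI);
  NumericVector T_e = clone(T_E0);

  double* vee = REAL(V_ee);
  double* vei = REAL(V_ei);
  double* wie = REAL(W_IE);
  int* mei = INTEGER(mask_EI);

  std::vector<double> sc_ee(NE, 1.0), sc_ei(NE, 1.0);
  std::vector<double> rs_ee(NE, 0.0), rs_ei(NE, 0.0);
  physical_renorm(vee, NE, NE, sc_ee, rs_ee);  // sc is 1: just builds sums
  physical_renorm(vei, NE, NI, sc_ei, rs_ei);

  std::vector<int> x(x0.begin(), x0.end());
  std::vector<int> y(y0.begin(), y0.end());
  std::vector<int> x_new(NE), y_new(NI);
  std::vector<double> accE(NE), accI(NE), drive_E(NE), drive_I(NI);
  std::vector<int> active_E, active_E_new, active_I;
  active_E.reserve(NE);
  active_E_new.reserve(NE);
  active_I.reserve(NI);

  long long nnz = 0;
  for (int j = 0; j < NE; ++j)
    for (int i = 0; i < NE; ++i)
      if (vee[i + (long long)j * NE] > 0.0) ++nnz;
  const long long max_pairs = (long long)NE * (NE - 1);

  Stream rng_noise((uint64_t)noise_seed);
  Stream rng_sp((uint64_t)sp_seed);

  const bool have_input = input_letters.size() > 0;
  std::vector<std::vector<int>> subsets;
  for (int k = 0; k < input_subsets.size(); ++k) {
    IntegerVector s = input_subsets[k];
    subsets.push_back(std::vector<int>(s.begin(), s.end()));
  }

  IntegerVector activity(n_steps);
  std::vector<int> rast_t, rast_u;
  IntegerMatrix features;
  if (record_features) features = IntegerMatrix(n_steps, NE);
  std::vector<double> conn_frac;
  std::vector<int> conn_step;

  const bool count_all = count_units.size() == 0;
  std::vector<char> counted(NE, 1);
  if (!count_all) {
    std::fill(counted.begin(), counted.end(), 0);
    for (int k = 0; k < count_units.size(); ++k) counted[count_units[k]] = 1;
  }

  for (int s = 0; s < n_steps; ++s) {
    const int t_now = t0 + s + 1;  // model time of the state computed now

    // ---- recurrent drive onto excitatory units
    std::fill(accE.begin(), accE.end(), 0.0);
    active_E.clear();
    for (int j = 0; j < NE; ++j)
      if (x[j]) active_E.push_back(j);
    for (size_t a = 0; a < active_E.size(); ++a) {
      const double* col = vee + (long long)active_E[a] * NE;
      for (int i = 0; i < NE; ++i) accE[i] += col[i];
    }
    std::fill(accI.begin(), accI.end(), 0.0);
    active_I.clear();
    for (int k = 0; k < NI; ++k)
      if (y[k]) active_I.push_back(k);
    for (size_t a = 0; a < active_I.size(); ++a) {
      const double* col = vei + (long long)active_I[a] * NE;
      for (int i = 0; i < NE; ++i) accI[i] += col[i];
    }
    for (int i = 0; i < NE; ++i)
      drive_E[i] = sc_ee[i] * accE[i] - sc_ei[i] * accI[i] - T_e[i];

    // readout feature x'(t): thresholded recurrent drive without the
    // external input term (and, by default, without the noise draw)
    if (record_features && !features_with_noise) {
      int* fmat = INTEGER(features);
      for (int i = 0; i < NE; ++i)
        fmat[s + (long long)i * n_steps] = (drive_E[i] >= 0.0) ? 1 : 0;
    }

    // ---- membrane noise, excitatory units first (fixed draw order)
    if (nkind == 1) {
      if (nsub.size() == 0) {
        for (int i = 0; i < NE; ++i) drive_E[i] += nsd * rng_noise.normal();
      } else {
        for (int k = 0; k < nsub.size(); ++k)
          drive_E[nsub[k]] += nsd * rng_noise.normal();
      }
    } else if (nkind == 2) {
      if (nsub.size() == 0) {
        for (int i = 0; i < NE; ++i)
          if (rng_noise.unif() < p_s) drive_E[i] += SPIKE_DRIVE;
      } else {
        for (int k = 0; k < nsub.size(); ++k)
          if (rng_noise.unif() < p_s) drive_E[nsub[k]] += SPIKE_DRIVE;
      }
    }

    if (record_features && features_with_noise) {
      int* fmat = INTEGER(features);
      for (int i = 0; i < NE; ++i)
        fmat[s + (long long)i * n_steps] = (drive_E[i] >= 0.0) ? 1 : 0;
    }

    // ---- external letter input
    if (have_input) {
      const int letter = input_letters[s];
      if (letter > 0) {
        const std::vector<int>& sub = subsets[letter - 1];
        for (size_t k = 0; k < sub.size(); ++k)
          drive_E[sub[k]] += input_amplitude;
      }
    }

    // Theta(0) = 1: a unit whose drive exactly matches threshold fires
    active_E_new.clear();
    for (int i = 0; i < NE; ++i) {
      x_new[i] = (drive_E[i] >= 0.0) ? 1 : 0;
      if (x_new[i]) active_E_new.push_back(i);
    }

    // ---- inhibitory units: instantaneous response to the new excitatory
    // state, so the E->I->E loop has an effective delay of one step
    for (int i = 0; i < NI; ++i) drive_I[i] = -T_I[i];
    for (size_t a = 0; a < active_E_new.size(); ++a) {
      const double* col = wie + (long long)active_E_new[a] * NI;
      for (int i = 0; i < NI; ++i) drive_I[i] += col[i];
    }
    if (noise_on_I && nsub.size() == 0) {
      if (nkind == 1) {
        for (int i = 0; i < NI; ++i) drive_I[i] += nsd * rng_noise.normal();
      } else if (nkind == 2) {
        for (int i = 0; i < NI; ++i)
          if (rng_noise.unif() < p_s) drive_I[i] += SPIKE_DRIVE;
      }
    }
    for (int i = 0; i < NI; ++i) y_new[i] = (drive_I[i] >= 0.0) ? 1 : 0;

    // ---- STDP on existing E->E synapses, with immediate pruning
    if (f_stdp) {
      for (size_t a = 0; a < active_E.size(); ++a) {  // j fired at t-1
        const int j = active_E[a];
        double* col = vee + (long long)j * NE;
        for (size_t b = 0; b < active_E_new.size(); ++b) {  // i fires at t
          const int i = active_E_new[b];
          if (i != j && col[i] > 0.0) {
            const double d = eta_stdp / sc_ee[i];
            col[i] += d;
            rs_ee[i] += d;
          }
        }
      }
      for (size_t a = 0; a < active_E_new.size(); ++a) {  // j fires at t
        const int j = active_E_new[a];
        double* col = vee + (long long)j * NE;
        for (size_t b = 0; b < active_E.size(); ++b) {  // i fired at t-1
          const int i = active_E[b];
          if (i != j && col[i] > 0.0) {
            const double d = eta_stdp / sc_ee[i];
            if (col[i] - d <= 0.0) {  // prune: remove from structure
              rs_ee[i] -= col[i];
              col[i] = 0.0;
              --nnz;
            } else {
              col[i] -= d;
              rs_ee[i] -= d;
            }
          }
        }
      }
    }

    // ---- iSTDP on existing I->E synapses (structure fixed, floor at 0)
    if (f_istdp) {
      for (size_t a = 0; a < active_I.size(); ++a) {  // j fired at t-1
        const int j = active_I[a];
        double* col = vei + (long long)j * NE;
        const int* mcol = mei + (long long)j * NE;
        for (int i = 0; i < NE; ++i) {
          if (!mcol[i]) continue;
          if (x_new[i]) {
            const double d = (eta_inh / mu_ip) / sc_ei[i];
            col[i] += d;
            rs_ei[i] += d;
          } else {
            const double d = eta_inh / sc_ei[i];
            if (col[i] - d < 0.0) {  // floor at 0, slot retained
              rs_ei[i] -= col[i];
              col[i] = 0.0;
            } else {
              col[i] -= d;
              rs_ei[i] -= d;
            }
          }
        }
      }
    }

    // ---- structural plasticity: at most one new synapse per step
    if (f_sp) {
      const double u = rng_sp.unif();
      if (u < p_sp && nnz < max_pairs) {
        int i, j;
        do {
          i = rng_sp.randint(NE);
          j = rng_sp.randint(NE);
        } while (i == j || vee[i + (long long)j * NE] > 0.0);
        const double d = eta_sp / sc_ee[i];
        vee[i + (long long)j * NE] = d;
        rs_ee[i] += d;
        ++nnz;
      }
    }

    // ---- intrinsic plasticity on excitatory thresholds
    if (f_ip) {
      for (int i = 0; i < NE; ++i) T_e[i] += eta_ip * (x_new[i] - H_ip[i]);
    }

    // ---- synaptic normalization: refresh the row scales
    if (f_sn) {
      for (int i = 0; i < NE; ++i)
        sc_ee[i] = (rs_ee[i] > 0.0) ? 1.0 / rs_ee[i] : 1.0;
      for (int i = 0; i < NE; ++i)
        sc_ei[i] = (rs_ei[i] > 0.0) ? 1.0 / rs_ei[i] : 1.0;
    }

    // periodically fold scales into V and rebuild exact row sums
    if (((s + 1) % RENORM) == 0) {
      physical_renorm(vee, NE, NE, sc_ee, rs_ee);
      physical_renorm(vei, NE, NI, sc_ei, rs_ei);
    }

    // ---- commit state and record
    x.swap(x_new);
    for (int i = 0; i < NI; ++i) y[i] = y_new[i];

    int a_t = 0;
    for (size_t b = 0; b < active_E_new.size(); ++b)
      if (counted[active_E_new[b]]) ++a_t;
    activity[s] = a_t;
    if (record_raster) {
      for (size_t b = 0; b < active_E_new.size(); ++b) {
        rast_t.push_back(t_now);
        rast_u.push_back(active_E_new[b]);
      }
    }
    if (conn_stride > 0 && (t_now % conn_stride) == 0) {
      conn_frac.push_back((double)nnz / (double)max_pairs);
      conn_step.push_back(t_now);
    }

    if ((s & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  // return true weights
  physical_renorm(vee, NE, NE, sc_ee, rs_ee);
  physical_renorm(vei, NE, NI, sc_ei, rs_ei);

  List out = List::create(
      _["x"] = IntegerVector(x.begin(), x.end()),
      _["y"] = IntegerVector(y.begin(), y.end()), _["W_EE"] = V_ee,
      _["W_EI"] = V_ei, _["T_E"] = T_e, _["t"] = t0 + n_steps,
      _["activity"] = activity,
      _["conn_fraction"] = NumericVector(conn_frac.begin(), conn_frac.end()),
      _["conn_step"] = IntegerVector(conn_step.begin(), conn_step.end()),
      _["nnz"] = (double)nnz);
  if (record_raster) {
    out["raster_t"] = IntegerVector(rast_t.begin(), rast_t.end());
    out["raster_unit"] = IntegerVector(rast_u.begin(), rast_u.end());
  }
  if (record_features) out["features"] = features;
  return out;
}
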