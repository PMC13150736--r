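// Core simulation loop: recurrent network dynamics in a discrete event
// stream, and the (1+2) mirrored random-search trainer.  Kept in C++ because
// a single reduction experiment replays millions of network-generations.
//
// Randomness: xoshiro256++ seeded via splitmix64.  Two independent,
// platform-stable streams per evolve() call (mutation vs environment) so the
// two sources of trajectory divergence can be isolated and reproduced.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed into the full state
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() {           // [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
  inline double unif(double lo, double hi) {
    return lo + (hi - lo) * unif();
  }
  inline int unif_int(int n) {     // 0 .. n-1, n tiny so modulo-free scaling is fine
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

// Signal codes: A=(1,0), B=(0,1), C=(1,1); pause=(0,0).
const double SIG0[3] = {1.0, 0.0, 1.0};
const double SIG1[3] = {0.0, 1.0, 1.0};

struct Stream {
  std::vector<double> in0, in1, tg0, tg1;
  std::vector<int> sym, onset, pause;
};

// One stimulus symbol occupies: stim_ticks of the signal code, then `window`
// silent processing ticks, then a pause of p ~ U{pause_min..pause_max}
// silent ticks.  A leading pause is emitted before the first symbol.
//
// Required response: at every tick the target is the classification of the
// most recent stimulus that ended at least `window` ticks earlier — (1,1)
// if it was the correct signal, (0,0) otherwise (and (0,0) before any
// stimulus has been classified).  The network therefore has `window` ticks
// to process each stimulus and must then hold its answer until the next
// stimulus has been processed in turn.
void gen_stream(Xoshiro& rng, int correct, int window, int n_symbols,
                int pause_min, int pause_max, int stim_ticks, Stream& st) {
  st.in0.clear(); st.in1.clear(); st.tg0.clear(); st.tg1.clear();
  st.sym.clear(); st.onset.clear(); st.pause.clear();
  int span = pause_max - pause_min + 1;
  int lead = pause_min + rng.unif_int(span);
  for (int t = 0; t < lead; ++t) {
    st.in0.push_back(0); st.in1.push_back(0);
    st.tg0.push_back(0); st.tg1.push_back(0);
  }
  for (int k = 0; k < n_symbols; ++k) {
    int sym = rng.unif_int(3);            // 0=A, 1=B, 2=C
    int p = pause_min + rng.unif_int(span);
    st.sym.push_back(sym);
    st.onset.push_back((int)st.in0.size() + 1);  // 1-based tick of first stimulus tick
    st.pause.push_back(p);
    for (int t = 0; t < stim_ticks; ++t) {
      st.in0.push_back(SIG0[sym]); st.in1.push_back(SIG1[sym]);
    }
    for (int t = 0; t < window + p; ++t) {
      st.in0.push_back(0); st.in1.push_back(0);
    }
  }
  // causal target sweep: tick t answers the last stimulus whose processing
  // window (counted from the end of its presentation) has elapsed
  int T = (int)st.in0.size();
  st.tg0.assign(T, 0.0); st.tg1.assign(T, 0.0);
  int offset = stim_ticks - 1 + window;
  int k = -1;
  for (int t = 1; t <= T; ++t) {          // 1-based ticks
    while (k + 1 < n_symbols && st.onset[k + 1] + offset <= t) ++k;
    double resp = (k >= 0 && st.sym[k] == correct) ? 1.0 : 0.0;
    st.tg0[t - 1] = resp; st.tg1[t - 1] = resp;
  }
}

// Run the network over the stream from the all-zero state; accumulate the
// goal function (summed squared output deviation) and the count of ticks on
// which a thresholded output disagrees with the target.  x is n x n
// row-major, x[i*n+j] = synapse j -> i.
// `cutoff`: once the accumulated goal strictly exceeds it the evaluation
// stops (the network can no longer win the selection); the returned goal is
// then only a lower bound.  Exact ties are unaffected (strict comparison).
void eval_net(const double* x, int n, int in0, int in1, int out0, int out1,
              double a, const Stream& st, double thr,
              double& goal, int& errors,
              double* trace0 = nullptr, double* trace1 = nullptr,
              double cutoff = std::numeric_limits<double>::infinity()) {
  std::vector<double> alpha(n, 0.0), nxt(n);
  goal = 0.0; errors = 0;
  int T = (int)st.in0.size();
  for (int t = 0; t < T; ++t) {
    if (goal > cutoff) return;
    for (int i = 0; i < n; ++i) {
      double rho = 0.0;
      const double* row = x + (size_t)i * n;
      for (int j = 0; j < n; ++j) rho += row[j] * alpha[j];
      if (i == in0) rho += st.in0[t];
      else if (i == in1) rho += st.in1[t];
      nxt[i] = std::tanh(a * rho);
    }
    alpha.swap(nxt);
    double o0 = alpha[out0], o1 = alpha[out1];
    double d0 = o0 - st.tg0[t], d1 = o1 - st.tg1[t];
    goal += d0 * d0 + d1 * d1;
    if (((o0 > thr) != (st.tg0[t] > 0.5)) || ((o1 > thr) != (st.tg1[t] > 0.5)))
      ++errors;
    if (trace0) { trace0[t] = o0; trace1[t] = o1; }
  }
}

Stream stream_from_sexp(const NumericMatrix& inputs, const NumericMatrix& targets) {
  Stream st;
  int T = inputs.nrow();
  st.in0.resize(T); st.in1.resize(T); st.tg0.resize(T); st.tg1.resize(T);
  for (int t = 0; t < T; ++t) {
    st.in0[t] = inputs(t, 0); st.in1[t] = inputs(t, 1);
    st.tg0[t] = targets(t, 0); st.tg1[t] = targets(t, 1);
  }
  return st;
}

}  // namespace

// [[Rcpp::export]]
List cpp_generate_stream(int correct, int window, int n_symbols,
                         int pause_min, int pause_max, int stim_ticks,
                         double seed) {
  Xoshiro rng((uint64_t)seed);
  Stream st;
  gen_stream(rng, correct, window, n_symbols, pause_min, pause_max,
             stim_ticks, st);
  int T = (int)st.in0.size();
  NumericMatrix inputs(T, 2), targets(T, 2);
  for (int t = 0; t < T; ++t) {
    inputs(t, 0) = st.in0[t]; inputs(t, 1) = st.in1[t];
    targets(t, 0) = st.tg0[t]; targets(t, 1) = st.tg1[t];
  }
  return List::create(_["inputs"] = inputs, _["targets"] = targets,
                      _["sym"] = wrap(st.sym), _["onset"] = wrap(st.onset),
                      _["pause"] = wrap(st.pause));
}

// [[Rcpp::export]]
NumericMatrix cpp_run_stream(NumericMatrix x, IntegerVector input_ids,
                             IntegerVector output_ids, double a,
                             NumericMatrix inputs, NumericVector init_state) {
  int n = x.nrow();
  int T = inputs.nrow();
  std::vector<double> xm((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) xm[(size_t)i * n + j] = x(i, j);
  std::vector<double> alpha(n), nxt(n);
  for (int i = 0; i < n; ++i) alpha[i] = init_state[i];
  int in0 = input_ids[0] - 1, in1 = input_ids[1] - 1;
  int out0 = output_ids[0] - 1, out1 = output_ids[1] - 1;
  NumericMatrix trace(T, 2);
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < n; ++i) {
      double rho = 0.0;
      const double* row = xm.data() + (size_t)i * n;
      for (int j = 0; j < n; ++j) rho += row[j] * alpha[j];
      if (i == in0) rho += inputs(t, 0);
      else if (i == in1) rho += inputs(t, 1);
      nxt[i] = std::tanh(a * rho);
    }
    alpha.swap(nxt);
    trace(t, 0) = alpha[out0];
    trace(t, 1) = alpha[out1];
  }
  return trace;
}

// [[Rcpp::export]]
NumericVector cpp_eval_stream(NumericMatrix x, IntegerVector input_ids,
                              IntegerVector output_ids, double a,
                              NumericMatrix inputs, NumericMatrix targets,
                              double threshold) {
  int n = x.nrow();
  std::vector<double> xm((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) xm[(size_t)i * n + j] = x(i, j);
  Stream st = stream_from_sexp(inputs, targets);
  double goal; int errors;
  eval_net(xm.data(), n, input_ids[0] - 1, input_ids[1] - 1,
           output_ids[0] - 1, output_ids[1] - 1, a, st, threshold,
           goal, errors);
  return NumericVector::create(goal, (double)errors);
}

// Mirrored random search: each generation draws one increment matrix Delta
// (zero on frozen synapses), evaluates parent, parent+Delta and parent-Delta
// on one common stream fragment, and keeps the argmin (ties: parent, then
// the "+" offspring).  Stopping: zero recognition errors and goal <=
// eps_per_tick * T on the training fragment, confirmed on a fresh
// validation stream.
// [[Rcpp::export]]
List cpp_evolve(NumericMatrix x0, LogicalMatrix frozen,
                IntegerVector input_ids, IntegerVector output_ids, double a,
                int correct, int window,
                int n_symbols, int pause_min, int pause_max, int stim_ticks,
                Nullable<NumericMatrix> fixed_inputs,
                Nullable<NumericMatrix> fixed_targets,
                double mutation_scale, double eps_per_tick, double threshold,
                int max_generations, double mutation_seed, double stream_seed,
                bool stop_on_success, int snapshot_stride,
                int validation_fragments) {
  int n = x0.nrow();
  size_t nn = (size_t)n * n;
  std::vector<double> x(nn), xp(nn), xmns(nn), delta(nn);
  std::vector<char> frz(nn);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      x[(size_t)i * n + j] = x0(i, j);
      frz[(size_t)i * n + j] = frozen(i, j) ? 1 : 0;
    }
  int in0 = input_ids[0] - 1, in1 = input_ids[1] - 1;
  int out0 = output_ids[0] - 1, out1 = output_ids[1] - 1;

  Xoshiro mrng((uint64_t)mutation_seed), erng((uint64_t)stream_seed);

  bool fixed = fixed_inputs.isNotNull();
  Stream fixed_st;
  if (fixed) {
    NumericMatrix fi(fixed_inputs.get()), ft(fixed_targets.get());
    fixed_st = stream_from_sexp(fi, ft);
  }

  std::vector<double> goal_traj; goal_traj.reserve(max_generations + 1);
  std::vector<int> err_traj; err_traj.reserve(max_generations + 1);
  std::vector<int> snap_gens;
  std::vector<double> snaps;  // row-major concatenation of flattened x

  Stream st, vst;
  bool success = false;
  int gen_used = 0;

  // success must be a robust property, not luck on one fragment: every one
  // of `validation_fragments` fresh fragments must be error-free
  auto validate = [&](void) -> bool {
    for (int v = 0; v < validation_fragments; ++v) {
      gen_stream(erng, correct, window, n_symbols, pause_min, pause_max,
                 stim_ticks, vst);
      double g; int e;
      eval_net(x.data(), n, in0, in1, out0, out1, a, vst, threshold, g, e);
      if (e != 0 || g > eps_per_tick * (double)vst.in0.size()) return false;
    }
    return true;
  };
  auto snapshot = [&](int gen) {
    snap_gens.push_back(gen);
    snaps.insert(snaps.end(), x.begin(), x.end());
  };

  // generation 0: record the starting point; a warm start may already solve
  // the task (reduction restarts, degenerate controls).
  {
    if (fixed) st = fixed_st;
    else gen_stream(erng, correct, window, n_symbols, pause_min, pause_max,
                    stim_ticks, st);
    double g; int e;
    eval_net(x.data(), n, in0, in1, out0, out1, a, st, threshold, g, e);
    goal_traj.push_back(g); err_traj.push_back(e);
    if (snapshot_stride > 0) snapshot(0);
    if (stop_on_success && e == 0 && g <= eps_per_tick * (double)st.in0.size())
      success = validate();
  }

  for (int gen = 1; gen <= max_generations && !success; ++gen) {
    if (fixed) st = fixed_st;
    else gen_stream(erng, correct, window, n_symbols, pause_min, pause_max,
                    stim_ticks, st);
    for (size_t k = 0; k < nn; ++k) {
      double d = frz[k] ? 0.0 : mrng.unif(-mutation_scale, mutation_scale);
      delta[k] = d;
      xp[k] = x[k] + d;
      xmns[k] = x[k] - d;
    }
    double gpar, gplus, gminus; int epar, eplus, eminus;
    eval_net(x.data(), n, in0, in1, out0, out1, a, st, threshold, gpar, epar);
    eval_net(xp.data(), n, in0, in1, out0, out1, a, st, threshold, gplus,
             eplus, nullptr, nullptr, gpar);
    eval_net(xmns.data(), n, in0, in1, out0, out1, a, st, threshold, gminus,
             eminus, nullptr, nullptr, std::min(gpar, gplus));
    double gsel; int esel;
    if (gpar <= gplus && gpar <= gminus) {
      gsel = gpar; esel = epar;                     // parent retained
    } else if (gplus <= gminus) {
      x.swap(xp); gsel = gplus; esel = eplus;
    } else {
      x.swap(xmns); gsel = gminus; esel = eminus;
    }
    goal_traj.push_back(gsel); err_traj.push_back(esel);
    gen_used = gen;
    if (snapshot_stride > 0 && gen % snapshot_stride == 0) snapshot(gen);
    if (stop_on_success && esel == 0 &&
        gsel <= eps_per_tick * (double)st.in0.size())
      success = validate();
  }

  NumericMatrix xout(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) xout(i, j) = x[(size_t)i * n + j];
  int nsnap = (int)snap_gens.size();
  NumericMatrix snapm(nsnap, (int)nn);
  for (int r = 0; r < nsnap; ++r)
    for (size_t k = 0; k < nn; ++k) snapm(r, (int)k) = snaps[(size_t)r * nn + k];
  return List::create(
      _["x"] = xout, _["generations"] = gen_used, _["success"] = success,
      _["goal"] = wrap(goal_traj), _["errors"] = wrap(err_traj),
      _["snapshot_generations"] = wrap(snap_gens), _["snapshots"] = snapm);
}

// Uniform draws from the named xoshiro stream; lets R-level operations
// (initial weights, mirrored increments) share the simulator's generator.
// [[Rcpp::export]]
NumericVector cpp_runif_stream(int n, double lo, double hi, double seed) {
  Xoshiro rng((uint64_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.unif(lo, hi);
  return out;
}
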