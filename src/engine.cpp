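// Gillespie simulation core for asynchronous Boolean networks.
//
// Layout of this file:
//   * xoshiro256++ RNG with per-trajectory substreams (splitmix64 seeding)
//   * a postfix stack VM evaluating compiled Boolean formula programs
//   * single-trajectory simulation (exposed for the R reference path)
//   * batch simulation with windowed/final/fixed statistics accumulated
//     through a canonical pairwise reduction tree, so the result is
//     bit-identical for every worker partition of the trajectory set.
//
// States are n-bit masks carried in uint64_t; the R interface exchanges
// them as doubles, hence the n <= 53 guard enforced on the R side.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <unordered_map>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG ---

static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  // substream keyed by (master seed, trajectory index)
  void seed(uint64_t master, uint64_t index) {
    uint64_t sm = master + 0x9E3779B97F4A7C15ULL * (index + 1ULL);
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
    if ((s[0] | s[1] | s[2] | s[3]) == 0) s[0] = 1;
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  // strictly inside (0,1): 52 random bits offset by half an ulp
  inline double uniform() {
    return (double)((next() >> 12) + 0.5) * (1.0 / 4503599627370496.0);
  }
};

// [[Rcpp::export(name = ".rng_new")]]
SEXP rng_new(double seed, double index) {
  Xoshiro *x = new Xoshiro();
  x->seed((uint64_t)seed, (uint64_t)index);
  XPtr<Xoshiro> p(x, true);
  return p;
}

// [[Rcpp::export(name = ".rng_uniform")]]
NumericVector rng_uniform(SEXP ptr, int k) {
  XPtr<Xoshiro> x(ptr);
  NumericVector out(k);
  for (int i = 0; i < k; ++i) out[i] = x->uniform();
  return out;
}

// ------------------------------------------------------- formula VM ----
// Programs are postfix instruction streams of (opcode, arg) int pairs:
//   0 PUSH_VAR arg=node index, 1 PUSH_CONST arg=0/1,
//   2 NOT, 3 AND, 4 OR, 5 XOR (arg ignored).

static inline int eval_program(const int *prog, int len, uint64_t S) {
  int stack[512];
  int sp = 0;
  for (int i = 0; i < len; i += 2) {
    int op = prog[i], arg = prog[i + 1];
    switch (op) {
    case 0: stack[sp++] = (int)((S >> arg) & 1ULL); break;
    case 1: stack[sp++] = arg; break;
    case 2: stack[sp - 1] = 1 - stack[sp - 1]; break;
    case 3: stack[sp - 2] = stack[sp - 2] & stack[sp - 1]; --sp; break;
    case 4: stack[sp - 2] = stack[sp - 2] | stack[sp - 1]; --sp; break;
    case 5: stack[sp - 2] = stack[sp - 2] ^ stack[sp - 1]; --sp; break;
    default: Rcpp::stop("bad opcode");
    }
  }
  return stack[0];
}

struct Model {
  int n;
  std::vector<std::vector<int>> progs;
  std::vector<double> up, down;

  // rate at which node i flips in state S (0 when logic agrees with value)
  inline double node_rate(int i, uint64_t S) const {
    int si = (int)((S >> i) & 1ULL);
    int fi = eval_program(progs[i].data(), (int)progs[i].size(), S);
    if (si == fi) return 0.0;
    return si ? down[i] : up[i];
  }
  inline double all_rates(uint64_t S, double *r) const {
    double tot = 0.0;
    for (int i = 0; i < n; ++i) { r[i] = node_rate(i, S); tot += r[i]; }
    return tot;
  }
};

static Model make_model(List programs, NumericVector up, NumericVector down) {
  Model m;
  m.n = programs.size();
  m.progs.resize(m.n);
  for (int i = 0; i < m.n; ++i) {
    IntegerVector p = programs[i];
    m.progs[i].assign(p.begin(), p.end());
  }
  m.up.assign(up.begin(), up.end());
  m.down.assign(down.begin(), down.end());
  return m;
}

// [[Rcpp::export(name = ".engine_rates")]]
NumericVector engine_rates(List programs, NumericVector rate_up,
                           NumericVector rate_down, double state) {
  Model m = make_model(programs, rate_up, rate_down);
  NumericVector out(m.n);
  uint64_t S = (uint64_t)state;
  for (int i = 0; i < m.n; ++i) out[i] = m.node_rate(i, S);
  return out;
}

// ------------------------------------------------ single trajectory ----

static const int END_TIMEOUT = 0, END_FIXED = 1, END_STEPCAP = 2;

static inline uint64_t draw_initial(const std::vector<double> &istate,
                                    Xoshiro &rng) {
  uint64_t S = 0;
  for (size_t i = 0; i < istate.size(); ++i)
    if (rng.uniform() < istate[i]) S |= (1ULL << i);
  return S;
}

// One Gillespie jump; returns end reason or -1 when a jump was taken.
static inline int step(const Model &m, double *rates, uint64_t &S, double &t,
                       double max_time, Xoshiro &rng) {
  double tot = m.all_rates(S, rates);
  if (tot == 0.0) return END_FIXED;
  double u1 = rng.uniform(), u2 = rng.uniform();
  double tnew = t - std::log(u1) / tot;
  if (tnew > max_time) return END_TIMEOUT;
  double target = u2 * tot, acc = 0.0;
  int j = m.n - 1;
  for (int i = 0; i < m.n; ++i) {
    acc += rates[i];
    if (acc > target) { j = i; break; }
  }
  S ^= (1ULL << j);
  t = tnew;
  return -1;
}

// [[Rcpp::export(name = ".engine_trajectory")]]
List engine_trajectory(List programs, NumericVector rate_up,
                       NumericVector rate_down, NumericVector istate,
                       double max_time, double seed, double index,
                       double max_steps) {
  Model m = make_model(programs, rate_up, rate_down);
  std::vector<double> ist(istate.begin(), istate.end());
  Xoshiro rng; rng.seed((uint64_t)seed, (uint64_t)index);
  std::vector<double> rates(m.n);
  uint64_t S = draw_initial(ist, rng);
  double t = 0.0;
  std::vector<double> states, times;
  states.push_back((double)S); times.push_back(0.0);
  int reason = END_TIMEOUT;
  bool unbounded = !(max_steps > 0);
  double k = 0;
  for (;;) {
    if (!unbounded && k >= max_steps) { reason = END_STEPCAP; break; }
    int r = step(m, rates.data(), S, t, max_time, rng);
    if (r >= 0) { reason = r; break; }
    states.push_back((double)S); times.push_back(t);
    k += 1;
  }
  return List::create(_["states"] = states, _["times"] = times,
                      _["end_reason"] = reason);
}

// ----------------------------------------- statistics accumulators ----
// Windowed weights live in either a dense histogram (2^width slots per
// window) or one hashmap per window. A trajectory's contribution is built
// in a scratch accumulator and folded into a canonical pairwise reduction
// tree keyed by the global trajectory index, which makes the final sums
// independent of how trajectories are partitioned across workers.

struct StatAcc {
  bool dense;
  int W;              // number of windows
  size_t slots;       // 2^width for the dense backend
  std::vector<double> hist;                       // W * slots
  std::vector<std::unordered_map<uint64_t, double>> maps;  // W maps

  void init(bool dense_, int W_, size_t slots_) {
    dense = dense_; W = W_; slots = slots_;
    if (dense) hist.assign((size_t)W * slots, 0.0);
    else maps.assign(W, std::unordered_map<uint64_t, double>());
  }
  void zero() {
    if (dense) std::fill(hist.begin(), hist.end(), 0.0);
    else for (auto &mp : maps) mp.clear();
  }
  inline void add(int w, uint64_t key, double d) {
    if (dense) hist[(size_t)w * slots + key] += d;
    else maps[w][key] += d;
  }
  // left (this) += right; addition order is canonical (left + right)
  void combine(const StatAcc &r) {
    if (dense) {
      for (size_t i = 0; i < hist.size(); ++i) hist[i] += r.hist[i];
    } else {
      for (int w = 0; w < W; ++w)
        for (const auto &kv : r.maps[w]) maps[w][kv.first] += kv.second;
    }
  }
};

// binary-counter pairwise reduction; blocks combine only when aligned
struct Reducer {
  struct Node { uint64_t start; int level; StatAcc acc; };
  std::vector<Node> stack;

  void push(StatAcc &&a, uint64_t start) {
    Node cur{start, 0, std::move(a)};
    while (!stack.empty()) {
      Node &top = stack.back();
      if (top.level != cur.level) break;
      uint64_t span = 1ULL << (top.level + 1);
      if (top.start % span != 0) break;
      top.acc.combine(cur.acc);
      cur = std::move(top);
      cur.level += 1;
      stack.pop_back();
    }
    stack.push_back(std::move(cur));
  }
  // fold leftovers left-to-right (lowest start first); fixed rule
  StatAcc finish(bool dense, int W, size_t slots) {
    if (stack.empty()) {
      StatAcc a; a.init(dense, W, slots); return a;
    }
    StatAcc out = std::move(stack.front().acc);
    for (size_t i = 1; i < stack.size(); ++i) out.combine(stack[i].acc);
    stack.clear();
    return out;
  }
};

// ------------------------------------------------------ batch engine ---

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(List programs, NumericVector rate_up, NumericVector rate_down,
                NumericVector istate, IntegerVector ext_idx,
                double max_time, double time_tick, double sample_count,
                double seed, int workers, double max_steps, bool dense) {
  Model m = make_model(programs, rate_up, rate_down);
  std::vector<double> ist(istate.begin(), istate.end());
  int width = ext_idx.size();
  size_t slots = dense ? ((size_t)1 << width) : 0;
  int W = (int)std::ceil(max_time / time_tick - 1e-9);
  if (W < 1) W = 1;
  uint64_t c = (uint64_t)sample_count;
  bool unbounded = !(max_steps > 0);

  std::vector<int> ext(ext_idx.begin(), ext_idx.end());
  auto project = [&](uint64_t S) -> uint64_t {
    uint64_t p = 0;
    for (int j = 0; j < width; ++j) p |= ((S >> ext[j]) & 1ULL) << j;
    return p;
  };
  // spread a stay [a,b) in projected state over the overlapped windows
  auto add_stay = [&](StatAcc &acc, double a, double b, uint64_t key) {
    if (b <= a) return;
    int w0 = (int)(a / time_tick); if (w0 >= W) w0 = W - 1;
    for (int w = w0; w < W; ++w) {
      double lo = w * time_tick, hi = std::min((w + 1) * time_tick, max_time);
      if (lo >= b) break;
      double d = std::min(b, hi) - std::max(a, lo);
      if (d > 0) acc.add(w, key, d);
    }
  };

  Reducer red;
  std::unordered_map<uint64_t, double> final_counts, fixed_counts;
  double n_fixed = 0, n_timeout = 0, n_stepcap = 0, total_steps = 0;
  std::vector<double> rates(m.n);

  // even contiguous partition over workers (remainder to the first ones);
  // purely structural here - the reduction tree makes it irrelevant
  uint64_t base = c / (uint64_t)workers, rem = c % (uint64_t)workers;
  uint64_t idx = 0;
  StatAcc scratch;

  for (int w = 0; w < workers; ++w) {
    uint64_t load = base + (w < (int)rem ? 1 : 0);
    for (uint64_t k = 0; k < load; ++k, ++idx) {
      Xoshiro rng; rng.seed((uint64_t)seed, idx);
      uint64_t S = draw_initial(ist, rng);
      double t = 0.0, steps = 0;
      int reason;
      scratch.init(dense, W, slots);
      for (;;) {
        if (!unbounded && steps >= max_steps) { reason = END_STEPCAP; break; }
        uint64_t Sprev = S; double tprev = t;
        int r = step(m, rates.data(), S, t, max_time, rng);
        if (r >= 0) { reason = r; break; }
        add_stay(scratch, tprev, t, project(Sprev));
        steps += 1;
      }
      // absorbing continuation: last state occupies [t, max_time]
      add_stay(scratch, t, max_time, project(S));
      final_counts[project(S)] += 1.0;
      if (reason == END_FIXED) { fixed_counts[S] += 1.0; n_fixed += 1; }
      else if (reason == END_STEPCAP) n_stepcap += 1;
      else n_timeout += 1;
      total_steps += steps;
      red.push(std::move(scratch), idx);
      if ((idx & 0x3FF) == 0) Rcpp::checkUserInterrupt();
    }
  }
  StatAcc wind = red.finish(dense, W, slots);

  // export windowed weights
  List windows(W);
  if (dense) {
    // zero slots are omitted so both backends export identical structures
    for (int w = 0; w < W; ++w) {
      std::vector<double> ks, ws;
      for (size_t s = 0; s < slots; ++s) {
        double v = wind.hist[(size_t)w * slots + s];
        if (v != 0.0) { ks.push_back((double)s); ws.push_back(v); }
      }
      windows[w] = List::create(_["key"] = NumericVector(ks.begin(), ks.end()),
                                _["weight"] = NumericVector(ws.begin(), ws.end()));
    }
  } else {
    for (int w = 0; w < W; ++w) {
      std::vector<std::pair<uint64_t, double>> kv(wind.maps[w].begin(),
                                                  wind.maps[w].end());
      std::sort(kv.begin(), kv.end());
      NumericVector keys(kv.size()), wt(kv.size());
      for (size_t i = 0; i < kv.size(); ++i) {
        keys[i] = (double)kv[i].first; wt[i] = kv[i].second;
      }
      windows[w] = List::create(_["key"] = keys, _["weight"] = wt);
    }
  }
  auto map_out = [](const std::unordered_map<uint64_t, double> &mp) {
    std::vector<std::pair<uint64_t, double>> kv(mp.begin(), mp.end());
    std::sort(kv.begin(), kv.end());
    NumericVector keys(kv.size()), val(kv.size());
    for (size_t i = 0; i < kv.size(); ++i) {
      keys[i] = (double)kv[i].first; val[i] = kv[i].second;
    }
    return List::create(_["key"] = keys, _["count"] = val);
  };
  return List::create(
      _["windows"] = windows, _["final"] = map_out(final_counts),
      _["fixed"] = map_out(fixed_counts), _["n_windows"] = W,
      _["n_fixed"] = n_fixed, _["n_timeout"] = n_timeout,
      _["n_stepcap"] = n_stepcap, _["total_steps"] = total_steps);
}
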