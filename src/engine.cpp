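// Continuous-time simulation core for critical-mass contagion on
// hypergraphs: a next-reaction (indexed priority queue) Gillespie engine,
// a quasi-stationary wrapper with the stored-states method, a direct-method
// variant used for cross-validation, the Poisson-binomial DFT kernel, and
// the individual-based mean-field right-hand side.

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: PCG32 (O'Neill's permuted congruential generator), one stream per run.
struct Pcg32 {
  uint64_t state, inc;
  Pcg32(uint64_t seed, uint64_t seq = 0xda3e39cb94b95bdbULL) {
    inc = (seq << 1u) | 1u;
    state = 0u; next(); state += seed; next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31u));
  }
  // uniform on (0, 1); never returns 0 so -log() is safe
  double uniform() { return (next() + 1.0) * (1.0 / 4294967297.0); }
  double exp_rv(double rate) { return -std::log(uniform()) / rate; }
  // uniform integer in [0, n)
  int below(int n) { return (int)(uniform() * n) % n; }
};

// ---------------------------------------------------------------------------
// Indexed binary min-heap over process firing times.
struct IndexedHeap {
  std::vector<int> heap;    // heap of process ids
  std::vector<int> pos;     // process id -> heap index, -1 if absent
  std::vector<double> key;  // process id -> firing time

  void init(int nproc) {
    pos.assign(nproc, -1);
    key.assign(nproc, 0.0);
    heap.clear();
  }
  bool contains(int p) const { return pos[p] >= 0; }
  void swap_nodes(int i, int j) {
    std::swap(heap[i], heap[j]);
    pos[heap[i]] = i; pos[heap[j]] = j;
  }
  void up(int i) {
    while (i > 0) {
      int par = (i - 1) / 2;
      if (key[heap[par]] <= key[heap[i]]) break;
      swap_nodes(i, par); i = par;
    }
  }
  void down(int i) {
    int n = (int)heap.size();
    for (;;) {
      int l = 2 * i + 1, r = 2 * i + 2, m = i;
      if (l < n && key[heap[l]] < key[heap[m]]) m = l;
      if (r < n && key[heap[r]] < key[heap[m]]) m = r;
      if (m == i) break;
      swap_nodes(i, m); i = m;
    }
  }
  void push(int p, double k) {
    key[p] = k; heap.push_back(p); pos[p] = (int)heap.size() - 1;
    up(pos[p]);
  }
  void erase(int p) {
    int i = pos[p];
    int last = heap.back();
    heap.pop_back(); pos[p] = -1;
    if (i < (int)heap.size()) {
      heap[i] = last; pos[last] = i;
      down(i); up(pos[last]);
    }
  }
  bool empty() const { return heap.empty(); }
  int top() const { return heap[0]; }
  double top_key() const { return key[heap[0]]; }
};

// ---------------------------------------------------------------------------
// Engine state. Process id space:
//   [0, N)                      node deactivation, rate delta
//   [N, N + M)                  hyperedge activation (cardinality >= 3)
//   [N + M + 2j, N + M + 2j+1]  directed pairwise infection for edge j
//                               (cardinality == 2), direction 0: m0 -> m1
struct Engine {
  int N, M;
  std::vector<int> ememb, eoff;       // CSR hyperedge members (0-based)
  std::vector<int> nedges, noff;      // CSR node -> incident hyperedges
  std::vector<int> theta, card;
  std::vector<double> erate;
  double delta;

  std::vector<uint8_t> Y;
  std::vector<int> T;                 // active members per hyperedge
  int n_active;
  double t;
  IndexedHeap pq;
  Pcg32 rng;

  // per-node occupancy accounting
  std::vector<double> active_time, last_change;

  Engine(int N_, const IntegerVector& ememb_, const IntegerVector& eoff_,
         const IntegerVector& theta_, const NumericVector& erate_,
         double delta_, uint64_t seed)
    : N(N_), delta(delta_), rng(seed) {
    M = eoff_.size() - 1;
    ememb.assign(ememb_.begin(), ememb_.end());
    eoff.assign(eoff_.begin(), eoff_.end());
    theta.assign(theta_.begin(), theta_.end());
    erate.assign(erate_.begin(), erate_.end());
    card.resize(M);
    std::vector<int> deg(N, 0);
    for (int j = 0; j < M; ++j) {
      card[j] = eoff[j + 1] - eoff[j];
      for (int p = eoff[j]; p < eoff[j + 1]; ++p) deg[ememb[p]]++;
    }
    noff.assign(N + 1, 0);
    for (int i = 0; i < N; ++i) noff[i + 1] = noff[i] + deg[i];
    nedges.resize(noff[N]);
    std::vector<int> cur(noff.begin(), noff.end() - 1);
    for (int j = 0; j < M; ++j)
      for (int p = eoff[j]; p < eoff[j + 1]; ++p)
        nedges[cur[ememb[p]]++] = j;
  }

  int nproc() const { return N + M + 2 * M; }

  bool edge_proc_live(int j) const {
    return T[j] >= theta[j] && T[j] < card[j];
  }
  bool pair_proc_live(int j, int d) const {
    int a = ememb[eoff[j] + d], b = ememb[eoff[j] + 1 - d];
    return Y[a] == 1 && Y[b] == 0;
  }

  void sync_process(int pid, bool live, double rate) {
    bool in = pq.contains(pid);
    if (live && !in) pq.push(pid, t + rng.exp_rv(rate));
    else if (!live && in) pq.erase(pid);
  }
  void refresh_edge(int j) {
    if (card[j] == 2) {
      sync_process(N + M + 2 * j, pair_proc_live(j, 0), erate[j]);
      sync_process(N + M + 2 * j + 1, pair_proc_live(j, 1), erate[j]);
    } else {
      sync_process(N + j, edge_proc_live(j), erate[j]);
    }
  }

  void set_state(const std::vector<uint8_t>& y0) {
    Y = y0;
    T.assign(M, 0);
    n_active = 0;
    for (int i = 0; i < N; ++i) if (Y[i]) ++n_active;
    for (int j = 0; j < M; ++j)
      for (int p = eoff[j]; p < eoff[j + 1]; ++p) T[j] += Y[ememb[p]];
    pq.init(nproc());
    for (int i = 0; i < N; ++i)
      if (Y[i]) pq.push(i, t + rng.exp_rv(delta));
    for (int j = 0; j < M; ++j) refresh_edge(j);
    last_change.assign(N, t);
  }

  void activate_node(int k) {
    if (Y[k]) return;
    Y[k] = 1; ++n_active;
    last_change[k] = t;
    pq.push(k, t + rng.exp_rv(delta));
    for (int p = noff[k]; p < noff[k + 1]; ++p) {
      int j = nedges[p];
      ++T[j];
      refresh_edge(j);
    }
  }
  void deactivate_node(int i) {
    Y[i] = 0; --n_active;
    active_time[i] += t - last_change[i];
    if (pq.contains(i)) pq.erase(i);
    for (int p = noff[i]; p < noff[i + 1]; ++p) {
      int j = nedges[p];
      --T[j];
      refresh_edge(j);
    }
  }

  // Execute the top process. Returns the flipped nodes in `flips`.
  // Precondition: heap not empty.
  void step(std::vector<int>& flips, int& kind, int& which_edge) {
    int pid = pq.top();
    t = pq.top_key();
    flips.clear();
    if (pid < N) {                      // deactivation
      kind = 0; which_edge = -1;
      deactivate_node(pid);
      flips.push_back(pid);
    } else if (pid < N + M) {           // hyperedge fires
      int j = pid - N;
      kind = 2; which_edge = j;
      for (int p = eoff[j]; p < eoff[j + 1]; ++p) {
        int k = ememb[p];
        if (!Y[k]) { activate_node(k); flips.push_back(k); }
      }
      // all members now active: refresh removes the process
      refresh_edge(j);
    } else {                            // directed pairwise infection
      int q = pid - N - M;
      int j = q / 2, d = q % 2;
      kind = 1; which_edge = j;
      int dst = ememb[eoff[j] + 1 - d];
      activate_node(dst);
      flips.push_back(dst);
    }
  }

  void finalize_times() {
    for (int i = 0; i < N; ++i)
      if (Y[i]) { active_time[i] += t - last_change[i]; last_change[i] = t; }
  }
};

static std::vector<uint8_t> as_state(const IntegerVector& init, int N) {
  if (init.size() != N) stop("initial state length mismatch");
  std::vector<uint8_t> y(N);
  for (int i = 0; i < N; ++i) y[i] = init[i] ? 1 : 0;
  return y;
}

// ---------------------------------------------------------------------------
// Plain next-reaction simulation with event logging.
// [[Rcpp::export]]
List cpp_simulate(int N, IntegerVector ememb, IntegerVector eoff,
                  IntegerVector theta, NumericVector erate, double delta,
                  IntegerVector init, double t_max, double seed,
                  int snapshot_stride, double max_events) {
  Engine eng(N, ememb, eoff, theta, erate, delta, (uint64_t)seed);
  eng.t = 0.0;
  eng.active_time.assign(N, 0.0);
  eng.set_state(as_state(init, N));

  std::vector<double> times;
  std::vector<int> kinds, edges_v, flip_flat, flip_off(1, 0), nact;
  std::vector<int> snap_flat;
  std::vector<double> snap_times;
  std::vector<int> flips;
  int kind, wedge;
  long long nev = 0;
  std::string status = "absorbed";

  while (!eng.pq.empty()) {
    if (eng.pq.top_key() > t_max) { eng.t = t_max; status = "t_max"; break; }
    eng.step(flips, kind, wedge);
    ++nev;
    times.push_back(eng.t);
    kinds.push_back(kind);
    edges_v.push_back(wedge < 0 ? NA_INTEGER : wedge + 1);
    for (size_t q = 0; q < flips.size(); ++q) flip_flat.push_back(flips[q] + 1);
    flip_off.push_back((int)flip_flat.size());
    nact.push_back(eng.n_active);
    if (snapshot_stride > 0 && nev % snapshot_stride == 0) {
      snap_times.push_back(eng.t);
      for (int i = 0; i < N; ++i) snap_flat.push_back(eng.Y[i]);
    }
    if ((double)nev >= max_events) { status = "max_events"; break; }
    if (eng.n_active == 0) break;
  }
  if (eng.pq.empty() && eng.n_active > 0) status = "stalled";
  eng.finalize_times();

  IntegerVector final_state(N);
  for (int i = 0; i < N; ++i) final_state[i] = eng.Y[i];
  return List::create(
    _["times"] = times, _["kind"] = kinds, _["edge"] = edges_v,
    _["flip_node"] = flip_flat, _["flip_off"] = flip_off,
    _["n_active"] = nact, _["final_state"] = final_state,
    _["t_end"] = eng.t, _["active_time"] = NumericVector(eng.active_time.begin(), eng.active_time.end()),
    _["snapshot_times"] = snap_times, _["snapshots"] = snap_flat,
    _["status"] = status);
}

// ---------------------------------------------------------------------------
// Direct-method variant (resample-on-change): recomputes the full set of
// live processes after every event and samples the next one from scratch.
// Statistically identical to the next-reaction engine; used to validate it.
// [[Rcpp::export]]
List cpp_simulate_direct(int N, IntegerVector ememb, IntegerVector eoff,
                         IntegerVector theta, NumericVector erate,
                         double delta, IntegerVector init, double t_max,
                         double seed, double max_events) {
  Engine eng(N, ememb, eoff, theta, erate, delta, (uint64_t)seed);
  eng.t = 0.0;
  eng.active_time.assign(N, 0.0);
  eng.set_state(as_state(init, N));   // heap unused below, kept for T/Y updates

  long long nev = 0;
  std::string status = "absorbed";
  std::vector<int> live; std::vector<double> rates;
  while (eng.n_active > 0) {
    live.clear(); rates.clear();
    double total = 0.0;
    for (int i = 0; i < N; ++i)
      if (eng.Y[i]) { live.push_back(i); rates.push_back(delta); total += delta; }
    for (int j = 0; j < eng.M; ++j) {
      if (eng.card[j] == 2) {
        for (int d = 0; d < 2; ++d)
          if (eng.pair_proc_live(j, d)) {
            live.push_back(N + eng.M + 2 * j + d);
            rates.push_back(eng.erate[j]); total += eng.erate[j];
          }
      } else if (eng.edge_proc_live(j)) {
        live.push_back(N + j); rates.push_back(eng.erate[j]); total += eng.erate[j];
      }
    }
    if (total <= 0.0) { status = "stalled"; break; }
    double dt = eng.rng.exp_rv(total);
    if (eng.t + dt > t_max) { eng.t = t_max; status = "t_max"; break; }
    eng.t += dt;
    double u = eng.rng.uniform() * total, acc = 0.0;
    int pid = live.back();
    for (size_t q = 0; q < live.size(); ++q) {
      acc += rates[q];
      if (u <= acc) { pid = live[q]; break; }
    }
    if (pid < N) eng.deactivate_node(pid);
    else if (pid < N + eng.M) {
      int j = pid - N;
      for (int p = eng.eoff[j]; p < eng.eoff[j + 1]; ++p)
        if (!eng.Y[eng.ememb[p]]) eng.activate_node(eng.ememb[p]);
    } else {
      int q = pid - N - eng.M;
      int j = q / 2, d = q % 2;
      eng.activate_node(eng.ememb[eng.eoff[j] + 1 - d]);
    }
    if ((double)(++nev) >= max_events) { status = "max_events"; break; }
  }
  eng.finalize_times();
  IntegerVector final_state(N);
  for (int i = 0; i < N; ++i) final_state[i] = eng.Y[i];
  return List::create(_["t_end"] = eng.t, _["final_state"] = final_state,
                      _["n_events"] = (double)nev, _["status"] = status,
                      _["active_time"] = NumericVector(eng.active_time.begin(), eng.active_time.end()));
}

// ---------------------------------------------------------------------------
// Quasi-stationary run: stored-states reactivation, time-weighted occupancy,
// adaptive sampling windows stopped on susceptibility convergence.
static double chi_of(const std::vector<double>& freq) {
  double tot = 0.0, m1 = 0.0, m2 = 0.0;
  for (size_t n = 0; n < freq.size(); ++n) tot += freq[n];
  if (tot <= 0.0) return NA_REAL;
  for (size_t n = 0; n < freq.size(); ++n) {
    double p = freq[n] / tot;
    m1 += n * p; m2 += (double)n * n * p;
  }
  if (m1 <= 0.0) return NA_REAL;
  return (m2 - m1 * m1) / m1;
}

// [[Rcpp::export]]
List cpp_qs_run(int N, IntegerVector ememb, IntegerVector eoff,
                IntegerVector theta, NumericVector erate, double delta,
                IntegerVector init, int M_list, double p_r, double t_r,
                double t_s, double eps, int c_max, double seed) {
  Engine eng(N, ememb, eoff, theta, erate, delta, (uint64_t)seed);
  eng.t = 0.0;
  eng.active_time.assign(N, 0.0);
  std::vector<uint8_t> y0 = as_state(init, N);
  eng.set_state(y0);
  if (eng.n_active == 0) stop("QS run needs an active initial state");

  std::vector< std::vector<uint8_t> > list_states(M_list, y0);
  std::vector<double> freq(N + 1, 0.0);
  std::vector<int> flips; int kind, wedge;
  std::vector<double> chi_trace;

  bool sampling = false;
  double last_acc = 0.0;             // time point accounted for so far
  std::vector<double> atime_offset(N, 0.0);
  double window_end = t_r;           // first boundary: end of relaxation
  double chi_prev = NA_REAL;
  int windows = 0;
  std::string status = "c_max";

  for (;;) {
    if (eng.pq.empty()) stop("internal: no live processes in active state");
    double t_next = eng.pq.top_key();
    while (t_next >= window_end) {
      // account the slice of the current dwell up to the boundary
      if (sampling) { freq[eng.n_active] += window_end - last_acc; }
      last_acc = window_end;
      if (!sampling) {
        // relaxation finished: snapshot per-node occupancy baseline
        sampling = true;
        eng.t = window_end;
        eng.finalize_times();
        for (int i = 0; i < N; ++i) atime_offset[i] = eng.active_time[i];
      } else {
        ++windows;
        double chi_now = chi_of(freq);
        chi_trace.push_back(chi_now);
        bool conv = R_finite(chi_now) && R_finite(chi_prev) &&
                    std::fabs(chi_now - chi_prev) < eps;
        chi_prev = chi_now;
        if (conv || windows >= c_max) {
          if (conv) status = "converged";
          eng.t = window_end;
          eng.finalize_times();
          NumericVector nat(N);
          for (int i = 0; i < N; ++i) nat[i] = eng.active_time[i] - atime_offset[i];
          double total = 0.0;
          for (int n = 0; n <= N; ++n) total += freq[n];
          IntegerVector final_state(N);
          for (int i = 0; i < N; ++i) final_state[i] = eng.Y[i];
          return List::create(
            _["freq"] = NumericVector(freq.begin(), freq.end()),
            _["sample_time"] = total, _["windows"] = windows,
            _["chi_trace"] = NumericVector(chi_trace.begin(), chi_trace.end()),
            _["node_active_time"] = nat, _["final_state"] = final_state,
            _["status"] = status);
        }
      }
      window_end += t_s;
    }
    // accrue dwell time in the pre-transition state
    if (sampling) freq[eng.n_active] += t_next - last_acc;
    last_acc = t_next;
    double dt = t_next - eng.t;
    eng.step(flips, kind, wedge);
    // stored-states list update
    if (eng.n_active > 0) {
      double p = p_r * dt;
      if (p >= 1.0 || eng.rng.uniform() < p)
        list_states[eng.rng.below(M_list)] = eng.Y;
    } else {
      // absorbed: replace with a uniformly drawn stored active state
      eng.finalize_times();
      const std::vector<uint8_t>& repl = list_states[eng.rng.below(M_list)];
      eng.set_state(repl);
      if (eng.n_active == 0) stop("stored QS state is absorbing");
    }
  }
}

// ---------------------------------------------------------------------------
// Poisson-binomial pmf via the DFT of the characteristic function.
// Given m probabilities, returns the pmf over counts 0..m, computed with
// roots of unity of order L = m + 1. Stable for large m, unlike the direct
// product-over-subsets expansion.
// [[Rcpp::export]]
NumericVector cpp_pb_dft(NumericVector probs) {
  int m = probs.size();
  int L = m + 1;
  NumericVector out(L);
  const double twopi = 2.0 * M_PI;
  std::vector< std::complex<double> > g(L);
  for (int l = 0; l < L; ++l) {
    std::complex<double> Cl(std::cos(twopi * l / L), std::sin(twopi * l / L));
    std::complex<double> prod(1.0, 0.0);
    for (int q = 0; q < m; ++q)
      prod *= (1.0 + (Cl - 1.0) * probs[q]);
    g[l] = prod;
  }
  for (int k = 0; k < L; ++k) {
    std::complex<double> s(0.0, 0.0);
    for (int l = 0; l < L; ++l) {
      std::complex<double> Cmlk(std::cos(-twopi * l * k / L),
                                std::sin(-twopi * l * k / L));
      s += Cmlk * g[l];
    }
    out[k] = s.real() / L;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Individual-based mean-field right-hand side:
//   dy_i/dt = -delta y_i + (1 - y_i) sum_{j in E_i} lambda_j P_i,j
// where P_i,j is the probability that at least Theta_j (and at most
// |e_j| - 1) of the OTHER members of e_j are active, under independence:
// a Poisson-binomial tail over the member activation probabilities with
// node i excluded, evaluated through the DFT identity.
// erate[j] here is lambda_j = lambda * modulation(|e_j|).
// [[Rcpp::export]]
NumericVector cpp_mf_rhs(NumericVector y, int N, IntegerVector ememb,
                         IntegerVector eoff, IntegerVector theta,
                         NumericVector erate, double delta) {
  if (y.size() != N) stop("state dimension mismatch");
  int M = eoff.size() - 1;
  NumericVector drive(N);   // sum over incident hyperedges of lambda_j * tail
  const double twopi = 2.0 * M_PI;
  for (int j = 0; j < M; ++j) {
    int L = eoff[j + 1] - eoff[j];
    int th = theta[j];
    if (th > L - 1) continue;                     // unreachable threshold
    const int* mem = &ememb[eoff[j]];
    // S_l = sum_{k=th}^{L-1} C^{-lk}, reused for every excluded member
    std::vector< std::complex<double> > S(L), Cl(L);
    for (int l = 0; l < L; ++l) {
      Cl[l] = std::complex<double>(std::cos(twopi * l / L),
                                   std::sin(twopi * l / L));
      std::complex<double> s(0.0, 0.0);
      for (int k = th; k <= L - 1; ++k)
        s += std::complex<double>(std::cos(-twopi * l * k / L),
                                  std::sin(-twopi * l * k / L));
      S[l] = s;
    }
    for (int p = 0; p < L; ++p) {
      int i = mem[p];
      std::complex<double> acc(0.0, 0.0);
      for (int l = 0; l < L; ++l) {
        std::complex<double> prod(1.0, 0.0);
        for (int q = 0; q < L; ++q) {
          if (q == p) continue;
          prod *= (1.0 + (Cl[l] - 1.0) * y[mem[q]]);
        }
        acc += prod * S[l];
      }
      double tail = acc.real() / L;
      if (tail < 0.0) tail = 0.0;
      if (tail > 1.0) tail = 1.0;
      drive[i] += erate[j] * tail;
    }
  }
  NumericVector out(N);
  for (int i = 0; i < N; ++i)
    out[i] = -delta * y[i] + (1.0 - y[i]) * drive[i];
  return out;
}
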