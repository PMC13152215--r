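// Birth-death Moran process with exponential fitness on a weighted, directed
// interaction/reproduction graph pair.
//
// Per step: (1) a birth node is drawn with probability proportional to
// exp(delta * total payoff), where the total payoff of node i is the sum over
// in-edges (tail j -> i) of w_ij * pi(state_i, state_j); (2) a death node is
// drawn among the birth node's reproduction out-neighbours proportional to
// edge weight; (3) with probability mu the death node receives a uniformly
// random strategy out of the 2m (label, phase) pairs, otherwise a copy of the
// birth node's state.
//
// Payoffs are maintained incrementally: when the death node's state changes,
// its own payoff is recomputed from its in-edges and the payoff of each head
// of its out-edges is adjusted by the difference on that single edge. Fitness
// weights are shifted by the maximum payoff before exponentiation (the
// softmax-style normalization is shift-invariant), guarding against overflow.
//
// All randomness flows through R's RNG, so a single set.seed() upstream makes
// runs bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Params {
  double B0, beta0, cost, alpha, delta, mu;
  int m;
  std::vector<double> fTab; // coupling (1 + cos(2*pi*d/m)) / 2, d = 0..m-1

  void init_coupling() {
    fTab.resize(m);
    for (int d = 0; d < m; ++d)
      fTab[d] = 0.5 * (1.0 + std::cos(2.0 * M_PI * d / m));
  }

  // payoff to the head from one game against the tail
  inline double pay(int lh, int kh, int lt, int kt) const {
    if (!lh && !lt) return 0.0;
    int d = kt - kh;
    if (d < 0) d += m;
    double f = fTab[d];
    if (lh && lt) return B0 * f - cost;
    if (lh) return 2.0 * alpha * beta0 * f - cost;
    return 2.0 * (1.0 - alpha) * beta0 * f;
  }
};

struct CSR { // per-node adjacency, flattened
  std::vector<int> start;   // size N + 1
  std::vector<int> other;   // neighbour node
  std::vector<double> w;    // edge weight
};

CSR build_csr(int N, const IntegerVector& key, const IntegerVector& other,
              const IntegerVector& weight) {
  int E = key.size();
  CSR a;
  a.start.assign(N + 1, 0);
  for (int e = 0; e < E; ++e) a.start[key[e] + 1]++;
  for (int i = 0; i < N; ++i) a.start[i + 1] += a.start[i];
  a.other.resize(E);
  a.w.resize(E);
  std::vector<int> fill(a.start.begin(), a.start.end() - 1);
  for (int e = 0; e < E; ++e) {
    int pos = fill[key[e]]++;
    a.other[pos] = other[e];
    a.w[pos] = weight[e];
  }
  return a;
}

struct Engine {
  int N;
  Params p;
  CSR in;      // interaction in-edges of node i (others = tails)
  CSR out;     // interaction out-edges of node i (others = heads)
  CSR rep;     // reproduction out-edges (others = death candidates)
  std::vector<double> repCum; // per-node total reproduction out-weight
  std::vector<int> label, phase;
  std::vector<double> payoff, selw;
  long long n_mut = 0;

  void init(const IntegerVector& tail, const IntegerVector& head,
            const IntegerVector& w, const IntegerVector& rtail,
            const IntegerVector& rhead, const IntegerVector& rw,
            const IntegerVector& lab0, const IntegerVector& k0,
            const List& par) {
    N = lab0.size();
    p.B0 = par["B0"]; p.beta0 = par["beta0"]; p.cost = par["c"];
    p.alpha = par["alpha"]; p.delta = par["delta"]; p.mu = par["mu"];
    p.m = par["m"];
    p.init_coupling();
    in = build_csr(N, head, tail, w);
    out = build_csr(N, tail, head, w);
    rep = build_csr(N, rtail, rhead, rw);
    repCum.assign(N, 0.0);
    for (int i = 0; i < N; ++i) {
      for (int e = rep.start[i]; e < rep.start[i + 1]; ++e) repCum[i] += rep.w[e];
      if (repCum[i] <= 0)
        stop("reproduction graph has a node with no out-edges");
    }
    label.assign(lab0.begin(), lab0.end());
    phase.assign(k0.begin(), k0.end());
    payoff.assign(N, 0.0);
    selw.assign(N, 0.0);
    for (int i = 0; i < N; ++i) payoff[i] = full_payoff(i);
  }

  double full_payoff(int i) const {
    double s = 0.0;
    for (int e = in.start[i]; e < in.start[i + 1]; ++e) {
      int t = in.other[e];
      s += in.w[e] * p.pay(label[i], phase[i], label[t], phase[t]);
    }
    return s;
  }

  int draw_birth() {
    double mx = payoff[0];
    for (int i = 1; i < N; ++i) if (payoff[i] > mx) mx = payoff[i];
    double tot = 0.0;
    for (int i = 0; i < N; ++i) {
      selw[i] = std::exp(p.delta * (payoff[i] - mx));
      tot += selw[i];
    }
    double u = unif_rand() * tot;
    for (int i = 0; i < N; ++i) {
      u -= selw[i];
      if (u <= 0) return i;
    }
    return N - 1;
  }

  int draw_death(int birth) {
    double u = unif_rand() * repCum[birth];
    int last = rep.start[birth];
    for (int e = rep.start[birth]; e < rep.start[birth + 1]; ++e) {
      last = e;
      u -= rep.w[e];
      if (u <= 0) break;
    }
    return rep.other[last];
  }

  void set_state(int d, int nl, int nk) {
    int ol = label[d], ok = phase[d];
    if (nl == ol && nk == ok) return;
    // heads of d's out-edges see d as a tail: adjust their payoff by the
    // difference on that edge (d's own term is handled by full recompute)
    for (int e = out.start[d]; e < out.start[d + 1]; ++e) {
      int h = out.other[e];
      if (h == d) continue;
      payoff[h] += out.w[e] * (p.pay(label[h], phase[h], nl, nk) -
                               p.pay(label[h], phase[h], ol, ok));
    }
    label[d] = nl;
    phase[d] = nk;
    payoff[d] = full_payoff(d);
  }

  void step() {
    int birth = draw_birth();
    int death = draw_death(birth);
    int nl, nk;
    if (unif_rand() < p.mu) {
      int idx = (int)(unif_rand() * (2.0 * p.m));
      if (idx >= 2 * p.m) idx = 2 * p.m - 1;
      nl = idx / p.m;
      nk = idx % p.m;
      ++n_mut;
    } else {
      nl = label[birth];
      nk = phase[birth];
    }
    set_state(death, nl, nk);
  }

  bool monomorphic() const {
    for (int i = 1; i < N; ++i)
      if (label[i] != label[0] || phase[i] != phase[0]) return false;
    return true;
  }
};

} // namespace

// [[Rcpp::export(name = ".run_moran_cpp")]]
List run_moran_cpp(IntegerVector tail, IntegerVector head, IntegerVector w,
                   IntegerVector rtail, IntegerVector rhead, IntegerVector rw,
                   IntegerVector label0, IntegerVector k0, List par,
                   double steps, int sample_every) {
  Engine eng;
  eng.init(tail, head, w, rtail, rhead, rw, label0, k0, par);
  long long T = (long long)steps;
  int nsamp = (int)(T / sample_every) + 1;
  IntegerMatrix labels(nsamp, eng.N), phases(nsamp, eng.N);
  NumericVector sampled_step(nsamp);
  int row = 0;
  for (int i = 0; i < eng.N; ++i) {
    labels(row, i) = eng.label[i];
    phases(row, i) = eng.phase[i];
  }
  sampled_step[row++] = 0;
  for (long long t = 1; t <= T; ++t) {
    eng.step();
    if (t % sample_every == 0 && row < nsamp) {
      for (int i = 0; i < eng.N; ++i) {
        labels(row, i) = eng.label[i];
        phases(row, i) = eng.phase[i];
      }
      sampled_step[row++] = (double)t;
    }
    if ((t & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
    _["labels"] = labels, _["phases"] = phases, _["step"] = sampled_step,
    _["payoff"] = NumericVector(eng.payoff.begin(), eng.payoff.end()),
    _["n_mutations"] = (double)eng.n_mut);
}

// [[Rcpp::export(name = ".run_to_fixation_cpp")]]
List run_to_fixation_cpp(IntegerVector tail, IntegerVector head, IntegerVector w,
                         IntegerVector rtail, IntegerVector rhead, IntegerVector rw,
                         IntegerVector label0, IntegerVector k0, List par,
                         double max_steps) {
  Engine eng;
  eng.init(tail, head, w, rtail, rhead, rw, label0, k0, par);
  long long T = (long long)max_steps;
  long long t = 0;
  bool fixed = eng.monomorphic();
  while (!fixed && t < T) {
    eng.step();
    ++t;
    fixed = eng.monomorphic();
    if ((t & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
    _["fixed"] = fixed, _["steps"] = (double)t,
    _["label"] = eng.label[0], _["k"] = eng.phase[0],
    _["labels"] = IntegerVector(eng.label.begin(), eng.label.end()),
    _["phases"] = IntegerVector(eng.phase.begin(), eng.phase.end()));
}
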