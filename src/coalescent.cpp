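// Structured-coalescent core: multi-population Kingman coalescent with
// population splits, piecewise-constant diploid sizes, continuous migration
// bands and instantaneous admixture pulses (all in backward time), plus
// infinite-sites mutation dropping and pairwise-TMRCA extraction.
//
// Conventions:
//  - time in generations before present, continuous; leaves at time 0
//  - diploid N_e: a pair of lineages in a population of size N coalesces
//    at rate 1/(2N) per generation
//  - own counter-seeded RNG (not R's) so each locus is reproducible in
//    isolation and results are identical across platforms

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>
#include <set>

using namespace Rcpp;

namespace {

// splitmix64: seeds the working RNG from (seed, stream) pairs
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t next_u64() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  // uniform in (0,1): never exactly 0 or 1
  double runif() {
    return (static_cast<double>(next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double rexp(double rate) { return -std::log(runif()) / rate; }
  // uniform integer in [0, n)
  int runif_int(int n) {
    return static_cast<int>(runif() * n) % n;
  }
  int rpois(double lambda) {
    // chunked Knuth: exact, avoids exp() underflow for large lambda
    int total = 0;
    while (lambda > 30.0) {
      total += rpois_small(30.0);
      lambda -= 30.0;
    }
    total += rpois_small(lambda);
    return total;
  }
  int rpois_small(double lambda) {
    if (lambda <= 0.0) return 0;
    double L = std::exp(-lambda), p = 1.0;
    int k = 0;
    do { ++k; p *= runif(); } while (p > L);
    return k - 1;
  }
};

uint64_t mix_seed(double seed, double stream) {
  Rng r(static_cast<uint64_t>(seed) * 0x9e3779b97f4a7c15ULL + 0x632be59bd9b4e019ULL);
  uint64_t a = r.next_u64();
  Rng r2(a ^ (static_cast<uint64_t>(stream) + 0x9e3779b97f4a7c15ULL));
  return r2.next_u64();
}

struct Epoch { int pop; double start, end, N; };
struct Band  { int source, dest; double rate, start, end; };
// type 0 = split (a = child_a, b = child_b, c = parent)
// type 1 = pulse (a = from_pop, b = into_pop, prop)
struct Event { double time; int type, a, b, c; double prop; };

double pop_size_at(const std::vector<Epoch>& epochs, int pop, double t) {
  for (const Epoch& e : epochs)
    if (e.pop == pop && t >= e.start && t < e.end) return e.N;
  stop("no epoch size defined for population %d at time %f", pop + 1, t);
  return 0.0;  // unreached
}

}  // namespace

struct ParsedModel {
  int n_pop;
  std::vector<Epoch> epochs;
  std::vector<Event> events;
  std::vector<Band> bands;
  std::set<double> bps;  // template of rate-change breakpoints
};

static ParsedModel parse_model(List model) {
  ParsedModel pm;
  NumericMatrix em = model["epochs"];
  for (int i = 0; i < em.nrow(); ++i)
    pm.epochs.push_back({static_cast<int>(em(i, 0)) - 1, em(i, 1), em(i, 2), em(i, 3)});

  NumericMatrix evm = model["events"];
  for (int i = 0; i < evm.nrow(); ++i)
    pm.events.push_back({evm(i, 0), static_cast<int>(evm(i, 1)),
                         static_cast<int>(evm(i, 2)) - 1, static_cast<int>(evm(i, 3)) - 1,
                         static_cast<int>(evm(i, 4)) - 1, evm(i, 5)});
  std::stable_sort(pm.events.begin(), pm.events.end(),
                   [](const Event& x, const Event& y) { return x.time < y.time; });

  NumericMatrix bm = model["bands"];
  for (int i = 0; i < bm.nrow(); ++i)
    pm.bands.push_back({static_cast<int>(bm(i, 0)) - 1, static_cast<int>(bm(i, 1)) - 1,
                        bm(i, 2), bm(i, 3), bm(i, 4)});

  pm.n_pop = as<int>(model["n_pop"]);
  for (const Epoch& e : pm.epochs) { pm.bps.insert(e.start); if (R_finite(e.end)) pm.bps.insert(e.end); }
  for (const Band& b : pm.bands)   { pm.bps.insert(b.start); if (R_finite(b.end)) pm.bps.insert(b.end); }
  for (const Event& e : pm.events) pm.bps.insert(e.time);
  return pm;
}

// one structured-coalescent realization; fills parent/ntime (size 2n-1)
static void sim_tree(const ParsedModel& pm, const std::vector<int>& sample_pop0,
                     Rng& rng, std::vector<int>& parent,
                     std::vector<double>& ntime) {
  const int n = static_cast<int>(sample_pop0.size());
  const int n_pop = pm.n_pop;
  const std::vector<Epoch>& epochs = pm.epochs;
  const std::vector<Event>& events = pm.events;
  const std::vector<Band>& bands = pm.bands;
  std::set<double> bps = pm.bps;

  const int n_nodes = 2 * n - 1;
  parent.assign(n_nodes, -1);
  ntime.assign(n_nodes, 0.0);
  // per-population registries of active lineages (node ids)
  std::vector<std::vector<int>> members(n_pop);
  for (int i = 0; i < n; ++i) {
    int p = sample_pop0[i];
    if (p < 0 || p >= n_pop) stop("sampled population index out of range");
    members[p].push_back(i);
  }
  int n_active = n, next_node = n;
  size_t ev_idx = 0;
  double t = 0.0;
  std::vector<double> coal_rate(n_pop, 0.0);
  // population sizes are constant between breakpoints: cache per segment
  std::vector<double> curN(n_pop, -1.0);
  std::vector<double> band_rate(bands.size(), 0.0);

  while (n_active > 1) {
    double next_bp = R_PosInf;
    for (double b : bps) if (b > t) { next_bp = b; break; }

    double R = 0.0;
    for (int p = 0; p < n_pop; ++p) {
      size_t kp = members[p].size();
      if (kp >= 2) {
        if (curN[p] < 0.0) curN[p] = pop_size_at(epochs, p, t);
        coal_rate[p] = kp * (kp - 1.0) / (4.0 * curN[p]);
        R += coal_rate[p];
      } else {
        coal_rate[p] = 0.0;
      }
    }
    for (size_t i = 0; i < bands.size(); ++i) {
      const Band& b = bands[i];
      size_t kd = members[b.dest].size();
      band_rate[i] = (t >= b.start && t < b.end && kd > 0) ? kd * b.rate : 0.0;
      R += band_rate[i];
    }

    double te = (R > 0.0) ? t + rng.rexp(R) : R_PosInf;

    if (te < next_bp) {
      t = te;
      double u = rng.runif() * R, acc = 0.0;
      int chosen_pop = -1, chosen_band = -1;
      for (int p = 0; p < n_pop && chosen_pop < 0 && chosen_band < 0; ++p) {
        acc += coal_rate[p];
        if (u < acc) chosen_pop = p;
      }
      if (chosen_pop < 0) {
        for (size_t i = 0; i < bands.size(); ++i) {
          acc += band_rate[i];
          if (u < acc) { chosen_band = static_cast<int>(i); break; }
        }
        if (chosen_band < 0) chosen_band = static_cast<int>(bands.size()) - 1;
      }
      if (chosen_pop >= 0) {
        // coalesce two uniformly chosen distinct lineages in chosen_pop
        std::vector<int>& mem = members[chosen_pop];
        int r1 = rng.runif_int(static_cast<int>(mem.size()));
        int node1 = mem[r1];
        mem[r1] = mem.back();
        mem.pop_back();
        int r2 = rng.runif_int(static_cast<int>(mem.size()));
        int node2 = mem[r2];
        int v = next_node++;
        parent[node1] = v;
        parent[node2] = v;
        ntime[v] = t;
        mem[r2] = v;  // merged lineage replaces the second pick
        --n_active;
      } else {
        const Band& b = bands[chosen_band];
        std::vector<int>& mem = members[b.dest];
        int r1 = rng.runif_int(static_cast<int>(mem.size()));
        members[b.source].push_back(mem[r1]);
        mem[r1] = mem.back();
        mem.pop_back();
      }
    } else {
      if (!R_finite(next_bp))
        stop("lineages stranded: %d lineages remain with no coalescence or migration route", n_active);
      t = next_bp;
      while (ev_idx < events.size() && events[ev_idx].time <= t) {
        const Event& e = events[ev_idx];
        if (e.time == t) {
          if (e.type == 0) {
            std::vector<int>& par_mem = members[e.c];
            for (int child : {e.a, e.b}) {
              for (int nd : members[child]) par_mem.push_back(nd);
              members[child].clear();
            }
          } else {
            std::vector<int>& from_mem = members[e.a];
            std::vector<int>& into_mem = members[e.b];
            size_t i = 0;
            while (i < into_mem.size()) {
              if (rng.runif() < e.prop) {
                from_mem.push_back(into_mem[i]);
                into_mem[i] = into_mem.back();
                into_mem.pop_back();
              } else {
                ++i;
              }
            }
          }
        }
        ++ev_idx;
      }
      bps.erase(t);
      std::fill(curN.begin(), curN.end(), -1.0);  // sizes may change here
    }
  }
}

// model: list(n_pop, epochs [pop,start,end,N], events [time,type,a,b,c,prop],
//             bands [source,dest,rate,start,end]); indices 1-based from R.
// sample_pop: 1-based population index per haplotype.
// Returns list(parent, time): nodes 0..n-1 leaves, n..2n-2 internal (1-based
// parent ids in R; root parent = 0).
// [[Rcpp::export]]
List cpp_sim_genealogy(List model, IntegerVector sample_pop, double seed,
                       double stream) {
  const int n = sample_pop.size();
  if (n < 1) stop("need at least one sampled haplotype");
  ParsedModel pm = parse_model(model);
  std::vector<int> sp0(n);
  for (int i = 0; i < n; ++i) sp0[i] = sample_pop[i] - 1;
  Rng rng(mix_seed(seed, stream));
  std::vector<int> parent;
  std::vector<double> ntime;
  sim_tree(pm, sp0, rng, parent, ntime);
  const int n_nodes = 2 * n - 1;
  IntegerVector par(n_nodes);
  NumericVector tim(n_nodes);
  for (int i = 0; i < n_nodes; ++i) {
    par[i] = parent[i] + 1;  // root -> 0
    tim[i] = ntime[i];
  }
  return List::create(_["parent"] = par, _["time"] = tim, _["n_leaves"] = n);
}

// Infinite-sites mutation dropping. Positions are distinct integers in
// [1, length_bp]; carriers are the leaves subtending the mutated branch.
// Returns list(pos ascending, geno sites x leaves 0/1).
// [[Rcpp::export]]
List cpp_drop_mutations(IntegerVector parent, NumericVector node_time,
                        int n_leaves, double mu, double length_bp,
                        double seed, double stream) {
  const int n_nodes = parent.size();
  Rng rng(mix_seed(seed, stream) ^ 0x5bf03635ULL);

  std::vector<double> cum_len(n_nodes, 0.0);
  double total = 0.0;
  for (int v = 0; v < n_nodes; ++v) {
    if (parent[v] > 0) total += node_time[parent[v] - 1] - node_time[v];
    cum_len[v] = total;
  }

  int n_mut = (total > 0.0) ? rng.rpois(mu * length_bp * total) : 0;
  const int Lbp = static_cast<int>(length_bp);
  if (n_mut > Lbp) n_mut = Lbp;  // infinite-sites cap at distinct positions

  // distinct positions
  std::set<int> pos_set;
  while (static_cast<int>(pos_set.size()) < n_mut)
    pos_set.insert(rng.runif_int(Lbp) + 1);
  std::vector<int> pos(pos_set.begin(), pos_set.end());

  // branch per mutation (position order is uniform, independent of branch)
  std::vector<int> mut_node(n_mut);
  for (int m = 0; m < n_mut; ++m) {
    double u = rng.runif() * total;
    int v = static_cast<int>(std::lower_bound(cum_len.begin(), cum_len.end(), u) -
                             cum_len.begin());
    while (v >= n_nodes || parent[v] == 0) --v;  // never the root
    mut_node[m] = v;
  }

  // children lists for subtree leaf collection
  std::vector<std::vector<int>> children(n_nodes);
  for (int v = 0; v < n_nodes; ++v)
    if (parent[v] > 0) children[parent[v] - 1].push_back(v);

  IntegerMatrix geno(n_mut, n_leaves);
  std::vector<int> stack;
  for (int m = 0; m < n_mut; ++m) {
    stack.clear();
    stack.push_back(mut_node[m]);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      if (v < n_leaves) geno(m, v) = 1;
      for (int c : children[v]) stack.push_back(c);
    }
  }
  return List::create(_["pos"] = wrap(pos), _["geno"] = geno);
}

// Fast path for summary-statistic pipelines: drop infinite-sites mutations
// and return only per-population derived-allele counts (sites x n_pop).
// Positions are irrelevant for frequency-based statistics over unlinked loci.
// [[Rcpp::export]]
IntegerMatrix cpp_mutation_pop_counts(IntegerVector parent,
                                      NumericVector node_time, int n_leaves,
                                      IntegerVector leaf_pop, int n_pop,
                                      double mu, double length_bp,
                                      double seed, double stream) {
  const int n_nodes = parent.size();
  Rng rng(mix_seed(seed, stream) ^ 0x5bf03635ULL);

  std::vector<double> cum_len(n_nodes, 0.0);
  double total = 0.0;
  for (int v = 0; v < n_nodes; ++v) {
    if (parent[v] > 0) total += node_time[parent[v] - 1] - node_time[v];
    cum_len[v] = total;
  }
  int n_mut = (total > 0.0) ? rng.rpois(mu * length_bp * total) : 0;
  const int Lbp = static_cast<int>(length_bp);
  if (n_mut > Lbp) n_mut = Lbp;

  // consume the position draws exactly as cpp_drop_mutations does, so the
  // two routes yield identical mutation sets from the same (seed, stream)
  std::set<int> pos_set;
  while (static_cast<int>(pos_set.size()) < n_mut)
    pos_set.insert(rng.runif_int(Lbp) + 1);

  // per-node subtended-leaf counts per population (nodes are created in
  // time order, so children always precede parents)
  std::vector<int> popcnt(static_cast<size_t>(n_nodes) * n_pop, 0);
  for (int v = 0; v < n_leaves; ++v) popcnt[v * n_pop + (leaf_pop[v] - 1)] = 1;
  for (int v = 0; v < n_nodes; ++v) {
    if (parent[v] > 0) {
      int p = parent[v] - 1;
      for (int k = 0; k < n_pop; ++k) popcnt[p * n_pop + k] += popcnt[v * n_pop + k];
    }
  }
  IntegerMatrix out(n_mut, n_pop);
  for (int m = 0; m < n_mut; ++m) {
    double u = rng.runif() * total;
    int v = static_cast<int>(std::lower_bound(cum_len.begin(), cum_len.end(), u) -
                             cum_len.begin());
    while (v >= n_nodes || parent[v] == 0) --v;
    for (int k = 0; k < n_pop; ++k) out(m, k) = popcnt[v * n_pop + k];
  }
  return out;
}

// Whole-row ABC kernel: n_loci independent genealogy + infinite-sites
// realizations, accumulating per-locus (block) sums of the configured
// F statistics plus per-population diversity components, without ever
// materializing genotype matrices. RNG streams per locus match
// cpp_sim_genealogy / cpp_drop_mutations exactly.
// stats: n_stats x 5 integer matrix (kind 2/3/4, pop indices i1..i4,
// 1-based into the sample-population list, 0 when unused).
// [[Rcpp::export]]
List cpp_sim_summary_blocks(List model, IntegerVector sample_pop_model,
                            IntegerVector sample_pop_stat, int n_spop,
                            IntegerVector hap_n, double mu, double length_bp,
                            int n_loci, IntegerMatrix stats, double seed) {
  const int n = sample_pop_model.size();
  ParsedModel pm = parse_model(model);
  std::vector<int> sp0(n), st0(n);
  for (int i = 0; i < n; ++i) {
    sp0[i] = sample_pop_model[i] - 1;
    st0[i] = sample_pop_stat[i] - 1;
  }
  const int n_stats = stats.nrow();
  NumericMatrix sums(n_loci, n_stats), counts(n_loci, n_stats);
  NumericVector pop_pi(n_spop), pop_S(n_spop);

  // per-stat usability is constant: every involved population needs >= 2
  // called haplotypes
  std::vector<bool> stat_ok(n_stats, true);
  for (int s = 0; s < n_stats; ++s) {
    int kind = stats(s, 0);
    int nargs = (kind == 2) ? 2 : (kind == 3 ? 3 : 4);
    for (int a = 0; a < nargs; ++a)
      if (hap_n[stats(s, 1 + a) - 1] < 2) stat_ok[s] = false;
  }

  std::vector<int> parent;
  std::vector<double> ntime;
  std::vector<double> p(n_spop), hn(n_spop);
  const int Lbp = static_cast<int>(length_bp);

  for (int loc = 0; loc < n_loci; ++loc) {
    Rng rng(mix_seed(seed, loc + 1));
    sim_tree(pm, sp0, rng, parent, ntime);
    const int n_nodes = 2 * n - 1;

    Rng mrng(mix_seed(seed, loc + 1) ^ 0x5bf03635ULL);
    std::vector<double> cum_len(n_nodes, 0.0);
    double total = 0.0;
    for (int v = 0; v < n_nodes; ++v) {
      if (parent[v] >= 0) total += ntime[parent[v]] - ntime[v];
      cum_len[v] = total;
    }
    int n_mut = (total > 0.0) ? mrng.rpois(mu * length_bp * total) : 0;
    if (n_mut > Lbp) n_mut = Lbp;
    std::set<int> pos_set;
    while (static_cast<int>(pos_set.size()) < n_mut)
      pos_set.insert(mrng.runif_int(Lbp) + 1);

    std::vector<int> popcnt(static_cast<size_t>(n_nodes) * n_spop, 0);
    for (int v = 0; v < n; ++v) popcnt[v * n_spop + st0[v]] = 1;
    for (int v = 0; v < n_nodes; ++v) {
      if (parent[v] >= 0) {
        int pp = parent[v];
        for (int k = 0; k < n_spop; ++k)
          popcnt[pp * n_spop + k] += popcnt[v * n_spop + k];
      }
    }

    for (int m = 0; m < n_mut; ++m) {
      double u = mrng.runif() * total;
      int v = static_cast<int>(std::lower_bound(cum_len.begin(), cum_len.end(), u) -
                               cum_len.begin());
      while (v >= n_nodes || parent[v] < 0) --v;
      const int* der = &popcnt[v * n_spop];
      for (int k = 0; k < n_spop; ++k) {
        int nk = hap_n[k];
        if (nk >= 2) {
          double pk = static_cast<double>(der[k]) / nk;
          p[k] = pk;
          hn[k] = pk * (1.0 - pk) / (nk - 1);
          if (der[k] > 0 && der[k] < nk) {
            pop_S[k] += 1.0;
            pop_pi[k] += 2.0 * pk * (1.0 - pk) * nk / (nk - 1.0);
          }
        } else {
          p[k] = 0.0;
          hn[k] = 0.0;
        }
      }
      for (int s = 0; s < n_stats; ++s) {
        if (!stat_ok[s]) continue;
        int i1 = stats(s, 1) - 1, i2 = stats(s, 2) - 1;
        double v2;
        if (stats(s, 0) == 2) {
          double d = p[i1] - p[i2];
          v2 = d * d - hn[i1] - hn[i2];
        } else if (stats(s, 0) == 3) {
          int i3 = stats(s, 3) - 1;
          v2 = (p[i1] - p[i2]) * (p[i1] - p[i3]) - hn[i1];
        } else {
          int i3 = stats(s, 3) - 1, i4 = stats(s, 4) - 1;
          v2 = (p[i1] - p[i2]) * (p[i3] - p[i4]);
        }
        sums(loc, s) += v2;
        counts(loc, s) += 1.0;
      }
    }
  }
  return List::create(_["sums"] = sums, _["counts"] = counts,
                      _["pop_pi"] = pop_pi, _["pop_S"] = pop_S);
}

// TMRCA for explicit leaf pairs (1-based ids in `pairs`, 2 columns).
// [[Rcpp::export]]
NumericVector cpp_pair_mrca(IntegerVector parent, NumericVector node_time,
                            IntegerMatrix pairs) {
  const int n_nodes = parent.size();
  const int m = pairs.nrow();
  NumericVector out(m);
  std::vector<int> mark(n_nodes, -1);
  for (int i = 0; i < m; ++i) {
    int a = pairs(i, 0) - 1, b = pairs(i, 1) - 1;
    int v = a;
    while (v >= 0) { mark[v] = i; v = parent[v] - 1; }
    v = b;
    while (v >= 0 && mark[v] != i) v = parent[v] - 1;
    if (v < 0) stop("leaf pair has no common ancestor");
    out[i] = node_time[v];
  }
  return out;
}
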