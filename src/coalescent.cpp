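#include <Rcpp.h>
#include <set>
#include <algorithm>
using namespace Rcpp;

// Hudson-style structured coalescent, one independent genealogy per block.
// Populations are demes with constant (diploid-scale) size Ne; a pair of
// lineages in a deme coalesces at rate 1/(2 Ne) per generation. Demes can be
// merged at scheduled times (lineage movement + optional new size for the
// destination deme), and tips can enter the simulation at positive times
// (used for the neo-W stem lineage, which carries the whole neo-W clade).
// Mutations are dropped on branches as Poisson(mu * block_length * len) and
// assigned unique positions within the block (infinite-sites within a block).

// [[Rcpp::export]]
List cpp_sim_blocks(int n_blocks, int block_length, double mu,
                    IntegerVector tip_pop, NumericVector tip_time,
                    NumericVector ne,
                    NumericVector ev_time, IntegerVector ev_from,
                    IntegerVector ev_to, NumericVector ev_ne) {
  const int n_tips = tip_pop.size();
  const int n_pop = ne.size();
  const int n_ev = ev_time.size();
  if (n_tips > 64) stop("at most 64 tips per block simulation");
  for (int e = 1; e < n_ev; ++e)
    if (ev_time[e] < ev_time[e - 1]) stop("events must be sorted by time");

  // activation order of delayed tips
  std::vector<int> ord(n_tips);
  for (int i = 0; i < n_tips; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return tip_time[a] < tip_time[b]; });

  std::vector<int> mut_block, mut_pos;
  std::vector<uint64_t> mut_mask;

  for (int b = 0; b < n_blocks; ++b) {
    std::vector<uint64_t> mask;
    std::vector<double> birth;
    std::vector<int> pop;
    std::vector<double> neCur(ne.begin(), ne.end());
    mask.reserve(n_tips); birth.reserve(n_tips); pop.reserve(n_tips);

    double t = 0.0;
    int ai = 0;  // next activation index in ord
    int ei = 0;  // next merge event index
    // activate tips with time <= 0 now
    while (ai < n_tips && tip_time[ord[ai]] <= 0.0) {
      int i = ord[ai++];
      mask.push_back(1ULL << i);
      birth.push_back(0.0);
      pop.push_back(tip_pop[i]);
    }

    std::set<int> used;
    auto emit = [&](uint64_t m, double len) {
      if (len <= 0) return;
      int nm = (int)R::rpois(mu * (double)block_length * len);
      for (int k = 0; k < nm; ++k) {
        int posn = -1;
        for (int tries = 0; tries < 200; ++tries) {
          int p = (int)(unif_rand() * block_length);
          if (p >= block_length) p = block_length - 1;
          if (used.insert(p).second) { posn = p; break; }
        }
        if (posn < 0) continue;  // block saturated; drop excess mutation
        mut_block.push_back(b);
        mut_pos.push_back(posn);
        mut_mask.push_back(m);
      }
    };

    while (true) {
      if ((int)mask.size() <= 1 && ai >= n_tips) break;
      // coalescence rates per deme
      std::vector<int> cnt(n_pop, 0);
      for (size_t j = 0; j < pop.size(); ++j) cnt[pop[j]]++;
      double rate = 0.0;
      std::vector<double> prate(n_pop, 0.0);
      for (int p = 0; p < n_pop; ++p) {
        if (cnt[p] > 1) {
          prate[p] = cnt[p] * (cnt[p] - 1.0) / (4.0 * neCur[p]);
          rate += prate[p];
        }
      }
      double t_act = (ai < n_tips) ? tip_time[ord[ai]] : R_PosInf;
      double t_ev = (ei < n_ev) ? ev_time[ei] : R_PosInf;
      double sched = std::min(t_act, t_ev);
      double tc = (rate > 0) ? t + exp_rand() / rate : R_PosInf;

      if (tc < sched) {
        // coalescence: pick deme, then uniform pair within it
        double u = unif_rand() * rate, acc = 0.0;
        int psel = -1;
        for (int p = 0; p < n_pop; ++p) {
          acc += prate[p];
          if (u <= acc) { psel = p; break; }
        }
        if (psel < 0) psel = n_pop - 1;
        std::vector<int> idx;
        for (size_t j = 0; j < pop.size(); ++j)
          if (pop[j] == psel) idx.push_back((int)j);
        int a = (int)(unif_rand() * idx.size());
        int c = (int)(unif_rand() * (idx.size() - 1));
        if (c >= a) c++;
        int ia = idx[a], ic = idx[c];
        t = tc;
        emit(mask[ia], t - birth[ia]);
        emit(mask[ic], t - birth[ic]);
        mask[ia] |= mask[ic];
        birth[ia] = t;
        mask.erase(mask.begin() + ic);
        birth.erase(birth.begin() + ic);
        pop.erase(pop.begin() + ic);
      } else if (!R_finite(sched)) {
        stop("lineages can never coalesce: demes are never merged");
      } else {
        t = sched;
        while (ai < n_tips && tip_time[ord[ai]] <= t) {
          int i = ord[ai++];
          mask.push_back(1ULL << i);
          birth.push_back(tip_time[i]);
          pop.push_back(tip_pop[i]);
        }
        while (ei < n_ev && ev_time[ei] <= t) {
          int from = ev_from[ei], to = ev_to[ei];
          for (size_t j = 0; j < pop.size(); ++j)
            if (pop[j] == from) pop[j] = to;
          if (R_finite(ev_ne[ei]) && ev_ne[ei] > 0) neCur[to] = ev_ne[ei];
          ei++;
        }
      }
    }
  }

  const int n_mut = (int)mut_block.size();
  IntegerMatrix carriers(n_mut, n_tips);
  IntegerVector blk(n_mut), pos(n_mut);
  for (int k = 0; k < n_mut; ++k) {
    blk[k] = mut_block[k];
    pos[k] = mut_pos[k];
    for (int i = 0; i < n_tips; ++i)
      carriers(k, i) = (mut_mask[k] >> i) & 1ULL;
  }
  return List::create(_["block"] = blk, _["pos"] = pos,
                      _["carriers"] = carriers);
}

// Single-deme coalescent tree with an optional hard cap on depth: lineages
// still uncoalesced at the cap are joined in one polytomy (used for the
// neo-W clade, whose TMRCA is bounded by the last recombination-rescue
// sweep). Returns parent pointers and node times; tips are nodes 1..n.

// [[Rcpp::export]]
List cpp_sim_tree(int n_tips, double ne, double cap) {
  std::vector<int> parent(n_tips, -1);
  std::vector<double> time(n_tips, 0.0);
  std::vector<int> active(n_tips);
  for (int i = 0; i < n_tips; ++i) active[i] = i;
  double t = 0.0;
  while ((int)active.size() > 1) {
    double k = (double)active.size();
    double rate = k * (k - 1.0) / (4.0 * ne);
    double dt = exp_rand() / rate;
    if (R_finite(cap) && t + dt >= cap) {
      // polytomy at the cap
      t = cap;
      int node = (int)parent.size();
      parent.push_back(-1);
      time.push_back(t);
      for (size_t j = 0; j < active.size(); ++j) parent[active[j]] = node;
      active.clear();
      active.push_back(node);
      break;
    }
    t += dt;
    int a = (int)(unif_rand() * k);
    int c = (int)(unif_rand() * (k - 1.0));
    if (c >= a) c++;
    int node = (int)parent.size();
    parent.push_back(-1);
    time.push_back(t);
    parent[active[a]] = node;
    parent[active[c]] = node;
    if (a > c) std::swap(a, c);
    active.erase(active.begin() + c);
    active[a] = node;
  }
  return List::create(_["parent"] = IntegerVector(parent.begin(), parent.end()),
                      _["time"] = NumericVector(time.begin(), time.end()),
                      _["n_tips"] = n_tips);
}
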