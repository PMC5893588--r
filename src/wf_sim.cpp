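// Forward-time Wright-Fisher simulator with recombination, infinite-sites
// mutation, population splits, an optional admixture event and an optional
// additive selective sweep conditioned on non-loss.
//
// Haplotypes are shared, immutable vectors of mutation ids kept sorted by
// physical position: a gamete with no crossover and no new mutation is a
// pointer copy of a parental haplotype, so per-generation cost is dominated
// by the minority of recombinant/mutated gametes.  Every modification is
// copy-on-write, which also makes the saved state for sweep restarts a
// cheap pointer snapshot.  All randomness comes from R's RNG so that
// set.seed() on the R side makes whole runs byte-reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <memory>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

namespace {

typedef std::vector<int> Vec;
typedef std::shared_ptr<const Vec> Hap;  // sorted by bp position

struct Registry {
  std::vector<int> pos;             // 1-based bp position per mutation id
  std::vector<int> gen;             // generation in which the mutation arose
  std::vector<char> retired;        // lost-or-fixed ids, skipped by pruning
  std::unordered_set<int> active;   // bp positions currently occupied
};

inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? (n - 1) : k;
}

int new_mutation(Registry &reg, int L, int gen) {
  int p;
  do {
    p = 1 + runif_int(L);
  } while (reg.active.count(p));
  int id = (int)reg.pos.size();
  reg.pos.push_back(p);
  reg.gen.push_back(gen);
  reg.retired.push_back(0);
  reg.active.insert(p);
  return id;
}

inline void insert_sorted(Registry &reg, Vec &v, int id) {
  int p = reg.pos[id];
  Vec::iterator it = std::lower_bound(
      v.begin(), v.end(), p,
      [&reg](int id2, int pp) { return reg.pos[id2] < pp; });
  v.insert(it, id);
}

// child gamete: recombine the two parental haplotypes, then mutate;
// unmodified gametes share the parental haplotype
Hap make_gamete(Registry &reg, const Hap &h1, const Hap &h2, int L,
                double rec_total, double mu_total, int gen) {
  int k = (int)R::rpois(rec_total);
  int m = (int)R::rpois(mu_total);
  bool use1 = unif_rand() < 0.5;
  if (k == 0 && m == 0) return use1 ? h1 : h2;
  Vec out;
  if (k == 0) {
    out = *(use1 ? h1 : h2);
  } else {
    std::vector<double> brk(k);
    for (int i = 0; i < k; ++i) brk[i] = unif_rand() * L;
    std::sort(brk.begin(), brk.end());
    out.reserve(h1->size() + m);
    size_t i1 = 0, i2 = 0;
    for (int b = 0; b <= k; ++b) {
      double lim = (b < k) ? brk[b] : (double)L + 1.0;
      while (i1 < h1->size() && reg.pos[(*h1)[i1]] <= lim) {
        if (use1) out.push_back((*h1)[i1]);
        ++i1;
      }
      while (i2 < h2->size() && reg.pos[(*h2)[i2]] <= lim) {
        if (!use1) out.push_back((*h2)[i2]);
        ++i2;
      }
      use1 = !use1;
    }
  }
  for (int j = 0; j < m; ++j) insert_sorted(reg, out, new_mutation(reg, L, gen));
  return std::make_shared<const Vec>(std::move(out));
}

inline bool carries(const Registry &reg, const Hap &h, int id) {
  int p = reg.pos[id];
  Vec::const_iterator it = std::lower_bound(
      h->begin(), h->end(), p,
      [&reg](int id2, int pp) { return reg.pos[id2] < pp; });
  return it != h->end() && *it == id;
}

// one WF generation for a single population; additive fitness 1, 1+s/2, 1+s
// at the sweep locus when sel is true
void next_generation(Registry &reg, std::vector<Hap> &cur,
                     std::vector<Hap> &nxt, int L, double rec_total,
                     double mu_total, int gen, bool sel, int sweep_id,
                     double s) {
  int twoN = (int)cur.size(), N = twoN / 2;
  std::vector<double> cum;
  if (sel) {
    cum.resize(N);
    double acc = 0.0;
    for (int i = 0; i < N; ++i) {
      int g = (carries(reg, cur[2 * i], sweep_id) ? 1 : 0) +
              (carries(reg, cur[2 * i + 1], sweep_id) ? 1 : 0);
      acc += (g == 0) ? 1.0 : ((g == 1) ? 1.0 + s / 2.0 : 1.0 + s);
      cum[i] = acc;
    }
  }
  nxt.resize(twoN);
  for (int i = 0; i < N; ++i) {
    int mom, dad;
    if (sel) {
      double tot = cum[N - 1];
      mom = (int)(std::lower_bound(cum.begin(), cum.end(), unif_rand() * tot) -
                  cum.begin());
      dad = (int)(std::lower_bound(cum.begin(), cum.end(), unif_rand() * tot) -
                  cum.begin());
      if (mom >= N) mom = N - 1;
      if (dad >= N) dad = N - 1;
    } else {
      mom = runif_int(N);
      dad = runif_int(N);
    }
    nxt[2 * i] = make_gamete(reg, cur[2 * mom], cur[2 * mom + 1], L,
                             rec_total, mu_total, gen);
    nxt[2 * i + 1] = make_gamete(reg, cur[2 * dad], cur[2 * dad + 1], L,
                                 rec_total, mu_total, gen);
  }
  cur.swap(nxt);
}

// drop mutations lost everywhere, strip mutations fixed in every population
// (copy-on-write, so snapshots of earlier states stay valid)
void prune(Registry &reg, std::vector<std::vector<Hap> > &pops, int keep_id) {
  size_t nm = reg.pos.size();
  std::vector<int> cnt(nm, 0);
  long nh = 0;
  for (size_t p = 0; p < pops.size(); ++p) {
    nh += (long)pops[p].size();
    for (size_t h = 0; h < pops[p].size(); ++h)
      for (size_t j = 0; j < pops[p][h]->size(); ++j)
        cnt[(*pops[p][h])[j]]++;
  }
  std::vector<char> drop(nm, 0);
  bool any_fixed = false;
  for (size_t id = 0; id < nm; ++id) {
    if (reg.retired[id] || (int)id == keep_id) continue;
    if (cnt[id] == 0) {
      reg.active.erase(reg.pos[id]);
      reg.retired[id] = 1;
    } else if (cnt[id] == nh) {
      drop[id] = 1;
      any_fixed = true;
      reg.active.erase(reg.pos[id]);
      reg.retired[id] = 1;
    }
  }
  if (!any_fixed) return;
  std::unordered_map<const Vec *, Hap> repl;
  for (size_t p = 0; p < pops.size(); ++p)
    for (size_t h = 0; h < pops[p].size(); ++h) {
      const Vec *key = pops[p][h].get();
      std::unordered_map<const Vec *, Hap>::iterator it = repl.find(key);
      if (it != repl.end()) {
        pops[p][h] = it->second;
        continue;
      }
      bool any = false;
      for (size_t j = 0; j < key->size(); ++j)
        if (drop[(*key)[j]]) { any = true; break; }
      if (any) {
        Vec nv;
        nv.reserve(key->size());
        for (size_t j = 0; j < key->size(); ++j)
          if (!drop[(*key)[j]]) nv.push_back((*key)[j]);
        Hap np = std::make_shared<const Vec>(std::move(nv));
        repl[key] = np;
        pops[p][h] = np;
      } else {
        repl[key] = pops[p][h];
      }
    }
}

}  // namespace

// [[Rcpp::export]]
List wf_sim_cpp(int Ne, int n_pops, int burn_gens, int split_gens,
                IntegerVector sample_sizes, double seq_len, double mu,
                double rec, bool has_sweep, int sweep_pop, int sweep_pos,
                double sweep_s, int sweep_origin, bool has_admix,
                int admix_gens_ago, IntegerVector admix_sources,
                NumericVector admix_props, int max_restarts) {
  int L = (int)seq_len;
  double mu_total = mu * L, rec_total = rec * L;
  Registry reg;
  Hap empty = std::make_shared<const Vec>();
  std::vector<std::vector<Hap> > pops(1);
  pops[0].assign(2 * Ne, empty);
  std::vector<Hap> scratch;

  const int prune_every = 64;
  int gen = 0;

  // burn-in: one ancestral population
  for (; gen < burn_gens; ++gen) {
    next_generation(reg, pops[0], scratch, L, rec_total, mu_total, gen, false,
                    -1, 0.0);
    if (gen % prune_every == prune_every - 1) prune(reg, pops, -1);
  }

  // instantaneous split into n_pops isolated copies
  for (int p = 1; p < n_pops; ++p) pops.push_back(pops[0]);

  int total_pops = n_pops + (has_admix ? 1 : 0);
  int sweep_id = -1;
  int sweep_pos_actual = sweep_pos;
  int n_restarts = 0;
  bool sweep_fixed = false;
  std::vector<std::vector<Hap> > saved_pops;
  size_t saved_n_mut = 0;
  std::unordered_set<int> saved_active;
  std::vector<char> saved_retired;

  int t_admix = has_admix ? (split_gens - admix_gens_ago) : -1;

  for (int t = 0; t < split_gens; ++t) {
    // admixture event: new population founded by gametes from the sources
    if (has_admix && t == t_admix && (int)pops.size() < total_pops) {
      std::vector<Hap> adm(2 * Ne);
      for (int h = 0; h < 2 * Ne; ++h) {
        int src = (unif_rand() < admix_props[0]) ? admix_sources[0]
                                                 : admix_sources[1];
        int par = runif_int(Ne);
        adm[h] = make_gamete(reg, pops[src][2 * par], pops[src][2 * par + 1],
                             L, rec_total, mu_total, gen);
      }
      pops.push_back(adm);
    }
    // sweep injection (snapshot allows restart-on-loss conditioning; all
    // later modifications are copy-on-write, so the snapshot stays intact)
    if (has_sweep && t == sweep_origin && sweep_id < 0) {
      if (n_restarts == 0) {
        saved_pops = pops;
        saved_n_mut = reg.pos.size();
        saved_active = reg.active;
        saved_retired = reg.retired;
      }
      while (reg.active.count(sweep_pos_actual)) ++sweep_pos_actual;
      sweep_id = (int)reg.pos.size();
      reg.pos.push_back(sweep_pos_actual);
      reg.gen.push_back(gen);
      reg.retired.push_back(0);
      reg.active.insert(sweep_pos_actual);
      int h = runif_int(2 * Ne);
      Vec nv = *pops[sweep_pop][h];
      insert_sorted(reg, nv, sweep_id);
      pops[sweep_pop][h] = std::make_shared<const Vec>(std::move(nv));
    }

    for (size_t p = 0; p < pops.size(); ++p) {
      bool sel = has_sweep && sweep_id >= 0 && !sweep_fixed &&
                 (int)p == sweep_pop && sweep_s != 0.0;
      next_generation(reg, pops[p], scratch, L, rec_total, mu_total, gen, sel,
                      sweep_id, sweep_s);
    }

    // condition on non-loss of the beneficial allele
    if (has_sweep && sweep_id >= 0 && !sweep_fixed) {
      int carriers = 0;
      for (int h = 0; h < 2 * Ne; ++h)
        if (carries(reg, pops[sweep_pop][h], sweep_id)) ++carriers;
      if (carriers == 0) {
        if (++n_restarts > max_restarts)
          stop("sweep allele lost in more than %d attempts; "
               "increase the selection coefficient s",
               max_restarts);
        pops = saved_pops;
        reg.pos.resize(saved_n_mut);
        reg.gen.resize(saved_n_mut);
        reg.retired = saved_retired;
        reg.active = saved_active;
        sweep_id = -1;
        gen = burn_gens + sweep_origin;
        t = sweep_origin - 1;  // loop ++ returns to the injection step
        continue;
      }
      if (carriers == 2 * Ne) sweep_fixed = true;
    }
    ++gen;
    if (gen % prune_every == prune_every - 1)
      prune(reg, pops, has_sweep ? sweep_id : -1);
  }

  // ---- output: sampled haplotypes, polymorphic in the pooled sample ----
  int total_sampled = 0;
  for (int p = 0; p < total_pops; ++p) total_sampled += 2 * sample_sizes[p];

  size_t nm = reg.pos.size();
  std::vector<int> scnt(nm, 0);
  for (int p = 0; p < total_pops; ++p)
    for (int h = 0; h < 2 * sample_sizes[p]; ++h)
      for (size_t j = 0; j < pops[p][h]->size(); ++j)
        scnt[(*pops[p][h])[j]]++;

  std::vector<int> site_ids;
  for (size_t id = 0; id < nm; ++id)
    if (scnt[id] > 0 && scnt[id] < total_sampled) site_ids.push_back((int)id);
  std::sort(site_ids.begin(), site_ids.end(),
            [&reg](int a, int b) { return reg.pos[a] < reg.pos[b]; });
  int ns = (int)site_ids.size();

  std::unordered_map<int, int> row_of;
  row_of.reserve(ns * 2);
  for (int r = 0; r < ns; ++r) row_of[site_ids[r]] = r;

  IntegerMatrix alleles(ns, total_sampled);
  int col = 0;
  for (int p = 0; p < total_pops; ++p)
    for (int h = 0; h < 2 * sample_sizes[p]; ++h, ++col)
      for (size_t j = 0; j < pops[p][h]->size(); ++j) {
        std::unordered_map<int, int>::iterator it =
            row_of.find((*pops[p][h])[j]);
        if (it != row_of.end()) alleles(it->second, col) = 1;
      }

  // population-level (all 2*Ne haplotypes) derived counts per output site
  IntegerMatrix pop_counts(ns, total_pops);
  for (int p = 0; p < total_pops; ++p)
    for (size_t h = 0; h < pops[p].size(); ++h)
      for (size_t j = 0; j < pops[p][h]->size(); ++j) {
        std::unordered_map<int, int>::iterator it =
            row_of.find((*pops[p][h])[j]);
        if (it != row_of.end()) pop_counts(it->second, p)++;
      }

  IntegerVector out_pos(ns), out_gen(ns);
  for (int r = 0; r < ns; ++r) {
    out_pos[r] = reg.pos[site_ids[r]];
    out_gen[r] = reg.gen[site_ids[r]];
  }

  NumericVector sweep_freq(total_pops, NA_REAL);
  if (has_sweep && sweep_id >= 0) {
    for (int p = 0; p < total_pops; ++p) {
      int c = 0;
      for (size_t h = 0; h < pops[p].size(); ++h)
        if (carries(reg, pops[p][h], sweep_id)) ++c;
      sweep_freq[p] = (double)c / (double)pops[p].size();
    }
  }

  return List::create(
      _["pos"] = out_pos, _["alleles"] = alleles, _["pop_counts"] = pop_counts,
      _["origin_gen"] = out_gen, _["sweep_pos"] = sweep_pos_actual,
      _["sweep_freq"] = sweep_freq, _["n_restarts"] = n_restarts,
      _["split_gen"] = burn_gens);
}
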