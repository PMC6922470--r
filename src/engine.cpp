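#include <Rcpp.h>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// One occupied transcript molecule. Unbound molecules are only counted.
struct Mol {
  int gene;
  std::vector<int> occ_sites;   // occupied site positions (any family)
  std::vector<int> occ_fams;    // bound miRNA families, parallel multiset
  int deadline;                 // iteration at which removal is due
  int pos_in_gene;              // index into the gene's occupied list
  bool alive;
};

static inline int draw_index(double total) {
  // uniform integer in [0, total); guards the unif_rand()==1 edge
  int k = (int)(unif_rand() * total);
  if (k >= (int)total) k = (int)total - 1;
  return k;
}

// Core iterative loop. All indices 0-based; all randomness from R's RNG.
// records: one row per (gene, family); sites sorted ascending.
// [[Rcpp::export(name = ".comics_run_cpp")]]
List comics_run_cpp(IntegerVector gene_init,
                    IntegerVector family_free,
                    IntegerVector rec_gene,
                    IntegerVector rec_family,
                    NumericVector rec_prob,
                    List rec_sites,
                    int n_iterations,
                    int removal_delay,
                    int checkpoint_interval,
                    int min_spacing,
                    bool clock_last) {
  const int G = gene_init.size();
  const int F = family_free.size();
  const int R = rec_gene.size();

  std::vector<int> unbound(gene_init.begin(), gene_init.end());
  std::vector<int> free_cnt(family_free.begin(), family_free.end());
  long long free_total = 0;
  for (int f = 0; f < F; ++f) free_total += free_cnt[f];
  const long long mirna_pool = free_total;
  long long bound_total = 0;

  std::vector<std::vector<int>> fam_recs(F);       // family -> record rows
  for (int r = 0; r < R; ++r) fam_recs[rec_family[r]].push_back(r);
  std::vector<std::vector<int>> sites(R);
  for (int r = 0; r < R; ++r) {
    IntegerVector s = rec_sites[r];
    sites[r].assign(s.begin(), s.end());
  }

  std::vector<Mol> arena;
  arena.reserve(1024);
  std::vector<std::vector<int>> occ(G);            // gene -> arena ids
  std::vector<int> live(G);
  for (int g = 0; g < G; ++g) live[g] = unbound[g];

  // removal schedule: bucket per iteration, lazy validity check on pop
  std::vector<std::vector<int>> bucket(n_iterations + 2);

  std::unordered_map<long long, int> engaged;      // (g,f) -> first iteration
  const int n_check = n_iterations / checkpoint_interval;
  NumericMatrix retention(G, n_check);
  IntegerVector check_iter(n_check);
  NumericVector conservation(n_check);
  long long n_success = 0, n_failed = 0;

  int ck = 0;
  for (int t = 1; t <= n_iterations; ++t) {
    // 1. due removals: recycle bound miRNAs, delete the molecule
    std::vector<int> &due = bucket[t];
    for (size_t q = 0; q < due.size(); ++q) {
      Mol &m = arena[due[q]];
      if (!m.alive || m.deadline != t) continue;   // stale entry
      for (size_t b = 0; b < m.occ_fams.size(); ++b) {
        ++free_cnt[m.occ_fams[b]];
        ++free_total;
      }
      bound_total -= (long long)m.occ_fams.size();
      std::vector<int> &og = occ[m.gene];
      int last = og.back();
      og[m.pos_in_gene] = last;
      arena[last].pos_in_gene = m.pos_in_gene;
      og.pop_back();
      --live[m.gene];
      m.alive = false;
    }
    due.clear();

    bool success = false;
    if (free_total > 0) {
      // 2. draw a miRNA family, weighted by free counts
      double x = unif_rand() * (double)free_total;
      int fam = -1;
      double acc = 0.0;
      for (int f = 0; f < F; ++f) {
        acc += free_cnt[f];
        if (x < acc) { fam = f; break; }
      }
      if (fam < 0) fam = F - 1;

      // 3. draw a target gene among the family's targets, weighted by
      //    live (not yet removed) molecules; occupied molecules eligible
      const std::vector<int> &recs = fam_recs[fam];
      long long W = 0;
      for (size_t k = 0; k < recs.size(); ++k) W += live[rec_gene[recs[k]]];
      if (W > 0) {
        double y = unif_rand() * (double)W;
        int rec = -1;
        double acc2 = 0.0;
        for (size_t k = 0; k < recs.size(); ++k) {
          acc2 += live[rec_gene[recs[k]]];
          if (y < acc2) { rec = recs[k]; break; }
        }
        if (rec < 0) rec = recs.back();
        int g = rec_gene[rec];

        // 4. molecule uniform among the gene's live molecules
        int mi = draw_index((double)live[g]);
        int mol_id = (mi < unbound[g]) ? -1 : occ[g][mi - unbound[g]];

        // 5. probabilistic binding, then site eligibility
        if (unif_rand() < rec_prob[rec]) {
          const std::vector<int> &cand = sites[rec];
          int chosen = -1;
          if (mol_id < 0) {
            chosen = cand[draw_index((double)cand.size())];
          } else {
            Mol &m = arena[mol_id];
            std::vector<int> elig;
            for (size_t s = 0; s < cand.size(); ++s) {
              bool ok = true;
              for (size_t o = 0; o < m.occ_sites.size(); ++o) {
                int d = cand[s] - m.occ_sites[o];
                if (d < 0) d = -d;
                if (d < min_spacing) { ok = false; break; }
              }
              if (ok) elig.push_back(cand[s]);
            }
            if (!elig.empty()) chosen = elig[draw_index((double)elig.size())];
          }
          if (chosen >= 0) {
            success = true;
            --free_cnt[fam];
            --free_total;
            ++bound_total;
            int deadline = t + removal_delay;
            if (mol_id < 0) {
              Mol m;
              m.gene = g;
              m.occ_sites.push_back(chosen);
              m.occ_fams.push_back(fam);
              m.deadline = deadline;
              m.pos_in_gene = (int)occ[g].size();
              m.alive = true;
              arena.push_back(m);
              mol_id = (int)arena.size() - 1;
              occ[g].push_back(mol_id);
              --unbound[g];
              if (deadline < (int)bucket.size()) bucket[deadline].push_back(mol_id);
            } else {
              Mol &m = arena[mol_id];
              m.occ_sites.push_back(chosen);
              m.occ_fams.push_back(fam);
              if (clock_last) {   // re-binding restarts the removal clock
                m.deadline = deadline;
                if (deadline < (int)bucket.size()) bucket[deadline].push_back(mol_id);
              }
            }
            long long key = (long long)g * (long long)F + fam;
            if (engaged.find(key) == engaged.end()) engaged[key] = t;
          }
        }
      }
    }
    if (!success) ++n_failed; else ++n_success;

    if (t % checkpoint_interval == 0) {
      for (int g = 0; g < G; ++g) {
        retention(g, ck) = 100.0 * (double)live[g] / (double)gene_init[g];
      }
      check_iter[ck] = t;
      conservation[ck] = (double)(free_total + bound_total);
      ++ck;
    }
  }

  IntegerVector eng_gene(engaged.size()), eng_fam(engaged.size()),
      eng_iter(engaged.size());
  int i = 0;
  for (std::unordered_map<long long, int>::iterator it = engaged.begin();
       it != engaged.end(); ++it, ++i) {
    eng_gene[i] = (int)(it->first / F);
    eng_fam[i] = (int)(it->first % F);
    eng_iter[i] = it->second;
  }

  IntegerVector live_out(G), unbound_out(G);
  for (int g = 0; g < G; ++g) { live_out[g] = live[g]; unbound_out[g] = unbound[g]; }
  IntegerVector free_out(F);
  for (int f = 0; f < F; ++f) free_out[f] = free_cnt[f];

  return List::create(
      _["retention"] = retention,
      _["checkpoints"] = check_iter,
      _["conservation"] = conservation,
      _["mirna_pool"] = (double)mirna_pool,
      _["live"] = live_out,
      _["unbound"] = unbound_out,
      _["free_mirna"] = free_out,
      _["engaged_gene"] = eng_gene,
      _["engaged_family"] = eng_fam,
      _["engaged_iteration"] = eng_iter,
      _["n_success"] = (double)n_success,
      _["n_failed"] = (double)n_failed);
}
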