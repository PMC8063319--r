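// Forward Wright-Fisher simulation of one chromosome under strict neutrality,
// with crossover recombination and infinite-sites mutation, plus a small
// resampling kernel for the Lindley local-score threshold.
//
// Haplotypes are sorted vectors of mutation positions (1-based bp).  Under
// the infinite-sites convention a position identifies a mutation uniquely, so
// recombination is a positional merge of the two parental vectors.  Because
// demes are fully isolated and there is no back-mutation, a mutation fixed
// within a deme can never segregate there again: such sites are periodically
// moved out of the haplotypes into a per-deme fixed background, keeping the
// merge vectors down to within-deme segregating sites.  Site bookkeeping
// (occupancy, fixation counts) uses flat position-indexed arrays rather than
// hashing.  All randomness comes from R's RNG: callers control determinism
// with set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

typedef std::vector<int> Hap;
typedef std::vector<Hap> Pop;

struct Deme {
  Pop pop;       // 2N haplotypes of within-deme segregating mutations
  Hap fixed_bg;  // mutations carried by every haplotype of this deme
};

static inline int runif_int(int n) {
  // uniform integer in 0..n-1
  int k;
  do {
    k = static_cast<int>(unif_rand() * n);
  } while (k >= n);
  return k;
}

// Produce one gamete from the two haplotypes of a parent individual.
// rec_len = expected crossovers per meiosis (r * L); chrom_len in bp.
static void make_gamete(const Hap &A, const Hap &B, double rec_len,
                        double chrom_len, double mut_len,
                        std::vector<unsigned char> &occupied, Hap &out) {
  int k = static_cast<int>(R::rpois(rec_len));
  bool use_a = unif_rand() < 0.5;
  if (k == 0) {
    out = use_a ? A : B;
  } else {
    std::vector<double> bp(k);
    for (int i = 0; i < k; ++i) bp[i] = unif_rand() * chrom_len;
    std::sort(bp.begin(), bp.end());
    out.clear();
    out.reserve(std::max(A.size(), B.size()) + 8);
    const auto lt = [](int pos, double cut) { return pos < cut; };
    Hap::const_iterator pa = A.begin(), pb = B.begin();
    for (int s = 0; s <= k; ++s) {
      double seg_end = (s < k) ? bp[s] : chrom_len + 2.0;
      Hap::const_iterator ea = std::lower_bound(pa, A.end(), seg_end, lt);
      Hap::const_iterator eb = std::lower_bound(pb, B.end(), seg_end, lt);
      out.insert(out.end(), use_a ? pa : pb, use_a ? ea : eb);
      pa = ea;
      pb = eb;
      use_a = !use_a;
    }
  }
  // new mutations: Poisson(mu * L), uniform positions, redraw on collision
  int m = static_cast<int>(R::rpois(mut_len));
  if (m > 0) {
    size_t tail = out.size();
    for (int i = 0; i < m; ++i) {
      int pos;
      do {
        pos = runif_int(static_cast<int>(chrom_len)) + 1;
      } while (occupied[pos]);
      occupied[pos] = 1;
      out.push_back(pos);
    }
    std::sort(out.begin() + tail, out.end());
    std::inplace_merge(out.begin(), out.begin() + tail, out.end());
  }
}

// One Wright-Fisher generation within a deme: n_ind offspring, each from two
// (possibly identical) uniformly chosen parents in `parents`.
static void wf_generation(const Pop &parents, int n_ind, double rec_len,
                          double chrom_len, double mut_len,
                          std::vector<unsigned char> &occupied,
                          Pop &children) {
  int n_par = static_cast<int>(parents.size()) / 2;
  children.resize(2 * static_cast<size_t>(n_ind));
  for (int i = 0; i < n_ind; ++i) {
    int p1 = runif_int(n_par), p2 = runif_int(n_par);
    make_gamete(parents[2 * p1], parents[2 * p1 + 1], rec_len, chrom_len,
                mut_len, occupied, children[2 * i]);
    make_gamete(parents[2 * p2], parents[2 * p2 + 1], rec_len, chrom_len,
                mut_len, occupied, children[2 * i + 1]);
  }
}

// Move within-deme fixed mutations out of the haplotypes into the deme's
// fixed background (keep_bg = false discards them instead: during burn-in a
// fixed mutation is fixed in the whole metapopulation and can be dropped).
// `cnt` and `is_fixed` are reusable position-indexed scratch arrays that
// must be all-zero on entry and are re-zeroed before returning.
static void prune_deme(Deme &deme, bool keep_bg, std::vector<int> &cnt,
                       std::vector<unsigned char> &is_fixed,
                       std::vector<int> &touched) {
  touched.clear();
  for (const Hap &h : deme.pop)
    for (int pos : h)
      if (cnt[pos]++ == 0) touched.push_back(pos);
  const int total = static_cast<int>(deme.pop.size());
  bool any_fixed = false;
  for (int pos : touched)
    if (cnt[pos] == total) {
      is_fixed[pos] = 1;
      any_fixed = true;
      if (keep_bg) deme.fixed_bg.push_back(pos);
    }
  if (any_fixed)
    for (Hap &h : deme.pop)
      h.erase(std::remove_if(h.begin(), h.end(),
                             [&](int p) { return is_fixed[p] != 0; }),
              h.end());
  for (int pos : touched) {
    cnt[pos] = 0;
    is_fixed[pos] = 0;
  }
}

// [[Rcpp::export(name = ".wf_sim_chrom")]]
List wf_sim_chrom(int n_anc, int t_burn, int n_demes, int n_deme, int t_split,
                  double chrom_len, double mu, double rec) {
  const double rec_len = rec * chrom_len;
  const double mut_len = mu * chrom_len;
  const int L = static_cast<int>(chrom_len);
  std::vector<unsigned char> occupied(L + 2, 0);
  std::vector<int> cnt(L + 2, 0);
  std::vector<unsigned char> is_fixed(L + 2, 0);
  std::vector<int> touched;

  // burn-in: a single ancestral deme starting with no variation
  Deme anc;
  anc.pop.assign(2 * static_cast<size_t>(n_anc), Hap());
  Pop scratch;
  for (int g = 0; g < t_burn; ++g) {
    wf_generation(anc.pop, n_anc, rec_len, chrom_len, mut_len, occupied,
                  scratch);
    anc.pop.swap(scratch);
    if ((g + 1) % 8 == 0) prune_deme(anc, false, cnt, is_fixed, touched);
  }
  prune_deme(anc, false, cnt, is_fixed, touched);

  // split into n_demes isolated demes and drift for t_split generations;
  // the first post-split generation is drawn from the ancestral deme
  std::vector<Deme> demes(n_demes);
  if (t_split == 0) {
    for (int d = 0; d < n_demes; ++d) {
      demes[d].pop.resize(2 * static_cast<size_t>(n_deme));
      for (int i = 0; i < 2 * n_deme; ++i)
        demes[d].pop[i] = anc.pop[runif_int(2 * n_anc)];
    }
  } else {
    for (int d = 0; d < n_demes; ++d)
      wf_generation(anc.pop, n_deme, rec_len, chrom_len, mut_len, occupied,
                    demes[d].pop);
    anc.pop.clear();
    for (int g = 1; g < t_split; ++g) {
      for (int d = 0; d < n_demes; ++d) {
        wf_generation(demes[d].pop, n_deme, rec_len, chrom_len, mut_len,
                      occupied, scratch);
        demes[d].pop.swap(scratch);
      }
      if ((g + 1) % 8 == 0)
        for (int d = 0; d < n_demes; ++d)
          prune_deme(demes[d], true, cnt, is_fixed, touched);
    }
  }
  for (int d = 0; d < n_demes; ++d)
    prune_deme(demes[d], true, cnt, is_fixed, touched);

  // tabulate derived-allele counts per deme (haplotypes + fixed background)
  // at sites segregating in the metapopulation, via one flat count array
  // per deme
  const int hap_per_deme = 2 * n_deme;
  const int total_haps = n_demes * hap_per_deme;
  std::vector<std::vector<int>> deme_cnt(
      n_demes, std::vector<int>(static_cast<size_t>(L) + 2, 0));
  touched.clear();
  for (int d = 0; d < n_demes; ++d) {
    for (const Hap &h : demes[d].pop)
      for (int pos : h) {
        if (!is_fixed[pos]) {
          is_fixed[pos] = 1;
          touched.push_back(pos);
        }
        deme_cnt[d][pos] += 1;
      }
    for (int pos : demes[d].fixed_bg) {
      if (!is_fixed[pos]) {
        is_fixed[pos] = 1;
        touched.push_back(pos);
      }
      deme_cnt[d][pos] += hap_per_deme;
    }
  }
  std::vector<int> positions;
  positions.reserve(touched.size());
  for (int pos : touched) {
    is_fixed[pos] = 0;
    int tot = 0;
    for (int d = 0; d < n_demes; ++d) tot += deme_cnt[d][pos];
    if (tot > 0 && tot < total_haps) positions.push_back(pos);
  }
  std::sort(positions.begin(), positions.end());

  int S = static_cast<int>(positions.size());
  IntegerVector pos_out(S);
  IntegerMatrix cnt_out(S, n_demes);
  for (int s = 0; s < S; ++s) {
    pos_out[s] = positions[s];
    for (int d = 0; d < n_demes; ++d)
      cnt_out(s, d) = deme_cnt[d][positions[s]];
  }
  return List::create(_["positions"] = pos_out, _["counts"] = cnt_out,
                      _["n_hap"] = hap_per_deme);
}

// [[Rcpp::export(name = ".lindley_max_boot")]]
NumericVector lindley_max_boot(NumericVector scores, int n, int B) {
  // B resamples (with replacement, each of length n) of per-SNP scores;
  // returns the maximum of the Lindley track of each resample.
  int m = scores.size();
  NumericVector out(B);
  for (int b = 0; b < B; ++b) {
    double h = 0.0, hmax = 0.0;
    for (int i = 0; i < n; ++i) {
      h += scores[runif_int(m)];
      if (h < 0.0) h = 0.0;
      if (h > hmax) hmax = h;
    }
    out[b] = hmax;
  }
  return out;
}
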