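#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// One haplotype on one chromosome: tract right endpoints (last == L) and
// tract ancestries (1 or 2). Tracts tile [0, L); adjacent tracts always
// differ in ancestry after merging.
struct Hap {
  std::vector<double> ends;
  std::vector<int> anc;
};

static Hap meiosis(const Hap &h1, const Hap &h2, double L) {
  int k = (int)R::rpois(L);
  if (k == 0) return (unif_rand() < 0.5) ? h1 : h2;
  std::vector<double> cuts(k);
  for (int i = 0; i < k; ++i) cuts[i] = unif_rand() * L;
  std::sort(cuts.begin(), cuts.end());
  bool use1 = unif_rand() < 0.5;
  Hap out;
  out.ends.reserve(h1.ends.size() + h2.ends.size() + k);
  out.anc.reserve(out.ends.capacity());
  double a = 0.0;
  for (int s = 0; s <= k; ++s) {
    double b = (s < k) ? cuts[s] : L;
    const Hap &h = use1 ? h1 : h2;
    if (b > a) {
      // first tract of h with end > a
      size_t i0 = std::upper_bound(h.ends.begin(), h.ends.end(), a) -
                  h.ends.begin();
      for (size_t i = i0; i < h.ends.size(); ++i) {
        double e = std::min(h.ends[i], b);
        int an = h.anc[i];
        if (!out.anc.empty() && out.anc.back() == an) {
          out.ends.back() = e;  // merge equal-ancestry neighbors
        } else {
          out.ends.push_back(e);
          out.anc.push_back(an);
        }
        if (h.ends[i] >= b) break;
      }
      a = b;
    }
    use1 = !use1;
  }
  out.ends.back() = L;  // guard against float drift at the right edge
  return out;
}

// Forward propagation of ancestry tracts through g generations of random
// mating in a population of n_dip diploids. Founder haplotypes carry a
// single ancestry label (one-pulse admixture); recombination is a Poisson
// process of rate 1 per Morgan per meiosis, shared pedigree across
// chromosomes. Returns tracts of the first n_sample haplotypes.
// [[Rcpp::export]]
List forward_tracts_cpp(int n_dip, int g, NumericVector chrom_lengths,
                        IntegerVector founder_anc, int n_sample) {
  int n_hap = 2 * n_dip;
  int n_chr = chrom_lengths.size();
  if (founder_anc.size() != n_hap)
    stop("founder_anc must have length 2 * n_dip");
  if (n_sample > n_hap) stop("n_sample exceeds population haplotypes");

  // pop[c][h]
  std::vector<std::vector<Hap>> pop(n_chr, std::vector<Hap>(n_hap));
  for (int c = 0; c < n_chr; ++c)
    for (int h = 0; h < n_hap; ++h) {
      pop[c][h].ends.assign(1, chrom_lengths[c]);
      pop[c][h].anc.assign(1, founder_anc[h]);
    }

  std::vector<int> parent(n_hap);
  std::vector<std::vector<Hap>> next(n_chr, std::vector<Hap>(n_hap));
  for (int gen = 0; gen < g; ++gen) {
    for (int h = 0; h < n_hap; ++h)
      parent[h] = (int)(unif_rand() * n_dip);
    for (int c = 0; c < n_chr; ++c) {
      for (int h = 0; h < n_hap; ++h) {
        int p = parent[h];
        next[c][h] = meiosis(pop[c][2 * p], pop[c][2 * p + 1],
                             chrom_lengths[c]);
      }
      std::swap(pop[c], next[c]);
    }
  }

  // flatten sampled haplotypes
  std::vector<int> hap_out, chr_out, anc_out;
  std::vector<double> start_out, end_out;
  for (int h = 0; h < n_sample; ++h) {
    for (int c = 0; c < n_chr; ++c) {
      const Hap &hp = pop[c][h];
      double a = 0.0;
      for (size_t i = 0; i < hp.ends.size(); ++i) {
        hap_out.push_back(h + 1);
        chr_out.push_back(c + 1);
        start_out.push_back(a);
        end_out.push_back(hp.ends[i]);
        anc_out.push_back(hp.anc[i]);
        a = hp.ends[i];
      }
    }
  }
  return List::create(_["haplotype"] = wrap(hap_out),
                      _["chromosome"] = wrap(chr_out),
                      _["start_M"] = wrap(start_out),
                      _["end_M"] = wrap(end_out),
                      _["ancestry"] = wrap(anc_out));
}
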