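// Integrated EHH (iHH) kernel used by the XP-EHH scan.
//
// For each core SNP the population's haplotypes are partitioned by their
// allele string from the core outwards; EHH at a site is the probability
// that two distinct haplotypes fall in the same class,
//   EHH = sum_h C(c_h, 2) / C(c, 2).
// EHH is a step function of physical distance: it changes only at
// informative sites, holding its value across each inter-site gap.  iHH
// integrates that step curve exactly (each gap contributes the EHH value
// carried into it), starting at EHH = 1 at the core and truncating at the
// first site whose EHH falls below the cutoff (that terminal gap is still
// covered by the pre-cutoff value), at max_extend, or at the contig end.
// Integrating the step curve exactly is what makes iHH invariant to
// inserting a site at which all haplotypes agree.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

double directional_ihh(const IntegerMatrix &alleles, const IntegerVector &pos,
                       const IntegerVector &contig, const std::vector<int> &cols,
                       int core, int step, double cutoff, double max_extend) {
  int n_sites = alleles.nrow();
  int nh = (int)cols.size();
  double denom = (double)nh * (nh - 1);
  std::vector<int> grp(nh, 0), relab, cnt;
  int ng = 1;
  double prev_ehh = 1.0, prev_pos = (double)pos[core], total = 0.0;
  for (int j = core + step; j >= 0 && j < n_sites; j += step) {
    if (contig[j] != contig[core]) break;
    double d = std::fabs((double)pos[j] - (double)pos[core]);
    if (d > max_extend) break;
    relab.assign(2 * ng, -1);
    int newng = 0;
    for (int h = 0; h < nh; ++h) {
      int code = grp[h] * 2 + alleles(j, cols[h]);
      if (relab[code] < 0) relab[code] = newng++;
      grp[h] = relab[code];
    }
    ng = newng;
    cnt.assign(ng, 0);
    for (int h = 0; h < nh; ++h) cnt[grp[h]]++;
    double hom = 0.0;
    for (int g = 0; g < ng; ++g) hom += (double)cnt[g] * (cnt[g] - 1);
    double ehh = hom / denom;
    total += prev_ehh * std::fabs((double)pos[j] - prev_pos);
    if (ehh < cutoff) break;
    prev_ehh = ehh;
    prev_pos = (double)pos[j];
    if (ng == nh) break;  // fully dissolved; EHH stays 0
  }
  return total;
}

}  // namespace

// [[Rcpp::export]]
NumericVector ihh_cpp(IntegerMatrix alleles, IntegerVector pos,
                      IntegerVector contig, IntegerVector cols, double cutoff,
                      double max_extend) {
  int n_sites = alleles.nrow();
  std::vector<int> cc(cols.size());
  for (int i = 0; i < cols.size(); ++i) cc[i] = cols[i] - 1;  // 1-based from R
  NumericVector out(n_sites);
  for (int i = 0; i < n_sites; ++i) {
    out[i] = directional_ihh(alleles, pos, contig, cc, i, -1, cutoff,
                             max_extend) +
             directional_ihh(alleles, pos, contig, cc, i, +1, cutoff,
                             max_extend);
  }
  return out;
}
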