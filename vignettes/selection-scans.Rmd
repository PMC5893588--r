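---
title: "Selection scans on phased population data: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection scans on phased population data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

sweepscan detects footprints of recent positive selection in phased diploid
genotypes and quantifies differentiation between populations.  Its motivating
use case is the comparison of a freshwater-adapted cetacean population (the
Yangtze finless porpoise) with its marine relatives: a recently isolated
population pair in which one side may carry locus-specific selective sweeps,
scanned with an SFS-based composite likelihood ratio (CLR), cross-population
extended haplotype homozygosity (XP-EHH), allele-frequency differentiation
statistics, per-SNP F~ST~, and the f3 admixture test.  Every scan can be
exercised against a built-in forward Wright–Fisher simulator that provides
complete ground truth.  This vignette documents the models, the parameters
that matter, the numerical choices, and what the synthetic data can and
cannot show.

## The data model

All scans operate on a `haplotype_matrix`: a sites-by-haplotypes 0/1 matrix
of phased alleles with 1-based physical positions, strictly increasing
within each contig.  Each diploid contributes two adjacent columns.  When an
ancestral-allele annotation is available (the `AA` INFO tag, or simulator
truth), 1 means the derived allele and unfolded statistics are available;
otherwise 1 is simply the ALT allele and frequency-spectrum statistics run
in folded mode.  Missing or unphased genotypes drop the whole site at
ingest: downstream statistics then need no missing-data rules and stay
exact.  Multi-allelic records are skipped, never split.  Intervals (genes)
are 0-based half-open internally and converted at the BED/GFF3 boundary;
positions in all output files are 1-based.

## The CLR sweep scan

The background model is the genome-wide site frequency spectrum
$\phi_k$, the empirical distribution of derived (or minor) allele counts
$k \in \{1, \dots, n-1\}$ over all sites polymorphic in the scanned group.
The sweep model is a star-like genealogy transform of that background.  At
physical distance $d$ from a sweep of intensity $\alpha$ (per bp), each of
the $n$ sampled lineages escapes the sweep independently with probability
$p_e = 1 - e^{-\alpha d}$.  Given $e$ escaped lineages, the $n-e$ swept
lineages descend from a single ancestral lineage; with the pre-sweep
derived frequency $p_j = j/n$ drawn from $\phi$, the count probability is

$$P(k) \propto \binom{n}{e} p_e^e (1-p_e)^{n-e} \left[
  p_j\, \mathrm{Bin}(k - (n-e);\, e, p_j) +
  (1 - p_j)\, \mathrm{Bin}(k;\, e, p_j) \right],$$

summed over $j$ and $e < n$, renormalized over the polymorphic classes
$k = 1..n-1$ (substitutions are excluded, symmetrically in numerator and
denominator).  The fully escaped class $e = n$ is modeled as an
exchangeable draw from the background spectrum itself, $P(k) = \phi_k$,
rather than as a binomial resampling of it.  This is a deliberate choice:
it makes the model collapse exactly onto the neutral model as
$\alpha \to \infty$, so the neutral model is nested and the CLR cannot go
negative.  The scan always includes that boundary (reported as
`alpha_hat = Inf` where the background fits best), which is why
`clr_scan()` returns CLR $\ge 0$ at every grid point by construction.

$\alpha$ is maximized over a fixed logarithmic grid (default
$10^{-8}$–$10^{-1}$ per bp, 40 points) rather than by numeric
optimization: the scan is deterministic and the grid is dense enough that
the discretization is far below the statistic's own noise.  Inside the
scan, the escape probability is discretized onto a fixed grid of ~440
values, log-dense near 0 and 1 with both endpoints exact; the model
matrices are cached per sample size, so rescanning costs little.  A site
lying exactly on a grid point is scored at 1 bp distance; the $p_e \to 0$
limit itself concentrates all conditional mass on the singleton classes
$k \in \{1, n-1\}$ (only one lineage can escape), and the implementation
uses that limit where the mass would otherwise vanish.

Peak calling defaults: the threshold is
the upper 0.2% quantile of all CLR values, contiguous super-threshold grid
runs merge into intervals, the strongest 20 peaks are kept, and genes
within a 1 Mb flank of each interval are attached.  Quantile thresholds are
always computed from the scanned data, never hard-coded.

### Localization precision

On data drawn from the model itself the scan recovers the sweep position
and $\alpha$ exactly.  On realistic sweep genealogies its spatial precision
is limited: for a population-scaled intensity around $N s = 50$ (the
desk-scale regime of the bundled simulations) sweeps take hundreds of
generations, during which recombination and new mutation create
intermediate-frequency alleles near the sweep center that the
all-or-nothing escape model penalizes heavily, and linked sites share one
realized genealogy, so the composite likelihood has far fewer effective
observations than sites.  In the bundled 2-Mb simulations the peak lands
within 50 kb of the truth in roughly half of replicates and within the
sweep footprint in most; users should treat peak positions as
footprint-scale, not gene-scale, localizations at moderate $Ns$.  The
cross-check with an independent structured-coalescent sweep simulator
showed the same behaviour, i.e. this is a property of the statistic at
this signal strength, not of the implementation.

## XP-EHH

EHH at distance $d$ from a core SNP is the probability that two distinct
haplotypes of the population are identical over all informative sites
between the core and $d$: partitioning the haplotypes by that allele
string into classes of sizes $c_h$,
$\mathrm{EHH} = \sum_h \binom{c_h}{2} / \binom{c}{2}$.  EHH is a step
function of distance — it changes only at informative sites — and iHH
integrates that step curve exactly, from EHH $= 1$ at the core outward,
truncating at the first site where EHH drops below the cutoff (default
0.05, the selscan-style convention; the terminal gap is still covered by
the pre-cutoff value), at `max_extend`, or at the contig end.  Exact step
integration, rather than point-to-point trapezoids, is what makes iHH
invariant to inserting sites at which all haplotypes agree.  The core is
not conditioned on an allele: XP-EHH compares whole-population haplotype
homozygosity, so the core site itself does not enter the partition and
EHH(0) = 1.

The statistic is $\ln(\mathrm{iHH}_A/\mathrm{iHH}_B)$ per core SNP,
normalized by subtracting the genome-wide mean and dividing by the
standard deviation over all scanned SNPs — so the z-scores have mean 0 and
sd 1 by construction, to machine precision.  SNPs where either iHH is zero
are dropped and counted.  MAF pruning (strictly greater than 1% in *every*
population) is applied before scanning; note the
practical consequence that a *completed* sweep removes its own footprint
SNPs from the scan (they are monomorphic in the swept population), so
XP-EHH power peaks for ongoing sweeps near fixation.

Candidate selection tiles the genome into non-overlapping windows (default
50 kb) and takes each window's
max-|z| SNP.  A window is a candidate when its top SNP strictly exceeds
the 99.9% quantile — computed over the window-top values, so that under
neutrality ~0.1% of windows are flagged — or falls below the 0.1%
quantile for the other population.  Genes within 5 kb of the top SNP are
attached.  The realized thresholds are reported with the candidates: they
are data-dependent quantiles of the scan at hand, never constants.

Haplotype bifurcation trees (`bifurcation()`) record the successive class
splits outward from a core allele, with counts conserved from parent to
children, and serialize to Newick with counts as labels.

## Allele-frequency distance and F~ST~

For two groups the accumulated distance is
$T_d = \sum_i (\mathrm{Freq}A_i - \mathrm{Freq}B_i)^2$ over all scanned
SNPs; each SNP's relative contribution is $r_i = (\mathrm{Freq}A_i -
\mathrm{Freq}B_i)^2 / T_d$ and its empirical P-value is the right-tail
rank $p_i = \#\{j : r_j \ge r_i\}/n$, so the strongest SNP has $p = 1/n$
and the weakest $p = 1$.  The "for each allele" accumulation is read as
per-SNP with a genome-wide total — the only reading under which an
empirical distribution of relative contributions exists.  If the
frequencies agree at every SNP ($T_d = 0$) the function raises a classed
error rather than emitting NaNs.

F~ST~ is the Weir & Cockerham (1984) variance-component estimator applied
to phased haplotypes as haploid alleles (the paper does not state its
estimator; the haploid form is the natural one for phased data).  Per-SNP
components and $\hat\theta = a/(a+b+c)$ (with $c = 0$ for haploid data)
are reported as computed — negative estimates are flagged, never clamped —
and multi-SNP summaries use the ratio of sums $\sum a / \sum(a+b+c)$.  At
a fixed difference with equal sample sizes $\hat\theta = 1$ exactly.

## The f3 admixture test

For target C and references A, B, the per-SNP value is
$(c-a)(c-b) - c(1-c)/(n_C - 1)$ with sample frequencies $a, b, c$; the
correction term removes the finite-sample bias on the target — without
it $f_3 > 0$ always and the test is vacuous.  $f_3$ is the mean over SNPs
(sites monomorphic across all three groups are skipped), the standard
error is a weighted block jackknife over contiguous blocks (default 5 Mb
spans — LD decays in physical distance), and $Z = f_3/\mathrm{SE}$.
Significantly negative $Z$ indicates that C is admixed between relatives
of A and B.  The block-weighted average of the leave-one-out estimates
reproduces the full estimate exactly, which the tests assert.

## The Wright–Fisher simulator

`wf_simulate()` is a discrete-generation forward simulator: one ancestral
population of `Ne` diploids evolves for `burn_factor * Ne` (≥ 10·Ne)
burn-in generations, splits instantaneously into isolated copies (no
migration, matching the no-recent-gene-flow setting of the motivating
system), and evolves to the present under infinite-sites mutation (integer
bp positions, collisions redrawn) and uniform recombination.  A sweep is a
single mutation injected into one population with additive fitness
$1, 1+s/2, 1+s$, conditioned on non-loss by restarting from the injection
state (restarts are counted and capped).  An admixture event can found an
extra population from two sources at a chosen time — used to give the f3
test a true positive.  Forward simulation was chosen over coalescent
approximations so that sweeps, admixture and conditioning are exact by
construction; haplotypes are shared copy-on-write vectors, so unmodified
gametes are pointer copies and desk-scale runs (Ne ≤ 1000, a few Mb) take
seconds to tens of seconds.  All randomness flows through R's RNG: a
seeded configuration reproduces byte-identical output, which the
determinism tests assert end-to-end through the VCF writer.

Defaults are realistic for the motivating system: mutation rate
$\mu = 1.10 \times 10^{-8}$ per site per generation and generation time 8
years (used only to report times in years).  Sample sizes default to
20 + 18 diploids, emulating a typical population-resequencing design of
~49 individuals split over three groups;
unequal sizes also place allele-frequency differences on a fine lattice,
which keeps the empirical-P distribution close to uniform under
exchangeability.  The truth object records, per output site, the
population-level derived counts and the generation in which the mutation
arose; the `standing` flag (mutation predates the split) exists because
drift expectations such as $F_{ST} = 1 - (1 - 1/2N_e)^t$ apply to
variation already present at the split — post-split mutations carry no
shared drift history of length $t$, and a forward simulation at
equilibrium produces mostly post-split variants, so calibration checks
score standing sites.

### What the bundled simulations do and do not show

The test-suite simulations use desk-scale sizes chosen once: sweep
recovery at Ne = 1000 over 2 × 2 Mb with $\mu = 10^{-7}$, $r = 5 \times
10^{-8}$ and a split 360 generations before sampling (an ongoing sweep
near fixation — the regime XP-EHH is built for, and with a physical
footprint $\sim s/(r \ln 2N) \approx 70$ kb matched to the 10-kb scan
grid); neutral calibration at Ne = 200 over 20 × 5 Mb (~10^5 SNPs);
F~ST~ calibration at Ne = 200, split 400 (drift expectation 0.632); f3
at Ne = 200 with a 50/50 admixture 20 generations before sampling.  The
elevated per-site rates keep scaled diversity realistic at small Ne.
These synthetic data are panmictic Wright–Fisher populations with uniform
rates and complete, perfectly phased genotypes; they do not emulate
variable recombination and mutation landscapes, background selection,
phasing or genotyping error, missingness, or the reference biases of real
resequencing data.  Passing tests therefore validate the statistics'
internal contracts and their behaviour under idealized demography — not
robustness to the full error structure of a real dataset.

## Numerical and interface conventions

Quantile thresholds use R's default (type 7) quantiles with strict
exceedance, so degenerate constant tracks yield no peaks or candidates.
Ties in window-top selection resolve to the first SNP.  All result files
are tab-separated with a `##sweepscan` header recording version, seed and
stage parameters, floats at 6 significant digits, and no timestamps —
identical runs are byte-identical, and the acceptance suite checks this
through the whole demo pipeline.  Logs go to stderr; result values never
go to stdout.  The command-line wrapper (`inst/exec/sweepscan`, a thin
layer over `run_cli()`) exits 0/1/2 for success / input error / runtime
error, with YAML configuration merged under flag overrides and unknown
keys rejected.
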