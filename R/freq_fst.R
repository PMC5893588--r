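#' Accumulated allele-frequency distance and per-SNP empirical P-values
#'
#' For two groups A and B, the accumulated distance is
#'   T_d = sum_i (FreqA_i - FreqB_i)^2
#' over all scanned SNPs i.  Each SNP's relative contribution is
#' `r_i = (FreqA_i - FreqB_i)^2 / T_d`, and its empirical P-value is the
#' right-tail rank of `r_i` in the genome-wide distribution,
#' `p_i = #\{j : r_j >= r_i\} / n_SNPs`, so the strongest SNP has
#' `p = 1/n` and the weakest `p = 1`.
#'
#' @param hm a [haplotype_matrix()].
#' @param pop_a,pop_b population labels.
#' @return A data.frame of class `freq_diff_track` with columns `contig`,
#'   `pos`, `freq_a`, `freq_b`, `sq_diff`, `rel_contrib`, `emp_p`;
#'   attributes `td` and `n_snps`.  If the frequencies are identical at
#'   every SNP (T_d = 0) a classed error (`sweepscan_td_zero`) is thrown,
#'   never NaNs.
#' @export
freq_diff <- function(hm, pop_a, pop_b) {
  if (n_sites(hm) < 1L) stop_input("no SNPs to score")
  fa <- pop_freq(hm, pop_a)
  fb <- pop_freq(hm, pop_b)
  sq <- (fa - fb)^2
  td <- sum(sq)
  if (td == 0)
    stop_runtime(paste0("T_d = 0: groups '%s' and '%s' have identical ",
                        "frequencies at every SNP; relative contributions ",
                        "and empirical P-values are undefined"),
                 pop_a, pop_b, class = "sweepscan_td_zero")
  r <- sq / td
  n <- length(r)
  p <- (n - rank(r, ties.method = "min") + 1) / n
  out <- data.frame(contig = hm$contig, pos = hm$pos, freq_a = fa,
                    freq_b = fb, sq_diff = sq, rel_contrib = r, emp_p = p,
                    stringsAsFactors = FALSE)
  attr(out, "td") <- td
  attr(out, "n_snps") <- n
  attr(out, "pops") <- c(A = pop_a, B = pop_b)
  class(out) <- c("freq_diff_track", "data.frame")
  out
}

#' Per-SNP Weir-Cockerham F_ST on haplotypes as alleles
#'
#' The Weir & Cockerham (1984) two-population variance-component estimator,
#' applied to phased haplotypes treated as haploid allele samples: with
#' sample sizes `n_i` (haplotypes), frequencies `p_i`, r (= 2) populations,
#' `n_bar` the mean size, `n_c` the size correction, `p_bar` the weighted
#' mean frequency and `s2` the sample variance of frequencies,
#'   a = (n_bar / n_c) * (s2 - (p_bar q_bar - s2 (r-1)/r) / (n_bar - 1))
#'   b = (n_bar / (n_bar - 1)) * (p_bar q_bar - s2 (r-1)/r)
#'   c = 0   (no heterozygote term for haploid alleles)
#' and `theta = a / (a + b + c)`.  Negative estimates are reported as
#' computed (flagged, never clamped); SNPs monomorphic across both samples
#' have an undefined estimate and are flagged.
#'
#' @param hm a [haplotype_matrix()].
#' @param pop_a,pop_b population labels (each >= 2 haplotypes).
#' @return A data.frame of class `fst_track` with columns `contig`, `pos`,
#'   `a`, `b`, `c`, `fst`, `monomorphic`.  The ratio-of-sums genome-wide
#'   estimate `sum(a)/sum(a+b+c)` is available via [fst_overall()].
#' @export
wc_fst <- function(hm, pop_a, pop_b) {
  cols_a <- hap_cols(hm, pop_a)
  cols_b <- hap_cols(hm, pop_b)
  n1 <- length(cols_a)
  n2 <- length(cols_b)
  if (n1 < 2L || n2 < 2L)
    stop_input("each population needs >= 2 haplotypes")
  p1 <- rowMeans(hm$alleles[, cols_a, drop = FALSE])
  p2 <- rowMeans(hm$alleles[, cols_b, drop = FALSE])
  r <- 2
  n_bar <- (n1 + n2) / r
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  inner <- p_bar * (1 - p_bar) - s2 * (r - 1) / r
  a <- (n_bar / n_c) * (s2 - inner / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) * inner
  cc <- rep(0, length(a))
  mono <- p_bar %in% c(0, 1) | (a + b) == 0
  fst <- ifelse(mono, NA_real_, a / (a + b + cc))
  out <- data.frame(contig = hm$contig, pos = hm$pos, a = a, b = b, c = cc,
                    fst = fst, monomorphic = mono, stringsAsFactors = FALSE)
  attr(out, "pops") <- c(A = pop_a, B = pop_b)
  class(out) <- c("fst_track", "data.frame")
  out
}

#' Ratio-of-sums multi-SNP F_ST
#'
#' `sum(a) / sum(a + b + c)` over the (non-monomorphic) SNPs of a
#' [wc_fst()] track — the standard way to combine Weir-Cockerham
#' components across loci or within windows.
#'
#' @param track an `fst_track`.
#' @return A single numeric value.
#' @export
fst_overall <- function(track) {
  ok <- !track$monomorphic
  sum(track$a[ok]) / sum(track$a[ok] + track$b[ok] + track$c[ok])
}
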