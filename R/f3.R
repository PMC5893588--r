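#' Weighted block jackknife over contiguous genomic blocks
#'
#' Leave-one-block-out resampling for a mean over per-SNP values, with the
#' weighted jackknife variance of Busing et al. (1999) — the standard
#' LD-robust error for genome-wide f-statistics.  The block-weighted
#' average of the leave-one-out estimates equals the full estimate exactly.
#'
#' @param values numeric vector of per-SNP statistics.
#' @param blocks block assignment, one per value (factor or vector).
#' @return A list with `est`, `se`, `n_blocks`, and a data.frame `blocks`
#'   (`block`, `n`, `loo`).
#' @export
block_jackknife <- function(values, blocks) {
  blocks <- as.character(blocks)
  ok <- is.finite(values)
  values <- values[ok]
  blocks <- blocks[ok]
  bl <- unique(blocks)
  m <- vapply(bl, function(b) sum(blocks == b), numeric(1))
  if (length(bl) < 2L) stop_input("need >= 2 non-empty blocks")
  n <- length(values)
  s_tot <- sum(values)
  s_j <- vapply(bl, function(b) sum(values[blocks == b]), numeric(1))
  est <- s_tot / n
  loo <- (s_tot - s_j) / (n - m)
  g <- length(bl)
  h <- n / m
  theta_dot <- g * est - sum((1 - m / n) * loo)
  var_j <- sum((h * est - (h - 1) * loo - theta_dot)^2 / (h - 1)) / g
  list(est = est, se = sqrt(var_j), n_blocks = g,
       blocks = data.frame(block = bl, n = as.integer(m), loo = loo,
                           stringsAsFactors = FALSE, row.names = NULL))
}

#' f3 admixture statistic with block-jackknife Z-score
#'
#' Tests whether a target population C is admixed between relatives of A
#' and B.  Per SNP, with sample frequencies `a`, `b`, `c` and `n_C`
#' haplotypes sampled in C, the site value is
#'   (c - a)(c - b) - c(1 - c) / (n_C - 1),
#' the second term being the finite-sample heterozygosity correction on the
#' target (without it the statistic is positively biased and the test is
#' vacuous).  f3 is the mean over SNPs; the standard error comes from a
#' weighted block jackknife over contiguous blocks of `block_bp`, and
#' `Z = f3 / SE`.  Significantly negative Z indicates admixture in C.
#'
#' @param hm a [haplotype_matrix()].
#' @param pop_c target population.
#' @param pop_a,pop_b reference populations (f3 is symmetric in A and B).
#' @param block_bp jackknife block span, bp.
#' @return An object of class `f3_result`: `f3`, `se`, `z`, `n_blocks`,
#'   `n_snps`, and the per-block leave-one-out table.
#' @export
f3 <- function(hm, pop_c, pop_a, pop_b, block_bp = 5e6) {
  v <- f3_site_values(hm, pop_c, pop_a, pop_b)
  poly <- !is.na(v)
  if (!any(poly)) stop_input("no SNP polymorphic across the three groups")
  blocks <- paste(hm$contig, (hm$pos - 1) %/% block_bp, sep = ":")
  jk <- block_jackknife(v[poly], blocks[poly])
  structure(list(f3 = jk$est, se = jk$se, z = jk$est / jk$se,
                 n_blocks = jk$n_blocks, n_snps = sum(poly),
                 blocks = jk$blocks,
                 pops = c(C = pop_c, A = pop_a, B = pop_b),
                 block_bp = block_bp),
            class = "f3_result")
}

#' Per-SNP f3 site values
#'
#' `(c - a)(c - b) - c(1 - c)/(n_C - 1)` per SNP; SNPs monomorphic across
#' the three groups are returned as `NA` (they are skipped by [f3()]).
#'
#' @inheritParams f3
#' @return Numeric vector, one value per site.
#' @export
f3_site_values <- function(hm, pop_c, pop_a, pop_b) {
  cols_c <- hap_cols(hm, pop_c)
  if (length(cols_c) < 2L)
    stop_input("target population '%s' needs >= 2 haplotypes", pop_c)
  fa <- pop_freq(hm, pop_a)
  fb <- pop_freq(hm, pop_b)
  fc <- pop_freq(hm, pop_c)
  n_c <- length(cols_c)
  v <- (fc - fa) * (fc - fb) - fc * (1 - fc) / (n_c - 1)
  v[(fa == 0 & fb == 0 & fc == 0) | (fa == 1 & fb == 1 & fc == 1)] <- NA_real_
  v
}

#' @export
print.f3_result <- function(x, ...) {
  cat(sprintf("f3(%s; %s, %s) = %.6g  SE = %.3g  Z = %.2f\n",
              x$pops["C"], x$pops["A"], x$pops["B"], x$f3, x$se, x$z))
  cat(sprintf("  %d SNPs in %d jackknife blocks of %g bp\n",
              x$n_snps, x$n_blocks, x$block_bp))
  invisible(x)
}
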