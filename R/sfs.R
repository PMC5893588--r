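#' Genome-wide background site frequency spectrum
#'
#' Empirical distribution of derived-allele counts (unfolded) or minor
#' counts (folded) over all sites polymorphic within the group, normalized
#' to sum to one.  This is the background model that the CLR sweep scan
#' contrasts against local spectra.
#'
#' @param hm a [haplotype_matrix()].
#' @param group population label.
#' @param folded fold the spectrum over minor counts?  Defaults to folded
#'   when the matrix is not polarized (no ancestral annotation).
#' @return An object of class `sfs`: list with `n` (haploid sample size),
#'   `phi` (probabilities for counts `1..n-1`, or `1..floor(n/2)` when
#'   folded), `folded`, `n_sites_used`.
#' @export
background_sfs <- function(hm, group, folded = !hm$polarized) {
  cols <- hap_cols(hm, group)
  n <- length(cols)
  if (n < 2L) stop_input("group '%s' must have >= 2 haplotypes", group)
  k <- as.integer(rowSums(hm$alleles[, cols, drop = FALSE]))
  k <- k[k > 0L & k < n]
  if (length(k) == 0L)
    stop_input("no sites polymorphic within group '%s'", group)
  if (folded) {
    k <- pmin(k, n - k)
    phi <- tabulate(k, nbins = n %/% 2L)
  } else {
    phi <- tabulate(k, nbins = n - 1L)
  }
  structure(list(n = n, phi = phi / sum(phi), folded = folded,
                 n_sites_used = length(k)), class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("%s site frequency spectrum, n = %d haplotypes, %d sites\n",
              if (x$folded) "folded" else "unfolded", x$n, x$n_sites_used))
  cat("  phi:", paste(sprintf("%.4f", head(x$phi, 10)), collapse = " "),
      if (length(x$phi) > 10) "...\n" else "\n")
  invisible(x)
}
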