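# small in-code fixtures shared across the suite

# haplotype matrix with given per-site allele vectors (sites x haplotypes)
make_hm <- function(alleles, pos = NULL, pops = NULL, contig = "chr1",
                    polarized = TRUE) {
  alleles <- as.matrix(alleles)
  n_ind <- ncol(alleles) / 2L
  if (is.null(pos)) pos <- seq_len(nrow(alleles)) * 100L
  if (is.null(pops)) pops <- rep("p1", n_ind)
  haplotype_matrix(contig, pos, alleles, sprintf("s%02d", seq_len(n_ind)),
                   pops, polarized = polarized)
}

# random biallelic matrix: n_sites x n_hap, allele frequencies away from 0/1
random_hm <- function(n_sites, n_hap, pops = NULL, seed = NULL,
                      contig = "chr1") {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(0L, n_sites, n_hap)
  for (i in seq_len(n_sites)) {
    k <- sample(seq_len(n_hap - 1L), 1L)
    a[i, sample(n_hap, k)] <- 1L
  }
  pos <- sort(sample(seq_len(n_sites * 500L), n_sites))
  make_hm(a, pos = pos, pops = pops, contig = contig)
}

# a tiny phased VCF written by hand; returns its path
write_tiny_vcf <- function(dir = tempdir(), gts, pos = NULL, chrom = "chr1",
                           ref = "A", alt = "T", info = ".",
                           samples = NULL, name = "tiny.vcf") {
  n_rec <- length(gts)
  n_smp <- length(strsplit(gts[[1L]], "\t", fixed = TRUE)[[1L]])
  if (is.null(pos)) pos <- seq_len(n_rec) * 10L
  if (is.null(samples)) samples <- sprintf("ind%d", seq_len(n_smp))
  ref <- rep_len(ref, n_rec); alt <- rep_len(alt, n_rec)
  info <- rep_len(info, n_rec)
  path <- file.path(dir, name)
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    paste(chrom, pos, ".", ref, alt, ".", "PASS", info, "GT",
          unlist(gts), sep = "\t")), path)
  path
}

popmap_df <- function(samples, groups) {
  data.frame(sample = samples, group = groups, stringsAsFactors = FALSE)
}

# brute-force EHH: probability two distinct haplotypes are identical over
# the allele string accumulated moving away from the core (the core site
# itself is not part of the string: EHH at offset 0 is 1 by definition)
brute_ehh <- function(alleles, cols, core, direction, cutoff = 0.05) {
  n <- nrow(alleles)
  step <- if (direction == "right") 1L else -1L
  c_n <- length(cols)
  offs <- 0
  vals <- 1
  j <- core + step
  idx <- integer(0)
  while (j >= 1L && j <= n) {
    idx <- c(idx, j)
    strings <- apply(alleles[idx, cols, drop = FALSE], 2L, paste, collapse = "")
    same <- 0L
    for (x in seq_len(c_n - 1L))
      for (y in (x + 1L):c_n) if (strings[x] == strings[y]) same <- same + 1L
    e <- same / choose(c_n, 2L)
    if (e < cutoff) break
    offs <- c(offs, j)
    vals <- c(vals, e)
    j <- j + step
  }
  list(site = offs, ehh = vals)
}

# Monte-Carlo star-genealogy oracle for the sweep site model: with escape
# probability pe, each of n lineages escapes independently; all non-escaped
# lineages descend from one ancestral lineage whose pre-sweep derived state
# has probability p_j = j/n with j ~ phi; a fully escaped sample is an
# exchangeable draw from the background itself.  Conditioned on polymorphism.
mc_star_oracle <- function(n, phi, pe, n_draws, seed = 1) {
  set.seed(seed)
  ks <- integer(0)
  while (length(ks) < n_draws) {
    m <- n_draws - length(ks)
    e <- rbinom(m, n, pe)
    j <- sample(seq_len(n - 1), m, replace = TRUE, prob = phi)
    p_j <- j / n
    anc <- rbinom(m, 1, p_j)
    k <- ifelse(e == n,
                sample(seq_len(n - 1), m, replace = TRUE, prob = phi),
                (n - e) * anc + rbinom(m, pmin(e, n), p_j))
    k <- k[k >= 1 & k <= n - 1]
    ks <- c(ks, k)
  }
  tabulate(ks[seq_len(n_draws)], nbins = n - 1) / n_draws
}

uniform_sfs <- function(n) {
  structure(list(n = n, phi = rep(1 / (n - 1), n - 1), folded = FALSE,
                 n_sites_used = 1000L), class = "sfs")
}
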