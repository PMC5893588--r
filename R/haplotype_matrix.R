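#' Phased haplotype matrix
#'
#' The central container of the package: a sites-by-haplotypes 0/1 matrix of
#' phased alleles together with physical positions, contig labels, sample
#' identifiers and population labels.  Each diploid individual contributes
#' two adjacent haplotype columns.  When `polarized` is `TRUE`, 1 means the
#' derived allele (ancestral state known, e.g. from the AA INFO tag or from
#' the simulator's truth); otherwise 1 simply means the ALT allele.
#'
#' Positions are 1-based physical coordinates and must be strictly
#' increasing within each contig; sites of different contigs must form
#' contiguous blocks.
#'
#' @param contig character vector, one contig name per site (recycled if
#'   length 1).
#' @param pos integer vector of 1-based positions, one per site.
#' @param alleles integer matrix of 0/1 alleles, sites x haplotypes, with
#'   two columns per individual (columns of an individual adjacent).
#' @param sample_ids character vector of diploid sample names.
#' @param pop character vector of population labels, one per sample.
#' @param polarized logical flag: is 0/1 ancestral/derived?
#' @param ref,alt,aa optional per-site REF/ALT/ancestral bases carried along
#'   for VCF round-trips; synthesized as "A"/"T" when absent.
#'
#' @return An object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(contig, pos, alleles, sample_ids, pop,
                             polarized = FALSE, ref = NULL, alt = NULL,
                             aa = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  n_sites <- nrow(alleles)
  if (length(contig) == 1L) contig <- rep(contig, n_sites)
  pos <- as.integer(pos)
  if (length(pos) != n_sites || length(contig) != n_sites)
    stop_input("positions/contigs (%d/%d) do not match %d sites",
               length(pos), length(contig), n_sites)
  if (ncol(alleles) != 2L * length(sample_ids))
    stop_input("expected %d haplotype columns for %d diploid samples, got %d",
               2L * length(sample_ids), length(sample_ids), ncol(alleles))
  if (length(pop) != length(sample_ids))
    stop_input("one population label per sample required")
  if (n_sites > 0L) {
    if (!all(alleles %in% c(0L, 1L)))
      stop_input("allele matrix must contain only 0/1")
    for (ct in unique(contig)) {
      p <- pos[contig == ct]
      if (any(diff(p) <= 0L))
        stop_input("positions not strictly increasing on contig %s", ct)
    }
    idx <- which(!duplicated(contig))
    if (any(duplicated(contig[idx])))
      stop_input("sites of each contig must be contiguous")
  }
  if (is.null(ref)) ref <- rep("A", n_sites)
  if (is.null(alt)) alt <- rep("T", n_sites)
  if (is.null(aa) && polarized) aa <- ref
  structure(
    list(contig = as.character(contig), pos = pos, alleles = alleles,
         sample_ids = as.character(sample_ids),
         pop = setNames(as.character(pop), sample_ids),
         polarized = isTRUE(polarized),
         ref = ref, alt = alt, aa = aa),
    class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf(
    "haplotype_matrix: %d sites on %d contig(s), %d samples (%d haplotypes)\n",
    n_sites(x), length(unique(x$contig)), length(x$sample_ids),
    ncol(x$alleles)))
  tab <- table(x$pop)
  cat("  populations:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  cat(sprintf("  polarized (0/1 = ancestral/derived): %s\n", x$polarized))
  invisible(x)
}

#' Number of sites in a haplotype matrix
#' @param hm a [haplotype_matrix()].
#' @return Integer site count.
#' @export
n_sites <- function(hm) nrow(hm$alleles)

#' Haplotype column indices of a population
#'
#' @param hm a [haplotype_matrix()].
#' @param group population label.
#' @return Integer vector of haplotype column indices.
#' @export
hap_cols <- function(hm, group) {
  if (!group %in% hm$pop)
    stop_input("population '%s' not present (have: %s)", group,
               paste(unique(hm$pop), collapse = ", "))
  sel <- which(hm$pop == group)
  as.integer(sort(c(2L * sel - 1L, 2L * sel)))
}

#' Derived (or ALT) allele frequencies of a population
#' @param hm a [haplotype_matrix()].
#' @param group population label.
#' @return Numeric vector, one frequency per site.
#' @export
pop_freq <- function(hm, group) {
  cols <- hap_cols(hm, group)
  rowMeans(hm$alleles[, cols, drop = FALSE])
}

#' Subset a haplotype matrix by site index
#' @param hm a [haplotype_matrix()].
#' @param i integer or logical site index.
#' @return A [haplotype_matrix()] with the selected sites.
#' @export
hm_subset <- function(hm, i) {
  haplotype_matrix(hm$contig[i], hm$pos[i],
                   hm$alleles[i, , drop = FALSE],
                   hm$sample_ids, unname(hm$pop), hm$polarized,
                   ref = hm$ref[i], alt = hm$alt[i],
                   aa = if (is.null(hm$aa)) NULL else hm$aa[i])
}

#' Concatenate per-contig haplotype matrices
#'
#' Binds the per-contig matrices returned by [read_phased_vcf()] into a
#' single multi-contig object (same samples, same polarization) so that
#' genome-wide scans and normalizations can run across contigs.
#'
#' @param hms list of [haplotype_matrix()] objects.
#' @return A single [haplotype_matrix()].
#' @export
hm_bind <- function(hms) {
  if (inherits(hms, "haplotype_matrix")) return(hms)
  stopifnot(length(hms) >= 1L)
  h1 <- hms[[1L]]
  for (h in hms[-1L]) {
    if (!identical(h$sample_ids, h1$sample_ids) ||
        !identical(h$polarized, h1$polarized))
      stop_input("haplotype matrices to bind must share samples and polarization")
  }
  haplotype_matrix(
    unlist(lapply(hms, `[[`, "contig")),
    unlist(lapply(hms, `[[`, "pos")),
    do.call(rbind, lapply(hms, `[[`, "alleles")),
    h1$sample_ids, unname(h1$pop), h1$polarized,
    ref = unlist(lapply(hms, `[[`, "ref")),
    alt = unlist(lapply(hms, `[[`, "alt")),
    aa = if (is.null(h1$aa)) NULL else unlist(lapply(hms, `[[`, "aa")))
}
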