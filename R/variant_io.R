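#' Read a population map
#'
#' Two-column tab-separated file without header: sample identifier and group
#' name.
#'
#' @param path file path.
#' @return A data.frame with columns `sample` and `group`.
#' @export
read_popmap <- function(path) {
  if (!file.exists(path)) stop_input("popmap file not found: %s", path)
  pm <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE,
                   col.names = c("sample", "group"))
  if (anyDuplicated(pm$sample))
    stop_input("duplicated sample ids in popmap: %s",
               paste(pm$sample[duplicated(pm$sample)], collapse = ", "))
  pm
}

#' Read phased biallelic SNPs from a VCF into haplotype matrices
#'
#' Retains biallelic SNP records whose genotypes are all phased ("|") and
#' non-missing for the samples in the population map; everything else is
#' dropped and counted.  With `require_aa = TRUE` the 0/1 encoding is
#' polarized by the AA INFO tag (sites whose AA matches neither REF nor ALT
#' are dropped); otherwise 0 = REF and the result is unpolarized.
#'
#' @param vcf_path path to a VCF 4.x file (plain or gzip).
#' @param popmap a data.frame as returned by [read_popmap()], a named
#'   character vector (names = samples, values = groups), or a file path.
#' @param require_aa polarize by the ancestral-allele (AA) INFO tag?
#' @return A named list with one [haplotype_matrix()] per contig, in file
#'   order, with attribute `counts` recording how many records were dropped
#'   at each filter (multi-allelic / non-SNP, unphased or missing, AA
#'   missing or inconsistent, duplicated position).
#' @export
read_phased_vcf <- function(vcf_path, popmap, require_aa = FALSE) {
  if (!file.exists(vcf_path)) stop_input("VCF not found: %s", vcf_path)
  if (is.character(popmap) && length(popmap) == 1L && file.exists(popmap))
    popmap <- read_popmap(popmap)
  if (is.character(popmap))
    popmap <- data.frame(sample = names(popmap), group = unname(popmap),
                         stringsAsFactors = FALSE)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt_all <- vcf@gt
  vcf_samples <- colnames(gt_all)[-1L]
  missing <- setdiff(popmap$sample, vcf_samples)
  if (length(missing) > 0L)
    stop_input("sample(s) in popmap absent from VCF: %s",
               paste(missing, collapse = ", "))

  counts <- c(non_biallelic_snp = 0L, unphased_or_missing = 0L,
              aa_unusable = 0L, duplicated_position = 0L)

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  bases <- c("A", "C", "G", "T")
  bi <- !is.na(ref) & !is.na(alt) & toupper(ref) %in% bases &
    toupper(alt) %in% bases
  counts["non_biallelic_snp"] <- sum(!bi)

  info <- paste0(";", fix[, "INFO"])
  aa <- rep(NA_character_, nrow(fix))
  m <- regexpr(";AA=[^;]*", info)
  hit <- m > 0L
  aa[hit] <- toupper(substring(regmatches(info, m), 5L))

  # genotype strings for the mapped samples only, FORMAT column removed
  fmt <- gt_all[, 1L]
  gt <- gt_all[, popmap$sample, drop = FALSE]
  gt_field <- vapply(strsplit(fmt, ":", fixed = TRUE),
                     function(x) which(x == "GT")[1L], integer(1))
  if (anyNA(gt_field)) stop_input("VCF records without GT field")
  if (any(gt_field != 1L)) {
    for (j in seq_len(ncol(gt)))
      gt[, j] <- vapply(strsplit(gt[, j], ":", fixed = TRUE),
                        function(x, k) x[k], character(1), k = gt_field[1L])
  } else {
    gt[] <- sub(":.*$", "", gt)
  }
  ok_gt <- rep(TRUE, nrow(fix))
  for (j in seq_len(ncol(gt)))
    ok_gt <- ok_gt & grepl("^[01]\\|[01]$", gt[, j])
  counts["unphased_or_missing"] <- sum(bi & !ok_gt)

  keep <- bi & ok_gt
  flip <- rep(FALSE, nrow(fix))
  if (require_aa) {
    usable <- keep & !is.na(aa) & (aa == toupper(ref) | aa == toupper(alt))
    counts["aa_unusable"] <- sum(keep & !usable)
    flip <- usable & aa == toupper(alt)
    keep <- usable
  }

  if (!any(keep)) stop_input("zero sites retained from %s", vcf_path)

  idx <- which(keep)
  chrom <- fix[idx, "CHROM"]
  pos <- as.integer(fix[idx, "POS"])
  # enforce strictly increasing positions per contig (keep first occurrence)
  mono <- logical(length(idx))
  for (ct in unique(chrom)) {
    ii <- which(chrom == ct)
    mx <- -Inf
    for (i in ii) {
      if (pos[i] > mx) { mono[i] <- TRUE; mx <- pos[i] }
    }
  }
  if (!all(mono)) {
    counts["duplicated_position"] <- sum(!mono)
    warning(sprintf("%d record(s) with non-increasing position dropped",
                    sum(!mono)))
    idx <- idx[mono]; chrom <- chrom[mono]; pos <- pos[mono]
  }

  n_ind <- nrow(popmap)
  mat <- matrix(0L, length(idx), 2L * n_ind)
  for (j in seq_len(n_ind)) {
    g <- gt[idx, j]
    mat[, 2L * j - 1L] <- as.integer(substr(g, 1L, 1L))
    mat[, 2L * j]      <- as.integer(substr(g, 3L, 3L))
  }
  fl <- which(flip[idx])
  if (length(fl) > 0L) mat[fl, ] <- 1L - mat[fl, , drop = FALSE]

  out <- list()
  for (ct in unique(chrom)) {
    s <- chrom == ct
    out[[ct]] <- haplotype_matrix(
      ct, pos[s], mat[s, , drop = FALSE], popmap$sample, popmap$group,
      polarized = require_aa,
      ref = toupper(fix[idx[s], "REF"]), alt = toupper(fix[idx[s], "ALT"]),
      aa = if (require_aa) aa[idx[s]] else NULL)
  }
  attr(out, "counts") <- counts
  out
}

#' Write a haplotype matrix as a phased VCF
#'
#' Positions are written 1-based (VCF convention).  When the matrix is
#' polarized, the AA INFO tag records the ancestral base so that
#' [read_phased_vcf()] with `require_aa = TRUE` round-trips the matrix
#' exactly.  Output is deterministic (no timestamps).
#'
#' @param hm a [haplotype_matrix()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_phased_vcf <- function(hm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=sweepscan-%s", as.character(packageVersion("sweepscan"))),
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    sprintf("##contig=<ID=%s>", unique(hm$contig)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", hm$sample_ids), collapse = "\t")), con)
  if (n_sites(hm) == 0L) return(invisible(path))
  a <- hm$alleles
  n_ind <- length(hm$sample_ids)
  gt_cols <- vapply(seq_len(n_ind), function(j)
    paste0(a[, 2L * j - 1L], "|", a[, 2L * j]), character(nrow(a)))
  if (is.null(dim(gt_cols)))
    gt_cols <- matrix(gt_cols, nrow = 1L)
  info <- if (!is.null(hm$aa)) paste0("AA=", hm$aa) else "."
  lines <- paste(hm$contig, hm$pos, ".", hm$ref, hm$alt, ".", "PASS",
                 info, "GT",
                 apply(gt_cols, 1L, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Minor-allele-frequency filter
#'
#' Retains exactly the sites where the minor allele frequency is strictly
#' greater than `maf_min` in every named group (the scan convention of
#' pruning SNPs for MAF > 1% in each population).
#'
#' @param hm a [haplotype_matrix()].
#' @param groups character vector of group names to test.
#' @param maf_min minimum minor allele frequency, in `[0, 0.5]`.
#' @return A filtered [haplotype_matrix()].
#' @export
filter_maf <- function(hm, groups = unique(hm$pop), maf_min = 0.01) {
  if (maf_min < 0 || maf_min > 0.5)
    stop_input("maf_min must be in [0, 0.5], got %g", maf_min)
  keep <- rep(TRUE, n_sites(hm))
  for (g in groups) {
    f <- pop_freq(hm, g)   # errors on absent/empty group
    keep <- keep & pmin(f, 1 - f) > maf_min
  }
  hm_subset(hm, keep)
}
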