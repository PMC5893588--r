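#' Extended haplotype homozygosity decay from a core site
#'
#' Moving away from the core, the population's haplotypes are partitioned
#' by their allele string from the core to the current site; EHH is the
#' probability that two distinct haplotypes belong to the same class,
#' `sum_h C(c_h, 2) / C(c, 2)`.  The decay starts at 1 at the core and is
#' recorded at every informative site until it drops below `cutoff`,
#' `max_extend` is exceeded, or the contig ends.
#'
#' @param hm a [haplotype_matrix()].
#' @param pop population label.
#' @param core_index site index of the core SNP.
#' @param direction `"left"` or `"right"`.
#' @param cutoff stop when EHH falls below this value (that value is not
#'   recorded).
#' @param max_extend maximum extension from the core, bp.
#' @return An object of class `ehh_decay`: list with `core_index`, `pop`,
#'   `direction`, `offset` (bp, 0 first) and `ehh`.
#' @export
ehh <- function(hm, pop, core_index, direction = c("right", "left"),
                cutoff = 0.05, max_extend = Inf) {
  direction <- match.arg(direction)
  cols <- hap_cols(hm, pop)
  c_n <- length(cols)
  if (c_n < 2L) stop_input("population '%s' must have >= 2 haplotypes", pop)
  step <- if (direction == "right") 1L else -1L
  n <- n_sites(hm)
  stopifnot(core_index >= 1L, core_index <= n)
  denom <- c_n * (c_n - 1) / 2
  grp <- rep(1L, c_n)
  offs <- 0
  vals <- 1
  j <- core_index + step
  while (j >= 1L && j <= n) {
    if (hm$contig[j] != hm$contig[core_index]) break
    d <- abs(hm$pos[j] - hm$pos[core_index])
    if (d > max_extend) break
    grp <- as.integer(interaction(grp, hm$alleles[j, cols], drop = TRUE))
    cnt <- tabulate(grp)
    e <- sum(cnt * (cnt - 1) / 2) / denom
    if (e < cutoff) break
    offs <- c(offs, d * step)
    vals <- c(vals, e)
    j <- j + step
  }
  structure(list(core_index = core_index, pop = pop, direction = direction,
                 offset = offs, ehh = vals), class = "ehh_decay")
}

#' Integrated EHH (iHH) at every site for one population
#'
#' Integral over bp of the EHH decay (left plus right) for every core SNP.
#' EHH is a step function of distance — it changes only at informative
#' sites — and the integral covers each inter-site gap with the EHH value
#' carried into it, truncating at the first site where EHH < `cutoff`
#' (that terminal gap is still covered), at `max_extend`, or at the contig
#' end.
#'
#' @inheritParams xpehh_scan
#' @param pop population label.
#' @return Numeric vector, one iHH (bp) per site.
#' @export
xpehh_ihh <- function(hm, pop, cutoff = 0.05, max_extend = 1e6) {
  cols <- hap_cols(hm, pop)
  if (length(cols) < 2L) stop_input("population needs >= 2 haplotypes")
  contig_code <- as.integer(factor(hm$contig, levels = unique(hm$contig)))
  ihh_cpp(hm$alleles, hm$pos, contig_code, cols, cutoff, max_extend)
}

#' Cross-population EHH (XP-EHH) scan
#'
#' For every core SNP, the integrated EHH (iHH, integral of the EHH decay
#' over bp as in [xpehh_ihh()], left plus right, truncated where EHH <
#' `cutoff`) is computed in both populations; the raw statistic is
#' `ln(iHH_A / iHH_B)`
#' and is normalized genome-wide by subtracting the mean and dividing by
#' the standard deviation over all scanned SNPs.  SNPs where either iHH is
#' zero are dropped and counted.  MAF pruning (see [filter_maf()]) is
#' expected to have been applied beforehand.
#'
#' @param hm a [haplotype_matrix()].
#' @param pop_a,pop_b population labels; extreme positive normalized scores
#'   suggest a sweep in `pop_a`, extreme negative in `pop_b`.
#' @param cutoff EHH truncation level.
#' @param max_extend maximum extension from each core, bp.
#' @return A data.frame of class `xpehh_track` with columns `contig`,
#'   `pos`, `ihh_a`, `ihh_b`, `raw`, `z`; attributes `mean`, `sd`,
#'   `n_dropped`.
#' @export
xpehh_scan <- function(hm, pop_a, pop_b, cutoff = 0.05, max_extend = 1e6) {
  cols_a <- hap_cols(hm, pop_a)
  cols_b <- hap_cols(hm, pop_b)
  if (length(cols_a) < 2L || length(cols_b) < 2L)
    stop_input("both populations need >= 2 haplotypes")
  contig_code <- as.integer(factor(hm$contig, levels = unique(hm$contig)))
  ihh_a <- ihh_cpp(hm$alleles, hm$pos, contig_code, cols_a, cutoff, max_extend)
  ihh_b <- ihh_cpp(hm$alleles, hm$pos, contig_code, cols_b, cutoff, max_extend)
  ok <- is.finite(ihh_a) & is.finite(ihh_b) & ihh_a > 0 & ihh_b > 0
  n_dropped <- sum(!ok)
  if (sum(ok) < 2L)
    stop_input("fewer than 2 scored SNPs; cannot normalize")
  raw <- log(ihh_a[ok] / ihh_b[ok])
  mu <- mean(raw)
  sigma <- sd(raw)
  if (sigma == 0) {
    warning("all raw XP-EHH values identical (e.g. identical populations); ",
            "z-scores undefined and set to NA")
    z <- rep(NA_real_, length(raw))
  } else {
    z <- (raw - mu) / sigma
  }
  out <- data.frame(contig = hm$contig[ok], pos = hm$pos[ok],
                    ihh_a = ihh_a[ok], ihh_b = ihh_b[ok], raw = raw,
                    z = z, stringsAsFactors = FALSE)
  attr(out, "mean") <- mu
  attr(out, "sd") <- sigma
  attr(out, "n_dropped") <- n_dropped
  attr(out, "pops") <- c(A = pop_a, B = pop_b)
  class(out) <- c("xpehh_track", "data.frame")
  out
}

#' Select XP-EHH candidate windows and assign genes
#'
#' The genome is tiled into non-overlapping windows of `window_bp`; each
#' window is represented by its SNP with the largest `|z|`.  A window is an
#' upper (population A) candidate when its top SNP's z strictly exceeds the
#' `upper_q` quantile of all window-top z values, and a lower (population
#' B) candidate when it falls strictly below the `lower_q` quantile.  Genes
#' within `flank_bp` of the top SNP are attached.  The realized thresholds
#' are reported alongside (they are data-dependent quantiles, never
#' constants).
#'
#' @param track an `xpehh_track` from [xpehh_scan()].
#' @param upper_q,lower_q quantiles of the window-top z distribution.
#' @param window_bp window size, bp (> 0).
#' @param genes optional [gene_set()].
#' @param flank_bp flank around the top SNP for gene assignment, bp.
#' @return A list of class `xpehh_candidates`: data.frames `upper` and
#'   `lower` (columns `contig`, `win_start`, `win_end`, `pos`, `z`,
#'   `genes`), plus `thresholds` and `n_windows`.
#' @export
select_candidates <- function(track, upper_q = 0.999, lower_q = 0.001,
                              window_bp = 50000, genes = NULL,
                              flank_bp = 5000) {
  stopifnot(nrow(track) > 0L)
  if (window_bp <= 0) stop_input("window_bp must be > 0")
  win <- (track$pos - 1L) %/% as.integer(window_bp)
  key <- paste(track$contig, win, sep = "\r")
  top_idx <- vapply(split(seq_len(nrow(track)), key), function(ii)
    ii[which.max(abs(track$z[ii]))], integer(1))
  tops <- data.frame(
    contig = track$contig[top_idx],
    win_start = win[top_idx] * window_bp + 1,
    win_end = (win[top_idx] + 1) * window_bp,
    pos = track$pos[top_idx], z = track$z[top_idx],
    stringsAsFactors = FALSE)
  thr_hi <- quantile(tops$z, upper_q, names = FALSE, type = 7)
  thr_lo <- quantile(tops$z, lower_q, names = FALSE, type = 7)
  annotate <- function(d) {
    d <- d[order(d$contig, d$pos), , drop = FALSE]
    d$genes <- vapply(seq_len(nrow(d)), function(r)
      paste(genes_near(genes, d$contig[r], d$pos[r], d$pos[r], flank_bp),
            collapse = ","), character(1))
    rownames(d) <- NULL
    d
  }
  structure(list(
    upper = annotate(tops[tops$z > thr_hi, , drop = FALSE]),
    lower = annotate(tops[tops$z < thr_lo, , drop = FALSE]),
    thresholds = c(upper = thr_hi, lower = thr_lo),
    n_windows = nrow(tops),
    params = list(upper_q = upper_q, lower_q = lower_q,
                  window_bp = window_bp, flank_bp = flank_bp)),
    class = "xpehh_candidates")
}

#' @export
print.xpehh_candidates <- function(x, ...) {
  cat(sprintf(
    "xpehh_candidates: %d window(s); thresholds z > %.3f / z < %.3f\n",
    x$n_windows, x$thresholds["upper"], x$thresholds["lower"]))
  cat(sprintf("  upper (pop A) candidates: %d, lower (pop B): %d\n",
              nrow(x$upper), nrow(x$lower)))
  invisible(x)
}

#' Haplotype bifurcation tree from a core allele
#'
#' Restricted to the haplotypes carrying `core_allele` at the core site,
#' the tree records the successive splits of the haplotype classes at each
#' informative site moving away from the core; each node carries the number
#' of haplotypes in its class, and children counts sum to their parent's.
#'
#' @param hm a [haplotype_matrix()].
#' @param pop population label.
#' @param core_index core site index.
#' @param core_allele 0 or 1.
#' @param direction `"left"` or `"right"`.
#' @param max_sites number of sites to extend over.
#' @return A nested list of class `bifurcation_tree`: nodes have `count`
#'   and `children` (named by the allele taken).
#' @export
bifurcation <- function(hm, pop, core_index, core_allele = 1L,
                        direction = c("right", "left"), max_sites = 10L) {
  direction <- match.arg(direction)
  cols <- hap_cols(hm, pop)
  carriers <- cols[hm$alleles[core_index, cols] == core_allele]
  if (length(carriers) == 0L)
    stop_input("no haplotype carries allele %d at the core", core_allele)
  step <- if (direction == "right") 1L else -1L
  n <- n_sites(hm)
  build <- function(hap_cols_here, j, depth) {
    node <- list(count = length(hap_cols_here), children = list())
    if (depth >= max_sites || j < 1L || j > n) return(node)
    if (hm$contig[j] != hm$contig[core_index]) return(node)
    a <- hm$alleles[j, hap_cols_here]
    for (al in sort(unique(a))) {
      node$children[[as.character(al)]] <-
        build(hap_cols_here[a == al], j + step, depth + 1L)
    }
    node
  }
  tree <- build(carriers, core_index + step, 0L)
  class(tree) <- "bifurcation_tree"
  tree
}

#' Serialize a bifurcation tree as Newick with counts as labels
#' @param tree a [bifurcation()] tree.
#' @return A Newick string, e.g. `"((2,1)3);"`.
#' @export
bifurcation_newick <- function(tree) {
  rec <- function(node) {
    if (length(node$children) == 0L) return(as.character(node$count))
    paste0("(", paste(vapply(node$children, rec, character(1)),
                      collapse = ","), ")", node$count)
  }
  paste0(rec(tree), ";")
}

#' @export
print.bifurcation_tree <- function(x, ...) {
  cat("bifurcation_tree:", bifurcation_newick(x), "\n")
  invisible(x)
}
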