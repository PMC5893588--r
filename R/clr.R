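# Composite likelihood ratio sweep scan.
#
# The sweep model is a star-like genealogy transform of the background SFS:
# at distance d from a sweep of intensity alpha (per bp), each of the n
# sampled lineages escapes the sweep independently with probability
#   p_e = 1 - exp(-alpha * d).
# Conditional on e escaped lineages, the n - e swept lineages descend from a
# single ancestral lineage.  With the pre-sweep derived frequency p_j = j/n
# drawn from the background spectrum phi:
#   e <  n : the ancestral lineage of the swept class is derived with
#            probability p_j, so
#            P(k) = p_j * Bin(k - (n - e); e, p_j) + (1 - p_j) * Bin(k; e, p_j)
#   e == n : every lineage escaped, i.e. the sample is untouched by the
#            sweep; its count distribution is the background itself, phi_k.
# The e = n class is the exchangeable background draw (rather than a
# binomial resampling of it) so that the model is exactly nested in the
# neutral model: as alpha -> infinity, P(k) -> phi_k and the CLR -> 0.
# Finally, substitutions are excluded by renormalizing over k = 1..n-1
# (polymorphic conditioning), symmetrically in numerator and denominator.

# per-(k,j) escape tensor, independent of phi and p_e: T[k, j, e + 1] for
# e = 0..n-1 (the e = n class is handled via phi directly); cached per n
.sweep_cache <- new.env(parent = emptyenv())

sweep_escape_tensor <- function(n) {
  key <- as.character(n)
  if (!is.null(.sweep_cache[[key]])) return(.sweep_cache[[key]])
  ks <- seq_len(n - 1L)
  js <- seq_len(n - 1L)
  es <- 0:(n - 1L)
  k_arr <- array(rep(ks, times = (n - 1L) * n), dim = c(n - 1L, n - 1L, n))
  j_arr <- array(rep(rep(js, each = n - 1L), times = n),
                 dim = c(n - 1L, n - 1L, n))
  e_arr <- array(rep(es, each = (n - 1L) * (n - 1L)),
                 dim = c(n - 1L, n - 1L, n))
  p_arr <- j_arr / n
  tens <- p_arr * dbinom(k_arr - (n - e_arr), e_arr, p_arr) +
    (1 - p_arr) * dbinom(k_arr, e_arr, p_arr)
  tens <- matrix(tens, nrow = (n - 1L) * (n - 1L), ncol = n)  # (k,j) x e
  .sweep_cache[[key]] <- tens
  tens
}

# unfolded sweep-model pmf over k = 1..n-1 for exact escape probabilities
# pe (vector); phi_u must be an unfolded spectrum over 1..n-1
sweep_model_pmf <- function(n, phi_u, pe) {
  tens <- sweep_escape_tensor(n)
  w <- vapply(pe, function(p) dbinom(0:n, n, p), numeric(n + 1L))  # (e) x pe
  head_w <- w[seq_len(n), , drop = FALSE]
  g <- tens %*% head_w                             # (k,j) x pe
  dim(g) <- c(n - 1L, n - 1L, length(pe))
  out <- vapply(seq_along(pe), function(b)
    as.numeric(g[, , b] %*% phi_u), numeric(n - 1L))
  out <- out + outer(phi_u, w[n + 1L, ])           # e = n: background draw
  tot <- colSums(out)
  # pe = 0: every lineage swept, so conditional on polymorphism only the
  # e = 1 escape class survives in the limit, putting equal mass on the
  # singleton classes k = 1 and k = n - 1
  zero <- tot == 0
  if (any(zero)) {
    out[, zero] <- 0
    out[1L, zero] <- 0.5
    out[n - 1L, zero] <- 0.5
    tot[zero] <- 1
  }
  out <- sweep(out, 2L, tot, "/")                  # polymorphic conditioning
  out                                              # (n-1) x length(pe)
}

# fold an unfolded pmf matrix (rows k = 1..n-1) onto minor counts
fold_pmf <- function(p_mat, n) {
  half <- n %/% 2L
  out <- p_mat[seq_len(half), , drop = FALSE]
  for (k in seq_len(half)) {
    if (n - k != k) out[k, ] <- out[k, ] + p_mat[n - k, , drop = FALSE]
  }
  out
}

# represent a (possibly folded) background as an unfolded spectrum for the
# sweep transform: folded mass is split evenly between k and n - k
unfold_phi <- function(sfs) {
  n <- sfs$n
  if (!sfs$folded) return(sfs$phi)
  phi_u <- numeric(n - 1L)
  for (k in seq_along(sfs$phi)) {
    if (n - k == k) phi_u[k] <- sfs$phi[k]
    else {
      phi_u[k] <- sfs$phi[k] / 2
      phi_u[n - k] <- sfs$phi[k] / 2
    }
  }
  phi_u
}

#' Sweep-model probability of an allele count
#'
#' Probability of observing `k` derived (or minor, for a folded background)
#' alleles among `n` at physical distance `d` from a sweep of intensity
#' `alpha` per bp, given the genome-wide background spectrum.  See the
#' package vignette for the star-like genealogy model.
#'
#' @param k allele count(s), in `1..n-1` (unfolded) or `1..floor(n/2)`
#'   (folded background).
#' @param n haploid sample size (must equal `sfs$n`).
#' @param d distance from the proposed sweep site, bp (>= 0).
#' @param alpha sweep intensity per bp (> 0; the model is degenerate at
#'   `alpha * d = 0` only in the sense that all lineages are swept).
#' @param sfs background [background_sfs()].
#' @return Numeric vector of probabilities, renormalized over the
#'   polymorphic classes.
#' @export
sweep_site_prob <- function(k, n, d, alpha, sfs) {
  stopifnot(inherits(sfs, "sfs"))
  if (n != sfs$n) stop_input("n (%d) must match sfs$n (%d)", n, sfs$n)
  if (d < 0 || alpha < 0) stop_input("d and alpha must be >= 0")
  kmax <- if (sfs$folded) n %/% 2L else n - 1L
  if (any(k < 1L | k > kmax))
    stop_input("k out of range 1..%d", kmax)
  pe <- -expm1(-alpha * d)
  phi_u <- unfold_phi(sfs)
  pmf <- sweep_model_pmf(n, phi_u, pe)
  if (sfs$folded) {
    pmf <- fold_pmf(pmf, n)
    pmf <- pmf / sum(pmf)
  }
  pmf[k, 1L]
}

# escape-probability grid used to discretize the model inside the scan;
# log-dense near both endpoints, with 0 and 1 exact
pe_grid <- function() {
  unique(sort(c(0, 1, 0.5,
                10^seq(-8, log10(0.5), length.out = 220),
                1 - 10^seq(-8, log10(0.5), length.out = 220))))
}

#' Composite likelihood ratio scan for selective sweeps
#'
#' For each grid position L along every contig,
#'   CLR(L) = 2 max_alpha sum_i ( log P(k_i; d_i, alpha) - log phi_(k_i) )
#' over the sites within `window_bp` of L, where P is the sweep model of
#' [sweep_site_prob()] and phi the genome-wide background.  alpha is
#' maximized over a fixed logarithmic grid, which keeps the scan
#' deterministic; the neutral model is always included as the alpha ->
#' infinity boundary of the family (reported as `alpha_hat = Inf`), so the
#' model nests the background exactly and CLR >= 0 everywhere.  Grid points
#' with no sites in the window get CLR 0 and are flagged.
#'
#' @param hm a [haplotype_matrix()].
#' @param group population to scan.
#' @param sfs background spectrum; computed from `hm`/`group` when `NULL`.
#' @param folded fold the spectrum?  Defaults to folded when `hm` is not
#'   polarized.  Requesting unfolded on unpolarized data is an error
#'   (ancestral states unknown; run in folded mode).
#' @param grid_step spacing of test positions, bp.
#' @param alpha_grid intensities to maximize over (per bp); must contain a
#'   value large enough that `exp(-alpha * window_bp) < 1e-12`.
#' @param window_bp half-width of the window of sites scored at each grid
#'   point.
#' @param include_snp_positions also test every SNP position?
#' @return A data.frame of class `clr_track` with columns `contig`, `pos`,
#'   `clr`, `alpha_hat`, `n_sites_window`.
#' @export
clr_scan <- function(hm, group, sfs = NULL, folded = !hm$polarized,
                     grid_step = 10000, alpha_grid = NULL,
                     window_bp = 100000, include_snp_positions = FALSE) {
  if (!hm$polarized && !folded)
    stop_input(paste0("data are not polarized (no ancestral annotation): ",
                      "an unfolded scan is impossible; run in folded mode"))
  if (grid_step <= 0) stop_input("grid_step must be > 0")
  if (is.null(alpha_grid))
    alpha_grid <- 10^seq(-8, -1, length.out = 40)
  if (min(exp(-max(alpha_grid) * window_bp)) >= 1e-12)
    stop_input("alpha_grid must contain a value with exp(-alpha*window_bp) < 1e-12")
  if (is.null(sfs)) sfs <- background_sfs(hm, group, folded = folded)
  n <- sfs$n
  cols <- hap_cols(hm, group)
  stopifnot(length(cols) == n)

  k_all <- as.integer(rowSums(hm$alleles[, cols, drop = FALSE]))
  poly <- k_all > 0L & k_all < n
  if (folded) k_all <- pmin(k_all, n - k_all)

  # discretized model: log P(k | pe bin), exact at pe = 0 and pe = 1
  pe <- pe_grid()
  pmf <- sweep_model_pmf(n, unfold_phi(sfs), pe)
  if (folded) {
    pmf <- fold_pmf(pmf, n)
    pmf <- sweep(pmf, 2L, colSums(pmf), "/")
  }
  log_pmf <- log(pmf)
  log_phi <- log(sfs$phi)
  cuts <- c(-Inf, (pe[-1L] + pe[-length(pe)]) / 2, Inf)  # nearest-bin edges

  res <- list()
  for (ct in unique(hm$contig)) {
    in_ct <- hm$contig == ct & poly
    pos <- hm$pos[in_ct]
    k <- k_all[in_ct]
    pmax_ct <- max(hm$pos[hm$contig == ct])
    grid <- seq(grid_step, pmax_ct + grid_step - 1, by = grid_step)
    if (include_snp_positions) grid <- sort(unique(c(grid, pos)))
    clr <- numeric(length(grid))
    a_hat <- rep(NA_real_, length(grid))
    nw <- integer(length(grid))
    for (gi in seq_along(grid)) {
      L <- grid[gi]
      sel <- which(pos >= L - window_bp & pos <= L + window_bp)
      nw[gi] <- length(sel)
      if (length(sel) == 0L) next
      d <- pmax(abs(pos[sel] - L), 1)  # a site on the grid point itself is
                                       # scored at 1 bp, not at the pe = 0
                                       # degenerate limit
      ks <- k[sel]
      null_ll <- sum(log_phi[ks])
      pe_mat <- -expm1(-outer(d, alpha_grid))           # sites x alphas
      bins <- findInterval(pe_mat, cuts)
      ll <- colSums(matrix(
        log_pmf[cbind(rep(ks, times = length(alpha_grid)), as.vector(bins))],
        nrow = length(sel)))
      ll <- c(ll, null_ll)  # alpha -> Inf boundary: the background itself
      best <- which.max(ll)
      clr[gi] <- 2 * (ll[best] - null_ll)
      a_hat[gi] <- c(alpha_grid, Inf)[best]
    }
    res[[ct]] <- data.frame(contig = ct, pos = grid, clr = clr,
                            alpha_hat = a_hat, n_sites_window = nw,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "group") <- group
  attr(out, "folded") <- folded
  attr(out, "params") <- list(grid_step = grid_step, window_bp = window_bp,
                              alpha_grid = alpha_grid)
  class(out) <- c("clr_track", "data.frame")
  out
}

#' Call sweep peaks from a CLR track and assign genes
#'
#' The threshold is the `1 - top_quantile` empirical quantile of all CLR
#' values ("a CLR higher than `top_quantile` of all CLRs"); contiguous
#' super-threshold grid runs are merged into intervals, ranked by their peak
#' CLR, and the strongest `max_peaks` returned.  Genes overlapping each
#' interval extended by `flank_bp` on both sides are attached.
#'
#' @param track a `clr_track` from [clr_scan()].
#' @param top_quantile upper tail fraction defining the threshold.
#' @param max_peaks maximum number of peaks returned.
#' @param genes optional [gene_set()].
#' @param flank_bp flank for gene assignment, bp.
#' @return A data.frame of class `sweep_peaks` with columns `contig`,
#'   `start`, `end`, `peak_pos`, `peak_clr`, `genes` (comma-separated).
#' @export
call_peaks <- function(track, top_quantile = 0.002, max_peaks = 20,
                       genes = NULL, flank_bp = 1e6) {
  stopifnot(nrow(track) > 0L)
  thr <- quantile(track$clr, 1 - top_quantile, names = FALSE, type = 7)
  above <- track$clr > thr
  out <- data.frame(contig = character(0), start = integer(0),
                    end = integer(0), peak_pos = integer(0),
                    peak_clr = numeric(0), genes = character(0),
                    stringsAsFactors = FALSE)
  if (any(above)) {
    idx <- which(above)
    brk <- c(0L, which(diff(idx) > 1L |
                         track$contig[idx[-1L]] !=
                           track$contig[idx[-length(idx)]]),
             length(idx))
    runs <- lapply(seq_len(length(brk) - 1L), function(r)
      idx[(brk[r] + 1L):brk[r + 1L]])
    out <- do.call(rbind, lapply(runs, function(ii) {
      pk <- ii[which.max(track$clr[ii])]
      data.frame(contig = track$contig[pk],
                 start = min(track$pos[ii]), end = max(track$pos[ii]),
                 peak_pos = track$pos[pk], peak_clr = track$clr[pk],
                 genes = NA_character_, stringsAsFactors = FALSE)
    }))
    out <- out[order(-out$peak_clr), , drop = FALSE]
    out <- head(out, max_peaks)
    if (!is.null(genes) && nrow(out) > 0L) {
      out$genes <- vapply(seq_len(nrow(out)), function(r)
        paste(genes_near(genes, out$contig[r], out$start[r], out$end[r],
                         flank_bp), collapse = ","),
        character(1))
    }
    rownames(out) <- NULL
  }
  attr(out, "threshold") <- thr
  attr(out, "params") <- list(top_quantile = top_quantile,
                              max_peaks = max_peaks, flank_bp = flank_bp)
  class(out) <- c("sweep_peaks", "data.frame")
  out
}
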