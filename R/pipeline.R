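# End-to-end pipeline stages.  Results go to files, log lines to stderr
# (via message()), nothing on stdout.

log_msg <- function(fmt, ...) message(sprintf(paste0("[sweepscan] ", fmt), ...))

#' Generate a synthetic gene annotation for a simulated genome
#'
#' Uniformly placed, non-overlapping gene intervals per contig, for
#' exercising the peak/candidate gene-assignment rules on simulated data.
#' Purely synthetic; lengths and counts are configurable.
#'
#' @param contigs character vector of contig names.
#' @param seq_len contig length, bp.
#' @param n_per_contig genes per contig.
#' @param min_len,max_len gene length range, bp.
#' @return A [gene_set()] (0-based half-open).
#' @export
synthetic_genes <- function(contigs, seq_len, n_per_contig = 25,
                            min_len = 2000, max_len = 10000) {
  res <- lapply(contigs, function(ct) {
    len <- as.integer(runif(n_per_contig, min_len, max_len))
    start <- sort(as.integer(runif(n_per_contig, 0, seq_len - max_len)))
    # push overlapping neighbours apart; drop any that fall off the contig
    for (i in seq_len(n_per_contig)[-1L]) {
      if (start[i] < start[i - 1L] + len[i - 1L])
        start[i] <- start[i - 1L] + len[i - 1L] + 1L
    }
    keep <- start + len <= seq_len
    data.frame(contig = ct, start = start[keep],
               end = (start + len)[keep],
               strand = rep_len(c("+", "-"), sum(keep)),
               gene = sprintf("%s_g%03d", ct, which(keep)),
               stringsAsFactors = FALSE)
  })
  g <- do.call(rbind, res)
  class(g) <- c("gene_set", "data.frame")
  g
}

write_genes_bed <- function(genes, path) {
  con <- file(path, "w")
  writeLines(paste(genes$contig, genes$start, genes$end, genes$gene, 0,
                   genes$strand, sep = "\t"), con)
  close(con)
  invisible(path)
}

#' Run the full synthetic demonstration pipeline
#'
#' Simulates a three-population dataset (a freshwater-like population
#' carrying a selective sweep plus two marine-like relatives), writes it as
#' VCF/popmap/truth, reads it back, and runs every scan: CLR sweep scan
#' with peak calling, MAF filtering and XP-EHH with candidate windows,
#' allele-frequency differences with empirical P-values, per-SNP F_ST, and
#' the f3 admixture test.  All result tracks are written as deterministic
#' TSVs, plus a machine-readable `summary.json`.
#'
#' @param outdir output directory.
#' @param seed integer seed (overrides the config seed).
#' @param cfg configuration from [default_config()] / [load_config()].
#' @return Invisibly, the summary list.
#' @export
run_demo <- function(outdir, seed = 1L, cfg = default_config()) {
  cfg$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  scfg <- config_sim(cfg)
  log_msg("simulating: %d pops, Ne=%d, %d contig(s) x %g bp, seed=%d",
          length(scfg$pop_names), scfg$Ne, scfg$n_contigs, scfg$seq_len,
          cfg$seed)
  sim <- wf_simulate(scfg)
  log_msg("simulated %d segregating sites (sweep restarts: %d)",
          n_sites(sim$hm), sim$truth$n_restarts)
  paths <- write_sim(sim, outdir)

  genes <- synthetic_genes(unique(sim$hm$contig), scfg$seq_len,
                           cfg$genes$n_per_contig, cfg$genes$min_len,
                           cfg$genes$max_len)
  write_genes_bed(genes, file.path(outdir, "genes.bed"))

  hm <- hm_bind(read_phased_vcf(paths["vcf"], paths["popmap"],
                                require_aa = TRUE))
  log_msg("re-read VCF: %d sites, %d samples", n_sites(hm),
          length(hm$sample_ids))
  pops <- scfg$pop_names
  meta <- list(seed = cfg$seed)

  # CLR sweep scan in the sweep population
  sfs <- background_sfs(hm, pops[1L], folded = FALSE)
  clr <- clr_scan(hm, pops[1L], sfs = sfs, folded = FALSE,
                  grid_step = cfg$clr$grid_step,
                  alpha_grid = config_alpha_grid(cfg),
                  window_bp = cfg$clr$window_bp)
  write_track(clr, file.path(outdir, "clr_track.tsv"),
              c(meta, group = pops[1L],
                cfg$clr[c("grid_step", "window_bp")]))
  peaks <- call_peaks(clr, cfg$clr$top_quantile, cfg$clr$max_peaks, genes,
                      cfg$clr$flank_bp)
  write_track(peaks, file.path(outdir, "clr_peaks.tsv"),
              c(meta, cfg$clr[c("top_quantile", "max_peaks", "flank_bp")],
                threshold = attr(peaks, "threshold")))
  log_msg("CLR scan: %d grid points, %d peak(s) above the top-%.1f%% threshold",
          nrow(clr), nrow(peaks), 100 * cfg$clr$top_quantile)

  # XP-EHH between the sweep population and its closest marine relative
  hm_maf <- filter_maf(hm, pops[1:2], cfg$maf$min)
  log_msg("MAF > %g%% in both groups: %d of %d sites kept",
          100 * cfg$maf$min, n_sites(hm_maf), n_sites(hm))
  xp <- xpehh_scan(hm_maf, pops[1L], pops[2L], cfg$xpehh$cutoff,
                   cfg$xpehh$max_extend)
  write_track(xp, file.path(outdir, "xpehh_track.tsv"),
              c(meta, popA = pops[1L], popB = pops[2L],
                cfg$xpehh[c("cutoff", "max_extend")]))
  cand <- select_candidates(xp, cfg$xpehh$upper_q, cfg$xpehh$lower_q,
                            cfg$xpehh$window_bp, genes, cfg$xpehh$flank_bp)
  write_track(cand$upper, file.path(outdir, "xpehh_candidates_a.tsv"),
              c(meta, threshold = unname(cand$thresholds["upper"])))
  write_track(cand$lower, file.path(outdir, "xpehh_candidates_b.tsv"),
              c(meta, threshold = unname(cand$thresholds["lower"])))
  log_msg("XP-EHH: %d SNPs scored; thresholds %.3f / %.3f; %d + %d candidates",
          nrow(xp), cand$thresholds["upper"], cand$thresholds["lower"],
          nrow(cand$upper), nrow(cand$lower))

  # allele-frequency differences and F_ST on the same pair
  fd <- freq_diff(hm_maf, pops[1L], pops[2L])
  write_track(fd, file.path(outdir, "freqdiff.tsv"),
              c(meta, td = attr(fd, "td"), n_snps = attr(fd, "n_snps")))
  fst <- wc_fst(hm_maf, pops[1L], pops[2L])
  write_track(fst, file.path(outdir, "fst.tsv"), meta)

  # f3 admixture test: is the freshwater population admixed?
  f3_res <- f3(hm, pops[1L], pops[2L], pops[3L], cfg$f3$block_bp)
  write_f3_report(f3_res, file.path(outdir, "f3.txt"),
                  c(meta, block_bp = cfg$f3$block_bp))
  log_msg("f3(%s; %s, %s) = %.4g (Z = %.1f)", pops[1L], pops[2L], pops[3L],
          f3_res$f3, f3_res$z)

  truth <- sim$truth
  near <- hm$contig == truth$sweep_contig &
    abs(hm$pos - truth$sweep_pos) <= 1e5
  best <- clr[which.max(clr$clr), ]
  summary <- list(
    seed = cfg$seed,
    n_snps = n_sites(hm),
    n_snps_maf = n_sites(hm_maf),
    sweep = list(contig = truth$sweep_contig, pos = truth$sweep_pos,
                 final_freq = as.list(truth$sweep_freq),
                 restarts = truth$n_restarts),
    clr = list(max = best$clr, max_pos = best$pos, max_contig = best$contig,
               peak_distance_bp =
                 if (best$contig == truth$sweep_contig)
                   abs(best$pos - truth$sweep_pos) else NA,
               n_peaks = nrow(peaks)),
    xpehh = list(thresholds = as.list(cand$thresholds),
                 n_upper = nrow(cand$upper), n_lower = nrow(cand$lower),
                 mean_z_near_sweep = mean(xp$z[xp$contig ==
                   truth$sweep_contig & abs(xp$pos - truth$sweep_pos) <= 1e5])),
    freq = list(td = attr(fd, "td"),
                min_emp_p = min(fd$emp_p),
                max_sq_diff = max(fd$sq_diff)),
    fst = list(overall = fst_overall(fst),
               mean_near_sweep = mean(
                 fst$fst[fst$contig == truth$sweep_contig &
                           abs(fst$pos - truth$sweep_pos) <= 1e5],
                 na.rm = TRUE)),
    f3 = list(f3 = f3_res$f3, se = f3_res$se, z = f3_res$z))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(summary)
}
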