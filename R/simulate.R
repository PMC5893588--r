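#' Simulation configuration
#'
#' Describes a forward Wright-Fisher simulation: a single ancestral
#' population of `Ne` diploids evolves for `burn_factor * Ne` burn-in
#' generations, splits instantaneously into `n_pops` isolated copies (no
#' migration), and evolves `split_gens` further generations with
#' infinite-sites mutation and uniform recombination.  Optionally one
#' population receives a single beneficial mutation with additive fitness
#' (1, 1 + s/2, 1 + s), conditioned on non-loss by restarting from the
#' injection state; optionally an admixed population is founded from two of
#' the split populations and evolves for the remaining generations.
#'
#' The default mutation rate (1.10e-8 per site per generation) and
#' generation time (8 years, used only to report times in years) are the
#' values used for the porpoise demographic reconstructions this package's
#' scans are designed around.
#'
#' @param n_pops number of populations after the split.
#' @param Ne diploid effective size of every population.
#' @param split_gens generations between the split and sampling.
#' @param sample_sizes diploids sampled per population (recycled; must also
#'   cover the admixed population when `admixture` is set).
#' @param seq_len contig length in bp.
#' @param n_contigs number of independently simulated contigs (unlinked
#'   chromosomes; the sweep, if any, is placed on the first).
#' @param mu per-site per-generation mutation rate.
#' @param rec_rate per-site per-generation recombination rate.
#' @param gen_time_years generation time, for reporting only.
#' @param sweep optional `list(pop =, pos =, s =, origin_gen =)`: population
#'   index, position in bp, selection coefficient, and generations after the
#'   split at which the beneficial mutation arises.
#' @param admixture optional `list(sources = c(i, j), props = c(p, 1 - p),
#'   gens_ago =)`: an extra population founded `gens_ago` generations before
#'   sampling from the two source populations.
#' @param pop_names population names (admixed population named last).
#' @param seed integer seed; every run with the same config is
#'   byte-identical.
#' @param burn_factor burn-in length in units of Ne generations (>= 10).
#' @param max_restarts restart budget for sweep non-loss conditioning.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_pops = 2, Ne = 1000, split_gens = 700,
                       sample_sizes = c(20, 18), seq_len = 2e6,
                       n_contigs = 1, mu = 1.10e-8, rec_rate = 1e-8,
                       gen_time_years = 8, sweep = NULL, admixture = NULL,
                       pop_names = NULL, seed = NULL, burn_factor = 10,
                       max_restarts = 500) {
  if (mu < 0 || rec_rate < 0) stop_input("rates must be >= 0")
  if (burn_factor < 10) stop_input("burn_factor must be >= 10")
  n_out <- n_pops + as.integer(!is.null(admixture))
  sample_sizes <- rep_len(as.integer(sample_sizes), n_out)
  if (any(sample_sizes > Ne))
    stop_input("sample sizes must not exceed Ne")
  if (any(sample_sizes < 1L)) stop_input("sample sizes must be >= 1")
  if (!is.null(sweep)) {
    stopifnot(is.list(sweep))
    sweep <- modifyList(list(pop = 1L, pos = floor(seq_len / 2), s = 0.05,
                             origin_gen = 0L), sweep)
    if (sweep$pos < 0 || sweep$pos >= seq_len)
      stop_input("sweep position must lie in [0, seq_len)")
    if (sweep$pop < 1 || sweep$pop > n_pops)
      stop_input("sweep population index out of range")
    if (sweep$origin_gen < 0 || sweep$origin_gen >= split_gens)
      stop_input("sweep origin must lie within the post-split epoch")
  }
  if (!is.null(admixture)) {
    stopifnot(is.list(admixture))
    admixture <- modifyList(list(sources = c(1L, 2L), props = c(0.5, 0.5),
                                 gens_ago = 20L), admixture)
    if (length(admixture$sources) != 2L ||
        any(admixture$sources < 1L | admixture$sources > n_pops))
      stop_input("admixture sources must name two split populations")
    if (abs(sum(admixture$props) - 1) > 1e-9)
      stop_input("admixture proportions must sum to 1")
    if (admixture$gens_ago < 0 || admixture$gens_ago > split_gens)
      stop_input("admixture time must lie within the post-split epoch")
  }
  if (is.null(pop_names))
    pop_names <- c(paste0("pop", seq_len(n_pops)),
                   if (!is.null(admixture)) "admixed")
  stopifnot(length(pop_names) == n_out)
  structure(list(
    n_pops = as.integer(n_pops), Ne = as.integer(Ne),
    split_gens = as.integer(split_gens), sample_sizes = sample_sizes,
    seq_len = as.numeric(seq_len), n_contigs = as.integer(n_contigs),
    mu = mu, rec_rate = rec_rate, gen_time_years = gen_time_years,
    sweep = sweep, admixture = admixture, pop_names = pop_names,
    seed = seed, burn_factor = burn_factor,
    max_restarts = as.integer(max_restarts)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d pop(s) of Ne=%d, split %d gens ago (~%.1f ky at g=%g y)\n",
    x$n_pops, x$Ne, x$split_gens,
    x$split_gens * x$gen_time_years / 1000, x$gen_time_years))
  cat(sprintf("  %d contig(s) x %g bp, mu=%g, rec=%g, samples: %s\n",
              x$n_contigs, x$seq_len, x$mu, x$rec_rate,
              paste(sprintf("%s=%d", x$pop_names, x$sample_sizes),
                    collapse = ", ")))
  if (!is.null(x$sweep))
    cat(sprintf("  sweep: pop %d @ %g bp, s=%g, origin %d gens post-split\n",
                x$sweep$pop, x$sweep$pos, x$sweep$s, x$sweep$origin_gen))
  if (!is.null(x$admixture))
    cat(sprintf("  admixture: pops %s at %d gens ago (props %s)\n",
                paste(x$admixture$sources, collapse = "+"),
                x$admixture$gens_ago,
                paste(x$admixture$props, collapse = "/")))
  invisible(x)
}

#' Forward Wright-Fisher simulation of phased multi-population data
#'
#' Runs the simulation described by a [sim_config()] and returns phased
#' haplotypes for the requested samples together with the full ground truth.
#' Alleles are polarized (0 = ancestral, 1 = derived) since the true
#' ancestral state is known.  Sites monomorphic across the whole sample are
#' excluded.
#'
#' @param cfg a [sim_config()].
#' @return A list with elements `hm` (a [haplotype_matrix()]) and `truth`
#'   (class `sim_truth`): the config, per-site population-level derived
#'   counts, per-site origin generation, a `standing` flag (mutation predates
#'   the split), realized sweep position/frequencies and restart count.
#' @export
wf_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  burn <- cfg$burn_factor * cfg$Ne
  has_sweep <- !is.null(cfg$sweep)
  has_admix <- !is.null(cfg$admixture)
  n_out <- length(cfg$pop_names)

  contigs <- sprintf("ctg%d", seq_len(cfg$n_contigs))
  per <- vector("list", cfg$n_contigs)
  for (k in seq_len(cfg$n_contigs)) {
    sweep_here <- has_sweep && k == 1L
    per[[k]] <- wf_sim_cpp(
      cfg$Ne, cfg$n_pops, burn, cfg$split_gens, cfg$sample_sizes,
      cfg$seq_len, cfg$mu, cfg$rec_rate,
      sweep_here,
      if (sweep_here) cfg$sweep$pop - 1L else 0L,
      if (sweep_here) as.integer(cfg$sweep$pos) else 0L,
      if (sweep_here) cfg$sweep$s else 0,
      if (sweep_here) as.integer(cfg$sweep$origin_gen) else 0L,
      has_admix,
      if (has_admix) as.integer(cfg$admixture$gens_ago) else 0L,
      if (has_admix) as.integer(cfg$admixture$sources) - 1L else c(0L, 0L),
      if (has_admix) as.numeric(cfg$admixture$props) else c(0.5, 0.5),
      cfg$max_restarts)
  }

  sample_ids <- unlist(lapply(seq_len(n_out), function(p)
    sprintf("%s_%02d", cfg$pop_names[p], seq_len(cfg$sample_sizes[p]))))
  pop <- rep(cfg$pop_names, cfg$sample_sizes)

  n_per <- vapply(per, function(x) length(x$pos), integer(1))
  hm <- haplotype_matrix(
    rep(contigs, n_per),
    unlist(lapply(per, `[[`, "pos")),
    do.call(rbind, lapply(per, `[[`, "alleles")),
    sample_ids, pop, polarized = TRUE)

  pop_counts <- do.call(rbind, lapply(per, `[[`, "pop_counts"))
  colnames(pop_counts) <- cfg$pop_names
  origin_gen <- unlist(lapply(per, `[[`, "origin_gen"))
  truth <- structure(list(
    config = cfg,
    contig = rep(contigs, n_per), pos = unlist(lapply(per, `[[`, "pos")),
    pop_counts = pop_counts, origin_gen = origin_gen,
    standing = origin_gen < per[[1L]]$split_gen,
    split_gen = per[[1L]]$split_gen,
    sweep_pos = if (has_sweep) per[[1L]]$sweep_pos else NA_integer_,
    sweep_contig = if (has_sweep) contigs[1L] else NA_character_,
    sweep_freq = if (has_sweep)
      setNames(as.numeric(per[[1L]]$sweep_freq), cfg$pop_names) else NULL,
    n_restarts = if (has_sweep) per[[1L]]$n_restarts else 0L,
    seed = cfg$seed), class = "sim_truth")
  list(hm = hm, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d segregating sites in sample, seed=%s\n",
              length(x$pos), format(x$seed)))
  if (!is.na(x$sweep_pos))
    cat(sprintf("  sweep @ %s:%d, restarts=%d, final freq: %s\n",
                x$sweep_contig, x$sweep_pos, x$n_restarts,
                paste(sprintf("%s=%.3f", names(x$sweep_freq), x$sweep_freq),
                      collapse = ", ")))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes a phased VCF with the AA INFO tag set to the true ancestral
#' allele, a popmap TSV, and the ground truth as JSON.  To exercise
#' reference-polarized ingest, each site's REF is the allele carried by the
#' first haplotype (a "reference individual"), so derived alleles appear as
#' REF at some sites and the AA tag is required to recover polarization.
#'
#' @param sim result of [wf_simulate()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, the named vector of file paths (`vcf`, `popmap`,
#'   `truth`).
#' @export
write_sim <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hm <- sim$hm
  # reference-polarized representation: REF = first haplotype's allele
  anc <- rep("A", n_sites(hm))
  der <- rep("T", n_sites(hm))
  first <- hm$alleles[, 1L]
  ref <- ifelse(first == 1L, der, anc)
  alt <- ifelse(first == 1L, anc, der)
  out <- hm
  out$ref <- ref
  out$alt <- alt
  out$aa <- anc
  flip <- first == 1L
  out$alleles[flip, ] <- 1L - out$alleles[flip, , drop = FALSE]
  paths <- c(vcf = file.path(outdir, "sim.vcf"),
             popmap = file.path(outdir, "popmap.tsv"),
             truth = file.path(outdir, "truth.json"))
  write_phased_vcf(out, paths["vcf"])
  write.table(data.frame(sample = hm$sample_ids, group = unname(hm$pop)),
              paths["popmap"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  tr <- sim$truth
  tr$config <- unclass(tr$config)
  tr$pop_counts <- unname(split(tr$pop_counts, col(tr$pop_counts)))
  names(tr$pop_counts) <- colnames(sim$truth$pop_counts)
  jsonlite::write_json(unclass(tr), paths["truth"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

#' Reload simulation ground truth written by [write_sim()]
#' @param path path to `truth.json`.
#' @return A `sim_truth` object.
#' @export
read_sim_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$pop_counts <- do.call(cbind, tr$pop_counts)
  cfg <- tr$config
  tr$config <- sim_config(
    n_pops = cfg$n_pops, Ne = cfg$Ne, split_gens = cfg$split_gens,
    sample_sizes = cfg$sample_sizes, seq_len = cfg$seq_len,
    n_contigs = cfg$n_contigs, mu = cfg$mu, rec_rate = cfg$rec_rate,
    gen_time_years = cfg$gen_time_years, sweep = cfg$sweep,
    admixture = cfg$admixture, pop_names = cfg$pop_names, seed = cfg$seed,
    burn_factor = cfg$burn_factor, max_restarts = cfg$max_restarts)
  if (is.null(tr$sweep_freq)) tr["sweep_freq"] <- list(NULL)
  structure(tr, class = "sim_truth")
}
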