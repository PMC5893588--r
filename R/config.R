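#' Default pipeline configuration
#'
#' One nested list holding every stage parameter of the pipeline, with the
#' scan defaults used throughout the package (MAF > 1% pruning, CLR top
#' 0.2% / top-20 peak rule with 1 Mb gene flank, XP-EHH top/bottom 0.1%
#' window rule with 5 kb gene flank, 5 Mb jackknife blocks) and a
#' desk-scale three-population demo simulation with a sweep in the
#' freshwater-like population.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    sim = list(
      n_pops = 3L, Ne = 250L, split_gens = 150L,
      sample_sizes = c(20L, 18L, 11L), seq_len = 5e5, n_contigs = 4L,
      mu = 4e-7, rec_rate = 1e-7, gen_time_years = 8,
      sweep = list(pop = 1L, pos = 250000, s = 0.1, origin_gen = 0L),
      admixture = NULL,
      pop_names = c("yangtze", "yellow_sea", "wide_ridged"),
      burn_factor = 10, max_restarts = 500L),
    maf = list(min = 0.01),
    clr = list(grid_step = 10000, window_bp = 100000,
               alpha_log10_min = -8, alpha_log10_max = -1, alpha_n = 40L,
               top_quantile = 0.002, max_peaks = 20L, flank_bp = 1e6),
    xpehh = list(cutoff = 0.05, max_extend = 1e6, window_bp = 50000,
                 upper_q = 0.999, lower_q = 0.001, flank_bp = 5000),
    f3 = list(block_bp = 5e6),
    genes = list(n_per_contig = 25L, min_len = 2000L, max_len = 10000L))
}

# keys whose values are free-form and merged atomically
.config_leaves <- c("sweep", "admixture", "sample_sizes", "pop_names",
                    "alpha_grid")

merge_config <- function(base, override, path = character()) {
  for (key in names(override)) {
    here <- paste(c(path, key), collapse = ".")
    if (!key %in% names(base))
      stop_input("unknown configuration key: %s", here)
    if (is.list(base[[key]]) && !key %in% .config_leaves) {
      if (!is.list(override[[key]]))
        stop_input("configuration key %s must be a mapping", here)
      base[[key]] <- merge_config(base[[key]], override[[key]],
                                  c(path, key))
    } else {
      base[key] <- override[key]
    }
  }
  base
}

#' Load a YAML configuration, merged over the defaults
#'
#' Keys absent from [default_config()] are rejected; values given in the
#' file override the defaults (command-line flags, in turn, override the
#' file).
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return Nested named list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop_input("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  merge_config(cfg, user)
}

config_sim <- function(cfg) {
  s <- cfg$sim
  sim_config(n_pops = s$n_pops, Ne = s$Ne, split_gens = s$split_gens,
             sample_sizes = s$sample_sizes, seq_len = s$seq_len,
             n_contigs = s$n_contigs, mu = s$mu, rec_rate = s$rec_rate,
             gen_time_years = s$gen_time_years, sweep = s$sweep,
             admixture = s$admixture, pop_names = s$pop_names,
             seed = cfg$seed, burn_factor = s$burn_factor,
             max_restarts = s$max_restarts)
}

config_alpha_grid <- function(cfg) {
  10^seq(cfg$clr$alpha_log10_min, cfg$clr$alpha_log10_max,
         length.out = cfg$clr$alpha_n)
}
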