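test_that("zero mutation rate yields an empty matrix", {
  cfg <- sim_config(n_pops = 1, Ne = 50, split_gens = 0, sample_sizes = 5,
                    seq_len = 1e4, mu = 0, rec_rate = 1e-8, seed = 1)
  sim <- wf_simulate(cfg)
  expect_equal(n_sites(sim$hm), 0L)
})

test_that("identical seeds reproduce haplotypes and truth exactly", {
  cfg <- sim_config(n_pops = 2, Ne = 60, split_gens = 50,
                    sample_sizes = c(6, 6), seq_len = 5e4, mu = 5e-7,
                    rec_rate = 1e-7, seed = 99)
  s1 <- wf_simulate(cfg)
  s2 <- wf_simulate(cfg)
  expect_identical(s1$hm$alleles, s2$hm$alleles)
  expect_identical(s1$hm$pos, s2$hm$pos)
  expect_identical(s1$truth$pop_counts, s2$truth$pop_counts)
})

test_that("sample allele columns are consistent with the population counts", {
  cfg <- sim_config(n_pops = 2, Ne = 40, split_gens = 30,
                    sample_sizes = c(40, 40), seq_len = 5e4, mu = 5e-7,
                    rec_rate = 1e-7, seed = 7)
  sim <- wf_simulate(cfg)  # samples are the whole populations
  for (p in c("pop1", "pop2")) {
    cols <- hap_cols(sim$hm, p)
    expect_equal(unname(rowSums(sim$hm$alleles[, cols])),
                 unname(sim$truth$pop_counts[, p]))
  }
})

test_that("neutral segregating sites match the Watterson expectation", {
  theta <- 4 * 200 * 2.5e-7 * 1e5
  n_hap <- 40
  expected <- theta * sum(1 / seq_len(n_hap - 1))
  set.seed(123)
  S <- vapply(seq_len(20), function(i) {
    cfg <- sim_config(n_pops = 1, Ne = 200, split_gens = 0, sample_sizes = 20,
                      seq_len = 1e5, mu = 2.5e-7, rec_rate = 1e-7)
    n_sites(wf_simulate(cfg)$hm)
  }, numeric(1))
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expected), 3 * se)
})

test_that("the neutral unfolded SFS has the expected singleton share", {
  set.seed(321)
  prop <- vapply(seq_len(20), function(i) {
    cfg <- sim_config(n_pops = 1, Ne = 150, split_gens = 0, sample_sizes = 10,
                      seq_len = 1e5, mu = 4e-7, rec_rate = 1e-7)
    sim <- wf_simulate(cfg)
    k <- rowSums(sim$hm$alleles)
    mean(k == 1)
  }, numeric(1))
  expected <- 1 / sum(1 / seq_len(19))
  se <- sd(prop) / sqrt(length(prop))
  expect_lt(abs(mean(prop) - expected), 3 * se)
})

test_that("a selected allele ends at higher frequency in the sweep
           population (paired sign test)", {
  set.seed(55)
  d <- vapply(seq_len(10), function(i) {
    cfg <- sim_config(n_pops = 2, Ne = 500, split_gens = 200,
                      sample_sizes = c(10, 10), seq_len = 1e5, mu = 1e-7,
                      rec_rate = 1e-8,
                      sweep = list(pop = 1, pos = 5e4, s = 0.1,
                                   origin_gen = 0))
    fr <- wf_simulate(cfg)$truth$sweep_freq
    fr[1] - fr[2]
  }, numeric(1))
  expect_lt(binom.test(sum(d > 0), length(d),
                       alternative = "greater")$p.value, 0.01)
})

test_that("a sweep config with s = 0 runs as a neutral simulation", {
  cfg <- sim_config(n_pops = 2, Ne = 50, split_gens = 40,
                    sample_sizes = c(5, 5), seq_len = 5e4, mu = 5e-7,
                    rec_rate = 1e-7,
                    sweep = list(pop = 1, pos = 2e4, s = 0, origin_gen = 0),
                    max_restarts = 2000, seed = 13)
  sim <- wf_simulate(cfg)
  expect_gt(n_sites(sim$hm), 0L)
  expect_true(is.finite(sim$truth$sweep_freq[1]))
})

test_that("write_sim/read round-trips the matrix and the truth", {
  cfg <- sim_config(n_pops = 2, Ne = 60, split_gens = 50,
                    sample_sizes = c(8, 8), seq_len = 5e4, mu = 5e-7,
                    rec_rate = 1e-7, seed = 17)
  sim <- wf_simulate(cfg)
  outdir <- file.path(tempdir(), "simrt")
  paths <- write_sim(sim, outdir)
  back <- hm_bind(read_phased_vcf(paths["vcf"], paths["popmap"],
                                  require_aa = TRUE))
  expect_equal(back$pos, sim$hm$pos)
  expect_equal(unname(back$alleles), unname(sim$hm$alleles))
  # the reference-polarized VCF must actually contain derived-as-REF sites
  unpol <- hm_bind(read_phased_vcf(paths["vcf"], paths["popmap"],
                                   require_aa = FALSE))
  expect_gt(sum(unpol$alleles[, 1L] != back$alleles[, 1L]), 0L)
  tr <- read_sim_truth(paths["truth"])
  expect_equal(unname(tr$pop_counts), unname(sim$truth$pop_counts))
  expect_equal(tr$pos, sim$truth$pos)
  expect_equal(tr$config$Ne, cfg$Ne)
  # same seed, same bytes
  paths2 <- write_sim(wf_simulate(cfg), file.path(tempdir(), "simrt2"))
  expect_identical(readLines(paths["vcf"]), readLines(paths2["vcf"]))
})

test_that("admixture events produce the extra population", {
  cfg <- sim_config(n_pops = 2, Ne = 50, split_gens = 60,
                    sample_sizes = c(6, 6, 6), seq_len = 5e4, mu = 5e-7,
                    rec_rate = 1e-7,
                    admixture = list(sources = c(1, 2), props = c(0.5, 0.5),
                                     gens_ago = 10), seed = 23)
  sim <- wf_simulate(cfg)
  expect_setequal(unique(unname(sim$hm$pop)), c("pop1", "pop2", "admixed"))
  expect_equal(ncol(sim$truth$pop_counts), 3L)
})
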