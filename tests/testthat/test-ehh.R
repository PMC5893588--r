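test_that("EHH matches hand pair-counts on small worked examples", {
  # 4 haplotypes; extending right from the core, the allele strings are
  # site 2: {0,0,0,1} -> classes {3,1} -> EHH = C(3,2)/C(4,2) = 3/6
  # site 3: {00,00,01,10} -> classes {2,1,1} -> EHH = C(2,2)/C(4,2) = 1/6
  a <- rbind(c(0L, 0L, 0L, 0L),   # core
             c(0L, 0L, 0L, 1L),
             c(0L, 0L, 1L, 0L))
  hm <- make_hm(a, pops = c("p1", "p1"))
  d <- ehh(hm, "p1", 1L, "right", cutoff = 0)
  expect_equal(d$ehh, c(1, 3 / 6, 1 / 6))
  expect_equal(d$offset, c(0, 100, 200))
})

test_that("identical haplotypes keep EHH at 1 over the full extension", {
  a <- matrix(rep(c(0L, 1L), each = 3L), nrow = 6L, ncol = 6L)
  hm <- make_hm(a, pops = rep("p1", 3L))
  d <- ehh(hm, "p1", 3L, "right")
  expect_true(all(d$ehh == 1))
  expect_equal(length(d$offset), 4L)  # core + 3 sites to the right
})

test_that("EHH equals the all-pairs brute-force oracle on random matrices", {
  set.seed(42)
  for (rep in 1:10) {
    hm <- random_hm(30, 20, pops = rep("p1", 10))
    core <- sample(5:25, 1)
    for (dir in c("left", "right")) {
      d <- ehh(hm, "p1", core, dir, cutoff = 0.05)
      o <- brute_ehh(hm$alleles, 1:20, core, dir, cutoff = 0.05)
      expect_equal(d$ehh, o$ehh)
      expect_equal(length(d$offset), length(o$site))
    }
  }
})

test_that("EHH decay is monotone non-increasing and within [0, 1]", {
  set.seed(7)
  hm <- random_hm(40, 16, pops = rep("p1", 8))
  d <- ehh(hm, "p1", 20L, "right", cutoff = 0)
  expect_true(all(diff(d$ehh) <= 1e-12))
  expect_true(all(d$ehh >= 0 & d$ehh <= 1))
})

test_that("xpehh z-scores are normalized to mean 0, sd 1 at machine precision", {
  set.seed(1)
  for (rep in 1:5) {
    hm <- random_hm(120, 24, pops = rep(c("A", "B"), each = 6))
    xp <- xpehh_scan(hm, "A", "B", cutoff = 0.05, max_extend = 1e6)
    expect_lt(abs(mean(xp$z)), 1e-12)
    expect_lt(abs(sd(xp$z) - 1), 1e-12)
  }
})

test_that("raw XP-EHH is zero for identical population haplotypes and
           anti-symmetric under swapping A and B", {
  set.seed(2)
  half <- matrix(rbinom(60 * 8, 1, 0.5), 60, 8)
  mode(half) <- "integer"
  a <- cbind(half[, rep(1:8, each = 1)], half)  # pop B identical to pop A
  a <- a[rowSums(a) > 0 & rowSums(a) < 16, ]
  hm <- make_hm(a, pops = c(rep("A", 4), rep("B", 4)))
  suppressWarnings(xp <- xpehh_scan(hm, "A", "B"))
  expect_true(all(xp$raw == 0))
  expect_true(all(is.na(xp$z)))

  hm2 <- random_hm(100, 20, pops = rep(c("A", "B"), each = 5), seed = 5)
  ab <- xpehh_scan(hm2, "A", "B")
  ba <- xpehh_scan(hm2, "B", "A")
  expect_equal(ab$raw, -ba$raw)
  expect_equal(ab$z, -ba$z)
})

test_that("iHH is invariant to inserting a site where all haplotypes agree", {
  set.seed(3)
  hm <- random_hm(50, 12, pops = rep("p1", 6))
  base <- xpehh_ihh(hm, "p1")
  ins <- 25L
  a2 <- rbind(hm$alleles[1:ins, ], rep(0L, 12), hm$alleles[(ins + 1):50, ])
  pos2 <- c(hm$pos[1:ins], hm$pos[ins] + 1L, hm$pos[(ins + 1):50])
  hm2 <- make_hm(a2, pos = pos2, pops = rep("p1", 6))
  with_site <- xpehh_ihh(hm2, "p1")
  # the inserted point lies on the step-function decay curve, so the
  # integral is unchanged exactly
  expect_equal(with_site[-(ins + 1L)], base)
})

test_that("candidate windows follow the quantile and flank rules", {
  set.seed(8)
  # 1000 windows with distinct z -> exactly 1 upper and 1 lower candidate
  n <- 1000
  tr <- data.frame(contig = "c1", pos = seq(25000, by = 50000, length.out = n),
                   ihh_a = 1, ihh_b = 1, raw = 0, z = sample(seq(-4, 4, length.out = n)))
  class(tr) <- c("xpehh_track", "data.frame")
  cand <- select_candidates(tr, window_bp = 50000)
  expect_equal(cand$n_windows, n)
  expect_equal(nrow(cand$upper), 1L)
  expect_equal(nrow(cand$lower), 1L)
  expect_equal(cand$upper$z, max(tr$z))
  expect_equal(cand$lower$z, min(tr$z))

  # all z equal -> no candidates
  tr2 <- tr
  tr2$z <- 1
  cand2 <- select_candidates(tr2, window_bp = 50000)
  expect_equal(nrow(cand2$upper), 0L)
  expect_equal(nrow(cand2$lower), 0L)

  # gene placed 4.9 kb from the top SNP is included, 5.1 kb is excluded
  top_pos <- cand$upper$pos[1L]
  genes <- gene_set("c1",
                    start = c(top_pos + 4900, top_pos + 5100),
                    end = c(top_pos + 4900 + 1000, top_pos + 5100 + 1000),
                    gene = c("near", "far"))
  cand3 <- select_candidates(tr, window_bp = 50000, genes = genes,
                             flank_bp = 5000)
  expect_equal(cand3$upper$genes, "near")
})

test_that("bifurcation trees conserve counts and serialize to Newick", {
  # 3 carriers with alleles (0),(0),(1) at the next site -> root 3, children 2/1
  a <- rbind(c(1L, 1L, 1L, 0L), c(0L, 0L, 1L, 0L))
  hm <- make_hm(a, pops = c("p1", "p1"))
  tr <- bifurcation(hm, "p1", 1L, core_allele = 1L, direction = "right")
  expect_equal(tr$count, 3L)
  expect_equal(sort(unname(vapply(tr$children, `[[`, integer(1), "count"))),
               c(1L, 2L))
  expect_equal(bifurcation_newick(tr), "(2,1)3;")

  # identical carriers -> a path; leaf counts sum to root count everywhere
  set.seed(4)
  hm2 <- random_hm(12, 10, pops = rep("p1", 5))
  tr2 <- bifurcation(hm2, "p1", 6L, core_allele = 1L, max_sites = 5L)
  leaf_sum <- function(node) {
    if (length(node$children) == 0L) return(node$count)
    sum(vapply(node$children, leaf_sum, numeric(1)))
  }
  expect_equal(leaf_sum(tr2), tr2$count)
  expect_error(bifurcation(make_hm(matrix(0L, 2, 4)), "p1", 1L, 1L),
               class = "sweepscan_input_error")
})
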