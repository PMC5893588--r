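test_that("background SFS counts derived and folded classes correctly", {
  # 4 haplotypes, derived counts {1,1,2,3}
  a <- rbind(c(1L, 0L, 0L, 0L), c(0L, 1L, 0L, 0L),
             c(1L, 1L, 0L, 0L), c(1L, 1L, 1L, 0L))
  hm <- make_hm(a, pops = c("p1", "p1"))
  s <- background_sfs(hm, "p1", folded = FALSE)
  expect_equal(s$phi, c(0.5, 0.25, 0.25))
  sf <- background_sfs(hm, "p1", folded = TRUE)
  # minor counts {1,1,2,1} -> (0.75, 0.25)
  expect_equal(sf$phi, c(0.75, 0.25))
  # monomorphic-only input errors
  hm0 <- make_hm(rbind(c(1L, 1L, 1L, 1L), c(0L, 0L, 0L, 1L)),
                 pops = c("p1", "p2"))
  expect_error(background_sfs(hm0, "p1"), class = "sweepscan_input_error")
})

test_that("sweep model is a proper distribution and recovers the background
           at full escape", {
  n <- 10
  set.seed(2)
  phi <- runif(n - 1)
  phi <- phi / sum(phi)
  sfs <- structure(list(n = n, phi = phi, folded = FALSE,
                        n_sites_used = 100L), class = "sfs")
  for (d in c(10, 1e4)) {
    for (alpha in c(1e-6, 1e-3, 1)) {
      p <- sweep_site_prob(seq_len(n - 1), n, d, alpha, sfs)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_true(all(p >= 0))
    }
  }
  # alpha large enough that exp(-alpha d) underflows: exactly the background
  p_inf <- sweep_site_prob(seq_len(n - 1), n, 1e6, 1, sfs)
  expect_equal(p_inf, phi)
})

test_that("the zero-escape class contributes nothing after polymorphic
           conditioning (n = 4 expansion)", {
  n <- 4
  sfs <- uniform_sfs(n)
  # full model at small alpha*d versus the e >= 1 terms only, expanded by
  # hand: e ~ Bin(4, pe); e = 0 forces k in {0, 4}, outside 1..3
  pe <- 0.2
  d <- 100; alpha <- -log(1 - pe) / d
  p_full <- sweep_site_prob(1:3, n, d, alpha, sfs)
  w <- dbinom(0:4, 4, pe)
  p_j <- (1:3) / 4
  unnorm <- sapply(1:3, function(k) {
    tot <- w[5] * (1 / 3)
    for (j in 1:3) for (e in 1:3)
      tot <- tot + (1 / 3) * w[e + 1] *
        (p_j[j] * dbinom(k - (4 - e), e, p_j[j]) +
           (1 - p_j[j]) * dbinom(k, e, p_j[j]))
    tot
  })
  expect_equal(p_full, unnorm / sum(unnorm), tolerance = 1e-12)
})

test_that("analytic sweep model matches the Monte-Carlo star oracle", {
  n <- 6
  sfs <- uniform_sfs(n)
  n_draws <- 1e5
  for (pe in c(0.1, 0.5, 0.9)) {
    d <- 1000
    alpha <- -log(1 - pe) / d
    p <- sweep_site_prob(seq_len(n - 1), n, d, alpha, sfs)
    emp <- mc_star_oracle(n, sfs$phi, pe, n_draws, seed = round(1000 * pe))
    se <- sqrt(emp * (1 - emp) / n_draws)
    expect_true(all(abs(p - emp) <= 3 * pmax(se, 1e-4)))
  }
})

test_that("CLR is non-negative everywhere and zero on background-only data", {
  set.seed(12)
  n <- 20
  phi <- 1 / seq_len(n - 1)
  phi <- phi / sum(phi)
  pos <- sort(sample(1:500000, 400))
  k <- sample(seq_len(n - 1), 400, replace = TRUE, prob = phi)
  a <- t(vapply(seq_along(pos), function(i) {
    v <- integer(n)
    v[sample(n, k[i])] <- 1L
    v
  }, integer(n)))
  hm <- make_hm(a, pos = pos, pops = rep("p1", n / 2))
  track <- clr_scan(hm, "p1", folded = FALSE, grid_step = 10000,
                    window_bp = 100000)
  expect_true(all(track$clr >= -1e-6))
  expect_lt(median(track$clr), 5)
})

test_that("unfolded scans refuse unpolarized data", {
  hm <- random_hm(50, 10, pops = rep("p1", 5), seed = 9)
  hm$polarized <- FALSE
  expect_error(clr_scan(hm, "p1", folded = FALSE),
               "folded", class = "sweepscan_input_error")
  expect_silent(t <- clr_scan(hm, "p1", grid_step = 5000, window_bp = 20000))
})

test_that("peak calling merges runs, ranks by height and applies the 1 Mb
           gene flank", {
  tr <- data.frame(
    contig = "c1", pos = seq(10000, by = 10000, length.out = 300),
    clr = c(rep(0, 100), rep(5, 3), rep(0, 97), 8, 6, rep(0, 98)),
    alpha_hat = 1e-4, n_sites_window = 10L)
  class(tr) <- c("clr_track", "data.frame")
  genes <- gene_set("c1",
                    start = c(1010000 + 900000, 1010000 + 1100000),
                    end = c(1010000 + 900000 + 5000, 1010000 + 1100000 + 5000),
                    gene = c("inFlank", "outFlank"))
  pk <- call_peaks(tr, top_quantile = 0.02, max_peaks = 20, genes = genes,
                   flank_bp = 1e6)
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$peak_clr, c(8, 5))       # ordered by peak height
  expect_equal(pk$start[1L], 2010000)      # the two-point run merged
  expect_equal(pk$end[1L], 2020000)
  g <- strsplit(pk$genes[2L], ",")[[1L]]
  expect_true("inFlank" %in% g)
  expect_false("outFlank" %in% g)

  # constant track: no strict exceedance, empty peak list
  tr2 <- tr
  tr2$clr <- 1
  expect_equal(nrow(call_peaks(tr2)), 0L)
})
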