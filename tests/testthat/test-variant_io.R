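test_that("phased biallelic VCF parses into the expected matrix", {
  p <- write_tiny_vcf(gts = list("0|1\t1|1", "0|0\t0|1", "1|0\t0|0"),
                      pos = c(100L, 200L, 350L))
  hms <- read_phased_vcf(p, popmap_df(c("ind1", "ind2"), c("A", "A")))
  expect_length(hms, 1L)
  hm <- hms[[1L]]
  expect_equal(dim(hm$alleles), c(3L, 4L))
  expect_equal(hm$pos, c(100L, 200L, 350L))
  expect_equal(hm$alleles[1L, ], c(0L, 1L, 1L, 1L))
  expect_false(hm$polarized)
})

test_that("missing and unphased genotypes drop the whole site, with counts", {
  p <- write_tiny_vcf(gts = list("0|1\t1|1", ".|.\t0|1", "0/1\t0|0"))
  hms <- read_phased_vcf(p, popmap_df(c("ind1", "ind2"), c("A", "A")))
  expect_equal(n_sites(hms[[1L]]), 1L)
  expect_equal(unname(attr(hms, "counts")["unphased_or_missing"]), 2L)
})

test_that("multi-allelic and non-SNP records are skipped, never split", {
  p <- write_tiny_vcf(gts = list("0|1\t1|1", "0|1\t0|1", "0|1\t0|0"),
                      alt = c("T", "T,G", "TA"))
  hms <- read_phased_vcf(p, popmap_df(c("ind1", "ind2"), c("A", "A")))
  expect_equal(n_sites(hms[[1L]]), 1L)
  expect_equal(unname(attr(hms, "counts")["non_biallelic_snp"]), 2L)
})

test_that("AA polarization flips exactly the AA=ALT sites", {
  gts <- list("0|1\t1|1", "0|0\t0|1", "1|0\t1|1")
  p <- write_tiny_vcf(gts = gts, info = c("AA=A", "AA=T", "AA=A"))
  pm <- popmap_df(c("ind1", "ind2"), c("A", "A"))
  unpol <- read_phased_vcf(p, pm, require_aa = FALSE)[[1L]]
  pol <- read_phased_vcf(p, pm, require_aa = TRUE)[[1L]]
  expect_true(pol$polarized)
  expect_equal(pol$alleles[1L, ], unpol$alleles[1L, ])       # AA = REF
  expect_equal(pol$alleles[2L, ], 1L - unpol$alleles[2L, ])  # AA = ALT
  expect_equal(pol$alleles[3L, ], unpol$alleles[3L, ])
})

test_that("sites lacking a usable AA tag are dropped under require_aa", {
  p <- write_tiny_vcf(gts = list("0|1\t1|1", "0|0\t0|1", "1|0\t1|1"),
                      info = c("AA=A", ".", "AA=C"))
  pm <- popmap_df(c("ind1", "ind2"), c("A", "A"))
  hm <- read_phased_vcf(p, pm, require_aa = TRUE)[[1L]]
  expect_equal(n_sites(hm), 1L)
})

test_that("a popmap sample absent from the VCF is a named hard error", {
  p <- write_tiny_vcf(gts = list("0|1\t1|1"))
  expect_error(
    read_phased_vcf(p, popmap_df(c("ind1", "ghost"), c("A", "B"))),
    "ghost", class = "sweepscan_input_error")
})

test_that("zero retained sites is a hard error", {
  p <- write_tiny_vcf(gts = list("./.\t0|1"))
  expect_error(read_phased_vcf(p, popmap_df(c("ind1", "ind2"), c("A", "A"))),
               "zero sites", class = "sweepscan_input_error")
})

test_that("VCF round-trip reproduces positions and alleles exactly", {
  hm <- random_hm(40, 12, pops = rep(c("A", "B"), each = 3), seed = 11)
  path <- file.path(tempdir(), "rt.vcf")
  write_phased_vcf(hm, path)
  back <- read_phased_vcf(path, popmap_df(hm$sample_ids, unname(hm$pop)),
                          require_aa = TRUE)[[1L]]
  expect_equal(back$pos, hm$pos)
  expect_equal(unname(back$alleles), unname(hm$alleles))
  expect_equal(back$sample_ids, hm$sample_ids)
})

test_that("filter_maf keeps exactly the strict-inequality sites, per group", {
  # 10 + 10 haplotypes in two groups
  hm <- random_hm(100, 20, pops = rep(c("A", "B"), each = 5), seed = 3)
  out <- filter_maf(hm, c("A", "B"), maf_min = 0.05)
  fa <- pop_freq(hm, "A")
  fb <- pop_freq(hm, "B")
  keep <- pmin(fa, 1 - fa) > 0.05 & pmin(fb, 1 - fb) > 0.05
  expect_equal(out$pos, hm$pos[keep])
  # idempotence
  again <- filter_maf(out, c("A", "B"), maf_min = 0.05)
  expect_equal(again$alleles, out$alleles)
})

test_that("monomorphic sites are removed at any maf_min, 50/50 retained", {
  a <- rbind(rep(0L, 8L),                      # monomorphic
             rep(c(0L, 1L), each = 4L))        # 50/50 in both groups
  hm <- make_hm(a, pops = c("A", "A", "B", "B"))
  # group columns: A = haps 1-4, B = haps 5-8; make 50/50 within each group
  a2 <- rbind(rep(0L, 8L), rep(c(0L, 1L), 4L))
  hm <- make_hm(a2, pops = c("A", "A", "B", "B"))
  out <- filter_maf(hm, c("A", "B"), maf_min = 0.01)
  expect_equal(n_sites(out), 1L)
  expect_equal(out$alleles[1L, ], a2[2L, ])
})

test_that("polarization changes encodings but never which sites survive MAF", {
  gts <- replicate(12, paste(sample(c("0|1", "1|0", "0|0", "1|1"), 4,
                                    replace = TRUE), collapse = "\t"),
                   simplify = FALSE)
  set.seed(9)
  p <- write_tiny_vcf(gts = gts, info = sample(c("AA=A", "AA=T"), 12,
                                               replace = TRUE))
  pm <- popmap_df(sprintf("ind%d", 1:4), rep("A", 4))
  unpol <- read_phased_vcf(p, pm, require_aa = FALSE)[[1L]]
  pol <- read_phased_vcf(p, pm, require_aa = TRUE)[[1L]]
  f_un <- filter_maf(unpol, "A", 0.1)
  f_po <- filter_maf(pol, "A", 0.1)
  expect_equal(f_un$pos, f_po$pos)
})

test_that("BED and GFF3 gene readers unify to 0-based half-open intervals", {
  bed <- file.path(tempdir(), "g.bed")
  writeLines(c("chr1\t100\t200\tgeneA", "chr1\t300\t250\tbad",
               "chr2\t0\t50\tgeneB\t0\t-"), bed)
  expect_warning(g <- read_genes(bed, "bed"), "rejected")
  expect_equal(nrow(g), 2L)
  expect_equal(g$start[g$gene == "geneA"], 100L)
  expect_equal(g$end[g$gene == "geneA"], 200L)
  expect_equal(g$strand[g$gene == "geneB"], "-")

  gff <- file.path(tempdir(), "g.gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1;Name=geneA",
               "chr1\tsrc\texon\t101\t150\t.\t+\t.\tID=e1",
               "chr1\tsrc\tgene\t500\t400\t.\t-\t.\tID=g2"), gff)
  expect_warning(g2 <- read_genes(gff, "gff3"), "rejected")
  expect_equal(nrow(g2), 1L)
  expect_equal(g2$start, 100L)  # 1-based closed -> 0-based half-open
  expect_equal(g2$end, 200L)
  expect_equal(g2$gene, "geneA")
})

test_that("track writer/reader round-trips and stamps the header", {
  x <- data.frame(contig = "c1", pos = c(1L, 2L), score = c(0.123456789, 1))
  path <- file.path(tempdir(), "t.tsv")
  write_track(x, path, params = list(seed = 7))
  lines <- readLines(path)
  expect_match(lines[1L], "^##sweepscan .*seed=7")
  expect_match(lines[2L], "^#contig\tpos\tscore")
  back <- read_track(path)
  expect_equal(back$score[1L], 0.123457, tolerance = 1e-6)
})
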