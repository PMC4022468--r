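test_that("diploid resolution policies behave as documented", {
  expect_equal(resolve_allele("A", "A", "random_draw"), "A")
  expect_equal(resolve_allele("A", "A", "homozygous_only"), "A")
  expect_equal(resolve_allele("A", "A", "major_allele"), "A")
  expect_true(is.na(resolve_allele("A", "C", "homozygous_only")))
  expect_equal(resolve_allele("C", "A", "major_allele"), "A")
  r1 <- resolve_allele(rep("A", 50), rep("C", 50), "random_draw", seed = 6)
  expect_identical(r1, resolve_allele(rep("A", 50), rep("C", 50),
                                      "random_draw", seed = 6))
  expect_true(all(c("A", "C") %in% r1))
  expect_true(is.na(resolve_allele("A", NA, "major_allele")))
  expect_error(resolve_allele("A", "C", "flip"))
})

test_that("pattern classification follows the four-genome definitions", {
  # BABA: G1 and archaic derived, G2 and outgroup ancestral (A<->T transversion)
  expect_equal(classify_pattern("T", "A", "T", "A"), "BABA")
  expect_equal(classify_pattern("A", "T", "T", "A"), "ABBA")
  # transitions are excluded even in perfect BABA configuration
  expect_equal(classify_pattern("G", "A", "G", "A"), "other")
  # archaic must differ from the outgroup
  expect_equal(classify_pattern("T", "A", "A", "A"), "other")
  # three distinct alleles -> other, not an error
  expect_equal(classify_pattern("C", "A", "T", "A"), "other")
  # missing allele -> other
  expect_equal(classify_pattern(NA, "A", "T", "A"), "other")
  expect_equal(classify_pattern(c("T", "A"), c("A", "T"), c("T", "T"),
                                c("A", "A")), c("BABA", "ABBA"))
})

test_that("the D-statistic point estimate matches its closed form", {
  expect_equal(dstatistic(73774, 69606, percent = TRUE),
               100 * (73774 - 69606) / (73774 + 69606))
  expect_equal(dstatistic(5, 5), 0)
  expect_equal(dstatistic(9, 0, percent = TRUE), 100)
  expect_error(dstatistic(0, 0), "undefined")
})

test_that("block partitioning tiles chromosomes from position 1", {
  sites <- data.frame(chrom = "1",
                      pos = c(1, 4999999, 5000001, 12e6),
                      pattern = c("BABA", "ABBA", "BABA", "other"))
  b <- block_partition(sites)
  expect_equal(nrow(b), 2)  # the 'other'-only block is empty and dropped
  expect_equal(b$start, c(1, 5000001))
  expect_equal(b$end, c(5000000, 10000000))
  expect_equal(b$n_baba, c(1L, 1L))
  expect_equal(b$n_abba, c(1L, 0L))
  expect_error(block_partition(sites[c(2, 1, 3, 4), ]), "sorted")
  # uniform sites over 50 Mb land in 10 blocks
  withr::with_seed(2, {
    u <- data.frame(chrom = "1", pos = sort(sample.int(5e7, 5000)),
                    pattern = sample(c("BABA", "ABBA"), 5000, replace = TRUE))
  })
  expect_equal(nrow(block_partition(u)), 10)
})

test_that("block totals equal the counts behind the point estimate", {
  sites <- simulate_dstat_sites(5e4, 12, 0.004, 0.002, seed = 44)
  sites$pattern <- classify_pattern(sites$g1, sites$g2, sites$archaic,
                                    sites$outgroup)
  blocks <- block_partition(sites)
  jk <- jackknife_dstat(blocks)
  expect_equal(jk$n_baba, sum(sites$pattern == "BABA"))
  expect_equal(jk$n_abba, sum(sites$pattern == "ABBA"))
  expect_equal(jk$dstat, dstatistic(jk$n_baba, jk$n_abba))
})

test_that("delete-one jackknife reproduces the hand-computed toy case", {
  b <- data.frame(n_baba = c(10, 0), n_abba = c(0, 10))
  jk <- jackknife_dstat(b)
  expect_equal(jk$dstat, 0)
  expect_equal(jk$se, 1)  # pseudo-estimates are -1 and +1
  expect_equal(jk$z, 0)
  # identical blocks: zero variance flagged as degenerate
  b2 <- data.frame(n_baba = rep(6, 4), n_abba = rep(3, 4))
  jk2 <- jackknife_dstat(b2)
  expect_true(jk2$degenerate)
  expect_equal(jk2$se, 0)
  expect_true(is.na(jk2$z))
  expect_error(jackknife_dstat(b[1, , drop = FALSE]), "at least 2")
})

test_that("swapping the two modern genomes negates D and preserves |Z|", {
  sites <- simulate_dstat_sites(4e4, 10, 0.005, 0.002, seed = 77)
  fwd <- dstat_analysis(sites)
  swp <- sites; swp$g1 <- sites$g2; swp$g2 <- sites$g1
  rev <- dstat_analysis(swp)
  expect_equal(rev$dstat_pct, -fwd$dstat_pct)
  expect_equal(rev$se_pct, fwd$se_pct)
  expect_equal(abs(rev$z), abs(fwd$z))
})

test_that("jackknife SE tracks the analytic multinomial SE", {
  se_hat <- vapply(1:30, function(s) {
    b <- simulate_dstat_counts(2e5, 100, 0.003, 0.002, seed = 300 + s)
    jackknife_dstat(b)$se
  }, numeric(1))
  se_true <- dstat_analytic_se(2e5, 0.003, 0.002)
  expect_lt(abs(mean(se_hat) / se_true - 1), 0.2)
})

test_that("the weighted jackknife agrees with equal weights on equal blocks", {
  b <- simulate_dstat_counts(1e5, 50, 0.004, 0.003, seed = 5)
  eq <- jackknife_dstat(b, weighted = FALSE)
  wt <- jackknife_dstat(b, weighted = TRUE)
  expect_equal(wt$dstat, eq$dstat)
  # near-equal block sizes: the two SEs should be close
  expect_lt(abs(wt$se / eq$se - 1), 0.2)
})

test_that("four-genome tables assemble from single-sample VCFs and outgroup", {
  # shared reference track across three genomes; transversion alt alleles
  mk <- function(gt, path = tempfile(fileext = ".vcf"))
    write_test_vcf(rep("1", 4), c(10, 20, 30, 40),
                   ref = c("A", "C", "G", "T"), alt = c("T", "G", "C", "A"),
                   gt = matrix(gt, ncol = 1), samples = "X", path = path)
  g1 <- mk(c("1/1", "0/0", "0/0", "0/0"))
  g2 <- mk(c("0/0", "1/1", "0/0", "0/0"))
  ar <- mk(c("1/1", "1/1", "0/0", "1/1"))
  og <- tempfile(fileext = ".tsv")
  write.table(data.frame(chrom = "1", pos = c(10, 20, 30, 40, 99),
                         base = c("A", "C", "G", "T", "G")),
              og, sep = "\t", quote = FALSE, row.names = FALSE)
  sites <- build_four_genome_sites(g1, g2, ar, og, policy = "homozygous_only")
  expect_equal(nrow(sites), 4)  # pos 99 has no reference record -> dropped
  pat <- classify_pattern(sites$g1, sites$g2, sites$archaic, sites$outgroup)
  expect_equal(pat, c("BABA", "ABBA", "other", "other"))
})
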