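mk_calls <- function(start, end, caller = "c1", chrom = "1", sample = "S1") {
  data.frame(chrom = chrom, start = start, end = end, caller = caller,
             sample = sample, stringsAsFactors = FALSE)
}

test_that("size window is inclusive at 50 bp and 10 Mb", {
  calls <- mk_calls(start = c(1, 1, 1, 1),
                    end = c(49, 50, 1e7, 1e7 + 1))  # lengths 49,50,1e7,1e7+1
  kept <- size_filter(calls)
  expect_equal(kept$end, c(50, 1e7))
})

test_that("union merging chains transitively and records caller evidence", {
  m1 <- merge_union(mk_calls(c(100, 150), c(200, 300), caller = c("A", "B")))
  expect_equal(nrow(m1), 1)
  expect_equal(c(m1$start, m1$end), c(100, 300))
  expect_equal(m1$callers, "A,B")
  m2 <- merge_union(mk_calls(c(100, 300), c(200, 400), caller = c("A", "B")))
  expect_equal(nrow(m2), 2)  # disjoint
  m3 <- merge_union(mk_calls(c(100, 190, 280), c(200, 290, 380),
                             caller = c("A", "B", "C")))
  expect_equal(nrow(m3), 1)  # transitive chain
  expect_equal(c(m3$start, m3$end, m3$n_callers), c(100, 380, 3))
  # abutting (0 bp overlap) calls are not merged
  m4 <- merge_union(mk_calls(c(100, 201), c(200, 300)))
  expect_equal(nrow(m4), 2)
})

test_that("union merging matches the brute-force component oracle", {
  withr::with_seed(33, {
    for (i in 1:25) {
      n <- sample(2:12, 1)
      st <- sample.int(500, n, replace = TRUE)
      en <- st + sample.int(80, n, replace = TRUE)
      got <- merge_union(mk_calls(st, en))
      want <- oracle_merge(st, en)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  })
})

test_that("merging is idempotent and conserves call multiplicities", {
  withr::with_seed(91, {
    for (i in 1:20) {
      n <- sample(3:15, 1)
      st <- sample.int(400, n, replace = TRUE)
      calls <- mk_calls(st, st + sample.int(60, n, replace = TRUE),
                        caller = sample(c("A", "B", "C"), n, replace = TRUE))
      m <- merge_union(calls)
      m2 <- merge_union(data.frame(chrom = m$chrom, start = m$start,
                                   end = m$end, caller = m$callers,
                                   sample = m$sample))
      expect_equal(m2[, c("start", "end")], m[, c("start", "end")])
      expect_lte(nrow(m), nrow(calls))
      expect_equal(sum(m$n_calls), nrow(calls))
    }
  })
})

test_that("merging respects sample and chromosome boundaries", {
  calls <- rbind(mk_calls(100, 200, sample = "S1"),
                 mk_calls(150, 250, sample = "S2"),
                 mk_calls(150, 250, chrom = "2"))
  expect_equal(nrow(merge_union(calls)), 3)
})

test_that("overlap fraction is coverage of the query by the catalog union", {
  q <- data.frame(chrom = "1", start = 100, end = 199)  # 100 bp
  expect_equal(overlap_fraction(q, data.frame(chrom = "1", start = 100,
                                              end = 149)), 0.5)
  expect_equal(overlap_fraction(q, data.frame(chrom = "2", start = 100,
                                              end = 199)), 0)
  # two abutting intervals covering the query: 1.0 with no double counting
  two <- data.frame(chrom = "1", start = c(100, 150), end = c(149, 199))
  expect_equal(overlap_fraction(q, two), 1)
  # duplicated/overlapping catalog entries are not double counted
  dup <- data.frame(chrom = "1", start = c(100, 100, 120), end = c(149, 149, 160))
  expect_equal(overlap_fraction(q, dup),
               oracle_overlap_fraction(100, 199, dup$start, dup$end))
})

test_that("overlap fraction is invariant to splitting catalog intervals", {
  withr::with_seed(12, {
    for (i in 1:20) {
      qs <- sample.int(200, 1); qe <- qs + sample.int(150, 1)
      cs <- sample.int(250, 3); ce <- cs + sample.int(100, 3)
      q <- data.frame(chrom = "1", start = qs, end = qe)
      whole <- data.frame(chrom = "1", start = cs, end = ce)
      # split each interval into two abutting halves
      mid <- pmax(cs, pmin(ce - 1, cs + (ce - cs) %/% 2))
      split2 <- data.frame(chrom = "1", start = c(cs, mid + 1),
                           end = c(mid, ce))
      expect_equal(overlap_fraction(q, split2), overlap_fraction(q, whole))
      expect_equal(overlap_fraction(q, whole),
                   oracle_overlap_fraction(qs, qe, cs, ce))
    }
  })
})

test_that("novelty uses a strict less-than-50% boundary", {
  cons <- data.frame(chrom = "1", start = c(100, 100), end = c(199, 199))
  cat1 <- list(data.frame(chrom = "1", start = c(100, 100),
                          end = c(149, 148)))
  r <- classify_sv_novelty(cons[1, ], list(data.frame(chrom = "1",
                                                      start = 100, end = 149)))
  expect_equal(r$novelty, "known")     # exactly 0.50 -> known
  r2 <- classify_sv_novelty(cons[1, ], list(data.frame(chrom = "1",
                                                       start = 100, end = 148)))
  expect_equal(r2$overlap_frac, 0.49)
  expect_equal(r2$novelty, "novel")    # 0.49 -> novel
})

test_that("noiseless simulation recovers planted deletions exactly", {
  sv <- simulate_sv_calls(n_true_deletions = 40, boundary_jitter_sd = 0,
                          detection_prob = 1, n_false_positives = 0,
                          seed = 19)
  cons <- consolidate_deletions(sv$calls)
  expect_equal(nrow(cons), 40)
  expect_equal(cons$start, sv$truth$start)
  expect_equal(cons$end, sv$truth$end)
  expect_true(all(cons$n_callers == 4))
})

test_that("post-merge size recheck can drop oversized unions", {
  calls <- mk_calls(c(1, 5e6), c(6e6, 10.5e6), caller = c("A", "B"))
  cons <- consolidate_deletions(calls, recheck_size = FALSE)
  expect_equal(nrow(cons), 1)
  expect_gt(cons$length, 1e7)
  expect_error(consolidate_deletions(calls, recheck_size = TRUE),
               NA)  # runs; the oversized union is filtered out
  expect_equal(nrow(consolidate_deletions(calls[c(1, 1), ],
                                          recheck_size = TRUE)), 1)
})
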