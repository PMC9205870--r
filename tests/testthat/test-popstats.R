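rec <- function(rl, al, nm, id = "r1", target = "g1") {
  data.frame(read_id = id, read_length = rl, aligned_length = al,
             edit_distance = nm, target_id = target,
             stringsAsFactors = FALSE)
}

test_that("alignment filter thresholds are inclusive at each boundary", {
  expect_equal(nrow(filterAlignments(rec(100, 100, 5))), 1)  # identity 95.0
  expect_equal(nrow(filterAlignments(rec(100, 100, 6))), 0)  # 94.0
  expect_equal(nrow(filterAlignments(rec(100, 79, 0))), 0)   # < 80 bp
  expect_equal(nrow(filterAlignments(rec(100, 80, 0))), 1)   # 80 bp & 80%
  expect_equal(nrow(filterAlignments(rec(101, 80, 0))), 0)   # 79.2% of read
  expect_error(filterAlignments(rec(100, 50, 60)), "edit_distance")
})

test_that("SNP verdicts follow depth and dominant-proportion rules", {
  p <- data.frame(contig = "c", pos = 1:3,
                  A = c(8, 9, 5), C = 0, G = 0, T = c(2, 1, 4))
  v <- snpSites(p)
  expect_equal(as.character(v$verdict), c("snp", "invariant", "untested"))
  expect_equal(v$depth, c(10, 10, 9))
  expect_equal(v$dominant, c(0.8, 0.9, 5 / 9))
})

test_that("SNP verdicts depend only on the count multiset", {
  set.seed(51)
  for (i in 1:25) {
    counts <- sample(0:12, 4, replace = TRUE)
    perm <- sample(4)
    p1 <- data.frame(contig = "c", pos = 1, A = counts[1], C = counts[2],
                     G = counts[3], T = counts[4])
    p2 <- data.frame(contig = "c", pos = 1, A = counts[perm[1]],
                     C = counts[perm[2]], G = counts[perm[3]],
                     T = counts[perm[4]])
    expect_identical(snpSites(p1)$verdict, snpSites(p2)$verdict)
  }
})

test_that("heterogeneity is SNP sites per kb of tested sites", {
  # 2 snps over 500 tested -> 4.0/kb
  p <- data.frame(contig = "c", pos = 1:500,
                  A = c(rep(7, 2), rep(10, 498)),
                  C = c(rep(3, 2), rep(0, 498)), G = 0, T = 0)
  expect_equal(heterogeneity(p), 4)
  p0 <- data.frame(contig = "c", pos = 1:10, A = 10, C = 0, G = 0, T = 0)
  expect_equal(heterogeneity(p0), 0)
  shallow <- data.frame(contig = "c", pos = 1, A = 3, C = 0, G = 0, T = 0)
  expect_warning(h <- heterogeneity(shallow), "undefined")
  expect_true(is.na(h))
})

test_that("simulated pileups recover the planted SNP rate", {
  p <- makePileup(100000, snpRate = 0.004, depthMean = 20, seed = 5)
  h <- heterogeneity(p$pileup)
  tested <- sum(rowSums(p$pileup[, c("A", "C", "G", "T")]) >= 10)
  sd3 <- 3 * 1000 * sqrt(0.004 * 0.996 / tested)
  expect_lt(abs(h - 4.0), sd3 + 1000 * abs(length(p$truth) / 1e5 - 0.004))
})

test_that("mean coverage averages over all positions including zeros", {
  expect_equal(meanCoverage(c(0, 10, 20)), 10)
  expect_equal(meanCoverage(rep(0, 5)), 0)
  expect_equal(meanCoverage(rep(12.9, 100)), 12.9)
  expect_equal(meanCoverage(c(10, 20), genomeLength = 4), 7.5)
  expect_error(meanCoverage(numeric(0)), "empty")
})

test_that("recruitment counts distinct reads against the target set", {
  a <- makeAlignments(1000, 0.4, seed = 2)
  r <- recruitmentFraction(a$records, a$totalReads, "rep1")
  expect_equal(r$fraction, 40)
  expect_equal(r$reads_mapped_pass, 400)

  # a read with two passing alignments counts once
  two <- rbind(rec(100, 100, 0), rec(100, 100, 1))
  r2 <- recruitmentFraction(two, 10, "g1")
  expect_equal(r2$reads_mapped_pass, 1)

  # empty target set recruits nothing
  r3 <- recruitmentFraction(a$records, a$totalReads, character(0))
  expect_equal(r3$fraction, 0)

  expect_equal(recruitmentFraction(makeAlignments(100, 0, 1)$records,
                                   100, "rep1")$fraction, 0)
  expect_equal(recruitmentFraction(makeAlignments(100, 1, 1)$records,
                                   100, "rep1")$fraction, 100)
})

test_that("tightening any threshold never increases recruitment", {
  set.seed(53)
  n <- 400
  recs <- data.frame(read_id = sprintf("r%03d", 1:n),
                     read_length = 100L,
                     aligned_length = sample(60:100, n, TRUE),
                     edit_distance = sample(0:8, n, TRUE),
                     target_id = "g1", stringsAsFactors = FALSE)
  recs$edit_distance <- pmin(recs$edit_distance, recs$aligned_length)
  base <- recruitmentFraction(recs, n, "g1")$fraction
  expect_lte(recruitmentFraction(recs, n, "g1", minIdentity = 97)$fraction,
             base)
  expect_lte(recruitmentFraction(recs, n, "g1", minLen = 90)$fraction, base)
  expect_lte(recruitmentFraction(recs, n, "g1", minFrac = 90)$fraction, base)
  # relaxing identity can only help (mirrors the ~7% gain at >= 90%)
  expect_gte(recruitmentFraction(recs, n, "g1", minIdentity = 90)$fraction,
             base)
})
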