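fixtureBin <- function(seed = 4) {
  host <- makeGenome(24 * 5100, seed = seed)
  makeBin(host, 24, seed = seed + 1, binId = "fx")
}

test_that("refineBin removes the union of planted contaminants, once each", {
  fx <- fixtureBin()
  r <- refineBin(fx$bin, fx$contigLineages, fx$genomeLineage, fx$evidence)
  s <- r$report$summary
  expect_equal(s$removed_tax, 1)
  expect_equal(s$removed_mobile, 1)
  expect_equal(s$removed_outlier, 1)
  expect_equal(s$contigs_removed, 3)
  expect_equal(s$contigs_after, s$contigs_before - 3)
  flags <- r$report$contigs
  expect_setequal(flags$contig_id[flags$tax], fx$truth$tax)
  expect_setequal(flags$contig_id[flags$mobile], fx$truth$mobile)
  expect_setequal(flags$contig_id[flags$outlier], fx$truth$outlier)
})

test_that("survivors keep input order and byte-identical sequences", {
  fx <- fixtureBin(seed = 10)
  r <- refineBin(fx$bin, fx$contigLineages, fx$genomeLineage, fx$evidence)
  keep <- names(contigs(r$bin))
  orig <- names(contigs(fx$bin))
  expect_identical(keep, orig[orig %in% keep])
  expect_identical(as.character(contigs(r$bin)),
                   as.character(contigs(fx$bin)[keep]))
})

test_that("a bin with no flags passes through unchanged", {
  host <- makeGenome(20000, seed = 2)
  fx <- makeBin(host, 3, plants = list(), seed = 3, binId = "clean")
  r <- refineBin(fx$bin, fx$contigLineages, fx$genomeLineage, fx$evidence)
  expect_equal(r$report$summary$contigs_removed, 0)
  expect_identical(as.character(contigs(r$bin)),
                   as.character(contigs(fx$bin)))
})

test_that("a contig flagged by two filters counts once in the union", {
  # host-derived contig with a conflicting lineage AND circular evidence
  host <- makeGenome(15000, seed = 6)
  seqs <- setNames(substring(host, c(1, 4001, 8001), c(4000, 8000, 12000)),
                   c("c1", "c2", "c3"))
  g <- Lineage(c("class", "order"), c("C1", "O1"))
  lin <- list(c1 = g, c2 = Lineage(c("class", "order"), c("C1", "O9")),
              c3 = g)
  ev <- data.frame(contig_id = "c2", circular = TRUE, category = NA_integer_,
                   viral_fraction = NA_real_, stringsAsFactors = FALSE)
  ev$terl_hits <- list(NULL)
  b <- GenomeBin("dbl", seqs)
  r <- refineBin(b, lin, g, ev)
  s <- r$report$summary
  expect_equal(s$removed_tax, 1)
  expect_equal(s$removed_mobile, 1)
  expect_equal(s$contigs_removed, 1)  # union, not sum
})

test_that("requalification keeps at the gate and discards below it", {
  fx <- fixtureBin(seed = 12)
  r <- refineBin(fx$bin, fx$contigLineages, fx$genomeLineage, fx$evidence)
  kept <- requalify(r$report, completeness = 80, contamination = 6,
                    qsBefore = 60)
  expect_equal(kept$summary$qs_after, 50)
  expect_false(kept$summary$discarded)
  dropped <- requalify(r$report, completeness = 79.9, contamination = 6)
  expect_true(dropped$summary$discarded)
  # QS may rise when contamination is removed
  up <- requalify(r$report, completeness = 82, contamination = 0.5,
                  qsBefore = 60)
  expect_gt(up$summary$qs_after, up$summary$qs_before)
})

test_that("run summaries aggregate counts, means and retention", {
  mk <- function(tax, mob, out, removed, discarded) {
    list(summary = data.frame(bin_id = "b", contigs_before = 10,
                              contigs_after = 10 - removed,
                              contigs_removed = removed,
                              removed_tax = tax, removed_mobile = mob,
                              removed_outlier = out, qs_before = NA,
                              qs_after = NA, discarded = discarded))
  }
  s <- summarizeRun(list(mk(2, 1, 0, 3, FALSE), mk(0, 0, 5, 5, TRUE)))
  expect_equal(s$bins_assessed, 2)
  expect_equal(s$removed_tax, 2)
  expect_equal(s$contigs_removed, 8)
  expect_equal(s$mean_removed_per_bin, 4)
  expect_equal(s$bins_discarded, 1)
  expect_equal(s$bins_retained, 1)

  empty <- summarizeRun(list())
  expect_equal(empty$bins_assessed, 0)
  expect_equal(empty$mean_removed_per_bin, 0)

  one <- summarizeRun(list(mk(1, 1, 2, 4, FALSE)))
  expect_equal(one$mean_removed_per_bin, 4)
})

test_that("filter flag sets are independent of execution order", {
  fx <- fixtureBin(seed = 20)
  # each filter run in isolation equals its slice of the full run
  full <- refineBin(fx$bin, fx$contigLineages, fx$genomeLineage,
                    fx$evidence)$report$contigs
  taxOnly <- taxonomicFilter(fx$bin, fx$contigLineages, fx$genomeLineage)
  mobOnly <- mobileElementFilter(fx$bin, fx$evidence)
  outOnly <- outlierContigs(fx$bin)
  expect_identical(full$tax, taxOnly$flagged)
  expect_identical(full$mobile, mobOnly$flagged)
  expect_identical(full$outlier, outOnly$flagged)
})
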