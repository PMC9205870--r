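test_that("planted terminal repeats are found, random sequence is not", {
  set.seed(5)
  p <- randDna(60)
  s <- paste0(p, randDna(1000), p)
  d <- detectTerminalRedundancy(s)
  expect_true(d$circular)
  expect_gte(d$overlap, 60)

  r <- detectTerminalRedundancy(randDna(1000))
  expect_false(r$circular)
  expect_equal(r$overlap, 0L)

  # short sequences: not circular, overlap 0, no error
  short <- detectTerminalRedundancy(randDna(80), minOverlap = 50)
  expect_false(short$circular)
})

test_that("redundancy verdicts agree with exhaustive prefix/suffix scan", {
  set.seed(6)
  for (i in 1:60) {
    core <- randDna(sample(500:2000, 1))
    if (i %% 2 == 0) {
      p <- randDna(sample(20:200, 1))
      s <- paste0(p, core, p)
    } else {
      s <- core
    }
    got <- detectTerminalRedundancy(s)
    want <- bruteTerminalRedundancy(s)
    expect_identical(got$circular, want$circular, info = paste("case", i))
    expect_equal(got$overlap, want$overlap, info = paste("case", i))
  }
})

test_that("redundancy is invariant under reverse complement", {
  set.seed(8)
  for (i in 1:20) {
    p <- randDna(70)
    s <- paste0(p, randDna(600), p)
    if (i %% 2 == 0) s <- randDna(700)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_identical(detectTerminalRedundancy(s),
                     detectTerminalRedundancy(rc))
  }
})

test_that("viral categories 1-3 are viral; 4-6 need >= 50% viral region", {
  expect_true(classifyViralPrediction(1))
  expect_true(classifyViralPrediction(2))
  expect_true(classifyViralPrediction(3))
  expect_true(classifyViralPrediction(5, 0.6))
  expect_true(classifyViralPrediction(4, 0.5))   # inclusive boundary
  expect_false(classifyViralPrediction(4, 0.4))
  expect_false(classifyViralPrediction(6, 0.49))
  expect_error(classifyViralPrediction(7), "category")
  expect_error(classifyViralPrediction(5, NA), "fraction")
})

test_that("terL identification needs all three criteria", {
  hit <- function(e, d, p) data.frame(evalue = e, domain = d,
                                      probability = p)
  expect_true(filterTerlHits(hit(1e-11, "Terminase_6", 98)))
  expect_false(filterTerlHits(hit(1e-9, "Terminase_6", 99)))   # evalue strict
  expect_false(filterTerlHits(hit(1e-10, "Terminase_6", 99)))  # boundary out
  expect_false(filterTerlHits(hit(1e-12, "Portal", 99)))       # wrong domain
  expect_false(filterTerlHits(hit(1e-12, "Terminase_1", 97)))  # prob strict
  expect_false(filterTerlHits(NULL))
  # any one passing hit among failures suffices
  hits <- rbind(hit(1e-9, "Terminase_3", 99), hit(1e-12, "DNA_pack_N", 98))
  expect_true(filterTerlHits(hits))
  expect_length(terlDomains(), 7)
})

test_that("the bin-level mobile filter ORs the three evidence routes", {
  lens <- c(big = 12000L, small = 2500L, circ = 5000L, plain = 4000L,
            terl = 5000L)
  ev <- data.frame(contig_id = c("big", "small", "terl"),
                   circular = FALSE,
                   category = c(1L, 1L, NA),
                   viral_fraction = NA_real_, stringsAsFactors = FALSE)
  ev$terl_hits <- list(NULL, NULL,
                       data.frame(evalue = 1e-12, domain = "Terminase_3C",
                                  probability = 99))
  evc <- rbind(ev, data.frame(contig_id = "circ", circular = TRUE,
                              category = NA, viral_fraction = NA,
                              terl_hits = I(list(NULL))))
  out <- mobileElementFilter(lens, evc)
  flags <- setNames(out$flagged, out$contig_id)
  expect_true(flags[["big"]])       # category 1, length >= 3 kb
  expect_false(flags[["small"]])    # category 1 but below predictor range
  expect_true(flags[["circ"]])      # circularity alone suffices
  expect_false(flags[["plain"]])    # no evidence at all
  expect_true(flags[["terl"]])      # terL in the 1-10 kb range
  # an 11 kb contig is outside the terL scan range
  out2 <- mobileElementFilter(c(terl = 11000L), ev[3, ])
  expect_false(out2$flagged)
})

test_that("removing evidence never adds flags (monotonicity)", {
  lens <- c(a = 5000L, b = 5000L)
  ev <- data.frame(contig_id = c("a", "b"), circular = c(TRUE, FALSE),
                   category = c(NA, 2L), viral_fraction = NA_real_,
                   stringsAsFactors = FALSE)
  ev$terl_hits <- list(NULL, NULL)
  full <- mobileElementFilter(lens, ev)
  less <- mobileElementFilter(lens, ev[1, ])
  none <- mobileElementFilter(lens, NULL)
  expect_true(all(less$flagged <= full$flagged))
  expect_true(all(none$flagged <= less$flagged))
})
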