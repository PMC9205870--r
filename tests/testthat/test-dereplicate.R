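test_that("threshold application on edges controls cluster membership", {
  sc <- c(g1 = 70, g2 = 60, g3 = 55)
  e <- data.frame(genome_a = "g1", genome_b = "g2", ani = 96,
                  aligned_fraction = 50)
  cl <- clusterSpecies(sc, e)
  expect_equal(sort(unique(cl$representative)), c("g1", "g3"))
  expect_true(cl$is_representative[cl$genome == "g1"])
  expect_false(cl$is_representative[cl$genome == "g2"])

  # aligned fraction below 30 keeps genomes apart despite high ANI
  e2 <- data.frame(genome_a = "g1", genome_b = "g3", ani = 99,
                   aligned_fraction = 20)
  cl2 <- clusterSpecies(sc, e2)
  expect_true(all(cl2$is_representative))

  # inclusive boundaries: exactly 95 / 30 merges
  e3 <- data.frame(genome_a = "g1", genome_b = "g2", ani = 95,
                   aligned_fraction = 30)
  expect_equal(sum(clusterSpecies(sc, e3)$is_representative), 2)

  expect_error(clusterSpecies(sc, data.frame(genome_a = "gX",
                                             genome_b = "g1", ani = 99,
                                             aligned_fraction = 99)),
               "unknown genome")
})

test_that("greedy centroid clustering breaks chains at the founder", {
  sc <- c(g1 = 70, g2 = 60, g3 = 55)
  e <- data.frame(genome_a = c("g1", "g2"), genome_b = c("g2", "g3"),
                  ani = 96, aligned_fraction = 50)
  cl <- clusterSpecies(sc, e)
  # g1 founds and absorbs g2; g3 has no edge to g1, founds its own cluster
  expect_equal(cl$representative[cl$genome == "g2"], "g1")
  expect_equal(cl$representative[cl$genome == "g3"], "g3")
  # every member has a direct edge to its representative
  pass <- e
  for (i in seq_len(nrow(cl))) {
    if (!cl$is_representative[i]) {
      r <- cl$representative[i]; g <- cl$genome[i]
      expect_true(any((pass$genome_a == g & pass$genome_b == r) |
                        (pass$genome_b == g & pass$genome_a == r)))
    }
  }
})

test_that("clusters partition the genomes; raising cutoffs never merges", {
  set.seed(33)
  ids <- paste0("g", 1:12)
  sc <- setNames(runif(12, 40, 90), ids)
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < 0.3
  e <- data.frame(genome_a = pairs[keep, 1], genome_b = pairs[keep, 2],
                  ani = runif(sum(keep), 90, 100),
                  aligned_fraction = runif(sum(keep), 10, 90))
  for (ani in c(93, 95, 97)) {
    cl <- clusterSpecies(sc, e, aniMin = ani)
    expect_setequal(cl$genome, ids)             # partition: all present once
    expect_equal(anyDuplicated(cl$genome), 0)
  }
  nLoose <- max(clusterSpecies(sc, e, aniMin = 93)$cluster)
  nTight <- max(clusterSpecies(sc, e, aniMin = 97)$cluster)
  expect_gte(nTight, nLoose)
  nAfLoose <- max(clusterSpecies(sc, e, afMin = 10)$cluster)
  nAfTight <- max(clusterSpecies(sc, e, afMin = 60)$cluster)
  expect_gte(nAfTight, nAfLoose)
})

test_that("two-round dereplication promotes the better cross-division twin", {
  sc <- c(a1 = 60, b1 = 65)
  dv <- c(a1 = "A", b1 = "B")
  e <- data.frame(genome_a = "a1", genome_b = "b1", ani = 100,
                  aligned_fraction = 100)
  r <- twoRoundDereplication(dv, sc, e)
  # round 1 keeps both (no within-division edge); round 2 merges, B's wins
  expect_equal(sum(r$round1$is_representative), 2)
  expect_identical(r$representatives, "b1")
})

test_that("round 2 is the identity without cross-division links, and a
           single division equals one round", {
  set.seed(35)
  ids <- paste0("g", 1:8)
  sc <- setNames(runif(8, 50, 80), ids)
  dv <- setNames(rep(c("A", "B"), each = 4), ids)
  within <- data.frame(genome_a = c("g1", "g5"), genome_b = c("g2", "g6"),
                       ani = 97, aligned_fraction = 60)
  r <- twoRoundDereplication(dv, sc, within)
  expect_setequal(r$representatives, r$round1$genome[r$round1$is_representative])

  one <- twoRoundDereplication(setNames(rep("only", 8), ids), sc, within)
  flat <- clusterSpecies(sc, within)
  expect_setequal(one$representatives, flat$genome[flat$is_representative])
})

test_that("k-mer ANI hits its limits and tracks simulated divergence", {
  g1 <- makeGenome(20000, seed = 11, gc = 0.5)
  same <- estimateAni(g1, g1)
  expect_equal(same$ani, 100, tolerance = 1e-9)
  expect_equal(same$aligned_fraction, 100, tolerance = 1e-9)

  # mutate 3% of sites; alignment-free estimate vs exact hamming identity
  withSeed(42, {
    v <- strsplit(g1, "", fixed = TRUE)[[1]]
    idx <- which(runif(length(v)) < 0.03)
    v[idx] <- vapply(v[idx], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    g2 <- paste(v, collapse = "")
    hamming <- 100 * mean(strsplit(g1, "")[[1]] == v)
    est <- estimateAni(g1, g2)
    expect_gt(est$ani, 95.5)
    expect_lt(est$ani, 98.5)
    expect_lt(abs(est$ani - hamming), 1.5)
  })

  # disjoint k-mer sets
  a <- strrep("A", 5000)
  c <- strrep("C", 5000)
  far <- estimateAni(a, c)
  expect_equal(far$ani, 0)
  expect_equal(far$aligned_fraction, 0)
  expect_error(estimateAni("ACGT", a), ">= 5 kb")
})
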