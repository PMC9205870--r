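#' Evaluate code under a temporary RNG seed
#'
#' Runs \code{code} with the RNG seeded to \code{seed} and restores the
#' caller's RNG state afterwards, so fixture generation never perturbs user
#' randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of \code{code}.
#' @export
withSeed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else suppressWarnings(rm(".Random.seed", envir = env))
  })
  set.seed(seed)
  force(code)
}

# order-3 Markov DNA using the current RNG: per-context GC targets jitter
# around `gc`, transition row = symmetric A/T, C/G split of that target
.markovSeq <- function(length, gc) {
  gcCtx <- pmin(0.95, pmax(0.05, gc + stats::runif(64, -0.08, 0.08)))
  p <- cbind((1 - gcCtx) / 2, gcCtx / 2, gcCtx / 2, (1 - gcCtx) / 2)
  c1 <- p[, 1]; c2 <- p[, 1] + p[, 2]; c3 <- 1 - p[, 4]
  u <- stats::runif(length)
  b <- integer(length)
  base0 <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  b[1:3] <- sample.int(4L, 3L, replace = TRUE, prob = base0)
  ctx <- (b[1] - 1L) * 16L + (b[2] - 1L) * 4L + b[3]
  for (i in 4:length) {
    bi <- 1L + (u[i] > c1[ctx]) + (u[i] > c2[ctx]) + (u[i] > c3[ctx])
    b[i] <- bi
    ctx <- ((ctx - 1L) %% 16L) * 4L + bi
  }
  paste(c("A", "C", "G", "T")[b], collapse = "")
}

.gcContent <- function(s) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  mean(v %in% c("G", "C"))
}

#' Generate a synthetic genome sequence
#'
#' Order-3 Markov DNA with context-jittered transition probabilities around
#' a target GC content. The realized GC is within 0.02 of the target (one
#' deterministic correction pass re-centers the target if the first draw
#' lands outside the band). Deterministic per (length, seed, gc).
#'
#' @param length sequence length in bp, >= 10 kb.
#' @param seed integer seed.
#' @param gc target GC content, strictly between 0.2 and 0.8.
#' @return A character DNA sequence.
#' @export
makeGenome <- function(length, seed, gc = 0.45) {
  if (length < 10000) stop("genome length must be >= 10 kb")
  if (gc <= 0.2 || gc >= 0.8) stop("gc must be in (0.2, 0.8)")
  withSeed(seed, {
    s <- .markovSeq(length, gc)
    realized <- .gcContent(s)
    if (abs(realized - gc) > 0.02)
      s <- .markovSeq(length, gc + (gc - realized))
    s
  })
}

#' Generate a synthetic genome bin with planted contaminants
#'
#' Fragments a host genome into contigs and plants contaminants of the
#' three kinds the decontamination filters target, with known ground
#' truth:
#' \describe{
#'   \item{tax}{host-derived sequence labelled with a lineage that
#'     conflicts with the bin lineage at the family rank;}
#'   \item{mobile}{evidence of a mobile element, cycling (per plant) among
#'     terminal redundancy written into the sequence, a whole-contig viral
#'     prediction (category 1--3), a provirus prediction (category 4--6,
#'     viral fraction >= 0.55), and a passing terL hit on a 1--10 kb
#'     contig;}
#'   \item{outlier}{sequence drawn from a divergent composition model (GC
#'     shifted by \code{gcShift}) with coverage scaled by
#'     \code{coverageScale} in the first sample.}
#' }
#' Host contigs receive lineages consistent with the bin lineage (full
#' path, prefixes, genus extensions, starred or species-bearing tails that
#' trimming removes, and some unclassified), host-like coverage, and no
#' mobile evidence.
#'
#' @param host host genome sequence (character), e.g. from
#'   \code{\link{makeGenome}}.
#' @param nContigs number of contigs in the bin (including plants).
#' @param plants named list of plant counts, e.g.
#'   \code{list(tax = 1, mobile = 1, outlier = 1)}; total must be below
#'   \code{nContigs}.
#' @param seed integer seed.
#' @param binId bin identifier.
#' @param nSamples samples in the coverage profile.
#' @param hostGc GC of the host model (used for the outlier shift).
#' @param gcShift composition shift of outlier plants (default 0.15, easy
#'   regime; the hard regime uses 0.04).
#' @param coverageScale coverage multiplier of outlier plants in sample 1
#'   (default 8; hard regime 2).
#' @param contigLengthRange range of contig lengths, bp; the default
#'   3--5 kb keeps every contig inside both the viral-predictor range
#'   (>= 3 kb) and the terL scan range (1--10 kb).
#' @return A list with \code{bin} (\linkS4class{GenomeBin}),
#'   \code{genomeLineage}, \code{contigLineages}, \code{evidence} and
#'   \code{truth} (list of planted ids per filter type plus the seed).
#' @export
makeBin <- function(host, nContigs, plants = list(tax = 1, mobile = 1,
                                                  outlier = 1),
                    seed = 1L, binId = "bin1", nSamples = 4L,
                    hostGc = 0.45, gcShift = 0.15, coverageScale = 8,
                    contigLengthRange = c(3000L, 5000L)) {
  nPlant <- sum(unlist(plants))
  if (nPlant >= nContigs) stop("plant counts must be below nContigs")
  withSeed(seed, {
    lens <- sample(contigLengthRange[1]:contigLengthRange[2], nContigs,
                   replace = TRUE)
    if (sum(lens) > nchar(host))
      stop("host genome too short for ", nContigs, " contigs this size")
    ids <- sprintf("%s_c%02d", binId, seq_len(nContigs))
    starts <- cumsum(c(1L, lens[-nContigs]))
    seqs <- substring(host, starts, starts + lens - 1L)

    roles <- rep("host", nContigs)
    plantIdx <- sample(nContigs, nPlant)
    roles[plantIdx] <- rep(names(plants), unlist(plants))
    mobileMode <- sample.int(4L, 1L) - 1L  # vary evidence routes across bins

    # bin lineage: sk;phylum;class;order;family
    gl <- Lineage(c("superkingdom", "phylum", "class", "order", "family"),
                  c("Bacteria", paste0("P_", binId), paste0("C_", binId),
                    paste0("O_", binId), paste0("F_", binId)))
    contigLineages <- vector("list", nContigs)
    names(contigLineages) <- ids
    evRows <- list()

    for (i in seq_len(nContigs)) {
      if (roles[i] == "tax") {
        # conflict at family rank
        contigLineages[[i]] <- Lineage(
          c("superkingdom", "phylum", "class", "order", "family"),
          c("Bacteria", paste0("P_", binId), paste0("C_", binId),
            paste0("O_", binId), paste0("F_alt_", binId)))
      } else if (roles[i] == "mobile") {
        mobileMode <- mobileMode %% 4L + 1L
        contigLineages[[i]] <- Lineage()
        if (mobileMode == 1L) {
          # terminal redundancy: 60 bp repeat copied to the end
          p <- substr(seqs[i], 1, 60)
          seqs[i] <- paste0(substr(seqs[i], 1, lens[i] - 60), p)
        } else if (mobileMode == 2L) {
          evRows[[length(evRows) + 1]] <- list(
            id = ids[i], circular = FALSE,
            category = sample(1:3, 1), fraction = NA_real_, hits = NULL)
        } else if (mobileMode == 3L) {
          evRows[[length(evRows) + 1]] <- list(
            id = ids[i], circular = FALSE,
            category = sample(4:6, 1),
            fraction = stats::runif(1, 0.55, 0.9), hits = NULL)
        } else {
          # terL route needs a 1-10 kb contig; lengths are drawn <= 5 kb
          evRows[[length(evRows) + 1]] <- list(
            id = ids[i], circular = FALSE,
            category = NA_integer_, fraction = NA_real_,
            hits = data.frame(
              evalue = c(10^stats::runif(1, -15, -11), 1e-8),
              domain = c(sample(terlDomains(), 1), "Portal"),
              probability = c(stats::runif(1, 98, 99.5), 99),
              stringsAsFactors = FALSE))
        }
      } else if (roles[i] == "outlier") {
        seqs[i] <- .markovSeq(lens[i], hostGc + gcShift)
        contigLineages[[i]] <- Lineage()
      } else {
        contigLineages[[i]] <- switch(1L + (i %% 6L),
          gl,
          Lineage(c("superkingdom", "phylum", "class", "order"),
                  c("Bacteria", paste0("P_", binId), paste0("C_", binId),
                    paste0("O_", binId))),
          Lineage(c("superkingdom", "phylum", "class", "order", "family",
                    "genus"),
                  c("Bacteria", paste0("P_", binId), paste0("C_", binId),
                    paste0("O_", binId), paste0("F_", binId),
                    paste0("G_", binId))),
          Lineage(),
          Lineage(c("superkingdom", "phylum", "class", "order", "family",
                    "genus", "species"),
                  c("Bacteria", paste0("P_", binId), paste0("C_", binId),
                    paste0("O_", binId), paste0("F_", binId),
                    paste0("G_", binId), paste0("S_", binId))),
          Lineage(c("superkingdom", "phylum", "class", "order", "family",
                    "genus"),
                  c("Bacteria", paste0("P_", binId), paste0("C_", binId),
                    paste0("O_", binId), paste0("F_", binId),
                    paste0("G_other_", binId)),
                  suggestive = c(rep(FALSE, 5), TRUE)))
      }
    }

    lambda <- stats::runif(nSamples, 5, 30)
    cov <- t(vapply(seq_len(nContigs), function(i)
      lambda * exp(stats::rnorm(nSamples, 0, 0.05)), numeric(nSamples)))
    cov[roles == "outlier", 1] <- cov[roles == "outlier", 1] * coverageScale
    dimnames(cov) <- list(ids, paste0("S", seq_len(nSamples)))

    evidence <- if (length(evRows) > 0) {
      df <- data.frame(
        contig_id = vapply(evRows, `[[`, character(1), "id"),
        circular = vapply(evRows, `[[`, logical(1), "circular"),
        category = vapply(evRows, `[[`, integer(1), "category"),
        viral_fraction = vapply(evRows, `[[`, numeric(1), "fraction"),
        stringsAsFactors = FALSE)
      df$terl_hits <- lapply(evRows, function(r)
        if (is.null(r$hits)) data.frame(evalue = numeric(0),
                                        domain = character(0),
                                        probability = numeric(0))
        else r$hits)
      df
    } else NULL

    bin <- GenomeBin(binId, stats::setNames(seqs, ids), coverage = cov)
    truth <- list(tax = ids[roles == "tax"],
                  mobile = ids[roles == "mobile"],
                  outlier = ids[roles == "outlier"], seed = seed)
    list(bin = bin, genomeLineage = gl, contigLineages = contigLineages,
         evidence = evidence, truth = truth)
  })
}

#' Generate a set of synthetic bins with planted contaminants
#'
#' The "easy" preset plants strongly divergent contaminants (GC shift 0.15,
#' coverage x8) that the filters recover completely; the "hard" preset
#' (GC shift 0.04, coverage x2) exists for sensitivity exploration and
#' carries no recovery guarantee. Per-bin seeds are derived
#' deterministically from \code{seed}.
#'
#' @param nBins number of bins.
#' @param seed master seed.
#' @param nContigs contigs per bin.
#' @param plants plant counts per bin (see \code{\link{makeBin}}).
#' @param preset "easy" or "hard".
#' @return A list of \code{\link{makeBin}} results, one per bin.
#' @export
makeFixtureSet <- function(nBins = 30L, seed = 7L, nContigs = 24L,
                           plants = list(tax = 1, mobile = 1, outlier = 1),
                           preset = c("easy", "hard")) {
  preset <- match.arg(preset)
  gcShift <- if (preset == "easy") 0.15 else 0.04
  covScale <- if (preset == "easy") 8 else 2
  lapply(seq_len(nBins), function(b) {
    binSeed <- as.integer((as.numeric(seed) * 1009 + b * 9176) %% 2147483647)
    host <- makeGenome(nContigs * 5100L, seed = binSeed, gc = 0.45)
    makeBin(host, nContigs, plants, seed = binSeed + 1L,
            binId = sprintf("bin%03d", b), gcShift = gcShift,
            coverageScale = covScale)
  })
}

#' Write a fixture set to disk in the toolkit's file formats
#'
#' Emits \code{bins/<id>.fasta}, \code{coverage.tsv},
#' \code{contig_tax.tsv}, \code{genome_tax.tsv}, \code{evidence.tsv} and
#' \code{truth.tsv} under \code{dir}.
#'
#' @param fixtures result of \code{\link{makeFixtureSet}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeFixtureSet <- function(fixtures, dir) {
  dir.create(file.path(dir, "bins"), recursive = TRUE, showWarnings = FALSE)
  covAll <- do.call(rbind, lapply(fixtures, function(f) coverage(f$bin)))
  writeCoverageTable(covAll, file.path(dir, "coverage.tsv"))
  ctax <- do.call(c, lapply(fixtures, function(f) f$contigLineages))
  writeLineageTable(ctax, file.path(dir, "contig_tax.tsv"))
  gtax <- lapply(fixtures, function(f) f$genomeLineage)
  names(gtax) <- vapply(fixtures, function(f) binId(f$bin), character(1))
  writeLineageTable(gtax, file.path(dir, "genome_tax.tsv"))
  ev <- do.call(rbind, Filter(Negate(is.null),
                              lapply(fixtures, function(f) f$evidence)))
  if (is.null(ev)) {
    writeLines(character(0), file.path(dir, "evidence.tsv"))
  } else {
    writeEvidenceTable(ev, file.path(dir, "evidence.tsv"))
  }
  truth <- do.call(rbind, lapply(fixtures, function(f)
    data.frame(bin = binId(f$bin),
               type = rep(c("tax", "mobile", "outlier"),
                          lengths(f$truth[c("tax", "mobile", "outlier")])),
               contig_id = unlist(f$truth[c("tax", "mobile", "outlier")]),
               stringsAsFactors = FALSE)))
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (f in fixtures)
    writeFasta(contigs(f$bin),
               file.path(dir, "bins", paste0(binId(f$bin), ".fasta")))
  invisible(dir)
}

#' Generate a synthetic pileup with planted SNP sites
#'
#' Depth is Poisson(\code{depthMean}); true SNP sites (per-site probability
#' \code{snpRate}) get a minor-allele fraction drawn in [0.25, 0.5]; other
#' sites carry at most 5% non-dominant bases, so their dominant fraction is
#' at least 0.95.
#'
#' @param genomeLength sites to simulate.
#' @param snpRate per-site SNP probability in [0, 0.05].
#' @param depthMean mean depth.
#' @param seed integer seed.
#' @param contig contig id for the table.
#' @return A list with \code{pileup} (data.frame \code{contig, pos, A, C,
#'   G, T}) and \code{truth} (1-based positions of true SNP sites).
#' @export
makePileup <- function(genomeLength, snpRate, depthMean, seed = 1L,
                       contig = "c1") {
  if (snpRate < 0 || snpRate > 0.05) stop("snpRate must be in [0, 0.05]")
  withSeed(seed, {
    depth <- stats::rpois(genomeLength, depthMean)
    isSnp <- stats::runif(genomeLength) < snpRate
    refBase <- sample.int(4L, genomeLength, replace = TRUE)
    altBase <- (refBase + sample.int(3L, genomeLength, replace = TRUE) - 1L) %% 4L + 1L
    minor <- integer(genomeLength)
    minor[isSnp] <- round(stats::runif(sum(isSnp), 0.25, 0.5) *
                            depth[isSnp])
    err <- floor(0.05 * depth)
    minor[!isSnp] <- pmin(err[!isSnp],
                          sample(0:2, sum(!isSnp), replace = TRUE))
    minor <- pmin(minor, depth)
    counts <- matrix(0L, nrow = genomeLength, ncol = 4,
                     dimnames = list(NULL, c("A", "C", "G", "T")))
    counts[cbind(seq_len(genomeLength), refBase)] <- depth - minor
    counts[cbind(seq_len(genomeLength), altBase)] <-
      counts[cbind(seq_len(genomeLength), altBase)] + minor
    list(pileup = data.frame(contig = contig, pos = seq_len(genomeLength),
                             counts, stringsAsFactors = FALSE),
         truth = which(isSnp))
  })
}

#' Generate alignment records with an exact expected recruitment
#'
#' Exactly \code{floor(nReads * passFraction)} reads receive one record
#' passing all three recruitment criteria (>= 95% identity, >= 80 bp,
#' >= 80% aligned fraction); every other read receives a record failing
#' exactly one criterion, cycling through the three.
#'
#' @param nReads total reads.
#' @param passFraction fraction in [0, 1].
#' @param seed integer seed.
#' @param target target id the records map to.
#' @return A list with \code{records} (alignment data.frame),
#'   \code{totalReads} and \code{expected} (the exact recruitment percent,
#'   100 * floor(nReads * passFraction) / nReads).
#' @export
makeAlignments <- function(nReads, passFraction, seed = 1L,
                           target = "rep1") {
  if (passFraction < 0 || passFraction > 1)
    stop("passFraction must be in [0, 1]")
  nPass <- floor(nReads * passFraction)
  withSeed(seed, {
    ids <- sprintf("read%06d", seq_len(nReads))
    rl <- integer(nReads); al <- integer(nReads); ed <- integer(nReads)
    if (nPass > 0) {
      rl[1:nPass] <- 100L; al[1:nPass] <- 100L
      ed[1:nPass] <- sample(0:5, nPass, replace = TRUE)
    }
    if (nPass < nReads) {
      failMode <- (seq_len(nReads - nPass) - 1L) %% 3L
      i <- (nPass + 1L):nReads
      rl[i][failMode == 0L] <- 100L  # identity fails: 94%
      al[i][failMode == 0L] <- 100L
      ed[i][failMode == 0L] <- 6L
      rl[i][failMode == 1L] <- 90L   # aligned length fails: 79 < 80
      al[i][failMode == 1L] <- 79L
      ed[i][failMode == 1L] <- 0L
      rl[i][failMode == 2L] <- 150L  # aligned fraction fails: 66.7%
      al[i][failMode == 2L] <- 100L
      ed[i][failMode == 2L] <- 0L
    }
    records <- data.frame(read_id = ids, read_length = rl,
                          aligned_length = al, edit_distance = ed,
                          target_id = target, stringsAsFactors = FALSE)
    list(records = records, totalReads = nReads,
         expected = 100 * nPass / nReads)
  })
}
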