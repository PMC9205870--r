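#' Detect terminal redundancy (circularity) in a contig
#'
#' A contig assembled from a circular template carries the same sequence at
#' both ends. The detector reports a contig circular when a prefix of at
#' least \code{minOverlap} bp matches a suffix of equal length within the
#' mismatch budget, and returns the longest such overlap. Candidate overlap
#' lengths are located by matching the first \code{minOverlap} bp seed along
#' the sequence and verified over the full overlap, so the scan stays fast
#' on long contigs. Sequences shorter than \code{2 * minOverlap} are
#' reported non-circular (overlap 0), not an error.
#'
#' @param seq a \code{DNAString}, \code{DNAStringSet} element or character
#'   DNA sequence.
#' @param minOverlap minimum overlap length in bp (default 50).
#' @param maxMismatchRate allowed mismatch fraction within the overlap
#'   (default 0, exact match; a tolerant mode uses e.g. 0.05).
#' @return A list with \code{circular} (logical) and \code{overlap}
#'   (bp, 0 when not circular).
#' @examples
#' p <- paste(rep("ACGTTGCA", 8), collapse = "")  # 64 bp repeat
#' s <- paste0(p, strrep("A", 500), p)
#' detectTerminalRedundancy(s)$circular  # TRUE
#' @export
detectTerminalRedundancy <- function(seq, minOverlap = 50L,
                                     maxMismatchRate = 0) {
  s <- if (is(seq, "DNAString")) seq else Biostrings::DNAString(as.character(seq))
  n <- length(s)
  if (n < 2L * minOverlap) return(list(circular = FALSE, overlap = 0L))
  seed <- Biostrings::subseq(s, 1L, minOverlap)
  seedMism <- floor(maxMismatchRate * minOverlap)
  hits <- Biostrings::matchPattern(seed, s, max.mismatch = seedMism)
  starts <- BiocGenerics::start(hits)
  # prefix L == suffix L requires the seed at position n - L + 1
  Ls <- n - starts + 1L
  Ls <- sort(Ls[Ls >= minOverlap & Ls <= n %/% 2L], decreasing = TRUE)
  for (L in Ls) {
    mism <- Biostrings::neditStartingAt(Biostrings::subseq(s, 1L, L), s,
                                        starting.at = n - L + 1L)
    if (mism <= floor(maxMismatchRate * L))
      return(list(circular = TRUE, overlap = as.integer(L)))
  }
  list(circular = FALSE, overlap = 0L)
}

#' Is a viral prediction category viral?
#'
#' Predictor categories 1--3 (whole-contig predictions) are viral outright;
#' categories 4--6 (provirus predictions) are viral only when the viral
#' region spans at least half of the contig (inclusive).
#'
#' @param category integer 1--6.
#' @param viralFraction fraction of the contig covered by the predicted
#'   viral region, in [0, 1]; required for categories 4--6.
#' @return TRUE or FALSE.
#' @export
classifyViralPrediction <- function(category, viralFraction = NA_real_) {
  if (is.na(category) || category < 1 || category > 6)
    stop("predictor category must be in 1..6")
  if (category <= 3) return(TRUE)
  if (is.na(viralFraction))
    stop("viral-region fraction required for categories 4-6")
  viralFraction >= 0.5
}

#' The pfam terminase large-subunit domains
#'
#' @return Character vector of the seven pfam terL domain names.
#' @export
terlDomains <- function() {
  c("Terminase_1", "Terminase_3", "Terminase_6", "Terminase_GpA",
    "DNA_pack_N", "Terminase_3C", "Terminase_6C")
}

#' Does a terL hit list identify a terminase gene?
#'
#' TRUE when some hit satisfies all three criteria: HMM e-value strictly
#' below 1e-10, best domain among the pfam terL domains, and HHsearch
#' probability strictly above 97%.
#'
#' @param hits data.frame with columns \code{evalue}, \code{domain},
#'   \code{probability} (percent).
#' @param domains terL domain set, default \code{\link{terlDomains}()}.
#' @param maxEvalue,minProbability thresholds (strict).
#' @return TRUE or FALSE.
#' @export
filterTerlHits <- function(hits, domains = terlDomains(),
                           maxEvalue = 1e-10, minProbability = 97) {
  if (is.null(hits) || nrow(hits) == 0) return(FALSE)
  any(hits$evalue < maxEvalue & hits$domain %in% domains &
        hits$probability > minProbability)
}

#' Mobile-element decontamination filter for one bin
#'
#' Flags a contig when any of three independent evidence routes fires:
#' \enumerate{
#'   \item it is circular by terminal redundancy (from the evidence table,
#'     OR-ed with in-package detection on the sequences when
#'     \code{detectCircular} is TRUE);
#'   \item it is at least \code{minPredictorLength} bp (the viral
#'     predictor's working range) and carries a viral prediction
#'     (\code{\link{classifyViralPrediction}});
#'   \item its length lies in \code{terlRange} (the short-contig terL scan
#'     range, inclusive) and it carries a confident terL hit
#'     (\code{\link{filterTerlHits}}).
#' }
#'
#' @param bin a \linkS4class{GenomeBin}, or a named vector of contig
#'   lengths (bp) when sequences are unavailable.
#' @param evidence data.frame as from \code{\link{readEvidenceTable}};
#'   contigs without a row simply have no evidence.
#' @param minPredictorLength viral-predictor length floor, default 3000 bp.
#' @param terlRange terL scan range, default c(1000, 10000) bp.
#' @param detectCircular run \code{\link{detectTerminalRedundancy}} on the
#'   sequences (ignored when \code{bin} is a length vector).
#' @param minOverlap,maxMismatchRate passed to the redundancy detector.
#' @return A data.frame with columns \code{contig_id}, \code{length},
#'   \code{circular}, \code{viral}, \code{terl} and \code{flagged} (the OR
#'   of the three routes).
#' @export
mobileElementFilter <- function(bin, evidence = NULL,
                                minPredictorLength = 3000L,
                                terlRange = c(1000L, 10000L),
                                detectCircular = TRUE,
                                minOverlap = 50L, maxMismatchRate = 0) {
  if (is(bin, "GenomeBin")) {
    ids <- names(contigs(bin))
    lens <- Biostrings::width(contigs(bin))
    seqs <- contigs(bin)
  } else {
    ids <- names(bin)
    lens <- as.integer(bin)
    seqs <- NULL
  }
  if (is.null(evidence))
    evidence <- data.frame(contig_id = character(0), circular = logical(0),
                           category = integer(0), viral_fraction = numeric(0),
                           terl_hits = I(list()))
  row <- match(ids, evidence$contig_id)
  out <- data.frame(contig_id = ids, length = lens,
                    circular = FALSE, viral = FALSE, terl = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    r <- row[i]
    circ <- !is.na(r) && isTRUE(evidence$circular[r])
    if (!circ && detectCircular && !is.null(seqs))
      circ <- detectTerminalRedundancy(seqs[[i]], minOverlap,
                                       maxMismatchRate)$circular
    out$circular[i] <- circ
    if (!is.na(r) && !is.na(evidence$category[r]) &&
        lens[i] >= minPredictorLength)
      out$viral[i] <- classifyViralPrediction(evidence$category[r],
                                              evidence$viral_fraction[r])
    if (!is.na(r) && lens[i] >= terlRange[1] && lens[i] <= terlRange[2])
      out$terl[i] <- filterTerlHits(evidence$terl_hits[[r]])
  }
  out$flagged <- out$circular | out$viral | out$terl
  out
}
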