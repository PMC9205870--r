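#' Filter alignment records for recruitment
#'
#' Keeps records with percent identity
#' \code{100 (aligned_length - edit_distance) / aligned_length >=
#' minIdentity}, aligned length \code{>= minLen} bp, and aligned fraction
#' of the read \code{100 aligned_length / read_length >= minFrac}. All
#' three thresholds are inclusive.
#'
#' @param records data.frame with columns \code{read_id, read_length,
#'   aligned_length, edit_distance, target_id}.
#' @param minIdentity percent identity floor, default 95.
#' @param minLen aligned-length floor in bp, default 80.
#' @param minFrac aligned-fraction-of-read floor in percent, default 80.
#' @return The surviving records (same columns, plus \code{identity}).
#' @export
filterAlignments <- function(records, minIdentity = 95, minLen = 80,
                             minFrac = 80) {
  records <- .validateAlignments(records)
  identity <- 100 * (records$aligned_length - records$edit_distance) /
    records$aligned_length
  frac <- 100 * records$aligned_length / records$read_length
  keep <- identity >= minIdentity & records$aligned_length >= minLen &
    frac >= minFrac
  out <- records[keep, , drop = FALSE]
  out$identity <- identity[keep]
  rownames(out) <- NULL
  out
}

#' Per-site SNP verdicts from pileup base counts
#'
#' Sites with depth below \code{minDepth} are untested. A tested site is a
#' SNP when the proportion of the dominant nucleotide is no more than
#' \code{maxDominant} (inclusive); otherwise it is invariant.
#'
#' @param pileup data.frame with columns \code{contig, pos, A, C, G, T}.
#' @param minDepth depth floor for testing, default 10.
#' @param maxDominant dominant-base proportion ceiling for a SNP call,
#'   default 0.8 (inclusive).
#' @return The pileup with added columns \code{depth}, \code{dominant}
#'   (proportion, NA when depth 0) and \code{verdict} (factor untested /
#'   invariant / snp).
#' @export
snpSites <- function(pileup, minDepth = 10, maxDominant = 0.8) {
  m <- as.matrix(pileup[, c("A", "C", "G", "T")])
  depth <- rowSums(m)
  dominant <- ifelse(depth > 0, apply(m, 1, max) / depth, NA_real_)
  verdict <- ifelse(depth < minDepth, "untested",
                    ifelse(dominant <= maxDominant, "snp", "invariant"))
  out <- pileup
  out$depth <- depth
  out$dominant <- dominant
  out$verdict <- factor(verdict, levels = c("untested", "invariant", "snp"))
  out
}

#' SNP heterogeneity in SNP sites per kb of tested sites
#'
#' 1000 x (number of SNP sites) / (number of tested sites), a within-
#' population polymorphism proxy. Undefined (NA) when no site passes the
#' depth floor.
#'
#' @param pileup data.frame with columns \code{contig, pos, A, C, G, T}.
#' @param minDepth,maxDominant as in \code{\link{snpSites}}.
#' @return SNP sites per kb (NA when zero tested sites).
#' @export
heterogeneity <- function(pileup, minDepth = 10, maxDominant = 0.8) {
  v <- snpSites(pileup, minDepth, maxDominant)$verdict
  tested <- sum(v != "untested")
  if (tested == 0) {
    warning("no tested sites; heterogeneity undefined")
    return(NA_real_)
  }
  1000 * sum(v == "snp") / tested
}

#' Mean read coverage over a genome
#'
#' Arithmetic mean of per-site depth over all genome positions, zero-depth
#' positions included. When the depth vector omits zero-depth sites,
#' supply \code{genomeLength} to restore them.
#'
#' @param depth numeric vector of per-site depths.
#' @param genomeLength total genome length in bp; default
#'   \code{length(depth)}.
#' @return Mean coverage.
#' @export
meanCoverage <- function(depth, genomeLength = length(depth)) {
  if (genomeLength < 1) stop("empty genome")
  if (length(depth) > genomeLength)
    stop("more depth values than genome positions")
  sum(depth) / genomeLength
}

#' Read-recruitment fraction onto a target set
#'
#' Applies the alignment filter, then counts distinct read ids with at
#' least one surviving alignment to any target in the set; a multi-mapped
#' read counts once.
#'
#' @param records alignment records (see \code{\link{filterAlignments}}).
#' @param totalReads total reads in the metagenome (>= 1).
#' @param targets character vector of target ids (genomes/contigs); an
#'   empty set recruits nothing.
#' @param minIdentity,minLen,minFrac filter thresholds.
#' @return A one-row data.frame with \code{reads_total},
#'   \code{reads_mapped_pass} and \code{fraction} (percent).
#' @export
recruitmentFraction <- function(records, totalReads, targets,
                                minIdentity = 95, minLen = 80,
                                minFrac = 80) {
  if (totalReads < 1) stop("totalReads must be >= 1")
  pass <- filterAlignments(records, minIdentity, minLen, minFrac)
  pass <- pass[pass$target_id %in% targets, , drop = FALSE]
  n <- length(unique(pass$read_id))
  data.frame(reads_total = totalReads, reads_mapped_pass = n,
             fraction = 100 * n / totalReads)
}
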