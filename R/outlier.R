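#' Canonical tetranucleotide frequencies of a sequence
#'
#' Counts overlapping 4-mers, pools each 4-mer with its reverse complement
#' into one of 136 canonical classes (120 pairs plus 16 palindromes) so the
#' profile is strand-symmetric, and normalizes to sum to 1. Windows
#' containing non-ACGT letters are skipped.
#'
#' @param seq a \code{DNAString} or character DNA sequence of length >= 4.
#' @return Named numeric vector over the 136 canonical 4-mer classes
#'   (names are the lexicographically smaller member of each pair).
#' @export
tetranucleotideFrequencies <- function(seq) {
  s <- if (is(seq, "DNAString")) seq else Biostrings::DNAString(as.character(seq))
  if (length(s) < 4) stop("sequence shorter than one 4-mer window")
  counts <- Biostrings::oligonucleotideFrequency(s, width = 4)
  pooled <- rowsum(as.numeric(counts), group = .canonical4mers())
  total <- sum(pooled)
  if (total == 0) stop("no valid 4-mer window (non-ACGT letters only)")
  stats::setNames(as.numeric(pooled) / total, rownames(pooled))
}

.canonicalCache <- new.env(parent = emptyenv())

.canonical4mers <- function() {
  if (is.null(.canonicalCache$map)) {
    kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 4)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(kmers)))
    .canonicalCache$map <- pmin(kmers, rc)
  }
  .canonicalCache$map
}

#' Composition matrix of a bin
#'
#' One row per contig of canonical tetranucleotide frequencies.
#'
#' @param bin a \linkS4class{GenomeBin} or \code{DNAStringSet}.
#' @return Numeric matrix, contigs x 136 canonical 4-mer classes.
#' @export
compositionMatrix <- function(bin) {
  seqs <- if (is(bin, "GenomeBin")) contigs(bin) else bin
  t(vapply(seq_along(seqs),
           function(i) tetranucleotideFrequencies(seqs[[i]]),
           numeric(136))) -> m
  rownames(m) <- names(seqs)
  m
}

#' Normalize a coverage matrix within each sample
#'
#' Each sample column is divided by its column sum over the bin's contigs,
#' so columns describe the within-bin distribution of coverage and samples
#' of very different sequencing depth become commensurate. An all-zero
#' column maps to all zeros.
#'
#' @param m numeric matrix, contigs x samples, values >= 0.
#' @return Matrix of the same shape with column sums 1 (or 0).
#' @export
normalizeCoverage <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("coverage values must be non-negative")
  cs <- colSums(m)
  cs[cs == 0] <- 1
  sweep(m, 2, cs, "/")
}

#' Standardized first-principal-component scores
#'
#' Centers the columns (no variance scaling), projects the rows onto the
#' first principal axis, and standardizes the scores to mean 0 and
#' population (n-denominator) standard deviation 1. Scores are undefined
#' (NA) for a single row or a matrix with zero total variance.
#'
#' @param m numeric matrix, rows are contigs.
#' @return Named numeric vector of z-scores (NA when undefined).
#' @export
pc1Zscores <- function(m) {
  m <- as.matrix(m)
  ids <- rownames(m)
  if (nrow(m) < 2)
    return(stats::setNames(rep(NA_real_, nrow(m)), ids))
  centered <- scale(m, center = TRUE, scale = FALSE)
  if (sum(centered^2) == 0)
    return(stats::setNames(rep(NA_real_, nrow(m)), ids))
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  s <- p$x[, 1]
  sdpop <- sqrt(mean((s - mean(s))^2))
  if (sdpop == 0)
    return(stats::setNames(rep(NA_real_, nrow(m)), ids))
  stats::setNames((s - mean(s)) / sdpop, ids)
}

#' Outlier decontamination filter for one bin
#'
#' Runs two separate first-principal-component analyses over the bin's
#' contigs -- one on the canonical tetranucleotide composition matrix, one
#' on the per-sample-normalized coverage matrix -- and flags contigs whose
#' standardized PC1 score falls strictly below -threshold or strictly above
#' +threshold in either analysis. Undefined scores (single-contig bin,
#' constant matrix, no coverage profile) never flag.
#'
#' @param bin a \linkS4class{GenomeBin}.
#' @param threshold z-score cut, default 2.5 (strict inequalities).
#' @return A data.frame with columns \code{contig_id},
#'   \code{z_composition}, \code{z_coverage} and \code{flagged}.
#' @export
outlierContigs <- function(bin, threshold = 2.5) {
  stopifnot(is(bin, "GenomeBin"))
  ids <- names(contigs(bin))
  zc <- pc1Zscores(compositionMatrix(bin))
  cov <- coverage(bin)
  zv <- if (ncol(cov) > 0) pc1Zscores(normalizeCoverage(cov))
        else stats::setNames(rep(NA_real_, length(ids)), ids)
  beyond <- function(z) !is.na(z) & (z < -threshold | z > threshold)
  data.frame(contig_id = ids,
             z_composition = unname(zc[ids]),
             z_coverage = unname(zv[ids]),
             flagged = beyond(zc[ids]) | beyond(zv[ids]),
             stringsAsFactors = FALSE)
}
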