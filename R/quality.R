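#' Genome quality score
#'
#' QS = completeness - 5 x contamination, both in percent. The score may be
#' negative for heavily contaminated bins.
#'
#' @param completeness percent in [0, 100].
#' @param contamination percent >= 0.
#' @return The quality score (vectorized).
#' @examples
#' qualityScore(85, 7)   # 50
#' qualityScore(50, 20)  # -50
#' @export
qualityScore <- function(completeness, contamination) {
  if (any(completeness < 0 | completeness > 100, na.rm = TRUE))
    stop("completeness must be in [0, 100]")
  if (any(contamination < 0, na.rm = TRUE))
    stop("contamination must be >= 0")
  completeness - 5 * contamination
}

#' Qualification gate on the quality score
#'
#' A genome is qualified when QS >= threshold (inclusive); the default gate
#' is 50.
#'
#' @param qs quality score(s).
#' @param threshold gate, default 50.
#' @return Logical vector.
#' @export
isQualified <- function(qs, threshold = 50) {
  qs >= threshold
}

#' Representative score for dereplication
#'
#' QS + ln(N50), with N50 in bp. Used to pick the species representative
#' within each cluster: the member with the highest score wins (ties broken
#' by lexicographically smallest genome id elsewhere).
#'
#' @param qs quality score(s).
#' @param n50 assembly N50 in bp, >= 1.
#' @return QS + log(N50) (vectorized).
#' @examples
#' representativeScore(60, 1000)  # 60 + ln(1000) = 66.9078
#' @export
representativeScore <- function(qs, n50) {
  if (any(n50 < 1, na.rm = TRUE)) stop("n50 must be >= 1 bp")
  qs + log(n50)
}

#' MIMAG draft-quality tier
#'
#' Tiers a genome against the MIMAG standard: "high" requires completeness
#' > 90%, contamination < 5%, the 5S, 16S and 23S rRNAs all present, and at
#' least 18 unique tRNAs; "medium" requires completeness >= 50% and
#' contamination < 10%; everything else is "low". Thresholds are exposed as
#' arguments.
#'
#' @param completeness,contamination percent.
#' @param has5S,has16S,has23S logical, rRNA presence (complete or >25%
#'   fragment).
#' @param uniqueTrnas integer count of distinct tRNA isotypes (0--64).
#' @param highCompleteness,highContamination,minTrnas,mediumCompleteness,mediumContamination
#'   tier thresholds.
#' @return Character vector in \code{c("high", "medium", "low")}.
#' @export
mimagTier <- function(completeness, contamination,
                      has5S, has16S, has23S, uniqueTrnas,
                      highCompleteness = 90, highContamination = 5,
                      minTrnas = 18,
                      mediumCompleteness = 50, mediumContamination = 10) {
  if (any(uniqueTrnas < 0 | uniqueTrnas > 64))
    stop("uniqueTrnas must be in [0, 64]")
  n <- max(length(completeness), length(contamination))
  completeness <- rep_len(completeness, n)
  contamination <- rep_len(contamination, n)
  has5S <- rep_len(has5S, n); has16S <- rep_len(has16S, n)
  has23S <- rep_len(has23S, n); uniqueTrnas <- rep_len(uniqueTrnas, n)
  high <- completeness > highCompleteness &
    contamination < highContamination &
    has5S & has16S & has23S & uniqueTrnas >= minTrnas
  medium <- completeness >= mediumCompleteness &
    contamination < mediumContamination
  ifelse(high, "high", ifelse(medium, "medium", "low"))
}
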