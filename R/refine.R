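#' Configuration for bin refinement
#'
#' Collects the tunable thresholds of the three decontamination filters and
#' the qualification gate. Defaults are the standard operating point:
#' outlier cut at 2.5 s.d., viral-predictor floor 3 kb, terL scan range
#' 1--10 kb, terminal-redundancy overlap 50 bp exact, QS gate 50.
#'
#' @param outlierThreshold PC1 z-score cut (strict).
#' @param minPredictorLength viral predictor length floor, bp.
#' @param terlRange terL scan range, bp, inclusive.
#' @param minOverlap,maxMismatchRate terminal-redundancy parameters.
#' @param detectCircular also detect circularity from the sequences.
#' @param qsThreshold qualification gate on QS.
#' @return A named list of settings.
#' @export
refineConfig <- function(outlierThreshold = 2.5,
                         minPredictorLength = 3000L,
                         terlRange = c(1000L, 10000L),
                         minOverlap = 50L, maxMismatchRate = 0,
                         detectCircular = TRUE,
                         qsThreshold = 50) {
  list(outlierThreshold = outlierThreshold,
       minPredictorLength = minPredictorLength,
       terlRange = terlRange, minOverlap = minOverlap,
       maxMismatchRate = maxMismatchRate,
       detectCircular = detectCircular, qsThreshold = qsThreshold)
}

#' Refine one genome bin with the three decontamination filters
#'
#' Runs the taxonomic, mobile-element and outlier filters independently on
#' the original bin (no filter sees another's removals), removes the union
#' of the flagged contigs, and returns the refined bin plus a report.
#' Survivor sequences are byte-identical to the input and keep input order.
#'
#' @param bin a \linkS4class{GenomeBin}.
#' @param contigLineages named list of \linkS4class{Lineage} per contig, or
#'   NULL to skip the taxonomic filter.
#' @param genomeLineage \linkS4class{Lineage} of the bin (required when
#'   \code{contigLineages} is given).
#' @param evidence mobile-element evidence data.frame (see
#'   \code{\link{readEvidenceTable}}), or NULL for no evidence.
#' @param config a \code{\link{refineConfig}} list.
#' @return A list with \code{bin} (the refined \linkS4class{GenomeBin}, or
#'   NULL when no contig survives) and \code{report}, itself a list with
#'   \code{contigs} (per-contig data.frame of the three verdicts and
#'   \code{removed}) and \code{summary} (one-row data.frame with bin id,
#'   contigs before/after/removed, per-filter counts, and placeholders
#'   \code{qs_before}, \code{qs_after}, \code{discarded} filled by
#'   \code{\link{requalify}}).
#' @export
refineBin <- function(bin, contigLineages = NULL, genomeLineage = NULL,
                      evidence = NULL, config = refineConfig()) {
  stopifnot(is(bin, "GenomeBin"))
  ids <- names(contigs(bin))

  taxFlag <- stats::setNames(rep(FALSE, length(ids)), ids)
  if (!is.null(contigLineages)) {
    if (is.null(genomeLineage))
      stop("genomeLineage required when contig lineages are given")
    tv <- taxonomicFilter(bin, contigLineages, genomeLineage)
    taxFlag[tv$contig_id] <- tv$flagged
  }
  mv <- mobileElementFilter(bin, evidence,
                            minPredictorLength = config$minPredictorLength,
                            terlRange = config$terlRange,
                            detectCircular = config$detectCircular,
                            minOverlap = config$minOverlap,
                            maxMismatchRate = config$maxMismatchRate)
  mobFlag <- stats::setNames(mv$flagged, mv$contig_id)[ids]
  ov <- outlierContigs(bin, threshold = config$outlierThreshold)
  outFlag <- stats::setNames(ov$flagged, ov$contig_id)[ids]

  perContig <- data.frame(contig_id = ids,
                          tax = unname(taxFlag), mobile = unname(mobFlag),
                          outlier = unname(outFlag),
                          stringsAsFactors = FALSE)
  perContig$removed <- perContig$tax | perContig$mobile | perContig$outlier

  keep <- ids[!perContig$removed]
  refined <- if (length(keep) > 0) {
    cov <- coverage(bin)
    GenomeBin(binId(bin), contigs(bin)[keep],
              coverage = if (ncol(cov) > 0) cov[keep, , drop = FALSE]
                         else NULL,
              division = bin@division, sample = bin@sample)
  } else NULL

  summary <- data.frame(bin_id = binId(bin),
                        contigs_before = length(ids),
                        contigs_after = length(keep),
                        contigs_removed = sum(perContig$removed),
                        removed_tax = sum(perContig$tax),
                        removed_mobile = sum(perContig$mobile),
                        removed_outlier = sum(perContig$outlier),
                        qs_before = NA_real_, qs_after = NA_real_,
                        discarded = NA, stringsAsFactors = FALSE)
  list(bin = refined,
       report = list(contigs = perContig, summary = summary))
}

#' Requalify a refined bin from a fresh quality assessment
#'
#' Completeness and contamination of the refined bin are re-estimated by an
#' external marker-gene tool and supplied here; the bin is discarded when
#' the new QS falls strictly below the threshold (QS >= threshold keeps).
#'
#' @param report a report from \code{\link{refineBin}}.
#' @param completeness,contamination fresh assessment of the refined bin
#'   (percent).
#' @param qsBefore optional QS of the bin before refinement, for the
#'   report.
#' @param threshold qualification gate, default 50.
#' @return The report with \code{qs_after} (and optionally
#'   \code{qs_before}) and \code{discarded} filled in.
#' @export
requalify <- function(report, completeness, contamination,
                      qsBefore = NA_real_, threshold = 50) {
  qs <- qualityScore(completeness, contamination)
  report$summary$qs_before <- qsBefore
  report$summary$qs_after <- qs
  report$summary$discarded <- !isQualified(qs, threshold)
  report
}

#' Summarize a refinement run over many bins
#'
#' @param reports list of reports from \code{\link{refineBin}} (after
#'   \code{\link{requalify}} where available).
#' @return A one-row data.frame with \code{bins_assessed}, per-filter
#'   removal totals, \code{contigs_removed} (union total),
#'   \code{mean_removed_per_bin}, \code{bins_discarded} and
#'   \code{bins_retained}.
#' @export
summarizeRun <- function(reports) {
  if (length(reports) == 0)
    return(data.frame(bins_assessed = 0L, removed_tax = 0L,
                      removed_mobile = 0L, removed_outlier = 0L,
                      contigs_removed = 0L, mean_removed_per_bin = 0,
                      bins_discarded = 0L, bins_retained = 0L))
  s <- do.call(rbind, lapply(reports, function(r) r$summary))
  catalogAccounting(binsAssessed = nrow(s),
                    removedTax = sum(s$removed_tax),
                    removedMobile = sum(s$removed_mobile),
                    removedOutlier = sum(s$removed_outlier),
                    removedTotal = sum(s$contigs_removed),
                    binsDiscarded = sum(s$discarded, na.rm = TRUE))
}

#' Refinement-run accounting from totals
#'
#' Pure arithmetic over run totals, shared by \code{\link{summarizeRun}}
#' and usable directly on published catalog counts: the mean number of
#' removed contigs per assessed bin and the number of retained bins.
#'
#' @param binsAssessed number of bins entering refinement.
#' @param removedTax,removedMobile,removedOutlier per-filter flag totals
#'   (a contig flagged by two filters counts in both).
#' @param removedTotal contigs removed (union over filters).
#' @param binsDiscarded bins whose post-refinement QS fell below the gate.
#' @return A one-row data.frame with the inputs plus
#'   \code{mean_removed_per_bin} (= removedTotal / binsAssessed) and
#'   \code{bins_retained} (= binsAssessed - binsDiscarded).
#' @export
catalogAccounting <- function(binsAssessed, removedTax = NA_integer_,
                              removedMobile = NA_integer_,
                              removedOutlier = NA_integer_,
                              removedTotal, binsDiscarded) {
  data.frame(bins_assessed = binsAssessed,
             removed_tax = removedTax, removed_mobile = removedMobile,
             removed_outlier = removedOutlier,
             contigs_removed = removedTotal,
             mean_removed_per_bin =
               if (binsAssessed > 0) removedTotal / binsAssessed else 0,
             bins_discarded = binsDiscarded,
             bins_retained = binsAssessed - binsDiscarded)
}

#' Species-catalog novelty accounting from counts
#'
#' Percentages of a species-representative set that are taxonomically
#' unassigned, that form clusters exclusive to the catalog, that win
#' non-exclusive clusters on genome quality, and that remain
#' representatives overall (exclusive + superior).
#'
#' @param nRepresentatives size of the representative set.
#' @param nUnassigned representatives with no species assignment in the
#'   reference taxonomy (NA to skip).
#' @param nExclusive clusters containing only catalog genomes.
#' @param nSuperior non-exclusive clusters won by a catalog genome on
#'   QS + ln(N50).
#' @return A one-row data.frame with the counts and the derived
#'   percentages \code{pct_unassigned}, \code{pct_exclusive},
#'   \code{pct_superior}, \code{pct_still_representative}.
#' @export
noveltyAccounting <- function(nRepresentatives, nUnassigned = NA_integer_,
                              nExclusive = NA_integer_,
                              nSuperior = NA_integer_) {
  pct <- function(x) 100 * x / nRepresentatives
  data.frame(n_representatives = nRepresentatives,
             n_unassigned = nUnassigned,
             n_exclusive = nExclusive, n_superior = nSuperior,
             n_still_representative = nExclusive + nSuperior,
             pct_unassigned = pct(nUnassigned),
             pct_exclusive = pct(nExclusive),
             pct_superior = pct(nSuperior),
             pct_still_representative = pct(nExclusive + nSuperior))
}
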