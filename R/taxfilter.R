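#' Trim unreliable tail nodes from a lineage
#'
#' Removes nodes from the low end of the lineage, repeatedly, while the
#' last node matches any of three reliability rules:
#' \describe{
#'   \item{A}{the assignment is suggestive (low confidence, starred in
#'     classifier output);}
#'   \item{B}{the rank is at or below species level (species, subspecies,
#'     strain; unrecognised ranks positioned below a species node count);}
#'   \item{C}{the assignment is ambiguous ("environmental samples", names
#'     starting with "unclassified", or a flagged node).}
#' }
#' The result is stable under re-application (idempotent).
#'
#' @param l A \linkS4class{Lineage}.
#' @return The trimmed \linkS4class{Lineage}.
#' @examples
#' l <- Lineage(c("family", "genus", "species"), c("F1", "G1", "S1"))
#' trimLineage(l)  # drops the species node
#' @export
trimLineage <- function(l) {
  stopifnot(is(l, "Lineage"))
  n <- length(l)
  while (n > 0 && .tailUnreliable(l, n)) n <- n - 1L
  if (n == length(l)) return(l)
  new("Lineage", rank = l@rank[seq_len(n)], name = l@name[seq_len(n)],
      suggestive = l@suggestive[seq_len(n)],
      ambiguous = l@ambiguous[seq_len(n)])
}

.tailUnreliable <- function(l, i) {
  if (l@suggestive[i] || l@ambiguous[i]) return(TRUE)        # rules A, C
  d <- .rankDepth(l@rank[i])                                  # rule B
  if (!is.na(d)) return(d >= .speciesDepth())
  # unrecognised rank: below species only if a species-or-lower node
  # precedes it (otherwise its depth is unknown and it is kept here;
  # parsing already flags unknown ranks ambiguous, which rule C catches)
  if (i > 1) {
    dprev <- .rankDepth(l@rank[seq_len(i - 1)])
    return(any(dprev >= .speciesDepth(), na.rm = TRUE))
  }
  FALSE
}

#' Lineage consistency by lowest common ancestor
#'
#' A genome/contig lineage pair is consistent when the lowest common
#' ancestor of the two paths equals one of them, i.e. when one (trimmed)
#' lineage is a prefix of the other. An empty lineage (unclassified) is
#' consistent with anything. Both inputs are expected to be already trimmed
#' (\code{\link{trimLineage}}); the relation is symmetric.
#'
#' @param genome,contig \linkS4class{Lineage} objects.
#' @return TRUE or FALSE.
#' @examples
#' g <- Lineage(c("class", "order", "family"), c("C1", "O1", "F1"))
#' isConsistent(g, Lineage(c("class", "order"), c("C1", "O1")))      # TRUE
#' isConsistent(g, Lineage(c("class", "order", "family"),
#'                         c("C1", "O1", "F2")))                     # FALSE
#' @export
isConsistent <- function(genome, contig) {
  stopifnot(is(genome, "Lineage"), is(contig, "Lineage"))
  m <- min(length(genome), length(contig))
  if (m == 0) return(TRUE)
  i <- seq_len(m)
  all(genome@rank[i] == contig@rank[i] & genome@name[i] == contig@name[i])
}

#' Taxonomic decontamination filter for one bin
#'
#' Trims the bin's lineage and every contig's lineage, then flags contigs
#' whose trimmed lineage is inconsistent with the bin's
#' (\code{\link{isConsistent}}). Unclassified contigs are never flagged.
#' The filter runs once, non-iteratively (the bin lineage is not re-derived
#' after removals).
#'
#' @param bin a \linkS4class{GenomeBin}, or a character vector of contig
#'   ids.
#' @param contigLineages named list of \linkS4class{Lineage}, one per bin
#'   contig; a missing entry is an error (distinct from an empty lineage).
#' @param genomeLineage \linkS4class{Lineage} of the bin.
#' @return A data.frame with columns \code{contig_id},
#'   \code{trimmed_genome}, \code{trimmed_contig} (text form),
#'   \code{consistent} (logical) and \code{flagged} (= !consistent).
#' @export
taxonomicFilter <- function(bin, contigLineages, genomeLineage) {
  ids <- if (is(bin, "GenomeBin")) names(contigs(bin)) else as.character(bin)
  missing <- setdiff(ids, names(contigLineages))
  if (length(missing) > 0)
    stop("no lineage entry for contig ", missing[1])
  g <- trimLineage(genomeLineage)
  res <- lapply(ids, function(id) {
    ct <- trimLineage(contigLineages[[id]])
    ok <- isConsistent(g, ct)
    data.frame(contig_id = id, trimmed_genome = lineageString(g),
               trimmed_contig = lineageString(ct), consistent = ok,
               flagged = !ok, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Default internal-standard species blacklist
#'
#' Species spiked into sequencing runs as internal standards; bins assigned
#' to them are dropped from a catalog before refinement.
#'
#' @return Character vector of species names.
#' @export
internalStandardSpecies <- function() {
  c("Thermus thermophilus", "Blautia producta")
}

#' Does a genome lineage hit the internal-standard blacklist?
#'
#' Matches untrimmed lineage node names against a blacklist of species
#' names, case-insensitively.
#'
#' @param genomeLineage \linkS4class{Lineage} (untrimmed).
#' @param blacklist character vector of species names; default
#'   \code{\link{internalStandardSpecies}()}.
#' @return TRUE or FALSE.
#' @export
isInternalStandard <- function(genomeLineage,
                               blacklist = internalStandardSpecies()) {
  stopifnot(is(genomeLineage, "Lineage"))
  if (length(genomeLineage) == 0 || length(blacklist) == 0) return(FALSE)
  any(tolower(genomeLineage@name) %in% tolower(blacklist))
}
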