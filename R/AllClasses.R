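#' Recognised taxonomic ranks, highest first
#'
#' The rank ladder used for lineage validity and for the "at or below
#' species" rule of lineage trimming. Ranks not on the ladder are permitted
#' in a \linkS4class{Lineage} but carry no depth of their own.
#'
#' @return Character vector of rank names, from superkingdom down to strain.
#' @export
taxRanks <- function() {
  c("superkingdom", "kingdom", "phylum", "class", "order",
    "family", "genus", "species", "subspecies", "strain")
}

.rankDepth <- function(rank) match(rank, taxRanks())

.speciesDepth <- function() match("species", taxRanks())

#' Ranked taxonomic lineage with confidence flags
#'
#' An ordered path through a taxonomy, highest rank first, as produced by
#' contig/genome classifiers in the CAT/BAT style. Each node carries two
#' confidence flags: \code{suggestive} (a low-support assignment, starred in
#' classifier output) and \code{ambiguous} (placeholder names such as
#' "environmental samples" or names starting with "unclassified", or an
#' unrecognised rank token). An empty lineage is valid and means
#' unclassified.
#'
#' @slot rank character, rank of each node.
#' @slot name character, taxon name of each node.
#' @slot suggestive logical, low-confidence flag per node.
#' @slot ambiguous logical, ambiguous-assignment flag per node.
#'
#' @seealso \code{\link{Lineage}}, \code{\link{trimLineage}},
#'   \code{\link{isConsistent}}
#' @exportClass Lineage
setClass("Lineage",
  representation(rank = "character", name = "character",
                 suggestive = "logical", ambiguous = "logical"))

setValidity("Lineage", function(object) {
  n <- length(object@rank)
  if (length(object@name) != n || length(object@suggestive) != n ||
      length(object@ambiguous) != n)
    return("rank, name, suggestive and ambiguous must have equal length")
  if (n > 0 && any(!nzchar(object@name)))
    return("taxon names must be non-empty")
  d <- .rankDepth(object@rank)
  dk <- d[!is.na(d)]
  if (length(dk) > 1 && any(diff(dk) <= 0))
    return("recognised ranks must strictly descend")
  TRUE
})

#' Construct a Lineage
#'
#' @param rank character vector of ranks (highest first); recognised ranks
#'   are those of \code{\link{taxRanks}}, others are kept but flagged
#'   ambiguous.
#' @param name character vector of taxon names, same length as \code{rank}.
#' @param suggestive logical, recycled; low-confidence flag.
#' @param ambiguous logical or NULL; when NULL (default) the flag is derived
#'   from the name ("environmental samples", "unclassified...") and from
#'   unrecognised rank tokens.
#' @return A \linkS4class{Lineage}.
#' @examples
#' Lineage(c("class", "order", "family"), c("C1", "O1", "F1"))
#' Lineage(character(), character())  # unclassified
#' @export
Lineage <- function(rank = character(), name = character(),
                    suggestive = FALSE, ambiguous = NULL) {
  rank <- as.character(rank); name <- as.character(name)
  n <- length(rank)
  suggestive <- rep_len(as.logical(suggestive), n)
  if (is.null(ambiguous)) {
    ambiguous <- .ambiguousName(name) | is.na(.rankDepth(rank))
  } else {
    ambiguous <- rep_len(as.logical(ambiguous), n) |
      .ambiguousName(name) | is.na(.rankDepth(rank))
  }
  new("Lineage", rank = rank, name = name,
      suggestive = suggestive, ambiguous = ambiguous)
}

.ambiguousName <- function(name) {
  if (length(name) == 0) return(logical(0))
  low <- tolower(name)
  grepl("environmental samples", low, fixed = TRUE) |
    startsWith(low, "unclassified")
}

setMethod("length", "Lineage", function(x) length(x@rank))

setMethod("show", "Lineage", function(object) {
  if (length(object) == 0) {
    cat("<unclassified Lineage>\n")
  } else {
    cat("Lineage:", lineageString(object), "\n")
  }
})

#' Serialize a Lineage to its text form
#'
#' The text dialect is semicolon-joined \code{rank:name} tokens with a
#' trailing \code{*} on suggestive nodes, e.g.
#' \code{"class:C1;order:O1;family:F1*"}.
#'
#' @param l A \linkS4class{Lineage}.
#' @return A single string ("" for an empty lineage).
#' @export
lineageString <- function(l) {
  stopifnot(is(l, "Lineage"))
  if (length(l) == 0) return("")
  paste0(l@rank, ":", l@name, ifelse(l@suggestive, "*", ""), collapse = ";")
}

#' A genome bin: contigs plus per-sample coverage
#'
#' Container for one MAG bin. Contig sequences live in a named
#' \code{\link[Biostrings]{DNAStringSet}}; the coverage slot is a numeric
#' matrix with one row per contig (same names, same order) and one column
#' per sample of the coverage profile used for binning. A bin with no
#' coverage profile has a 0-column matrix.
#'
#' @slot id single bin identifier.
#' @slot contigs DNAStringSet of member contigs, uniquely named.
#' @slot coverage numeric matrix, contigs x samples, values >= 0.
#' @slot division metagenome division (project grouping) of origin.
#' @slot sample sample of origin.
#'
#' @seealso \code{\link{GenomeBin}}, \code{\link{refineBin}}
#' @exportClass GenomeBin
setClass("GenomeBin",
  representation(id = "character", contigs = "DNAStringSet",
                 coverage = "matrix", division = "character",
                 sample = "character"))

setValidity("GenomeBin", function(object) {
  if (length(object@id) != 1 || !nzchar(object@id))
    return("id must be a single non-empty string")
  nm <- names(object@contigs)
  if (length(object@contigs) == 0)
    return("a bin must contain at least one contig")
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    return("contigs must have unique non-empty names")
  if (any(Biostrings::width(object@contigs) == 0))
    return("contigs must have non-zero length")
  cov <- object@coverage
  if (!is.numeric(cov) && length(cov) > 0)
    return("coverage must be a numeric matrix")
  if (nrow(cov) != length(object@contigs))
    return("coverage must have one row per contig")
  if (nrow(cov) > 0 && ncol(cov) > 0) {
    if (is.null(rownames(cov)) || !identical(rownames(cov), nm))
      return("coverage rownames must match contig names")
    if (any(cov < 0)) return("coverage values must be non-negative")
  }
  TRUE
})

#' Construct a GenomeBin
#'
#' @param id bin identifier.
#' @param contigs named \code{\link[Biostrings]{DNAStringSet}} or named
#'   character vector of DNA sequences.
#' @param coverage numeric matrix of per-sample coverage, one row per contig
#'   (rownames matching contig names) and one column per sample; NULL for a
#'   bin without a coverage profile.
#' @param division,sample provenance strings.
#' @return A \linkS4class{GenomeBin}.
#' @examples
#' b <- GenomeBin("bin1", c(c1 = "ACGTACGT", c2 = "GGGGCCCC"))
#' totalLength(b); contigN50(b)
#' @export
GenomeBin <- function(id, contigs, coverage = NULL,
                      division = NA_character_, sample = NA_character_) {
  if (!is(contigs, "DNAStringSet"))
    contigs <- Biostrings::DNAStringSet(contigs)
  if (is.null(coverage)) {
    coverage <- matrix(numeric(0), nrow = length(contigs), ncol = 0,
                       dimnames = list(names(contigs), NULL))
  } else {
    coverage <- as.matrix(coverage)
    if (is.null(rownames(coverage))) rownames(coverage) <- names(contigs)
    coverage <- coverage[names(contigs), , drop = FALSE]
  }
  new("GenomeBin", id = id, contigs = contigs, coverage = coverage,
      division = as.character(division), sample = as.character(sample))
}

setMethod("show", "GenomeBin", function(object) {
  w <- Biostrings::width(object@contigs)
  cat("GenomeBin", object@id, "\n")
  cat("  contigs:      ", length(w), "\n")
  cat("  total length: ", sum(w), "bp\n")
  cat("  N50:          ", computeN50(w), "bp\n")
  cat("  samples:      ", ncol(object@coverage), "\n")
})
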