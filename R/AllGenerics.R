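#' @rdname GenomeBin-accessors
#' @export
setGeneric("binId", function(x) standardGeneric("binId"))

#' @rdname GenomeBin-accessors
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))

#' @rdname GenomeBin-accessors
#' @export
setGeneric("coverage", function(x) standardGeneric("coverage"))

#' @rdname GenomeBin-accessors
#' @export
setGeneric("totalLength", function(x) standardGeneric("totalLength"))

#' @rdname GenomeBin-accessors
#' @export
setGeneric("contigN50", function(x) standardGeneric("contigN50"))

#' Accessors for GenomeBin
#'
#' \code{binId} returns the bin identifier; \code{contigs} the member
#' \code{DNAStringSet}; \code{coverage} the contigs x samples coverage
#' matrix; \code{totalLength} the summed contig length in bp;
#' \code{contigN50} the N50 recomputed from member contig lengths.
#'
#' @param x A \linkS4class{GenomeBin}.
#' @return See details per accessor.
#' @name GenomeBin-accessors
#' @aliases binId contigs coverage totalLength contigN50
NULL

#' @rdname GenomeBin-accessors
setMethod("binId", "GenomeBin", function(x) x@id)

#' @rdname GenomeBin-accessors
setMethod("contigs", "GenomeBin", function(x) x@contigs)

#' @rdname GenomeBin-accessors
setMethod("coverage", "GenomeBin", function(x) x@coverage)

#' @rdname GenomeBin-accessors
setMethod("totalLength", "GenomeBin",
          function(x) sum(Biostrings::width(x@contigs)))

#' @rdname GenomeBin-accessors
setMethod("contigN50", "GenomeBin",
          function(x) computeN50(Biostrings::width(x@contigs)))

#' Assembly N50 from contig lengths
#'
#' The largest length L such that contigs of length >= L cover at least half
#' of the total assembly.
#'
#' @param lengths integer vector of contig lengths (bp), all > 0.
#' @return N50 in bp.
#' @examples
#' computeN50(c(10, 10, 10, 30))  # 30
#' @export
computeN50 <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0 || any(lengths <= 0))
    stop("contig lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}
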