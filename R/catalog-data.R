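#' Published marine MAG catalog totals
#'
#' Run-level totals reported for a published large-scale marine prokaryote
#' MAG catalog (bins assessed, contigs flagged per decontamination filter,
#' bins discarded at requalification, and species-representative novelty
#' counts), shipped as a small table so the accounting functions can be
#' exercised against real catalog arithmetic without any external data.
#'
#' @return Named numeric vector of counts.
#' @seealso \code{\link{catalogAccounting}}, \code{\link{noveltyAccounting}}
#' @export
marineCatalogCounts <- function() {
  path <- system.file("extdata", "marine_mag_catalog_counts.tsv",
                      package = "magrefine", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$value), df$key)
}
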