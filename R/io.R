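#' Read contigs from a FASTA file
#'
#' Sequences are case-normalized to uppercase; every record must have a
#' non-empty sequence.
#'
#' @param path path to a FASTA file.
#' @return A named \code{\link[Biostrings]{DNAStringSet}}.
#' @seealso \code{\link{writeFasta}}
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("malformed FASTA header in ", path)
  empty <- Biostrings::width(x) == 0
  if (any(empty))
    stop("empty sequence ", names(x)[which(empty)[1]], " in ", path)
  x
}

#' Write contigs to a FASTA file
#'
#' @param x a named \code{DNAStringSet} (or named character vector).
#' @param path output path.
#' @param width line width for wrapping.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(x, path, width = 80L) {
  if (!is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a per-contig, per-sample coverage table
#'
#' TSV dialect: a header row naming the samples (first column header is the
#' contig-id column, conventionally "contig"), then one row per contig with
#' non-negative coverage values.
#'
#' @param path path to the TSV.
#' @return A list with \code{samples} (character roster, in file order) and
#'   \code{coverage} (numeric matrix, contigs x samples, rownamed by contig
#'   id).
#' @export
readCoverageTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("coverage table needs an id column and >=1 sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate id '", ids[duplicated(ids)][1], "' in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric coverage value in ", path)
  bad <- which(m < 0 | is.na(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("negative or missing coverage at line ", bad[1, 1] + 1L,
         " of ", path)
  rownames(m) <- ids
  list(samples = colnames(df)[-1], coverage = m)
}

#' Write a coverage table
#'
#' @param coverage numeric matrix, contigs x samples, rownamed.
#' @param path output path.
#' @param idColumn header for the id column.
#' @return \code{path}, invisibly.
#' @export
writeCoverageTable <- function(coverage, path, idColumn = "contig") {
  df <- data.frame(rownames(coverage), coverage, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- idColumn
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a lineage table
#'
#' TSV dialect: first column an id (contig or genome), second column the
#' lineage as semicolon-joined \code{rank:name} tokens, with a trailing
#' \code{*} marking a suggestive (low-confidence) node. An empty second
#' field is an unclassified lineage. Unrecognised rank tokens raise a
#' warning and mark the node ambiguous (not fatal).
#'
#' @param path path to the TSV (no header).
#' @return A named list of \linkS4class{Lineage} objects.
#' @seealso \code{\link{writeLineageTable}}, \code{\link{Lineage}}
#' @export
readLineageTable <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 1 || !nzchar(parts[1]))
      stop("missing id at line ", i, " of ", path)
    id <- parts[1]
    if (!is.null(out[[id]]))
      stop("duplicate id '", id, "' at line ", i, " of ", path)
    out[[id]] <- parseLineage(if (length(parts) >= 2) parts[2] else "")
  }
  out
}

#' Parse the text form of a lineage
#'
#' @param s a string like \code{"class:C1;order:O1;family:F1*"}; "" parses
#'   to an empty (unclassified) lineage.
#' @return A \linkS4class{Lineage}.
#' @export
parseLineage <- function(s) {
  s <- trimws(s)
  if (!nzchar(s)) return(Lineage())
  toks <- strsplit(s, ";", fixed = TRUE)[[1]]
  toks <- trimws(toks)
  sug <- endsWith(toks, "*")
  toks <- sub("\\*$", "", toks)
  colon <- regexpr(":", toks, fixed = TRUE)
  if (any(colon < 0))
    stop("malformed lineage token '", toks[which(colon < 0)[1]], "'")
  rank <- trimws(substr(toks, 1, colon - 1))
  name <- trimws(substr(toks, colon + 1, nchar(toks)))
  unk <- is.na(.rankDepth(rank))
  if (any(unk))
    warning("unknown rank token '", rank[which(unk)[1]],
            "'; node flagged ambiguous")
  Lineage(rank, name, suggestive = sug)
}

#' Write a lineage table
#'
#' @param lineages named list of \linkS4class{Lineage}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeLineageTable <- function(lineages, path) {
  lines <- vapply(seq_along(lineages), function(i)
    paste(names(lineages)[i], lineageString(lineages[[i]]), sep = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a single tree from a newick file
#'
#' Every edge must carry a branch length.
#'
#' @param path path to a newick file containing one tree.
#' @return An \code{\link[ape]{ape}} \code{phylo} object.
#' @export
readNewick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick in ", path)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1) stop("expected a single tree in ", path)
    tr <- tr[[1]]
  }
  if (is.null(tr$edge.length) || anyNA(tr$edge.length)) {
    node <- if (is.null(tr$edge.length)) "all nodes" else {
      ch <- tr$edge[which(is.na(tr$edge.length))[1], 2]
      if (ch <= length(tr$tip.label)) tr$tip.label[ch]
      else paste0("internal node ", ch)
    }
    stop("missing branch length (", node, ") in ", path)
  }
  tr
}

#' Write a tree to a newick file
#'
#' @param tree a \code{phylo} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a mobile-element evidence table
#'
#' TSV dialect (no header): contig_id, circular (0/1), predictor category
#' (1--6 or NA), viral-region fraction (0--1 or NA), then zero or more
#' repeated triplets \code{evalue, domain, probability} describing terminase
#' large-subunit (terL) hits.
#'
#' @param path path to the TSV.
#' @return A data.frame with columns \code{contig_id}, \code{circular},
#'   \code{category}, \code{viral_fraction}, and list-column
#'   \code{terl_hits} (each a data.frame with \code{evalue}, \code{domain},
#'   \code{probability}).
#' @export
readEvidenceTable <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  ev <- data.frame(contig_id = character(n), circular = logical(n),
                   category = rep(NA_integer_, n),
                   viral_fraction = rep(NA_real_, n),
                   stringsAsFactors = FALSE)
  hits <- vector("list", n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4)
      stop("evidence line ", i, " has fewer than 4 fields")
    ev$contig_id[i] <- f[1]
    ev$circular[i] <- as.integer(f[2]) != 0L
    ev$category[i] <- suppressWarnings(as.integer(f[3]))
    ev$viral_fraction[i] <- suppressWarnings(as.numeric(f[4]))
    rest <- f[-(1:4)]
    if (length(rest) %% 3 != 0)
      stop("evidence line ", i, ": terL fields are not triplets")
    if (length(rest) > 0) {
      m <- matrix(rest, ncol = 3, byrow = TRUE)
      hits[[i]] <- data.frame(evalue = as.numeric(m[, 1]),
                              domain = m[, 2],
                              probability = as.numeric(m[, 3]),
                              stringsAsFactors = FALSE)
    } else {
      hits[[i]] <- data.frame(evalue = numeric(0), domain = character(0),
                              probability = numeric(0))
    }
  }
  ev$terl_hits <- hits
  ev
}

#' Write a mobile-element evidence table
#'
#' @param evidence data.frame as returned by \code{\link{readEvidenceTable}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEvidenceTable <- function(evidence, path) {
  lines <- vapply(seq_len(nrow(evidence)), function(i) {
    h <- evidence$terl_hits[[i]]
    tail <- if (!is.null(h) && nrow(h) > 0)
      paste(t(cbind(format(h$evalue), h$domain, h$probability)),
            collapse = "\t") else NULL
    paste(c(evidence$contig_id[i], as.integer(evidence$circular[i]),
            evidence$category[i], evidence$viral_fraction[i], tail),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a pairwise ANI table
#'
#' TSV with header \code{genome_a, genome_b, ani, aligned_fraction}
#' (percent units). Pairs are unordered.
#'
#' @param path path to the TSV.
#' @return A data.frame with those four columns.
#' @export
readAniTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_a", "genome_b", "ani", "aligned_fraction")
  if (!all(need %in% colnames(df)))
    stop("ANI table must have columns ", paste(need, collapse = ", "))
  if (any(df$ani < 0 | df$ani > 100, na.rm = TRUE) ||
      any(df$aligned_fraction < 0 | df$aligned_fraction > 100, na.rm = TRUE))
    stop("ani and aligned_fraction must be in [0, 100]")
  df[need]
}

#' Read a pileup base-count table
#'
#' TSV with header \code{contig, pos, A, C, G, T}; positions are 1-based,
#' counts are non-negative integers. Depth at a site is the sum of the four
#' counts.
#'
#' @param path path to the TSV.
#' @return A data.frame with those six columns.
#' @export
readPileupTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "pos", "A", "C", "G", "T")
  if (!all(need %in% colnames(df)))
    stop("pileup table must have columns ", paste(need, collapse = ", "))
  m <- as.matrix(df[, c("A", "C", "G", "T")])
  if (any(m < 0 | is.na(m)))
    stop("pileup counts must be non-negative")
  df[need]
}
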