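#' Greedy centroid species clustering at ANI/AF cutoffs
#'
#' Deterministic species-level clustering on a pairwise ANI edge table.
#' Genomes are sorted by representative score (QS + ln(N50)) descending,
#' ties broken by lexicographically smallest id; each still-unassigned
#' genome founds a cluster and absorbs every unassigned genome linked to it
#' by an edge with \code{ani >= aniMin} and \code{aligned_fraction >=
#' afMin} (both inclusive). The founder is the cluster representative.
#'
#' @param scores named numeric vector of representative scores, one per
#'   genome (names are genome ids).
#' @param edges data.frame with columns \code{genome_a}, \code{genome_b},
#'   \code{ani}, \code{aligned_fraction} (percent, unordered pairs).
#' @param aniMin,afMin cutoffs in percent, default 95 and 30 (inclusive).
#' @return A data.frame with columns \code{genome}, \code{cluster},
#'   \code{representative} (the founder id) and \code{is_representative}.
#' @examples
#' sc <- c(g1 = 70, g2 = 60, g3 = 55)
#' ed <- data.frame(genome_a = "g1", genome_b = "g2",
#'                  ani = 96, aligned_fraction = 50)
#' clusterSpecies(sc, ed)
#' @export
clusterSpecies <- function(scores, edges, aniMin = 95, afMin = 30) {
  ids <- names(scores)
  if (is.null(ids) || anyDuplicated(ids))
    stop("scores must be uniquely named by genome id")
  unknown <- setdiff(c(edges$genome_a, edges$genome_b), ids)
  if (length(unknown) > 0)
    stop("edge references unknown genome ", unknown[1])
  pass <- edges$ani >= aniMin & edges$aligned_fraction >= afMin
  adj <- split(c(edges$genome_b[pass], edges$genome_a[pass]),
               c(edges$genome_a[pass], edges$genome_b[pass]))
  ord <- ids[order(-scores, ids)]
  assigned <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (g in ord) {
    if (!is.na(assigned[g])) next
    members <- c(g, intersect(unique(adj[[g]]),
                              names(assigned)[is.na(assigned)]))
    assigned[members] <- g
  }
  reps <- unique(assigned[ord])
  data.frame(genome = ids, cluster = match(assigned[ids], reps),
             representative = unname(assigned[ids]),
             is_representative = ids == assigned[ids],
             stringsAsFactors = FALSE)
}

#' Two-round species dereplication across divisions
#'
#' Round 1 clusters within each metagenome division (edges restricted to
#' within-division pairs); the round-1 representatives are pooled and round
#' 2 clusters the pool (edges restricted to pool members). Final
#' representatives are chosen by the same QS + ln(N50) criterion at both
#' rounds. With a single division the result equals one round of
#' \code{\link{clusterSpecies}}.
#'
#' @param divisions named character vector mapping genome id to division.
#' @param scores named numeric vector of representative scores.
#' @param edges pairwise ANI table as in \code{\link{clusterSpecies}}.
#' @param aniMin,afMin cutoffs in percent.
#' @return A list with \code{round1} (per-division clustering data.frame,
#'   with a \code{division} column), \code{round2} (clustering of the
#'   pooled representatives) and \code{representatives} (final
#'   representative ids).
#' @export
twoRoundDereplication <- function(divisions, scores, edges,
                                  aniMin = 95, afMin = 30) {
  ids <- names(scores)
  if (!setequal(names(divisions), ids))
    stop("divisions must cover exactly the scored genomes")
  r1 <- lapply(split(ids, divisions[ids]), function(members) {
    e <- edges[edges$genome_a %in% members & edges$genome_b %in% members, ,
               drop = FALSE]
    clusterSpecies(scores[members], e, aniMin, afMin)
  })
  round1 <- do.call(rbind, lapply(names(r1), function(d)
    cbind(r1[[d]], division = d, stringsAsFactors = FALSE)))
  rownames(round1) <- NULL
  pool <- round1$genome[round1$is_representative]
  e2 <- edges[edges$genome_a %in% pool & edges$genome_b %in% pool, ,
              drop = FALSE]
  round2 <- clusterSpecies(scores[pool], e2, aniMin, afMin)
  list(round1 = round1, round2 = round2,
       representatives = round2$genome[round2$is_representative])
}

#' Mash-style ANI estimate from canonical k-mer sets
#'
#' Approximates average nucleotide identity from the Jaccard index J of the
#' two genomes' canonical k-mer sets, ani = 100 (1 + ln(2J / (1 + J)) / k),
#' and approximates the aligned fraction by the shared-k-mer containment of
#' the smaller genome. This is a k-mer approximation, not an
#' alignment-based ANI; it is a convenience for building edge tables when
#' no aligner output is available.
#'
#' @param seqA,seqB DNA sequences (character or \code{DNAString}), each
#'   >= 5 kb.
#' @param k k-mer size, default 16.
#' @return A one-row data.frame \code{genome_a, genome_b, ani,
#'   aligned_fraction} (ids "a" and "b"; percent units; ani 0 when the
#'   k-mer sets are disjoint).
#' @export
estimateAni <- function(seqA, seqB, k = 16L) {
  a <- .canonicalKmerSet(seqA, k)
  b <- .canonicalKmerSet(seqB, k)
  shared <- length(intersect(a, b))
  J <- shared / length(union(a, b))
  ani <- if (J == 0) 0 else max(0, 100 * (1 + log(2 * J / (1 + J)) / k))
  af <- 100 * shared / min(length(a), length(b))
  data.frame(genome_a = "a", genome_b = "b", ani = ani,
             aligned_fraction = af, stringsAsFactors = FALSE)
}

.canonicalKmerSet <- function(seq, k) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  if (n < 5000) stop("sequences must be >= 5 kb for ANI estimation")
  if (n < k) stop("sequence shorter than k")
  fwd <- substring(s, 1:(n - k + 1), k:n)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  rev <- substring(rc, 1:(n - k + 1), k:n)
  # k-mer i on the forward strand pairs with k-mer n-k+2-i on the reverse
  unique(pmin(fwd, rev[(n - k + 1):1]))
}
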