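#' Read alignment records from the minimal TSV dialect
#'
#' TSV with header \code{read_id, read_length, aligned_length,
#' edit_distance, target_id}. This dialect carries exactly the quantities
#' the recruitment filter needs (see \code{\link{filterAlignments}}).
#'
#' @param path path to the TSV.
#' @return A data.frame with those five columns.
#' @seealso \code{\link{readSamAlignments}}
#' @export
readAlignmentTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("read_id", "read_length", "aligned_length", "edit_distance",
            "target_id")
  if (!all(need %in% colnames(df)))
    stop("alignment table must have columns ", paste(need, collapse = ", "))
  .validateAlignments(df[need])
}

.validateAlignments <- function(df) {
  if (any(df$aligned_length <= 0 | df$aligned_length > df$read_length))
    stop("aligned_length must satisfy 0 < aligned_length <= read_length (",
         df$read_id[which(df$aligned_length <= 0 |
                          df$aligned_length > df$read_length)[1]], ")")
  if (any(df$edit_distance < 0 | df$edit_distance > df$aligned_length))
    stop("edit_distance must be in [0, aligned_length] (",
         df$read_id[which(df$edit_distance < 0 |
                          df$edit_distance > df$aligned_length)[1]], ")")
  df
}

#' Read alignment records from a SAM file (subset)
#'
#' Parses mapped records of a plain-text SAM file into the minimal
#' alignment-record form. The aligned length is the number of read bases in
#' alignment-match CIGAR columns (M/=/X); the read length is the number of
#' query-consumed bases (M/I/S/=/X); the edit distance is the NM tag.
#' Records without an NM tag are rejected, unmapped records (flag 0x4 or
#' CIGAR *) are skipped.
#'
#' @param path path to a SAM file.
#' @return A data.frame with columns \code{read_id, read_length,
#'   aligned_length, edit_distance, target_id}.
#' @export
readSamAlignments <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  recs <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) stop("truncated SAM record: ", substr(ln, 1, 40))
    flag <- as.integer(f[2])
    cigar <- f[6]
    if (bitwAnd(flag, 4L) != 0L || cigar == "*") return(NULL)
    ops <- .parseCigar(cigar)
    alnLen <- sum(ops$len[ops$op %in% c("M", "=", "X")])
    readLen <- sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
    nm <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    if (length(nm) == 0)
      stop("SAM record for read ", f[1], " lacks an NM tag")
    data.frame(read_id = f[1], read_length = readLen,
               aligned_length = alnLen,
               edit_distance = as.integer(sub("^NM:i:", "", nm[1])),
               target_id = f[3], stringsAsFactors = FALSE)
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0)
    return(data.frame(read_id = character(0), read_length = integer(0),
                      aligned_length = integer(0), edit_distance = integer(0),
                      target_id = character(0)))
  .validateAlignments(do.call(rbind, recs))
}

.parseCigar <- function(cigar) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  if (m[1] == -1 || sum(attr(m, "match.length")) != nchar(cigar))
    stop("malformed CIGAR: ", cigar)
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
       op = sub("^[0-9]+", "", toks))
}
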