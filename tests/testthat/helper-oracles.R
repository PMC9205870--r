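# Independent oracles and small generators shared across tests.

randDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# --- taxonomy-tree LCA oracle -----------------------------------------------
# A complete 3-ary toy taxonomy of depth 5 (phylum..genus). Nodes are index
# paths like c(2, 1, 3); the root is integer(0). Consistency is judged by
# walking ancestor sets and testing whether the deepest common ancestor
# equals one of the two nodes -- fully independent of the prefix logic in
# isConsistent().
toyRanks <- c("phylum", "class", "order", "family", "genus")

randomTaxPath <- function(maxDepth = 5) {
  d <- sample(0:maxDepth, 1)
  if (d == 0) integer(0) else sample.int(3, d, replace = TRUE)
}

pathLineage <- function(path) {
  if (length(path) == 0) return(Lineage())
  nm <- vapply(seq_along(path), function(i)
    paste0(substr(toyRanks[i], 1, 1), paste(path[seq_len(i)], collapse = "")),
    character(1))
  Lineage(toyRanks[seq_along(path)], nm)
}

lcaOracleConsistent <- function(pathA, pathB) {
  ancestors <- function(p)
    lapply(0:length(p), function(k) p[seq_len(k)])
  aa <- ancestors(pathA)
  ab <- ancestors(pathB)
  common <- Filter(function(x)
    any(vapply(ab, identical, logical(1), x)), aa)
  lca <- common[[length(common)]]
  identical(lca, pathA) || identical(lca, pathB)
}

# --- first-principal-component oracle ---------------------------------------
# Direct eigendecomposition of the centered cross-product matrix.
pc1Oracle <- function(m) {
  X <- scale(m, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(X), symmetric = TRUE)
  s <- as.numeric(X %*% ev$vectors[, 1])
  sdpop <- sqrt(mean((s - mean(s))^2))
  (s - mean(s)) / sdpop
}

# --- terminal-redundancy brute force ----------------------------------------
# Exhaustive prefix/suffix comparison over every candidate overlap length.
bruteTerminalRedundancy <- function(s, minOverlap = 50) {
  n <- nchar(s)
  if (n >= 2 * minOverlap) {
    for (L in seq(n %/% 2, minOverlap)) {
      if (substr(s, 1, L) == substr(s, n - L + 1, n))
        return(list(circular = TRUE, overlap = L))
    }
  }
  list(circular = FALSE, overlap = 0L)
}

# --- PD category brute force ------------------------------------------------
# Per-edge descendant enumeration through phangorn::Descendants, independent
# of the postorder accumulation in pdCategories().
brutePdCategories <- function(tree, newSet) {
  isNew <- tree$tip.label %in% newSet
  newOnly <- 0
  for (i in seq_len(nrow(tree$edge))) {
    child <- tree$edge[i, 2]
    tips <- unlist(phangorn::Descendants(tree, child, "tips"))
    if (all(isNew[tips])) newOnly <- newOnly + tree$edge.length[i]
  }
  c(new_only = newOnly, other = sum(tree$edge.length) - newOnly)
}
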