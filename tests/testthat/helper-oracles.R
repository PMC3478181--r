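# Independent oracles and fixture builders shared across test files.

# Wild-type codons of the six amylase sites used in the screen fixture.
amy7cWildType <- c("89" = "GGC", "95" = "GAT", "100" = "CAT",
                   "144" = "GAT", "147" = "ACT", "197" = "AAT")

amy7cTableFile <- function() {
  system.file("extdata", "amy7c_substitutions.tsv", package = "coevolib",
              mustWork = TRUE)
}

# Brute-force mutual information oracle: explicit frequency tables over the
# observed symbols, nested loops, natural log rescaled to base 20. Kept
# deliberately naive and independent of the package internals.
bruteMI <- function(rowsA, rowsB) {
  keep <- !(rowsA %in% c("-", "X")) & !(rowsB %in% c("-", "X"))
  a <- rowsA[keep]; b <- rowsB[keep]
  n <- length(a)
  stopifnot(n >= 2)
  mi <- 0
  for (ai in unique(a)) {
    for (bj in unique(b)) {
      pab <- sum(a == ai & b == bj) / n
      if (pab == 0) next
      pa <- sum(a == ai) / n
      pb <- sum(b == bj) / n
      mi <- mi + pab * log(pab / (pa * pb))
    }
  }
  mi / log(20)
}

alnColumn <- function(aln, j) {
  vapply(strsplit(unname(alnSeqs(aln)), ""), `[`, character(1), j)
}

# Exhaustive gap-free-area optimum over all subsets of non-query sequences
# (feasible for <= 12 sequences). Returns the best achievable area.
exhaustiveMaxAlignArea <- function(aln) {
  seqs <- unname(alnSeqs(aln))
  ids <- alnIds(aln)
  qIdx <- match(queryId(aln), ids)
  others <- setdiff(seq_along(ids), qIdx)
  mat <- do.call(rbind, strsplit(seqs, ""))
  areaOf <- function(rows) {
    sub <- mat[rows, , drop = FALSE]
    length(rows) * sum(colSums(sub == "-") == 0)
  }
  best <- areaOf(qIdx)
  for (sz in seq_along(others)) {
    combos <- utils::combn(others, sz, simplify = FALSE)
    for (cmb in combos) best <- max(best, areaOf(c(qIdx, cmb)))
  }
  best
}

randomAlignment <- function(nSeqs, nCols, gapRate = 0, seed = 1) {
  set.seed(seed)
  chars <- matrix(sample(c("A","C","D","E","F","G","H","I","K","L",
                           "M","N","P","Q","R","S","T","V","W","Y"),
                         nSeqs * nCols, replace = TRUE), nrow = nSeqs)
  if (gapRate > 0) chars[runif(nSeqs * nCols) < gapRate] <- "-"
  ProteinAlignment(paste0("s", seq_len(nSeqs)),
                   apply(chars, 1, paste, collapse = ""))
}

writeFastaFixture <- function(ids, seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

writeClustalFixture <- function(ids, seqs, path = tempfile(fileext = ".aln")) {
  lines <- c("CLUSTAL W (1.83) multiple sequence alignment", "", "",
             sprintf("%-16s%s", ids, seqs))
  writeLines(lines, path)
  path
}

# Rank positions (1 = best) of the planted pairs in the weighted score
# ranking of all scored column pairs.
plantedPairRanks <- function(sim) {
  mi <- miMatrix(sim$alignment)
  rcw <- rcwMatrix(mi)
  s <- scores(rcw)
  ut <- which(upper.tri(s), arr.ind = TRUE)
  df <- data.frame(a = ut[, 1], b = ut[, 2], v = s[ut])
  df <- df[order(-df$v, df$a, df$b), ]
  df$rank <- seq_len(nrow(df))
  vapply(sim$truth$pairs, function(p) {
    a <- min(p); b <- max(p)
    df$rank[df$a == a & df$b == b]
  }, numeric(1))
}
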