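# Mutual information (base-20 logarithm) and row-and-column weighting over
# alignment columns; coevolving-pair selection and site geometry statistics.

# Integer-encode an alignment: values 1..20 index AA20, NA marks gap/missing.
encodeAlignment <- function(aln) {
  mat <- seqCharMatrix(aln@seqs)
  enc <- match(mat, AA20)
  dim(enc) <- dim(mat)
  enc
}

# MI between two encoded columns, restricted to rows observed at both.
# 0*log(0) contributes 0; small negative rounding is clamped at 0.
pairMI <- function(x, y, pseudocount = 0) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 2)
    coevStop("fewer than 2 rows with residues at both columns", "insufficient_data_error")
  counts <- tabulate((x[ok] - 1L) * 20L + y[ok], nbins = 400L)
  joint <- matrix(counts, nrow = 20, ncol = 20, byrow = TRUE) + pseudocount
  p <- joint / sum(joint)
  pa <- rowSums(p)
  pb <- colSums(p)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer(pa, pb)[nz])) / log(20)
  max(mi, 0)
}

# Column entropy with base-20 logarithm (used for the MI upper bound).
columnEntropy <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(0)
  p <- tabulate(x, nbins = 20L) / length(x)
  p <- p[p > 0]
  -sum(p * log(p)) / log(20)
}

#' Mutual information between two alignment columns
#'
#' Computes \deqn{MI(A:B) = \sum_i \sum_j P(a_i, b_j)\,
#' \log_{20} \frac{P(a_i, b_j)}{P(a_i) P(b_j)}}{MI(A:B) = sum_ij P(a_i,b_j)
#' log20[P(a_i,b_j) / (P(a_i) P(b_j))]} from the observed amino-acid
#' frequencies at the two columns. The logarithm base 20 is the size of the
#' protein alphabet, so MI is bounded by 1. Rows with a gap or \code{X} at
#' either column are excluded from the counts; marginals are taken on the
#' same row subset, so they are consistent with the joint.
#'
#' @param aln a [ProteinAlignment-class].
#' @param colA,colB 1-based alignment column indices.
#' @param pseudocount optional Laplace pseudocount added to every cell of the
#'   20 x 20 joint table (default 0: observed frequencies only).
#' @return A nonnegative score, at most \code{min} of the two column
#'   entropies (base 20).
#' @examples
#' aln <- ProteinAlignment(paste0("s", 1:4), c("AD", "AD", "CE", "CE"))
#' mutualInformation(aln, 1, 2)  # log20(2)
#' @export
mutualInformation <- function(aln, colA, colB, pseudocount = 0) {
  stopifnot(is(aln, "ProteinAlignment"))
  m <- nCols(aln)
  if (colA < 1 || colA > m || colB < 1 || colB > m)
    coevStop("column index out of range", "config_error")
  enc <- encodeAlignment(aln)
  pairMI(enc[, colA], enc[, colB], pseudocount = pseudocount)
}

#' Mutual information matrix over all column pairs
#'
#' Scores every unordered pair of alignment columns with
#' [mutualInformation()]. Pairs with fewer than two jointly observed rows are
#' recorded as \code{NA} rather than raising an error; the diagonal is left
#' \code{NA} (self-information is not defined here and is excluded from all
#' downstream row/column sums).
#'
#' @inheritParams mutualInformation
#' @return An [MIMatrix-class].
#' @export
miMatrix <- function(aln, pseudocount = 0) {
  stopifnot(is(aln, "ProteinAlignment"))
  enc <- encodeAlignment(aln)
  m <- ncol(enc)
  if (m < 2) coevStop("need at least two columns to score pairs", "config_error")
  s <- matrix(NA_real_, m, m, dimnames = list(seq_len(m), seq_len(m)))
  for (i in seq_len(m - 1L)) {
    xi <- enc[, i]
    for (j in seq.int(i + 1L, m)) {
      mi <- tryCatch(pairMI(xi, enc[, j], pseudocount = pseudocount),
                     coevolib_insufficient_data_error = function(e) NA_real_)
      s[i, j] <- mi
      s[j, i] <- mi
    }
  }
  new("MIMatrix", scores = s, nSeqs = nSeqs(aln))
}

#' Row-and-column-weighted mutual information matrix
#'
#' Weights each pair's mutual information by the average score of its
#' constituent sites:
#' \deqn{RCW(A:B) = \frac{MI_{ij}}{(MI_{i.} + MI_{.j} - 2 MI_{ij})/(n-1)}}{
#' RCW(A:B) = MI_ij / [(MI_i. + MI_.j - 2 MI_ij) / (n - 1)]}
#' where \eqn{MI_{i.}} and \eqn{MI_{.j}} are sums over the off-diagonal
#' entries of row \eqn{i} and column \eqn{j}. Positions that score highly
#' against everything (phylogenetic or entropic bias) are damped; a pair
#' stands out only if it scores highly relative to its own row and column.
#'
#' The count \eqn{n} is a common positive factor: pair rankings are identical
#' whichever convention is used. \code{"sequences"} (the default) takes the
#' number of alignment sequences; \code{"columns"} takes the number of
#' scored columns. When the denominator is zero (no information anywhere in
#' the pair's row and column) the score is defined as 0.
#'
#' @param mi an [MIMatrix-class] from [miMatrix()].
#' @param nMode \code{"sequences"} or \code{"columns"}.
#' @param n overrides the count; must be >= 2. Defaults to the number of
#'   sequences recorded in \code{mi} or the number of columns, per
#'   \code{nMode}.
#' @return An [RCWMatrix-class].
#' @examples
#' aln <- ProteinAlignment(paste0("s", 1:4), c("ADK", "ADK", "CEK", "CEL"))
#' rcwMatrix(miMatrix(aln))
#' @export
rcwMatrix <- function(mi, nMode = c("sequences", "columns"), n = NULL) {
  stopifnot(is(mi, "MIMatrix"))
  nMode <- match.arg(nMode)
  m <- nrow(mi@scores)
  if (is.null(n)) n <- if (nMode == "sequences") mi@nSeqs else m
  n <- as.integer(n)
  if (is.na(n) || n < 2L) coevStop("normalization count n must be >= 2", "invalid_n_error")

  rs <- rowSums(mi@scores, na.rm = TRUE)  # symmetric: row sums == column sums
  rcw <- matrix(NA_real_, m, m, dimnames = dimnames(mi@scores))
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      mij <- mi@scores[i, j]
      if (is.na(mij)) next
      denom <- (rs[i] + rs[j] - 2 * mij) / (n - 1L)
      val <- if (denom > 0) mij / denom else 0
      rcw[i, j] <- val
      rcw[j, i] <- val
    }
  }
  new("RCWMatrix", scores = rcw, mi = mi@scores, miRowSums = unname(rs),
      n = n, nMode = nMode)
}

#' Select coevolving site pairs from a weighted score matrix
#'
#' Ranks all scored column pairs by descending weighted score and applies a
#' selection rule, reporting the selected pairs in query-residue numbering
#' with the query's wild-type residues. Columns not covered by the map (the
#' query is gapped there) cannot be reported as sites and are skipped.
#'
#' @param rcw an [RCWMatrix-class].
#' @param cmap column map from [columnToQueryMap()] (recomputed after any
#'   column dropping so that it refers to the scored columns).
#' @param rule \code{"zscore"} (default): keep pairs whose score exceeds
#'   mean + \code{z} * SD of all finite off-diagonal scores; or
#'   \code{"topk"}: keep the \code{topK} best pairs.
#' @param z z-score cutoff for \code{rule = "zscore"} (default 2).
#' @param topK number of pairs for \code{rule = "topk"}.
#' @return data.frame with columns \code{siteA}, \code{wtA}, \code{siteB},
#'   \code{wtB}, \code{mi}, \code{rcw}, \code{rank}, sorted by descending
#'   score with ties broken by (siteA, siteB); \code{siteA < siteB} in every
#'   row. The induced unique site set is attached as attribute
#'   \code{"sites"}. An empty selection returns a zero-row data.frame.
#' @export
selectCoevolvingPairs <- function(rcw, cmap, rule = c("zscore", "topk"),
                                  z = 2, topK = NULL) {
  stopifnot(is(rcw, "RCWMatrix"))
  rule <- match.arg(rule)
  if (rule == "topk" && is.null(topK)) coevStop("topK required for rule 'topk'", "config_error")
  m <- nrow(rcw@scores)
  ut <- which(upper.tri(rcw@scores), arr.ind = TRUE)
  vals <- rcw@scores[ut]
  fin <- is.finite(vals)
  df <- data.frame(colA = ut[fin, 1], colB = ut[fin, 2], rcw = vals[fin])
  df$mi <- rcw@mi[cbind(df$colA, df$colB)]

  mapped <- match(df$colA, cmap$column)
  mappedB <- match(df$colB, cmap$column)
  keep <- !is.na(mapped) & !is.na(mappedB)
  if (any(!keep))
    message(sprintf("skipping %d pair(s) involving columns not mapped to query residues",
                    sum(!keep)))
  df <- df[keep, , drop = FALSE]
  mapped <- mapped[keep]; mappedB <- mappedB[keep]
  df$siteA <- cmap$residue[mapped]; df$wtA <- cmap$wt[mapped]
  df$siteB <- cmap$residue[mappedB]; df$wtB <- cmap$wt[mappedB]

  ord <- order(-df$rcw, df$siteA, df$siteB)
  df <- df[ord, , drop = FALSE]
  sel <- if (rule == "zscore") {
    allVals <- vals[fin]
    thr <- mean(allVals) + z * sd(allVals)
    which(df$rcw > thr)
  } else {
    seq_len(min(topK, nrow(df)))
  }
  out <- df[sel, c("siteA", "wtA", "siteB", "wtB", "mi", "rcw"), drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  if (nrow(out) == 0) message("selection rule matched no pairs")
  attr(out, "sites") <- sort(unique(c(out$siteA, out$siteB)))
  out
}

#' Pairwise distance statistics between coevolving sites
#'
#' Mean and sample standard deviation of all pairwise Euclidean distances
#' between representative atoms (conventionally C-alpha) of the given sites.
#'
#' @param sites query residue numbers (>= 2).
#' @param coords numeric matrix with 3 columns (x, y, z in Angstrom) whose
#'   rownames are residue numbers, e.g. from [readCalphaCoords()].
#' @return named numeric vector \code{c(mean = , sd = )} in Angstrom.
#' @examples
#' xyz <- matrix(c(0, 0, 0, 3, 0, 0, 0, 4, 0), ncol = 3, byrow = TRUE,
#'               dimnames = list(c(10, 20, 30), c("x", "y", "z")))
#' siteDistanceStats(c(10, 20, 30), xyz)  # mean 4, sd 1
#' @export
siteDistanceStats <- function(sites, coords) {
  if (length(sites) < 2)
    coevStop("at least two sites are required for distance statistics",
             "insufficient_sites_error")
  idx <- match(as.character(sites), rownames(coords))
  if (anyNA(idx))
    coevStop(sprintf("missing coordinates for residue(s): %s",
                     paste(sites[is.na(idx)], collapse = ", ")),
             "missing_coordinate_error")
  xyz <- coords[idx, , drop = FALSE]
  d <- as.vector(dist(xyz))
  c(mean = mean(d), sd = if (length(d) > 1) sd(d) else 0)
}

#' Read C-alpha coordinates of a chain from a PDB file
#'
#' Thin wrapper over \pkg{bio3d} returning the representative-atom
#' coordinates keyed by residue number, in the shape
#' [siteDistanceStats()] expects.
#'
#' @param path PDB file path.
#' @param chain chain identifier; default takes the first chain.
#' @return numeric matrix (x, y, z) with residue numbers as rownames.
#' @export
readCalphaCoords <- function(path, chain = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    coevStop("package 'bio3d' is required to read PDB coordinates", "dependency_error")
  pdb <- bio3d::read.pdb(path)
  atoms <- pdb$atom
  if (is.null(chain)) chain <- atoms$chain[1]
  ca <- atoms[atoms$elety == "CA" & atoms$chain == chain, , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  out <- as.matrix(ca[, c("x", "y", "z")])
  rownames(out) <- ca$resno
  out
}

#' Write a score matrix as square TSV
#'
#' Square tab-separated matrix with 1-based alignment column labels as both
#' header and first column; entries formatted with 6 decimals for
#' reproducible diffs.
#'
#' @param x an [MIMatrix-class] or [RCWMatrix-class].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeScoreMatrix <- function(x, path) {
  s <- scores(x)
  out <- matrix(fmtNum(s, 6), nrow = nrow(s), dimnames = dimnames(s))
  out[is.na(s)] <- "NA"
  df <- data.frame(column = rownames(s), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write selected coevolving pairs as TSV
#'
#' Columns: site_a, wt_a, site_b, wt_b, mi, rcw, rank.
#'
#' @param pairs data.frame from [selectCoevolvingPairs()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writePairTable <- function(pairs, path) {
  out <- data.frame(site_a = pairs$siteA, wt_a = pairs$wtA,
                    site_b = pairs$siteB, wt_b = pairs$wtB,
                    mi = fmtNum(pairs$mi, 6), rcw = fmtNum(pairs$rcw, 6),
                    rank = pairs$rank, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
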