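# Gap reduction before column scoring: drop sequences to maximise the
# gap-free area (kept sequences x columns with no gap in any kept sequence),
# then strip residual heavily gapped columns.

#' Reduce gapped columns by dropping sequences
#'
#' Greedy steepest-ascent removal of whole sequences so as to maximise the
#' area objective: (number of kept sequences) x (number of columns with no
#' gap in any kept sequence). At each step the single removal giving the
#' largest strict area improvement is applied; the loop stops when no removal
#' improves the area. The query sequence is protected and never removed.
#'
#' When no single removal improves the area, removals of sequence pairs are
#' also tried (two gappy sequences sharing gap columns only pay off when
#' both leave); the loop stops when neither a single nor a paired removal
#' improves the area, so the returned area is never below the input's.
#'
#' @param aln a [ProteinAlignment-class].
#' @param minSeqs minimum number of sequences the alignment may be reduced
#'   to (default 10). If an improving removal would take the alignment below
#'   this count, a too-few-sequences error is raised.
#' @return list with elements \code{alignment} (the reduced
#'   [ProteinAlignment-class]) and \code{report}, a list with
#'   \code{removedIds}, \code{gapFreeColumnsBefore}, \code{gapFreeColumnsAfter},
#'   \code{areaBefore}, \code{areaAfter}.
#' @examples
#' aln <- ProteinAlignment(c("q", "s2", "s3"), c("ACDE", "ACDE", "A---"))
#' maxAlignReduce(aln, minSeqs = 2)$report$removedIds
#' @export
maxAlignReduce <- function(aln, minSeqs = 10L) {
  stopifnot(is(aln, "ProteinAlignment"))
  gapMat <- seqCharMatrix(aln@seqs) == GAP_CHAR  # n_seqs x n_cols
  storage.mode(gapMat) <- "integer"
  keep <- rep(TRUE, nSeqs(aln))
  qIdx <- match(aln@queryId, aln@ids)

  colGaps <- colSums(gapMat)
  k <- sum(keep)
  gapFree <- sum(colGaps == 0L)
  areaBefore <- k * gapFree
  gapFreeBefore <- gapFree
  area <- areaBefore

  tooFew <- function() coevStop(sprintf(
    "gap reduction requires removing sequences below the minimum of %d", minSeqs),
    "too_few_sequences_error")

  repeat {
    candidates <- setdiff(which(keep), qIdx)
    if (length(candidates) == 0) break
    # best single removal
    singleAreas <- vapply(candidates, function(i)
      (k - 1L) * sum(colGaps - gapMat[i, ] == 0L), numeric(1))
    bestS <- which.max(singleAreas)
    if (singleAreas[bestS] > area) {
      if (k - 1L < minSeqs) tooFew()
      i <- candidates[bestS]
      keep[i] <- FALSE
      colGaps <- colGaps - gapMat[i, ]
      k <- k - 1L
      area <- singleAreas[bestS]
      next
    }
    # stalled: try pairs of removals
    if (length(candidates) < 2) break
    bestPair <- NULL
    bestPairArea <- area
    for (a in seq_len(length(candidates) - 1L)) {
      ga <- gapMat[candidates[a], ]
      for (b in seq.int(a + 1L, length(candidates))) {
        pairArea <- (k - 2L) * sum(colGaps - ga - gapMat[candidates[b], ] == 0L)
        if (pairArea > bestPairArea) {
          bestPairArea <- pairArea
          bestPair <- candidates[c(a, b)]
        }
      }
    }
    if (is.null(bestPair)) break
    if (k - 2L < minSeqs) tooFew()
    keep[bestPair] <- FALSE
    colGaps <- colGaps - gapMat[bestPair[1], ] - gapMat[bestPair[2], ]
    k <- k - 2L
    area <- bestPairArea
  }

  reduced <- new("ProteinAlignment", ids = aln@ids[keep], seqs = aln@seqs[keep],
                 queryId = aln@queryId)
  list(alignment = reduced,
       report = list(
         removedIds = aln@ids[!keep],
         gapFreeColumnsBefore = gapFreeBefore,
         gapFreeColumnsAfter = sum(colGaps == 0L),
         areaBefore = areaBefore,
         areaAfter = area))
}

#' Drop alignment columns exceeding a gap fraction
#'
#' Removes every column whose gap fraction is strictly greater than
#' \code{maxGapFraction}; a column at exactly the threshold is kept.
#' All-gap columns carry no data and are always removed, whatever the
#' threshold.
#'
#' @param aln a [ProteinAlignment-class].
#' @param maxGapFraction maximum tolerated per-column gap fraction in
#'   \code{[0, 1]} (default 0.5). \code{0} removes every column containing any
#'   gap; \code{1} removes only all-gap columns.
#' @return A [ProteinAlignment-class] with the offending columns removed.
#'   The retained original column indices are attached as attribute
#'   \code{"keptColumns"}.
#' @export
dropGappedColumns <- function(aln, maxGapFraction = 0.5) {
  stopifnot(is(aln, "ProteinAlignment"))
  if (maxGapFraction < 0 || maxGapFraction > 1)
    coevStop("maxGapFraction must lie in [0, 1]", "config_error")
  mat <- seqCharMatrix(aln@seqs)
  gapFrac <- colMeans(mat == GAP_CHAR)
  keepCols <- which(gapFrac <= maxGapFraction & gapFrac < 1)
  if (length(keepCols) == 0)
    coevStop("all columns exceed the gap-fraction threshold", "empty_alignment_error")
  seqs <- apply(mat[, keepCols, drop = FALSE], 1, paste, collapse = "")
  out <- new("ProteinAlignment", ids = aln@ids, seqs = seqs, queryId = aln@queryId)
  attr(out, "keptColumns") <- keepCols
  out
}
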