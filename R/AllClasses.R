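#' ProteinAlignment: a gapped protein multiple sequence alignment
#'
#' Holds equal-length aligned amino-acid rows over the 20-letter alphabet plus
#' the gap character \code{-} and the missing symbol \code{X}, together with a
#' designated query row whose ungapped residue numbering anchors all site
#' reports. Rows are case-normalized on construction; \code{.} gaps become
#' \code{-} and ambiguity letters (B, Z, J, U, O) become \code{X}.
#'
#' @slot ids character vector of unique sequence identifiers.
#' @slot seqs character vector of aligned rows, same length as \code{ids}.
#' @slot queryId identifier of the query row.
#'
#' @seealso [readAlignment()], [columnToQueryMap()]
#' @export
setClass("ProteinAlignment",
  representation(ids = "character", seqs = "character", queryId = "character"))

setValidity("ProteinAlignment", function(object) {
  msgs <- character(0)
  n <- length(object@ids)
  if (length(object@seqs) != n)
    msgs <- c(msgs, "number of ids must equal number of rows")
  if (n == 0)
    msgs <- c(msgs, "alignment must contain at least one sequence")
  if (anyDuplicated(object@ids))
    msgs <- c(msgs, sprintf("duplicate sequence id(s): %s",
                            paste(unique(object@ids[duplicated(object@ids)]), collapse = ", ")))
  if (n > 0 && length(unique(nchar(object@seqs))) > 1)
    msgs <- c(msgs, "all aligned rows must have identical length")
  if (length(object@queryId) != 1 || !(object@queryId %in% object@ids))
    msgs <- c(msgs, "queryId must name exactly one sequence present in the alignment")
  chars <- unique(strsplit(paste(object@seqs, collapse = ""), "")[[1]])
  bad <- setdiff(chars, c(AA20, GAP_CHAR, MISSING_CHAR))
  if (length(bad) > 0)
    msgs <- c(msgs, sprintf("rows contain characters outside the alphabet: %s",
                            paste(bad, collapse = ", ")))
  if (length(msgs) > 0) msgs else TRUE
})

#' Construct a ProteinAlignment
#'
#' @param ids character vector of unique sequence identifiers.
#' @param seqs character vector of aligned rows (equal lengths). Residues are
#'   normalized: upper-cased, \code{.} to \code{-}, non-standard letters
#'   (B, Z, J, U, O) to \code{X}.
#' @param queryId identifier of the query row; defaults to the first id.
#' @return A [ProteinAlignment-class] object.
#' @examples
#' aln <- ProteinAlignment(c("q", "s1"), c("AC-DE", "ACFDE"), queryId = "q")
#' nCols(aln)
#' @export
ProteinAlignment <- function(ids, seqs, queryId = ids[1]) {
  if (length(ids) == 0 || length(seqs) == 0)
    coevStop("empty input: no sequences", "empty_input_error")
  if (length(unique(nchar(seqs))) > 1)
    coevStop("alignment format error: rows have unequal lengths", "alignment_format_error")
  if (anyDuplicated(ids))
    coevStop(sprintf("duplicate sequence id(s): %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             "duplicate_id_error")
  new("ProteinAlignment", ids = as.character(ids),
      seqs = normalizeResidues(as.character(seqs)),
      queryId = as.character(queryId))
}

#' MIMatrix: mutual information between alignment columns
#'
#' Symmetric matrix of pairwise mutual information over alignment columns,
#' computed with a base-20 logarithm so that a perfectly coupled pair of
#' maximally diverse columns scores 1. The diagonal is not defined (stored as
#' \code{NA}); pairs with fewer than two usable rows are recorded as \code{NA}
#' rather than failing.
#'
#' @slot scores numeric symmetric matrix; dimnames are 1-based column labels.
#' @slot nSeqs number of alignment sequences the scores were computed from.
#' @seealso [miMatrix()], [rcwMatrix()]
#' @export
setClass("MIMatrix", representation(scores = "matrix", nSeqs = "integer"))

setValidity("MIMatrix", function(object) {
  s <- object@scores
  if (nrow(s) != ncol(s)) return("score matrix must be square")
  if (!isTRUE(all.equal(s, t(s)))) return("score matrix must be symmetric")
  off <- s[upper.tri(s)]
  if (any(off < -1e-12, na.rm = TRUE)) return("mutual information must be nonnegative")
  TRUE
})

#' RCWMatrix: row-and-column-weighted mutual information
#'
#' Each pair's mutual information divided by the average information of its
#' row and column, damping promiscuously high-scoring positions. Stores the
#' underlying MI matrix, the off-diagonal row sums, and the normalization
#' count \code{n} with its convention (\code{"sequences"} or \code{"columns"});
#' \code{n} enters only as a common positive factor, so pair rankings do not
#' depend on the convention.
#'
#' @slot scores numeric symmetric matrix of weighted scores.
#' @slot mi the underlying MI score matrix.
#' @slot miRowSums off-diagonal row sums of the MI matrix.
#' @slot n normalization count used.
#' @slot nMode \code{"sequences"} or \code{"columns"}.
#' @seealso [rcwMatrix()], [selectCoevolvingPairs()]
#' @export
setClass("RCWMatrix",
  representation(scores = "matrix", mi = "matrix", miRowSums = "numeric",
                 n = "integer", nMode = "character"))

setValidity("RCWMatrix", function(object) {
  if (!object@nMode %in% c("sequences", "columns"))
    return("nMode must be 'sequences' or 'columns'")
  if (object@n < 2L) return("normalization count n must be >= 2")
  if (any(object@scores[upper.tri(object@scores)] < 0, na.rm = TRUE))
    return("weighted scores must be nonnegative")
  TRUE
})

#' PrimerPair: complementary mutagenic oligos with one degenerate codon
#'
#' A forward/reverse primer pair for whole-plasmid mutagenesis carrying a
#' single in-frame degenerate codon at the target site; the reverse strand is
#' the exact reverse complement of the forward strand.
#'
#' @slot forward forward primer (5' to 3'), 33-35 nt.
#' @slot reverse reverse primer, exact reverse complement of \code{forward}.
#' @slot targetSite query residue number of the randomized codon.
#' @slot degenerateOffset 0-based offset of the degenerate codon in \code{forward}.
#' @slot code the degenerate codon (IUPAC, e.g. "NNK").
#' @slot meltingTemperature estimated Tm in degrees Celsius.
#' @seealso [designPrimerPair()]
#' @export
setClass("PrimerPair",
  representation(forward = "character", reverse = "character",
                 targetSite = "integer", degenerateOffset = "integer",
                 code = "character", meltingTemperature = "numeric"))

setValidity("PrimerPair", function(object) {
  msgs <- character(0)
  len <- nchar(object@forward)
  if (len < 33 || len > 35)
    msgs <- c(msgs, "primer length must lie in [33, 35]")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(object@forward)))
  if (!identical(rc, object@reverse))
    msgs <- c(msgs, "reverse primer must be the exact reverse complement of the forward primer")
  if (object@degenerateOffset < 0L || object@degenerateOffset + 3L > len)
    msgs <- c(msgs, "degenerate codon must lie within the primer")
  if (length(msgs) > 0) msgs else TRUE
})

#' LibraryDesign: a two-site combinatorial saturation-mutagenesis library
#'
#' The design of one focused library randomizing a pair of sites with
#' degenerate codons: the primer pair per site, the theoretical codon and
#' amino-acid combination counts, and the fraction of variants expected to
#' carry at least one stop codon.
#'
#' @slot sites query residue numbers of the randomized sites.
#' @slot code degenerate codon used at every site (IUPAC).
#' @slot primers list of [PrimerPair-class], one per site.
#' @slot codonCombinations product of per-site codon expansion sizes.
#' @slot aminoAcidCombinations product of per-site encoded amino-acid counts.
#' @slot stopFraction expected fraction of library members with >= 1 stop codon.
#' @slot wildTypeCodons named character vector of wild-type codons per site.
#' @seealso [libraryDesign()], [libraryCoverage()]
#' @export
setClass("LibraryDesign",
  representation(sites = "integer", code = "character", primers = "list",
                 codonCombinations = "numeric", aminoAcidCombinations = "numeric",
                 stopFraction = "numeric", wildTypeCodons = "character"))

setValidity("LibraryDesign", function(object) {
  exp1 <- length(expandDegenerateCodon(object@code))
  if (!isTRUE(all.equal(object@codonCombinations, exp1^length(object@sites))))
    return("codon combination count must equal the product of expansion sizes")
  TRUE
})

#' TallyTable: per-site substitution tallies of sequenced variants
#'
#' Counts of each observed amino-acid substitution per designed site with its
#' codon(s), annotated with the minimum number of nucleotide changes relative
#' to the wild-type codon. Entries whose recorded amino acid disagrees with
#' the translation of the recorded codon are kept as recorded (the sequencing
#' call is trusted) and reported in \code{conflicts}.
#'
#' @slot tally data.frame with columns site, aminoAcid, codon, count, minChanges.
#' @slot wildType named character vector: wild-type codon per site (names are
#'   query residue numbers).
#' @slot conflicts data.frame of entries whose recorded residue differs from
#'   the codon translation.
#' @seealso [tallyVariants()], [readSubstitutionTable()], [siteDiversity()]
#' @export
setClass("TallyTable",
  representation(tally = "data.frame", wildType = "character", conflicts = "data.frame"))

setValidity("TallyTable", function(object) {
  need <- c("site", "aminoAcid", "codon", "count", "minChanges")
  if (!all(need %in% names(object@tally)))
    return(sprintf("tally must have columns %s", paste(need, collapse = ", ")))
  if (nrow(object@tally) > 0 && any(object@tally$count < 0))
    return("counts must be nonnegative")
  TRUE
})
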