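#' @describeIn ProteinAlignment number of sequences
#' @param x a ProteinAlignment
#' @export
setMethod("nSeqs", "ProteinAlignment", function(x) length(x@ids))

#' @describeIn ProteinAlignment number of alignment columns
#' @export
setMethod("nCols", "ProteinAlignment", function(x) nchar(x@seqs[1]))

#' @describeIn ProteinAlignment sequence identifiers
#' @export
setMethod("alnIds", "ProteinAlignment", function(x) x@ids)

#' @describeIn ProteinAlignment aligned rows, named by id
#' @export
setMethod("alnSeqs", "ProteinAlignment", function(x) setNames(x@seqs, x@ids))

#' @describeIn ProteinAlignment query identifier
#' @export
setMethod("queryId", "ProteinAlignment", function(x) x@queryId)

#' @describeIn MIMatrix the symmetric MI score matrix
#' @param x an MIMatrix
#' @export
setMethod("scores", "MIMatrix", function(x) x@scores)

#' @describeIn RCWMatrix the symmetric weighted score matrix
#' @export
setMethod("scores", "RCWMatrix", function(x) x@scores)

#' @describeIn TallyTable the tally data.frame
#' @param x a TallyTable
#' @export
setMethod("tally", "TallyTable", function(x) x@tally)

setMethod("show", "ProteinAlignment", function(object) {
  cat(sprintf("ProteinAlignment: %d sequences x %d columns (query: %s)\n",
              nSeqs(object), nCols(object), object@queryId))
  shown <- head(object@ids, 3)
  for (id in shown) {
    s <- object@seqs[match(id, object@ids)]
    if (nchar(s) > 50) s <- paste0(substr(s, 1, 47), "...")
    cat(sprintf("  %-15s %s\n", id, s))
  }
  if (nSeqs(object) > 3) cat(sprintf("  ... and %d more\n", nSeqs(object) - 3))
})

setMethod("show", "MIMatrix", function(object) {
  off <- object@scores[upper.tri(object@scores)]
  cat(sprintf("MIMatrix: %d columns, %d sequences; off-diagonal MI in [%.4f, %.4f]\n",
              nrow(object@scores), object@nSeqs,
              suppressWarnings(min(off, na.rm = TRUE)),
              suppressWarnings(max(off, na.rm = TRUE))))
})

setMethod("show", "RCWMatrix", function(object) {
  off <- object@scores[upper.tri(object@scores)]
  cat(sprintf("RCWMatrix: %d columns (n = %d, mode = %s); off-diagonal scores in [%.4f, %.4f]\n",
              nrow(object@scores), object@n, object@nMode,
              suppressWarnings(min(off, na.rm = TRUE)),
              suppressWarnings(max(off, na.rm = TRUE))))
})

setMethod("show", "PrimerPair", function(object) {
  cat(sprintf("PrimerPair targeting residue %d (%s, offset %d, Tm %.1f C)\n",
              object@targetSite, object@code, object@degenerateOffset,
              object@meltingTemperature))
  cat(sprintf("  fwd 5'-%s-3'\n  rev 5'-%s-3'\n", object@forward, object@reverse))
})

setMethod("show", "LibraryDesign", function(object) {
  cat(sprintf("LibraryDesign at sites %s with %s codons\n",
              paste(object@sites, collapse = "/"), object@code))
  cat(sprintf("  %d codon combinations, %d amino-acid combinations, stop fraction %.4f\n",
              object@codonCombinations, object@aminoAcidCombinations, object@stopFraction))
})

setMethod("show", "TallyTable", function(object) {
  sites <- sort(unique(object@tally$site))
  cat(sprintf("TallyTable: %d substitution entries over %d site(s)\n",
              nrow(object@tally), length(sites)))
  if (length(sites) > 0) {
    div <- siteDiversity(object)
    cat("  distinct amino acids per site:",
        paste(sprintf("%d:%d", as.integer(names(div)), div), collapse = ", "), "\n")
  }
  if (nrow(object@conflicts) > 0)
    cat(sprintf("  %d entries have residue/codon translation conflicts\n",
                nrow(object@conflicts)))
})
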