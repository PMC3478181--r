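# Degenerate-codon algebra under the IUPAC nucleotide code and the standard
# genetic code. NNK (N = any base, K = G/T) is the workhorse: 32 codons
# covering all 20 amino acids with a single stop (TAG).

validCodon <- function(x) nchar(x) == 3 && grepl("^[ACGT]{3}$", x)

#' Expand a degenerate codon into its concrete codons
#'
#' @param code three IUPAC nucleotide letters, e.g. \code{"NNK"}.
#' @return character vector of distinct concrete codons in lexicographic
#'   order; its length is the product of the per-position degeneracies.
#' @examples
#' length(expandDegenerateCodon("NNK"))  # 32
#' expandDegenerateCodon("ATG")          # "ATG"
#' @export
expandDegenerateCodon <- function(code) {
  code <- toupper(code)
  if (nchar(code) != 3)
    coevStop("a degenerate codon must have exactly three letters", "invalid_code_error")
  letters3 <- strsplit(code, "")[[1]]
  bad <- setdiff(letters3, names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad) > 0)
    coevStop(sprintf("invalid IUPAC nucleotide letter(s): %s", paste(bad, collapse = ", ")),
             "invalid_code_error")
  per <- lapply(letters3, function(l) strsplit(Biostrings::IUPAC_CODE_MAP[[l]], "")[[1]])
  grid <- expand.grid(per[[3]], per[[2]], per[[1]], stringsAsFactors = FALSE)
  sort(unique(paste0(grid[[3]], grid[[2]], grid[[1]])))
}

#' Translate a set of codons under the standard genetic code
#'
#' @param codons character vector of concrete DNA triplets.
#' @return list with \code{aminoAcids} (sorted distinct one-letter codes,
#'   stops excluded) and \code{stopCodons} (sorted codons translating to a
#'   stop).
#' @examples
#' translateCodonSet(expandDegenerateCodon("NNK"))
#' @export
translateCodonSet <- function(codons) {
  ok <- vapply(codons, validCodon, logical(1))
  if (!all(ok))
    coevStop(sprintf("invalid codon(s): %s", paste(codons[!ok], collapse = ", ")),
             "invalid_codon_error")
  aa <- Biostrings::GENETIC_CODE[codons]
  list(aminoAcids = sort(unique(aa[aa != "*"])),
       stopCodons = sort(unique(codons[aa == "*"])))
}

#' Minimum nucleotide changes between two codons
#'
#' Positionwise Hamming distance between two concrete triplets: the minimum
#' number of single-nucleotide changes needed to turn one codon into the
#' other. Substitutions reachable only by two or three base changes per codon
#' are effectively inaccessible to error-prone PCR or single-gene shuffling,
#' which is what degenerate-codon saturation buys.
#'
#' @param codonWt,codonMut concrete DNA triplets.
#' @return integer in \code{0:3}.
#' @examples
#' minCodonChanges("GGC", "GGG")  # 1
#' minCodonChanges("AAT", "TGT")  # 2
#' @export
minCodonChanges <- function(codonWt, codonMut) {
  codonWt <- toupper(codonWt); codonMut <- toupper(codonMut)
  if (!validCodon(codonWt) || !validCodon(codonMut))
    coevStop("codons must be concrete ACGT triplets", "invalid_codon_error")
  sum(strsplit(codonWt, "")[[1]] != strsplit(codonMut, "")[[1]])
}
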