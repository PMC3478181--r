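# Mutagenic primer design for whole-plasmid (QuikChange-style) saturation
# mutagenesis: complementary 33-35 nt oligos with one in-frame degenerate
# codon replacing the target codon.

# Expected GC content of an IUPAC letter: fraction of G/C among its expansion.
iupacExpectedGC <- function(letters3) {
  vapply(letters3, function(l) {
    bases <- strsplit(Biostrings::IUPAC_CODE_MAP[[l]], "")[[1]]
    mean(bases %in% c("G", "C"))
  }, numeric(1))
}

# QuikChange manual estimate: Tm = 81.5 + 0.41 * %GC - 675 / N.
# Degenerate positions contribute their expected GC.
primerTm <- function(primer) {
  letters1 <- strsplit(toupper(primer), "")[[1]]
  gc <- sum(iupacExpectedGC(letters1))
  n <- length(letters1)
  81.5 + 0.41 * (100 * gc / n) - 675 / n
}

readSingleDNA <- function(cds) {
  if (is(cds, "DNAString")) return(as.character(cds))
  if (length(cds) == 1 && file.exists(cds)) {
    set <- Biostrings::readDNAStringSet(cds)
    if (length(set) == 0) coevStop(sprintf("empty input: %s", cds), "empty_input_error")
    return(as.character(set[[1]]))
  }
  toupper(as.character(cds))
}

#' Design a complementary primer pair with a degenerate codon at one site
#'
#' Builds a forward primer of the requested length with the degenerate codon
#' replacing the wild-type codon of the target residue, flanks copied
#' verbatim from the coding sequence, and the reverse primer as the exact
#' reverse complement. The degenerate codon is centered; when the total
#' flank length is odd the extra base goes to the 5' side. The melting
#' temperature is estimated as \eqn{81.5 + 0.41 \cdot \%GC - 675/N}
#' (degenerate positions counted at their expected GC); primers below 78 C
#' trigger a warning but are still returned.
#'
#' @param cds coding DNA sequence: a string, a \code{DNAString}, or a path to
#'   a FASTA file (first record used). Length must be a multiple of 3.
#' @param site 1-based codon (residue) number to randomize.
#' @param code degenerate codon (IUPAC), default \code{"NNK"}.
#' @param primerLength total primer length, 33-35 nt (default 33).
#' @return A [PrimerPair-class].
#' @examples
#' cds <- paste(rep("GCTGAAGTT", 20), collapse = "")
#' designPrimerPair(cds, site = 10)
#' @export
designPrimerPair <- function(cds, site, code = "NNK", primerLength = 33L) {
  seqDNA <- readSingleDNA(cds)
  if (!grepl("^[ACGT]*$", seqDNA))
    coevStop("coding sequence must contain only A, C, G, T", "invalid_codon_error")
  if (nchar(seqDNA) %% 3 != 0)
    coevStop("coding sequence length is not a multiple of 3", "frame_error")
  primerLength <- as.integer(primerLength)
  if (!primerLength %in% 33:35)
    coevStop("primer length must be 33, 34 or 35", "config_error")
  nCodons <- nchar(seqDNA) / 3
  if (site < 1 || site > nCodons)
    coevStop(sprintf("site %d outside the coding sequence (%d codons)", site, nCodons),
             "config_error")
  code <- toupper(code)
  expandDegenerateCodon(code)  # validates the IUPAC letters

  flankTotal <- primerLength - 3L
  left <- as.integer(ceiling(flankTotal / 2))  # extra base 5' when odd
  right <- flankTotal - left
  codonStart <- (site - 1L) * 3L + 1L
  if (codonStart - left < 1L || codonStart + 2L + right > nchar(seqDNA))
    coevStop(sprintf("site %d too close to the CDS ends for a %d nt primer",
                     site, primerLength), "flank_too_short_error")
  forward <- paste0(substr(seqDNA, codonStart - left, codonStart - 1L),
                    code,
                    substr(seqDNA, codonStart + 3L, codonStart + 2L + right))
  reverse <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(forward)))
  tm <- primerTm(forward)
  if (tm < 78)
    coevWarn(sprintf("primer for site %d has estimated Tm %.1f C (< 78 C)", site, tm),
             "low_tm_warning")
  new("PrimerPair", forward = forward, reverse = reverse,
      targetSite = as.integer(site), degenerateOffset = left,
      code = code, meltingTemperature = tm)
}

#' Design a combinatorial saturation-mutagenesis library at a site pair
#'
#' One primer pair per site (each oligo randomizes a single site; the sites
#' are mutagenized in the same construct), with the library's theoretical
#' accounting: codon combinations as independent draws from the degenerate
#' expansion at each site (32 x 32 = 1024 for two NNK sites), amino-acid
#' combinations, and the expected fraction of members carrying at least one
#' stop codon.
#'
#' @inheritParams designPrimerPair
#' @param sites vector of 1-based codon numbers to randomize (typically a
#'   coevolving pair of length 2).
#' @return A [LibraryDesign-class].
#' @examples
#' cds <- paste(rep("GCTGAAGTT", 20), collapse = "")
#' libraryDesign(cds, sites = c(10, 25))
#' @export
libraryDesign <- function(cds, sites, code = "NNK", primerLength = 33L) {
  if (length(sites) < 1) coevStop("at least one site is required", "config_error")
  seqDNA <- readSingleDNA(cds)
  primers <- lapply(sites, function(s)
    designPrimerPair(seqDNA, s, code = code, primerLength = primerLength))
  expansion <- expandDegenerateCodon(code)
  tr <- translateCodonSet(expansion)
  k <- length(sites)
  stopPerSite <- length(tr$stopCodons) / length(expansion)
  wt <- vapply(sites, function(s) substr(seqDNA, (s - 1) * 3 + 1, (s - 1) * 3 + 3),
               character(1))
  new("LibraryDesign",
      sites = as.integer(sites), code = toupper(code), primers = primers,
      codonCombinations = length(expansion)^k,
      aminoAcidCombinations = length(tr$aminoAcids)^k,
      stopFraction = 1 - (1 - stopPerSite)^k,
      wildTypeCodons = setNames(wt, sites))
}

#' Expected library coverage for a given screening effort
#'
#' Under uniform sampling of the \eqn{V} codon combinations of a library,
#' screening \eqn{L} clones is expected to observe
#' \eqn{V (1 - (1 - 1/V)^L)} distinct combinations (the coupon-collector
#' expectation). Completeness is that expectation divided by \eqn{V}.
#'
#' @param design a [LibraryDesign-class], or directly the number of codon
#'   combinations \eqn{V}.
#' @param clonesScreened number of clones screened, \eqn{L \ge 0}.
#' @return named numeric vector \code{c(expectedDistinct = , completeness = )}.
#' @examples
#' libraryCoverage(1024, 1001)
#' @export
libraryCoverage <- function(design, clonesScreened) {
  V <- if (is(design, "LibraryDesign")) design@codonCombinations else as.numeric(design)
  if (length(V) != 1 || is.na(V) || V < 1)
    coevStop("the library must have at least one codon combination", "config_error")
  L <- as.numeric(clonesScreened)
  if (is.na(L) || L < 0)
    coevStop("clonesScreened must be nonnegative", "config_error")
  expected <- V * (1 - (1 - 1 / V)^L)
  c(expectedDistinct = expected, completeness = expected / V)
}

#' Write primer pairs as TSV
#'
#' Columns: site, forward, reverse, length, tm, degenerate_offset (0-based).
#'
#' @param primers list of [PrimerPair-class] (e.g. the \code{primers} of a
#'   [LibraryDesign-class]).
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writePrimerTable <- function(primers, path) {
  df <- do.call(rbind, lapply(primers, function(p) data.frame(
    site = p@targetSite, forward = p@forward, reverse = p@reverse,
    length = nchar(p@forward), tm = fmtNum(p@meltingTemperature, 2),
    degenerate_offset = p@degenerateOffset, stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
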