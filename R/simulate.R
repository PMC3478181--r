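# Synthetic data with known ground truth: alignments carrying planted
# covarying column pairs, and variant pools drawn from degenerate-codon
# libraries. Rows are independent (no phylogenetic tree is simulated);
# coupling is a fixed residue bijection applied with a given probability,
# the simplest mechanism whose pair MI is analytically known at coupling 1
# (it equals the first column's empirical entropy).

#' Simulate an alignment with planted coevolving column pairs
#'
#' Background columns are drawn independently from a residue profile
#' (uniform over the 20 amino acids by default). For each planted pair
#' \code{c(a, b)}, column \code{a} is drawn from the profile and, per row,
#' with probability \code{coupling} the residue at column \code{b} is a
#' fixed bijection of the residue at \code{a}; otherwise it is drawn
#' independently. Gaps are then injected independently per cell at
#' \code{gapRate} (planted columns included, which exercises downstream
#' gap-exclusion rules). Fully reproducible from \code{seed}.
#'
#' @param nSeqs number of sequences (>= 2).
#' @param nCols number of columns (>= 2).
#' @param plantedPairs list of 2-vectors of distinct column indices; all
#'   planted columns must be distinct.
#' @param coupling probability in \code{[0, 1]} that a planted pair's second
#'   column copies the bijection of the first (default 1).
#' @param gapRate per-cell gap probability in \code{[0, 1]} (default 0).
#' @param profile numeric vector of 20 residue probabilities (default
#'   uniform); need not be normalized.
#' @param seed integer seed.
#' @return list with \code{alignment} (a [ProteinAlignment-class]; the first
#'   sequence, \code{seq1}, is the query) and \code{truth} (list with
#'   \code{pairs}, \code{coupling}, \code{gapRate}, \code{seed} and the
#'   per-pair residue \code{bijections}).
#' @examples
#' sim <- simulateCoevolvingAlignment(50, 10, list(c(2, 7)), coupling = 1, seed = 1)
#' sim$truth$pairs
#' @export
simulateCoevolvingAlignment <- function(nSeqs, nCols, plantedPairs = list(),
                                        coupling = 1, gapRate = 0,
                                        profile = NULL, seed = 1L) {
  if (is.na(nSeqs) || nSeqs < 2) coevStop("nSeqs must be >= 2", "config_error")
  if (is.na(nCols) || nCols < 2) coevStop("nCols must be >= 2", "config_error")
  if (coupling < 0 || coupling > 1) coevStop("coupling must lie in [0, 1]", "config_error")
  if (gapRate < 0 || gapRate > 1) coevStop("gapRate must lie in [0, 1]", "config_error")
  plantedCols <- unlist(plantedPairs)
  if (length(plantedCols) > 0) {
    if (any(plantedCols < 1 | plantedCols > nCols))
      coevStop("planted pair columns out of range", "config_error")
    if (anyDuplicated(plantedCols))
      coevStop("planted pair columns must be distinct", "config_error")
    if (any(vapply(plantedPairs, length, integer(1)) != 2))
      coevStop("each planted pair must name exactly two columns", "config_error")
  }
  if (is.null(profile)) profile <- rep(1, 20)
  if (length(profile) != 20 || any(profile < 0) || sum(profile) <= 0)
    coevStop("profile must be 20 nonnegative weights", "config_error")
  profile <- profile / sum(profile)

  set.seed(as.integer(seed))
  enc <- matrix(sample.int(20L, nSeqs * nCols, replace = TRUE, prob = profile),
                nrow = nSeqs, ncol = nCols)
  bijections <- lapply(plantedPairs, function(p) sample.int(20L))
  for (k in seq_along(plantedPairs)) {
    p <- plantedPairs[[k]]
    copy <- runif(nSeqs) < coupling
    enc[copy, p[2]] <- bijections[[k]][enc[copy, p[1]]]
  }
  chars <- matrix(AA20[enc], nrow = nSeqs)
  if (gapRate > 0) chars[runif(nSeqs * nCols) < gapRate] <- GAP_CHAR
  seqs <- apply(chars, 1, paste, collapse = "")
  aln <- new("ProteinAlignment", ids = paste0("seq", seq_len(nSeqs)),
             seqs = seqs, queryId = "seq1")
  list(alignment = aln,
       truth = list(pairs = plantedPairs, coupling = coupling,
                    gapRate = gapRate, seed = as.integer(seed),
                    bijections = bijections))
}

#' Simulate a sequenced variant pool from a degenerate-codon library
#'
#' Draws, for every variant and every designed site, a codon uniformly from
#' the degenerate expansion — the idealized content of a saturation library
#' before any screening bias. Ground-truth per-site codon counts are
#' returned alongside.
#'
#' @param design a [LibraryDesign-class], or a vector of site numbers (the
#'   degenerate code then comes from \code{code}).
#' @param nVariants number of variants to draw (>= 0).
#' @param seed integer seed.
#' @param code degenerate codon used when \code{design} is a plain site
#'   vector (default \code{"NNK"}).
#' @return list with \code{pool} (long data.frame: id, site, codon) and
#'   \code{truth}, a list of per-site codon count tables.
#' @examples
#' simulateVariantPool(c(89, 100), nVariants = 3, seed = 1)$pool
#' @export
simulateVariantPool <- function(design, nVariants, seed = 1L, code = "NNK") {
  if (is.na(nVariants) || nVariants < 0)
    coevStop("nVariants must be nonnegative", "config_error")
  if (is(design, "LibraryDesign")) {
    sites <- design@sites
    code <- design@code
  } else {
    sites <- as.integer(design)
  }
  if (length(sites) == 0) coevStop("at least one designed site is required", "config_error")
  expansion <- expandDegenerateCodon(code)
  set.seed(as.integer(seed))
  if (nVariants == 0) {
    pool <- data.frame(id = character(0), site = integer(0), codon = character(0),
                       stringsAsFactors = FALSE)
    truth <- lapply(sites, function(s) setNames(integer(length(expansion)), expansion))
    names(truth) <- sites
    return(list(pool = pool, truth = truth))
  }
  ids <- sprintf("v%05d", seq_len(nVariants))
  pool <- do.call(rbind, lapply(sites, function(s) data.frame(
    id = ids, site = s,
    codon = expansion[sample.int(length(expansion), nVariants, replace = TRUE)],
    stringsAsFactors = FALSE)))
  pool <- pool[order(pool$id, pool$site), , drop = FALSE]
  rownames(pool) <- NULL
  truth <- lapply(sites, function(s) {
    cod <- pool$codon[pool$site == s]
    counts <- table(factor(cod, levels = expansion))
    setNames(as.integer(counts), expansion)
  })
  names(truth) <- sites
  list(pool = pool, truth = truth)
}
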