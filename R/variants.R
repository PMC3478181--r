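# Post-screening sequence analysis: classify sequenced variants by how many
# designed sites changed at the protein level, and tabulate per-site
# amino-acid/codon substitution counts in the shape of a published mutant
# screen table.

VARIANT_CLASSES <- c("unchanged_or_synonymous", "single_missense",
                     "double_missense", "contains_stop")

translateCodons <- function(codons) unname(Biostrings::GENETIC_CODE[toupper(codons)])

checkWildType <- function(wildType) {
  if (is.null(names(wildType)) || any(!nzchar(names(wildType))))
    coevStop("wildType must be a named character vector: names are site numbers, values wild-type codons",
             "config_error")
  ok <- vapply(wildType, validCodon, logical(1))
  if (!all(ok))
    coevStop("wildType codons must be concrete ACGT triplets", "invalid_codon_error")
  wildType
}

#' Classify sequenced variants by designed-site changes
#'
#' Each variant is classified by the number of designed sites whose
#' translated residue differs from the wild type:
#' \code{unchanged_or_synonymous} (no amino-acid change at any designed
#' site; synonymous DNA changes land here), \code{single_missense},
#' \code{double_missense} (two or more changed sites), or
#' \code{contains_stop} if any designed-site codon is a stop.
#'
#' @param pool data.frame of sequenced variants in long format with columns
#'   \code{id}, \code{site}, \code{codon} — one row per designed site per
#'   variant.
#' @param wildType named character vector of wild-type codons; names are the
#'   designed site numbers.
#' @return data.frame with one row per variant: \code{id} and \code{class}
#'   (factor with the four class levels), in first-appearance order of ids.
#' @examples
#' wt <- c("95" = "GAT", "147" = "ACT")
#' pool <- data.frame(id = "v1", site = c(95, 147), codon = c("CAT", "TCT"))
#' classifyVariants(pool, wt)  # double_missense (D95H + T147S)
#' @export
classifyVariants <- function(pool, wildType) {
  wildType <- checkWildType(wildType)
  need <- c("id", "site", "codon")
  if (!all(need %in% names(pool)))
    coevStop("pool must have columns id, site, codon", "config_error")
  sites <- names(wildType)
  wtAA <- translateCodons(wildType)
  ids <- unique(pool$id)
  cls <- vapply(ids, function(v) {
    rows <- pool[pool$id == v, , drop = FALSE]
    hit <- match(sites, as.character(rows$site))
    if (anyNA(hit))
      coevStop(sprintf("variant %s is missing designed site(s): %s",
                       v, paste(sites[is.na(hit)], collapse = ", ")),
               "incomplete_record_error")
    codons <- toupper(rows$codon[hit])
    ok <- vapply(codons, validCodon, logical(1))
    if (!all(ok))
      coevStop(sprintf("variant %s has invalid codon(s): %s",
                       v, paste(codons[!ok], collapse = ", ")),
               "invalid_codon_error")
    aa <- translateCodons(codons)
    if (any(aa == "*")) return("contains_stop")
    nChanged <- sum(aa != wtAA)
    if (nChanged == 0) "unchanged_or_synonymous"
    else if (nChanged == 1) "single_missense"
    else "double_missense"
  }, character(1))
  data.frame(id = ids, class = factor(cls, levels = VARIANT_CLASSES),
             stringsAsFactors = FALSE)
}

buildTallyTable <- function(df, wildType, conflicts = NULL) {
  wildType <- checkWildType(wildType)
  if (nrow(df) > 0) {
    wtCodon <- wildType[as.character(df$site)]
    if (anyNA(wtCodon))
      coevStop("tally contains sites absent from the wild-type spec",
               "inconsistent_records_error")
    df$minChanges <- mapply(minCodonChanges, wtCodon, df$codon, USE.NAMES = FALSE)
    df <- df[order(df$site, df$aminoAcid, df$codon), , drop = FALSE]
    rownames(df) <- NULL
  } else {
    df <- data.frame(site = integer(0), aminoAcid = character(0),
                     codon = character(0), count = integer(0),
                     minChanges = integer(0), stringsAsFactors = FALSE)
  }
  if (is.null(conflicts))
    conflicts <- df[df$aminoAcid != translateCodons(df$codon), , drop = FALSE]
  new("TallyTable", tally = df, wildType = wildType, conflicts = conflicts)
}

#' Tally substitutions in a pool of sequenced variants
#'
#' Counts, per designed site, every codon that differs from the wild-type
#' codon (synonymous codon changes included: they are observed
#' substitutions at the DNA level whose residue equals the wild type), with
#' the translated amino acid and the minimum nucleotide changes relative to
#' the wild-type codon.
#'
#' All variant records must cover the same designed-site set.
#'
#' @inheritParams classifyVariants
#' @return A [TallyTable-class].
#' @examples
#' wt <- c("89" = "GGC")
#' pool <- data.frame(id = c("v1", "v2"), site = 89, codon = c("CGT", "GGC"))
#' tally(tallyVariants(pool, wt))  # one Arg substitution; v2 is unchanged
#' @export
tallyVariants <- function(pool, wildType) {
  wildType <- checkWildType(wildType)
  if (nrow(pool) == 0) return(buildTallyTable(pool, wildType))
  sites <- sort(names(wildType))
  perVariant <- split(as.character(pool$site), pool$id)
  consistent <- vapply(perVariant, function(s) identical(sort(unique(s)), sites), logical(1))
  if (!all(consistent))
    coevStop(sprintf("variant(s) %s do not cover the designed-site set",
                     paste(names(perVariant)[!consistent], collapse = ", ")),
             "inconsistent_records_error")
  pool$codon <- toupper(pool$codon)
  ok <- vapply(pool$codon, validCodon, logical(1))
  if (!all(ok))
    coevStop(sprintf("invalid codon(s): %s", paste(unique(pool$codon[!ok]), collapse = ", ")),
             "invalid_codon_error")
  sub <- pool[pool$codon != wildType[as.character(pool$site)], , drop = FALSE]
  if (nrow(sub) == 0) return(buildTallyTable(sub[, 0], wildType))
  agg <- aggregate(list(count = rep(1L, nrow(sub))),
                   by = list(site = as.integer(sub$site), codon = sub$codon), FUN = sum)
  agg$aminoAcid <- translateCodons(agg$codon)
  buildTallyTable(agg[, c("site", "aminoAcid", "codon", "count")], wildType)
}

#' Read a substitution table of sequenced variants
#'
#' Reads a TSV with columns \code{site}, \code{amino_acid}, \code{codon},
#' \code{count} — the layout of a published per-site substitution summary —
#' into a [TallyTable-class]. The recorded amino-acid call is trusted as
#' printed; entries whose codon translates to a different residue are kept
#' but collected in the table's \code{conflicts} slot and reported with a
#' message.
#'
#' @param path TSV file path.
#' @param wildType named character vector of wild-type codons per site.
#' @return A [TallyTable-class].
#' @export
readSubstitutionTable <- function(path, wildType) {
  if (!file.exists(path)) coevStop(sprintf("file not found: %s", path), "file_not_found_error")
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("site", "amino_acid", "codon", "count")
  if (!all(need %in% names(df)))
    coevStop(sprintf("substitution table must have columns %s", paste(need, collapse = ", ")),
             "config_error")
  df <- data.frame(site = as.integer(df$site), aminoAcid = toupper(df$amino_acid),
                   codon = toupper(df$codon), count = as.integer(df$count),
                   stringsAsFactors = FALSE)
  tt <- buildTallyTable(df, wildType)
  if (nrow(tt@conflicts) > 0)
    message(sprintf("%d entr%s where the recorded residue differs from the codon translation (kept as recorded)",
                    nrow(tt@conflicts), if (nrow(tt@conflicts) == 1) "y" else "ies"))
  tt
}

#' Per-site amino-acid diversity of a tally
#'
#' Number of distinct amino acids observed among the codon-changed entries
#' at each site. The most diverse site is attached as attribute
#' \code{"mostDiverse"}; ties are broken by the lower residue number.
#'
#' @param t a [TallyTable-class].
#' @return named integer vector of distinct amino-acid counts, named by
#'   site, in increasing site order.
#' @export
siteDiversity <- function(t) {
  stopifnot(is(t, "TallyTable"))
  sites <- sort(unique(c(as.integer(names(t@wildType)), t@tally$site)))
  div <- vapply(sites, function(s)
    length(unique(t@tally$aminoAcid[t@tally$site == s])), integer(1))
  out <- setNames(div, sites)
  if (length(out) > 0)
    attr(out, "mostDiverse") <- sites[which.max(div)]  # which.max takes first on ties
  out
}

#' Class percentages of a variant pool
#'
#' Percentage of variants in each class, rounded half-up to one decimal.
#'
#' @param classes vector (or factor) of class labels, e.g. the \code{class}
#'   column of [classifyVariants()].
#' @return named numeric vector of percentages, one per observed (or factor)
#'   level, summing to ~100.
#' @examples
#' summaryFractions(rep(c("unchanged_or_synonymous", "single_missense",
#'                        "double_missense"), c(28, 35, 35)))
#' @export
summaryFractions <- function(classes) {
  if (length(classes) == 0) coevStop("empty input: no class labels", "empty_input_error")
  counts <- table(classes)
  setNames(roundHalfUp(100 * as.numeric(counts) / length(classes), 1), names(counts))
}

#' Write a tally table as TSV
#'
#' Long-format mirror of a per-site substitution table: columns site,
#' amino_acid, codon, count, min_changes.
#'
#' @param t a [TallyTable-class].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeTallyTable <- function(t, path) {
  stopifnot(is(t, "TallyTable"))
  df <- t@tally
  out <- data.frame(site = df$site, amino_acid = df$aminoAcid, codon = df$codon,
                    count = df$count, min_changes = df$minChanges)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
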