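# Alignment input/output and the column -> query-residue map.

detectAlignmentFormat <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) coevStop(sprintf("empty input: %s", path), "empty_input_error")
  if (startsWith(trimws(lines[1]), ">")) return("fasta")
  if (grepl("^(CLUSTAL|MUSCLE|MAFFT)", lines[1], ignore.case = TRUE)) return("clustal")
  coevStop(sprintf("cannot infer alignment format of %s; pass format explicitly", path),
           "alignment_format_error")
}

#' Read a protein multiple sequence alignment
#'
#' Reads an aligned FASTA or CLUSTAL file into a [ProteinAlignment-class].
#' Sequence order is preserved; residues are normalized (upper case, \code{.}
#' to \code{-}, ambiguity letters to \code{X}).
#'
#' @param path path to the alignment file.
#' @param format \code{"auto"} (default, inferred from content), \code{"fasta"}
#'   or \code{"clustal"}.
#' @param queryId id of the query row; defaults to the first sequence.
#' @param dedup if \code{TRUE}, drop sequences whose aligned row is an exact
#'   duplicate of an earlier one (the query row is always kept). Default off.
#' @return A [ProteinAlignment-class].
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">q", "ACD-E", ">s1", "ACDFE"), f)
#' readAlignment(f)
#' @export
readAlignment <- function(path, format = c("auto", "fasta", "clustal"),
                          queryId = NULL, dedup = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) coevStop(sprintf("file not found: %s", path), "file_not_found_error")
  if (file.size(path) == 0) coevStop(sprintf("empty input: %s", path), "empty_input_error")
  if (format == "auto") format <- detectAlignmentFormat(path)

  if (format == "fasta") {
    # BStringSet is deliberately permissive: normalization and alphabet
    # checks happen in the ProteinAlignment constructor.
    set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                    error = function(e) coevStop(
                      sprintf("failed to parse FASTA %s: %s", path, conditionMessage(e)),
                      "alignment_format_error"))
    ids <- sub("\\s.*$", "", names(set))
    seqs <- as.character(set)
  } else {
    aln <- tryCatch(Biostrings::readAAMultipleAlignment(path, format = "clustal"),
                    error = function(e) coevStop(
                      sprintf("failed to parse CLUSTAL %s: %s", path, conditionMessage(e)),
                      "alignment_format_error"))
    seqs <- as.character(Biostrings::unmasked(aln))
    ids <- names(seqs)
    seqs <- unname(seqs)
  }
  if (length(seqs) == 0) coevStop(sprintf("empty input: %s", path), "empty_input_error")
  if (is.null(queryId)) queryId <- ids[1]
  if (isTRUE(dedup)) {
    keep <- !duplicated(seqs) | ids == queryId
    ids <- ids[keep]; seqs <- seqs[keep]
  }
  ProteinAlignment(ids, seqs, queryId = queryId)
}

#' Write an alignment as aligned FASTA
#'
#' @param aln a [ProteinAlignment-class].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeAlignment <- function(aln, path) {
  set <- Biostrings::BStringSet(setNames(aln@seqs, aln@ids))
  Biostrings::writeXStringSet(set, filepath = path, format = "fasta", width = 60L)
  invisible(path)
}

#' Map alignment columns to query residue numbers
#'
#' Query residue numbering is 1-based over the ungapped query sequence;
#' columns where the query row is gapped (or missing, \code{X}) are absent
#' from the map.
#'
#' @param aln a [ProteinAlignment-class].
#' @return data.frame with columns \code{column} (1-based alignment column),
#'   \code{residue} (1-based query residue number) and \code{wt} (the query's
#'   residue letter at that position).
#' @examples
#' aln <- ProteinAlignment(c("q", "s"), c("A-CD", "AHCD"))
#' columnToQueryMap(aln)
#' @export
columnToQueryMap <- function(aln) {
  stopifnot(is(aln, "ProteinAlignment"))
  q <- strsplit(aln@seqs[match(aln@queryId, aln@ids)], "")[[1]]
  mapped <- which(q != GAP_CHAR)
  if (length(mapped) == 0)
    coevStop(sprintf("query row '%s' is entirely gaps", aln@queryId), "empty_query_error")
  data.frame(column = mapped, residue = seq_along(mapped), wt = q[mapped],
             stringsAsFactors = FALSE)
}

#' Write a column-to-residue map as TSV
#'
#' Two columns: \code{column} (1-based alignment column) and
#' \code{query_residue} (1-based residue number in the ungapped query).
#'
#' @param cmap data.frame from [columnToQueryMap()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeColumnMap <- function(cmap, path) {
  out <- data.frame(column = cmap$column, query_residue = cmap$residue)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
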