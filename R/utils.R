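# Internal constants and helpers shared across modules.

# Canonical 20-letter amino-acid alphabet, alphabetical one-letter codes.
# Order is load-bearing: integer encodings index into this vector.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP_CHAR <- "-"
MISSING_CHAR <- "X"

# Ambiguity / non-standard residue letters collapsed to the missing symbol:
# B (Asx), Z (Glx), J (Xle), U (Sec), O (Pyl) and X itself.
NONSTANDARD_AA <- c("B", "Z", "J", "U", "O", "X")

#' @importFrom methods is new validObject slot
#' @importFrom stats sd setNames runif dist aggregate
#' @importFrom utils head read.delim write.table packageVersion
NULL

coevStop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("coevolib_", class), "coevolib_error", "error"),
                      call = if (isTRUE(call.)) sys.call(-1) else NULL))
}

coevWarn <- function(msg, class) {
  warning(warningCondition(msg, class = c(paste0("coevolib_", class), "coevolib_warning", "warning")))
}

# Normalize a raw sequence string to the declared alphabet:
# upper-case, '.' -> '-', non-standard residue letters -> 'X'.
normalizeResidues <- function(x) {
  x <- toupper(x)
  x <- chartr(".", GAP_CHAR, x)
  x <- chartr(paste(NONSTANDARD_AA, collapse = ""),
              strrep(MISSING_CHAR, length(NONSTANDARD_AA)), x)
  bad <- setdiff(unique(strsplit(paste(x, collapse = ""), "")[[1]]),
                 c(AA20, GAP_CHAR, MISSING_CHAR))
  if (length(bad) > 0) {
    coevStop(sprintf("invalid residue character(s): %s", paste(bad, collapse = ", ")),
             "alphabet_error")
  }
  x
}

# Character matrix (n_seqs x n_cols) from a set of equal-length strings.
seqCharMatrix <- function(seqs) {
  if (length(seqs) == 0) return(matrix(character(0), nrow = 0, ncol = 0))
  matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
         nrow = length(seqs), byrow = TRUE)
}

# Half-up rounding to `digits` decimals (round() in R is banker's).
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

fmtNum <- function(x, digits = 6) {
  formatC(x, format = "f", digits = digits)
}
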