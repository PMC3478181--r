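#' Number of sequences in an alignment
#' @param x a [ProteinAlignment-class]
#' @return integer count
#' @export
setGeneric("nSeqs", function(x) standardGeneric("nSeqs"))

#' Number of columns in an alignment
#' @param x a [ProteinAlignment-class]
#' @return integer count
#' @export
setGeneric("nCols", function(x) standardGeneric("nCols"))

#' Sequence identifiers
#' @param x a [ProteinAlignment-class]
#' @return character vector
#' @export
setGeneric("alnIds", function(x) standardGeneric("alnIds"))

#' Aligned rows as named character strings
#' @param x a [ProteinAlignment-class]
#' @return named character vector
#' @export
setGeneric("alnSeqs", function(x) standardGeneric("alnSeqs"))

#' Query sequence identifier
#' @param x a [ProteinAlignment-class]
#' @return character scalar
#' @export
setGeneric("queryId", function(x) standardGeneric("queryId"))

#' Score matrix of a pairwise column-score object
#' @param x an [MIMatrix-class] or [RCWMatrix-class]
#' @return numeric symmetric matrix
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' Tally data.frame of a TallyTable
#' @param x a [TallyTable-class]
#' @return data.frame with columns site, aminoAcid, codon, count, minChanges
#' @export
setGeneric("tally", function(x) standardGeneric("tally"))
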