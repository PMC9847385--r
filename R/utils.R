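# Internal helpers shared across modules.

#' Reverse-complement nucleotide sequences
#'
#' Vectorised reverse complement over character sequences (A/C/G/T/N, case
#' preserved as upper case).
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAN"))
revcomp <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Normalize chromosome names
#'
#' Unifies the two GRCh38 naming conventions ("1" vs "chr1") so tracks and
#' alignments from mixed sources can be joined. All comparisons inside the
#' package happen on the normalized ("chr"-prefixed) form.
#'
#' @param x Character vector of chromosome names.
#' @return Character vector with a "chr" prefix; "*" is passed through.
#' @export
#' @examples
#' normalize_chrom(c("1", "chr1", "MT", "*"))
normalize_chrom <- function(x) {
  if (length(x) == 0) return(character(0))
  bare <- sub("^chr", "", x, ignore.case = TRUE)
  bare[bare == "MT"] <- "M"
  out <- paste0("chr", bare)
  out[x == "*"] <- "*"
  out
}

#' Convert between Phred strings and integer scores
#'
#' @param qual A quality string; `phred` an integer vector of scores.
#' @param offset Encoding offset (33 for Phred+33).
#' @return `qual_to_phred()` an integer vector; `phred_to_qual()` a string.
#' @export
qual_to_phred <- function(qual, offset = 33L) {
  if (is.na(qual) || qual == "*") return(integer())
  as.integer(charToRaw(qual)) - offset
}

#' @rdname qual_to_phred
#' @param phred Integer vector of Phred scores.
#' @export
phred_to_qual <- function(phred, offset = 33L) {
  rawToChar(as.raw(phred + offset))
}

# stop with a classed error carrying a stage name (pipeline diagnostics)
vl_abort <- function(msg, class, ...) {
  abort(msg, class = c(class, "viralint_error"), ...)
}
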