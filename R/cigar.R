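# CIGAR parsing and arithmetic. Query-consuming ops: M I S = X;
# reference-consuming ops: M D N = X.

CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")
CIGAR_QUERY_OPS <- c("M", "I", "S", "=", "X")
CIGAR_REF_OPS <- c("M", "D", "N", "=", "X")

#' Parse a CIGAR string
#'
#' Decodes a SAM CIGAR string into an ordered table of operations. The
#' grammar is `(\\d+[MIDNSHP=X])+` or `"*"` (no alignment), which yields a
#' zero-row table.
#'
#' @param cigar A single CIGAR string.
#' @return A tibble with columns `op` (character) and `len` (integer), one
#'   row per operation in order.
#' @export
#' @examples
#' parse_cigar("50S100M")
parse_cigar <- function(cigar) {
  stopifnot(is.character(cigar), length(cigar) == 1)
  if (is.na(cigar) || cigar == "*") {
    return(tibble(op = character(), len = integer()))
  }
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (paste(toks, collapse = "") != cigar || length(toks) == 0) {
    vl_abort(paste0("malformed CIGAR string: '", cigar, "'"),
             "viralint_parse_error")
  }
  tibble(
    op = substring(toks, nchar(toks), nchar(toks)),
    len = as.integer(substring(toks, 1, nchar(toks) - 1))
  )
}

# vectorized validity check (TRUE for "*")
cigar_is_valid <- function(cigar) {
  ok <- cigar == "*" | grepl("^([0-9]+[MIDNSHP=X])+$", cigar)
  ok[is.na(cigar)] <- FALSE
  ok
}

# vectorized sum of op lengths for ops in `which`; 0 for "*"
cigar_op_sum <- function(cigar, which) {
  out <- integer(length(cigar))
  todo <- !is.na(cigar) & cigar != "*"
  if (!any(todo)) return(out)
  toks <- regmatches(cigar[todo], gregexpr("[0-9]+[MIDNSHP=X]", cigar[todo]))
  out[todo] <- vapply(toks, function(tk) {
    op <- substring(tk, nchar(tk), nchar(tk))
    sum(as.integer(substring(tk, 1, nchar(tk) - 1))[op %in% which])
  }, integer(1))
  out
}

#' Query length and reference span of CIGAR strings
#'
#' `cigar_query_len()` sums the query-consuming operations (M, I, S, =, X);
#' `cigar_ref_span()` sums the reference-consuming operations (M, D, N, =, X).
#' Both are vectorised and return 0 for `"*"`.
#'
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector.
#' @export
cigar_query_len <- function(cigar) cigar_op_sum(cigar, CIGAR_QUERY_OPS)

#' @rdname cigar_query_len
#' @export
cigar_ref_span <- function(cigar) cigar_op_sum(cigar, CIGAR_REF_OPS)

# vectorized leading/trailing soft-clip lengths (hard clips are transparent:
# they carry no sequence)
cigar_clip_len <- function(cigar, side = c("left", "right")) {
  side <- match.arg(side)
  pat <- if (side == "left") "^(?:[0-9]+H)?([0-9]+)S" else
    "([0-9]+)S(?:[0-9]+H)?$"
  m <- str_match(cigar, pat)[, 2]
  out <- as.integer(m)
  out[is.na(out)] <- 0L
  out[is.na(cigar) | cigar == "*"] <- 0L
  out
}
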