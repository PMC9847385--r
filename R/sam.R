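# SAM reading/writing. Only the 11 mandatory columns are interpreted;
# optional tags are carried as an opaque string so records round-trip
# byte-identically.

SAM_COLS <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
              "mrnm", "mpos", "tlen", "seq", "qual")

#' Parse one SAM alignment line
#'
#' Decodes a single tab-delimited SAM record into a one-row tibble with the
#' eleven mandatory fields plus a `tags` column holding any optional fields
#' verbatim. Malformed records (too few fields, bad CIGAR grammar,
#' non-numeric flag/pos, or a sequence/quality length mismatch) raise a
#' parse error naming the offending line.
#'
#' @param line A single SAM line (no trailing newline).
#' @param line_num Line number used in error messages.
#' @return One-row tibble with columns `qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `mrnm`, `mpos`, `tlen`, `seq`, `qual`, `tags`.
#' @export
#' @examples
#' parse_sam_record("r1\t69\tchr1\t0\t0\t*\t=\t100\t0\tACGT\tFFFF")
parse_sam_record <- function(line, line_num = 1L) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 11) {
    vl_abort(sprintf("SAM line %d has %d fields; 11 required",
                     line_num, length(f)), "viralint_parse_error")
  }
  rec <- tibble(
    qname = f[1], flag = suppressWarnings(as.integer(f[2])),
    rname = f[3], pos = suppressWarnings(as.integer(f[4])),
    mapq = suppressWarnings(as.integer(f[5])), cigar = f[6],
    mrnm = f[7], mpos = suppressWarnings(as.integer(f[8])),
    tlen = suppressWarnings(as.integer(f[9])),
    seq = f[10], qual = f[11],
    tags = if (length(f) > 11) paste(f[-(1:11)], collapse = "\t") else ""
  )
  validate_sam(rec, line_num)
  rec
}

validate_sam <- function(rec, line_nums = seq_len(nrow(rec))) {
  bad <- which(is.na(rec$flag) | is.na(rec$pos) | is.na(rec$mpos) |
                 is.na(rec$mapq) | is.na(rec$tlen))
  if (length(bad)) {
    vl_abort(sprintf("SAM line %d: non-numeric flag/pos/mapq/mpos/tlen",
                     line_nums[bad[1]]), "viralint_parse_error")
  }
  bad <- which(!cigar_is_valid(rec$cigar))
  if (length(bad)) {
    vl_abort(sprintf("SAM line %d: malformed CIGAR '%s'",
                     line_nums[bad[1]], rec$cigar[bad[1]]),
             "viralint_parse_error")
  }
  both <- rec$seq != "*" & rec$qual != "*"
  bad <- which(both & nchar(rec$seq) != nchar(rec$qual))
  if (length(bad)) {
    vl_abort(sprintf("SAM line %d: seq and qual lengths differ",
                     line_nums[bad[1]]), "viralint_parse_error")
  }
  mapped <- bitwAnd(rec$flag, 4L) == 0L & rec$cigar != "*" & rec$seq != "*"
  bad <- which(mapped & cigar_query_len(rec$cigar) != nchar(rec$seq))
  if (length(bad)) {
    vl_abort(sprintf(
      "SAM line %d: CIGAR query length %d != sequence length %d",
      line_nums[bad[1]], cigar_query_len(rec$cigar[bad[1]]),
      nchar(rec$seq[bad[1]])), "viralint_parse_error")
  }
  invisible(rec)
}

#' Read a SAM file into a tibble
#'
#' Reads a plain-text SAM file (header lines are retained as the `"header"`
#' attribute) and validates every record. Mate reference names of `"="` are
#' kept verbatim in `mrnm`; use [mate_rname()] for the resolved name.
#'
#' @param path Path to a SAM file.
#' @return Tibble with one row per alignment record (columns as in
#'   [parse_sam_record()]), plus a `"header"` attribute holding header lines.
#' @export
read_sam <- function(path) {
  lines <- readr::read_lines(path)
  hdr <- lines[startsWith(lines, "@")]
  body_idx <- which(!startsWith(lines, "@") & nzchar(lines))
  if (length(body_idx) == 0) {
    out <- tibble(qname = character(), flag = integer(), rname = character(),
                  pos = integer(), mapq = integer(), cigar = character(),
                  mrnm = character(), mpos = integer(), tlen = integer(),
                  seq = character(), qual = character(), tags = character())
    attr(out, "header") <- hdr
    return(out)
  }
  parts <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11)) {
    i <- which(nf < 11)[1]
    vl_abort(sprintf("SAM line %d has %d fields; 11 required",
                     body_idx[i], nf[i]), "viralint_parse_error")
  }
  get <- function(k) vapply(parts, `[[`, character(1), k)
  out <- tibble(
    qname = get(1), flag = as.integer(get(2)), rname = get(3),
    pos = as.integer(get(4)), mapq = as.integer(get(5)), cigar = get(6),
    mrnm = get(7), mpos = as.integer(get(8)), tlen = as.integer(get(9)),
    seq = get(10), qual = get(11),
    tags = vapply(parts, function(p) {
      if (length(p) > 11) paste(p[-(1:11)], collapse = "\t") else ""
    }, character(1))
  )
  validate_sam(out, body_idx)
  attr(out, "header") <- hdr
  out
}

#' Write SAM records
#'
#' Inverse of [read_sam()]: emits the stored header attribute (if any)
#' followed by the records. For records produced by the reader the mandatory
#' fields round-trip byte-identically.
#'
#' @param records Tibble of SAM records.
#' @param path Output path.
#' @param header Optional character vector of header lines; defaults to the
#'   records' `"header"` attribute.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, path, header = attr(records, "header")) {
  body <- paste(records$qname, records$flag, records$rname, records$pos,
                records$mapq, records$cigar, records$mrnm, records$mpos,
                records$tlen, records$seq, records$qual, sep = "\t")
  extra <- records$tags
  if (!is.null(extra)) {
    has <- nzchar(extra)
    body[has] <- paste(body[has], extra[has], sep = "\t")
  }
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Resolved mate reference name
#'
#' Expands the SAM `"="` shorthand to the record's own reference name.
#'
#' @param records Tibble of SAM records.
#' @return Character vector of mate reference names.
#' @export
mate_rname <- function(records) {
  ifelse(records$mrnm == "=", records$rname, records$mrnm)
}
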