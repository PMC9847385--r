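# FASTA/FASTQ I/O, backed by Biostrings for the heavy lifting.

#' Read a FASTA file
#'
#' Wraps `Biostrings::readDNAStringSet()` and enforces the panel contract:
#' sequences are folded to upper case, record ids (first whitespace token of
#' the header) must be unique and non-empty, and empty files or empty
#' sequences are format errors.
#'
#' @param path Path to a FASTA file.
#' @return Tibble with columns `id`, `description`, `seq`.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e) {
                    vl_abort(paste0("cannot read FASTA '", path, "': ",
                                    conditionMessage(e)),
                             "viralint_format_error")
                  })
  if (length(set) == 0) {
    vl_abort(paste0("FASTA file '", path, "' contains no records"),
             "viralint_format_error")
  }
  hdr <- names(set)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0)) {
    vl_abort(sprintf("FASTA record '%s' has an empty sequence",
                     id[which(nchar(seqs) == 0)[1]]),
             "viralint_format_error")
  }
  if (anyDuplicated(id)) {
    vl_abort(sprintf("duplicate FASTA id '%s'", id[duplicated(id)][1]),
             "viralint_format_error")
  }
  tibble(id = unname(id), description = unname(desc), seq = unname(seqs))
}

#' Write a FASTA file
#'
#' @param records Tibble with columns `id`, `seq` (and optionally
#'   `description`).
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  hdr <- records$id
  if ("description" %in% names(records)) {
    has <- nzchar(records$description)
    hdr[has] <- paste(hdr[has], records$description[has])
  }
  set <- Biostrings::DNAStringSet(records$seq)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a 4-line FASTQ file
#'
#' @param path Path to a FASTQ file (uncompressed or gzip).
#' @return Tibble with columns `id`, `seq`, `qual` (Phred+33 string).
#' @export
read_fastq <- function(path) {
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) {
      vl_abort(paste0("cannot read FASTQ '", path, "': ",
                      conditionMessage(e)), "viralint_format_error")
    })
  if (length(set) == 0) {
    vl_abort(paste0("FASTQ file '", path, "' contains no records"),
             "viralint_format_error")
  }
  tibble(
    id = unname(sub("\\s.*$", "", names(set))),
    seq = unname(toupper(as.character(set))),
    qual = unname(as.character(S4Vectors::mcols(set)$qualities))
  )
}

#' Write a 4-line FASTQ file
#'
#' @param records Tibble with columns `id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  lines <- as.vector(rbind(paste0("@", records$id), records$seq,
                           "+", records$qual))
  readr::write_lines(lines, path)
  invisible(path)
}
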