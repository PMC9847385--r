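# Shared fixture builders: everything is generated in code at test time.

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# one SAM body line from named fields
sam_line <- function(qname = "r1", flag = 0L, rname = "chr1", pos = 1L,
                     mapq = 60L, cigar = "*", mrnm = "*", mpos = 0L,
                     tlen = 0L, seq = "*", qual = "*") {
  paste(qname, flag, rname, pos, mapq, cigar, mrnm, mpos, tlen, seq, qual,
        sep = "\t")
}

sam_tbl <- function(...) {
  lines <- c(...)
  p <- tempfile(fileext = ".sam")
  writeLines(lines, p)
  read_sam(p)
}

# a small fixed two-virus panel (seeded so every test sees the same panel)
tiny_panel <- function(len = 600) {
  withr::with_seed(1234, tibble::tibble(
    id = c("virusA", "virusB"),
    seq = c(random_dna(len), random_dna(len))
  ))
}

# independent brute-force trimming oracle: scan every window position, cut
# at the first failing window start, then keep individual passing bases
oracle_trim <- function(phred, window, mean_q) {
  n <- length(phred)
  w <- min(window, n)
  cut <- n
  for (p in seq_len(max(1, n - w + 1))) {
    if (mean(phred[p:(p + w - 1)]) < mean_q) {
      cut <- p
      while (cut <= n && phred[cut] >= mean_q) cut <- cut + 1
      cut <- cut - 1
      break
    }
  }
  cut
}

# full local alignment oracle via Biostrings (gap of length L costs
# gapOpening + L * gapExtension = 1 + L, i.e. -2 first base, -1 extension)
oracle_local_score <- function(q, r) {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(q, r, type = "local",
                                      substitutionMatrix = m,
                                      gapOpening = 1, gapExtension = 1)
  pa
}

# diagonal range (j - i) touched by the oracle's optimal local alignment
oracle_diag_range <- function(pa) {
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  i <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  j <- Biostrings::start(Biostrings::subject(pa)) - 1L
  diags <- integer(length(ap))
  for (k in seq_along(ap)) {
    if (ap[k] != "-") i <- i + 1L
    if (as_[k] != "-") j <- j + 1L
    diags[k] <- j - i
  }
  range(diags)
}
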