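# Sliding-window quality trimming. A read is scanned 5'->3' with a window
# of `window` bases (step 1; reads shorter than the window form a single
# window). At the first window whose mean Phred score falls below `mean_q`
# the cut point is placed at the window start, then advanced past any
# individual bases still at or above `mean_q` so the kept prefix ends where
# base quality actually drops. Reads whose surviving prefix is shorter than
# `min_len` are removed.

#' Trimming parameters
#'
#' @param window Window size in bases.
#' @param mean_q Mean Phred threshold for a window.
#' @param min_len Minimum surviving read length; shorter reads are removed.
#' @param offset Phred encoding offset of quality strings.
#' @return A `trim_params` list.
#' @export
trim_params <- function(window = 4L, mean_q = 30, min_len = 50L,
                        offset = 33L) {
  stopifnot(window >= 1, mean_q >= 0, min_len >= 1)
  structure(list(window = as.integer(window), mean_q = mean_q,
                 min_len = as.integer(min_len), offset = as.integer(offset)),
            class = "trim_params")
}

# core scan on an integer quality vector; returns kept prefix length
trim_cut_point <- function(phred, window, mean_q) {
  n <- length(phred)
  if (n == 0) return(0L)
  w <- min(window, n)
  cs <- cumsum(c(0, phred))
  starts <- seq_len(max(1L, n - w + 1L))
  means <- (cs[starts + w] - cs[starts]) / w
  first_bad <- which(means < mean_q)[1]
  if (is.na(first_bad)) return(n)
  cut <- first_bad
  while (cut <= n && phred[cut] >= mean_q) cut <- cut + 1L
  cut - 1L
}

#' Sliding-window quality trim of a single read
#'
#' @param seq Nucleotide string.
#' @param qual Phred quality string (same length as `seq`) or an integer
#'   vector of scores.
#' @param params A [trim_params()] object.
#' @return A list with `seq`, `qual`, `removed` (logical) and `kept`
#'   (surviving prefix length). Removed reads have empty `seq`/`qual`.
#' @export
#' @examples
#' p <- trim_params(window = 4, mean_q = 30, min_len = 50)
#' sliding_window_trim(strrep("A", 60), strrep("I", 60), p)
sliding_window_trim <- function(seq, qual, params = trim_params()) {
  phred <- if (is.character(qual)) qual_to_phred(qual, params$offset) else
    as.integer(qual)
  if (nchar(seq) != length(phred)) {
    vl_abort("sequence and quality lengths differ", "viralint_input_error")
  }
  kept <- trim_cut_point(phred, params$window, params$mean_q)
  if (kept < params$min_len) {
    return(list(seq = "", qual = "", removed = TRUE, kept = 0L))
  }
  list(seq = substr(seq, 1L, kept),
       qual = if (is.character(qual)) substr(qual, 1L, kept) else
         phred_to_qual(phred[seq_len(kept)], params$offset),
       removed = FALSE, kept = kept)
}

#' Quality-trim a table of reads
#'
#' Vectorised [sliding_window_trim()] over a reads tibble.
#'
#' @param reads Tibble with columns `id`, `seq`, `qual`.
#' @param params A [trim_params()] object.
#' @return The input tibble with trimmed `seq`/`qual` and a logical
#'   `removed` column (removed reads are retained as rows so that mate
#'   pairing can be resolved by the caller).
#' @export
trim_reads <- function(reads, params = trim_params()) {
  res <- map2(reads$seq, reads$qual,
              function(s, q) sliding_window_trim(s, q, params))
  reads |>
    mutate(seq = map_chr(res, "seq"),
           qual = map_chr(res, "qual"),
           removed = map_lgl(res, "removed"))
}

#' Quality-trim a read pair (two FASTQ files)
#'
#' Applies [trim_reads()] to both mates. By default a pair is dropped when
#' either mate is removed; `keep_orphans = TRUE` instead keeps the surviving
#' mate (orphans are returned in a third table).
#'
#' @param r1,r2 Tibbles of reads (columns `id`, `seq`, `qual`), in matching
#'   order.
#' @param params A [trim_params()] object.
#' @param keep_orphans Keep single survivors of a pair?
#' @return List with tibbles `r1`, `r2` (surviving pairs, same order) and
#'   `orphans`.
#' @export
trim_read_pairs <- function(r1, r2, params = trim_params(),
                            keep_orphans = FALSE) {
  if (nrow(r1) != nrow(r2)) {
    vl_abort("mate files differ in read count", "viralint_input_error")
  }
  t1 <- trim_reads(r1, params)
  t2 <- trim_reads(r2, params)
  both <- !t1$removed & !t2$removed
  orphans <- if (keep_orphans) {
    bind_rows(t1[!t1$removed & t2$removed, , drop = FALSE],
              t2[t1$removed & !t2$removed, , drop = FALSE]) |>
      select(-"removed")
  } else {
    t1[0, setdiff(names(t1), "removed"), drop = FALSE]
  }
  list(r1 = select(t1[both, , drop = FALSE], -"removed"),
       r2 = select(t2[both, , drop = FALSE], -"removed"),
       orphans = orphans)
}
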