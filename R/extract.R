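# Candidate extraction from a host alignment: single-mate-unmapped reads
# (the `samtools view -f 4 -F 264` population) and soft-clipped fragments
# whose clipped tails may derive from integrated viral sequence.

#' Single-mate-unmapped flag filter
#'
#' The integration-candidate read filter on SAM flag bits: the read itself
#' is unmapped (bit 0x4 set) while its mate is mapped and the record is
#' primary (bits 0x8, 0x100 clear; exclude mask 264). Vectorised.
#'
#' @param flag Integer vector of SAM flags.
#' @param include_flag Bits that must all be set (default 4).
#' @param exclude_flag Bits that must all be clear (default 264).
#' @return Logical vector.
#' @export
#' @examples
#' passes_single_mate_unmapped_filter(c(69L, 77L, 101L))
passes_single_mate_unmapped_filter <- function(flag, include_flag = 4L,
                                               exclude_flag = 264L) {
  bitwAnd(flag, include_flag) == include_flag &
    bitwAnd(flag, exclude_flag) == 0L
}

#' Extract unmapped reads with mapped mates
#'
#' Selects records passing [passes_single_mate_unmapped_filter()] and
#' resolves each read's mapped-mate anchor. When the mate's own record is
#' present in the alignment its reference end is computed from its CIGAR
#' (`mate_end_exact = TRUE`); otherwise `mate_end` falls back to `mate_pos`
#' and is flagged approximate. Mates with mapping quality below `min_mapq`
#' are discarded as ambiguous anchors.
#'
#' @param records Tibble of SAM records from [read_sam()].
#' @param min_mapq Minimum mate mapping quality (applied when the mate
#'   record is available).
#' @return Tibble with columns `qname`, `seq`, `qual`, `mate_chrom`,
#'   `mate_pos`, `mate_strand`, `mate_end`, `mate_end_exact`, `mate_mapq`.
#' @export
extract_candidates <- function(records, min_mapq = 20L) {
  cand <- records[passes_single_mate_unmapped_filter(records$flag), ,
                  drop = FALSE]
  if (nrow(cand) == 0) {
    return(tibble(qname = character(), seq = character(), qual = character(),
                  mate_chrom = character(), mate_pos = integer(),
                  mate_strand = character(), mate_end = integer(),
                  mate_end_exact = logical(), mate_mapq = integer()))
  }
  if (any(cand$mrnm == "*")) {
    vl_abort(paste0("record '", cand$qname[cand$mrnm == "*"][1],
                    "' passes the single-mate-unmapped filter but has no ",
                    "mate reference name"), "viralint_consistency_error")
  }
  # primary mapped records indexed by (qname, which-in-pair) to find mates
  mates <- records |>
    filter(bitwAnd(.data$flag, 4L) == 0L,
           bitwAnd(.data$flag, 0x900L) == 0L) |>
    mutate(in_pair = bitwAnd(.data$flag, 0x40L) > 0L) |>
    transmute(qname = .data$qname, mate_in_pair = .data$in_pair,
              m_pos = .data$pos,
              m_end = .data$pos + cigar_ref_span(.data$cigar) - 1L,
              m_mapq = .data$mapq) |>
    distinct(.data$qname, .data$mate_in_pair, .keep_all = TRUE)
  out <- cand |>
    mutate(in_pair = bitwAnd(.data$flag, 0x40L) > 0L,
           mate_in_pair = !.data$in_pair,
           mate_chrom = mate_rname(cand)) |>
    left_join(mates, by = c("qname", "mate_in_pair")) |>
    transmute(
      qname = .data$qname, seq = .data$seq, qual = .data$qual,
      mate_chrom = .data$mate_chrom,
      mate_pos = .data$mpos,
      mate_strand = if_else(bitwAnd(.data$flag, 0x20L) > 0L, "-", "+"),
      mate_end = coalesce(.data$m_end, .data$mpos),
      mate_end_exact = !is.na(.data$m_end),
      mate_mapq = .data$m_mapq
    )
  out |>
    filter(is.na(.data$mate_mapq) | .data$mate_mapq >= min_mapq) |>
    arrange(.data$qname)
}

#' Extract soft-clipped fragments
#'
#' Pulls clipped terminal subsequences from mapped primary alignments. A
#' leading soft clip of length `s >= min_clip_len` yields a `left` fragment
#' anchored at the first aligned base (`anchor_pos = pos`); a trailing clip
#' yields a `right` fragment anchored at the last aligned base
#' (`anchor_pos = pos + reference_span - 1`). A read clipped on both sides
#' yields two fragments. Secondary and supplementary records (flag 0x900)
#' and hard clips (no bases available) are skipped.
#'
#' @param records Tibble of SAM records.
#' @param min_clip_len Minimum clipped length to report.
#' @param min_mapq Minimum anchor mapping quality.
#' @return Tibble with columns `source_qname`, `anchor_chrom`, `anchor_pos`,
#'   `side`, `clipped_seq`, `clipped_qual`, `anchor_mapq`.
#' @export
extract_softclip_fragments <- function(records, min_clip_len = 20L,
                                       min_mapq = 20L) {
  mapped <- records |>
    filter(bitwAnd(.data$flag, 4L) == 0L,
           bitwAnd(.data$flag, 0x900L) == 0L,
           .data$cigar != "*", .data$mapq >= min_mapq)
  empty <- tibble(source_qname = character(), anchor_chrom = character(),
                  anchor_pos = integer(), side = character(),
                  clipped_seq = character(), clipped_qual = character(),
                  anchor_mapq = integer())
  if (nrow(mapped) == 0) return(empty)
  lcl <- cigar_clip_len(mapped$cigar, "left")
  rcl <- cigar_clip_len(mapped$cigar, "right")
  span <- cigar_ref_span(mapped$cigar)
  left <- mapped[lcl >= min_clip_len, , drop = FALSE]
  lclk <- lcl[lcl >= min_clip_len]
  right <- mapped[rcl >= min_clip_len, , drop = FALSE]
  rclk <- rcl[rcl >= min_clip_len]
  spank <- span[rcl >= min_clip_len]
  out <- bind_rows(
    if (nrow(left)) tibble(
      source_qname = left$qname, anchor_chrom = left$rname,
      anchor_pos = left$pos, side = "left",
      clipped_seq = str_sub(left$seq, 1L, lclk),
      clipped_qual = ifelse(left$qual == "*", NA_character_,
                            str_sub(left$qual, 1L, lclk)),
      anchor_mapq = left$mapq),
    if (nrow(right)) tibble(
      source_qname = right$qname, anchor_chrom = right$rname,
      anchor_pos = right$pos + spank - 1L, side = "right",
      clipped_seq = str_sub(right$seq, -rclk),
      clipped_qual = ifelse(right$qual == "*", NA_character_,
                            str_sub(right$qual, -rclk)),
      anchor_mapq = right$mapq)
  )
  if (nrow(out) == 0) return(empty)
  arrange(out, .data$anchor_chrom, .data$anchor_pos, .data$side,
          .data$source_qname)
}
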