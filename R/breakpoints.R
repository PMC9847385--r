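# Breakpoint calling: convert viral-aligned evidence into host-genome
# integration coordinates and cluster them per sample.
#
# Junction-base convention: a breakpoint is the host base adjacent to the
# first viral base. A left-clipped read reports its first aligned host base
# and a right-clipped read its last aligned host base, so on clean
# integrations the soft-clip breakpoint equals the junction exactly.

#' Breakpoints from soft-clip evidence
#'
#' Joins soft-clip fragments with their viral hits and emits one exact
#' breakpoint per fragment whose clip aligned to the panel. The viral
#' coordinate adjacent to the junction is `r_end` for a left clip aligning
#' forward and `r_start` for a right clip, mirrored on the minus strand.
#'
#' @param fragments Tibble from [extract_softclip_fragments()], with a
#'   `query_id` column identifying each fragment.
#' @param hits Hit table from [align_many()] on the clipped sequences.
#' @param min_mapq Minimum host-anchor mapping quality.
#' @param sample_id Sample label.
#' @return Breakpoint tibble: `sample_id`, `chrom`, `pos`, `virus_id`,
#'   `evidence`, `precision`, `support`, `virus_pos`, `virus_strand`,
#'   `source_qname`.
#' @export
breakpoints_from_softclips <- function(fragments, hits, min_mapq = 20L,
                                       sample_id = "sample") {
  empty <- empty_breakpoints()
  if (nrow(fragments) == 0 || nrow(hits) == 0) return(empty)
  joined <- inner_join(fragments, hits, by = "query_id") |>
    filter(.data$anchor_mapq >= min_mapq)
  if (nrow(joined) == 0) return(empty)
  joined |>
    transmute(
      sample_id = sample_id,
      chrom = .data$anchor_chrom,
      pos = .data$anchor_pos,
      virus_id = .data$virus_id,
      evidence = "softclip",
      orientation = if_else(.data$side == "right", "HV", "VH"),
      precision = "exact",
      support = 1L,
      virus_pos = case_when(
        .data$side == "left" & .data$strand == "+" ~ .data$r_end,
        .data$side == "right" & .data$strand == "+" ~ .data$r_start,
        .data$side == "left" & .data$strand == "-" ~ .data$r_start,
        TRUE ~ .data$r_end
      ),
      virus_strand = .data$strand,
      source_qname = .data$source_qname
    )
}

#' Breakpoints from discordant (single-mate-unmapped) evidence
#'
#' The unmapped, virally-aligned mate implies an integration just beyond
#' the mapped mate: one base past the mate's reference end when the mate
#' maps to the + strand (the virus lies 3' of the anchor), one base before
#' its start on the - strand. These breakpoints are approximate (the true
#' junction lies within an insert length). Positions that would fall off
#' the chromosome start are skipped with a warning.
#'
#' @param candidates Tibble from [extract_candidates()] with a `query_id`
#'   column.
#' @param hits Hit table from [align_many()] on the candidate reads.
#' @param sample_id Sample label.
#' @return Breakpoint tibble (see [breakpoints_from_softclips()]).
#' @export
breakpoints_from_discordant <- function(candidates, hits,
                                        sample_id = "sample") {
  empty <- empty_breakpoints()
  if (nrow(candidates) == 0 || nrow(hits) == 0) return(empty)
  joined <- inner_join(candidates, hits, by = "query_id")
  if (nrow(joined) == 0) return(empty)
  out <- joined |>
    transmute(
      sample_id = sample_id,
      chrom = .data$mate_chrom,
      pos = if_else(.data$mate_strand == "+",
                    .data$mate_end + 1L, .data$mate_pos - 1L),
      virus_id = .data$virus_id,
      evidence = "discordant",
      orientation = if_else(.data$mate_strand == "+", "HV", "VH"),
      precision = "approximate",
      support = 1L,
      virus_pos = NA_integer_,
      virus_strand = .data$strand,
      source_qname = .data$qname
    )
  off <- out$pos < 1L
  if (any(off)) {
    warn(sprintf("%d discordant breakpoint(s) fall before position 1; skipped",
                 sum(off)))
    out <- out[!off, , drop = FALSE]
  }
  out
}

empty_breakpoints <- function() {
  tibble(sample_id = character(), chrom = character(), pos = integer(),
         virus_id = character(), evidence = character(),
         orientation = character(), precision = character(),
         support = integer(),
         virus_pos = integer(), virus_strand = character(),
         source_qname = character())
}

#' Cluster per-read breakpoints
#'
#' Within each (sample, virus, chromosome): exact breakpoints are clustered
#' by single linkage with gap at most `cluster_window`; approximate
#' (discordant) breakpoints attach to the nearest exact cluster within
#' `max_insert`, and any left over form approximate-only clusters (single
#' linkage at `max_insert`, the scale of their positional uncertainty). The
#' representative position is the median of the exact members (lower of the
#' two middle values for even counts), or of all members when no exact
#' member exists.
#'
#' @param breakpoints Per-read breakpoint tibble.
#' @param cluster_window Maximum gap between exact members of one cluster.
#' @param max_insert Attachment radius for approximate breakpoints.
#' @return Tibble of class `breakpoint_clusters`: `sample_id`, `virus_id`,
#'   `chrom`, `pos` (representative), `support`, `n_exact`, `n_approx`,
#'   `evidence`, `precision`, `virus_pos` (most common among exact
#'   members), `members` (list column of member positions), ordered by
#'   (sample, chrom, pos).
#' @export
cluster_breakpoints <- function(breakpoints, cluster_window = 10L,
                                max_insert = 1000L) {
  lower_median <- function(x) sort(x)[(length(x) + 1L) %/% 2L]
  single_linkage <- function(pos, gap) {
    o <- order(pos)
    grp <- integer(length(pos))
    grp[o] <- cumsum(c(1L, as.integer(diff(pos[o]) > gap)))
    grp
  }
  one_group <- function(bp) {
    ex <- bp[bp$precision == "exact", , drop = FALSE]
    ap <- bp[bp$precision != "exact", , drop = FALSE]
    clusters <- list()
    if (nrow(ex) > 0) {
      ex$cl <- single_linkage(ex$pos, cluster_window)
      reps <- ex |>
        group_by(.data$cl) |>
        summarise(rep = lower_median(.data$pos), .groups = "drop")
      if (nrow(ap) > 0) {
        d <- abs(outer(ap$pos, reps$rep, "-"))
        nearest <- apply(d, 1L, which.min)
        attach_ok <- d[cbind(seq_len(nrow(ap)), nearest)] <= max_insert
        ap$cl <- ifelse(attach_ok, reps$cl[nearest], NA_integer_)
      }
    } else if (nrow(ap) > 0) {
      ap$cl <- NA_integer_
    }
    stray <- if (nrow(ap) > 0) ap[is.na(ap$cl), , drop = FALSE] else ap
    if (nrow(stray) > 0) {
      stray$cl <- max(c(0L, if (nrow(ex)) ex$cl)) +
        single_linkage(stray$pos, max_insert)
      ap <- bind_rows(ap[!is.na(ap$cl), , drop = FALSE], stray)
    }
    members <- bind_rows(if (nrow(ex)) ex, if (nrow(ap)) ap)
    members |>
      group_by(.data$cl) |>
      summarise(
        pos = {
          e <- .data$pos[.data$precision == "exact"]
          lower_median(if (length(e)) e else .data$pos)
        },
        support = sum(.data$support),
        n_exact = sum(.data$precision == "exact"),
        n_approx = sum(.data$precision != "exact"),
        evidence = {
          ev <- unique(.data$evidence)
          if (length(ev) > 1) "both" else ev
        },
        precision = if_else(any(.data$precision == "exact"),
                            "exact", "approximate"),
        virus_pos = {
          vp <- .data$virus_pos[.data$precision == "exact" &
                                  !is.na(.data$virus_pos)]
          if (length(vp)) as.integer(names(sort(table(vp),
                                                decreasing = TRUE))[1])
          else NA_integer_
        },
        members = list(sort(.data$pos)),
        .groups = "drop"
      ) |>
      select(-"cl")
  }
  if (nrow(breakpoints) == 0) {
    out <- tibble(sample_id = character(), virus_id = character(),
                  chrom = character(), orientation = character(),
                  pos = integer(), support = integer(),
                  n_exact = integer(), n_approx = integer(),
                  evidence = character(), precision = character(),
                  virus_pos = integer(), members = list())
  } else {
    out <- breakpoints |>
      arrange(.data$sample_id, .data$virus_id, .data$chrom, .data$pos) |>
      group_by(.data$sample_id, .data$virus_id, .data$chrom,
               .data$orientation) |>
      group_modify(~ one_group(.x)) |>
      ungroup() |>
      arrange(.data$sample_id, .data$chrom, .data$pos, .data$virus_id)
  }
  class(out) <- c("breakpoint_clusters", class(out))
  out
}
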