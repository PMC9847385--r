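# Viral panel search: a k-mer seed index over both strands and a banded
# local (Smith-Waterman-Gotoh) extension around the best seed chain.
# Scoring: match +1, mismatch -1, first gap base -2, gap extension -1.

#' Build a k-mer seed index over a viral panel
#'
#' Indexes every k-mer of every panel sequence on both strands (the minus
#' strand via the reverse complement). K-mers containing N are skipped.
#' Offsets are 1-based positions on the indexed strand; for minus-strand
#' entries the offset refers to the reverse-complemented sequence and is
#' converted back to forward coordinates during seeding.
#'
#' @param panel Tibble from [read_fasta()] (columns `id`, `seq`).
#' @param k Seed length.
#' @return A `kmer_index` object.
#' @export
build_kmer_index <- function(panel, k = 15L) {
  if (nrow(panel) == 0) {
    vl_abort("viral panel is empty", "viralint_input_error")
  }
  lens <- nchar(panel$seq)
  if (k > min(lens)) {
    vl_abort(sprintf("k = %d exceeds the shortest panel sequence (%d nt)",
                     k, min(lens)), "viralint_input_error")
  }
  one_strand <- function(seqs, strand) {
    res <- map(seq_along(seqs), function(i) {
      s <- seqs[[i]]
      n <- nchar(s) - k + 1L
      km <- substring(s, 1:n, k:(k + n - 1L))
      keep <- !grepl("N", km, fixed = TRUE)
      tibble(kmer = km[keep], vidx = i, offset = which(keep),
             strand = strand)
    })
    list_rbind(res)
  }
  entries <- bind_rows(one_strand(panel$seq, "+"),
                       one_strand(revcomp(panel$seq), "-"))
  index <- new.env(parent = emptyenv(), size = nrow(entries))
  spl <- split(seq_len(nrow(entries)), entries$kmer)
  for (km in names(spl)) {
    rows <- spl[[km]]
    assign(km, cbind(vidx = entries$vidx[rows],
                     offset = entries$offset[rows],
                     minus = as.integer(entries$strand[rows] == "-")),
           envir = index)
  }
  structure(list(env = index, k = as.integer(k),
                 virus_id = panel$id, virus_len = lens,
                 seq = setNames(panel$seq, panel$id)),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("<kmer_index> k=", x$k, ", ", length(x$virus_id),
      " sequences\n", sep = "")
  invisible(x)
}

# collect seed hits for one query: tibble(vidx, strand, diag, qpos)
# qpos/diag are in the coordinates of the strand-adjusted query (the query
# itself for "+", its reverse complement for "-")
seed_hits <- function(query, index) {
  k <- index$k
  n <- nchar(query) - k + 1L
  if (n < 1L) return(NULL)
  kms <- substring(query, 1:n, k:(k + n - 1L))
  found <- map(seq_len(n), function(i) {
    ent <- get0(kms[i], envir = index$env, inherits = FALSE)
    if (is.null(ent)) return(NULL)
    cbind(ent, qpos = i)
  })
  found <- found[!vapply(found, is.null, logical(1))]
  if (length(found) == 0) return(NULL)
  m <- do.call(rbind, found)
  lq <- nchar(query)
  # minus-strand entries: the indexed offset is on revcomp(reference) and
  # matches the query k-mer directly; equivalently revcomp(query) matches
  # the forward reference. Convert both coordinates to that frame.
  vl <- index$virus_len[m[, "vidx"]]
  fwd_off <- ifelse(m[, "minus"] == 1L,
                    vl - (m[, "offset"] + k - 1L) + 1L, m[, "offset"])
  qpos2 <- ifelse(m[, "minus"] == 1L,
                  lq - (m[, "qpos"] + k - 1L) + 1L, m[, "qpos"])
  tibble(vidx = m[, "vidx"],
         strand = ifelse(m[, "minus"] == 1L, "-", "+"),
         diag = fwd_off - qpos2, qpos = qpos2)
}

#' Align a query to the viral panel
#'
#' Seed-and-extend alignment: seed k-mer hits are grouped per (virus,
#' strand, diagonal), nearby diagonals are chained, and the best chains are
#' extended by banded local dynamic programming. The best hit is reported
#' only if its identity (matches over alignment columns) is at least
#' `min_identity` and it spans at least `min_aln_len` columns; otherwise a
#' zero-row table is returned. Ties are resolved by identity, then
#' lexicographically smallest virus id, then + strand.
#'
#' @param query Nucleotide string.
#' @param index A [build_kmer_index()] object.
#' @param band Half-width of the DP band around the seed diagonal.
#' @param min_identity Minimum identity to report a hit.
#' @param min_aln_len Minimum alignment length (columns) to report a hit.
#' @param max_chains Number of top seed chains to extend.
#' @param scoring Named list with `match`, `mismatch`, `gap_first`,
#'   `gap_extend`.
#' @return Tibble with 0 or 1 row: `virus_id`, `score`, `identity`,
#'   `q_start`, `q_end`, `r_start`, `r_end`, `strand` (query coordinates are
#'   on the original query orientation; reference coordinates are 1-based
#'   forward).
#' @export
align_to_panel <- function(query, index, band = 15L, min_identity = 0.90,
                           min_aln_len = 30L, max_chains = 3L,
                           scoring = list(match = 1L, mismatch = -1L,
                                          gap_first = -2L, gap_extend = -1L)) {
  no_hit <- tibble(virus_id = character(), score = integer(),
                   identity = numeric(), q_start = integer(),
                   q_end = integer(), r_start = integer(), r_end = integer(),
                   strand = character())
  hits <- seed_hits(query, index)
  if (is.null(hits) || nrow(hits) == 0) return(no_hit)
  lq <- nchar(query)
  qrc <- revcomp(query)
  # chain seeds: per (virus, strand), merge diagonals within `band`
  chains <- hits |>
    arrange(.data$vidx, .data$strand, .data$diag) |>
    group_by(.data$vidx, .data$strand) |>
    mutate(chain = cumsum(c(1L, as.integer(diff(.data$diag) > band)))) |>
    group_by(.data$vidx, .data$strand, .data$chain) |>
    summarise(n_seeds = n(), d_min = min(.data$diag), d_max = max(.data$diag),
              .groups = "drop") |>
    arrange(desc(.data$n_seeds), .data$vidx, .data$strand, .data$d_min) |>
    head(max_chains)
  best <- NULL
  for (i in seq_len(nrow(chains))) {
    ch <- chains[i, ]
    qseq <- if (ch$strand == "-") qrc else query
    rseq <- index$seq[[ch$vidx]]
    res <- banded_local_align(qseq, rseq,
                              d_lo = ch$d_min - band, d_hi = ch$d_max + band,
                              match = scoring$match,
                              mismatch = scoring$mismatch,
                              gap_first = scoring$gap_first,
                              gap_extend = scoring$gap_extend)
    if (res$score <= 0) next
    identity <- res$matches / res$columns
    if (identity < min_identity || res$columns < min_aln_len) next
    # map query span back to the original orientation
    qs <- res$q_start; qe <- res$q_end
    if (ch$strand == "-") {
      qs <- lq - res$q_end + 1L
      qe <- lq - res$q_start + 1L
    }
    cand <- list(virus_id = index$virus_id[ch$vidx], score = res$score,
                 identity = identity, q_start = qs, q_end = qe,
                 r_start = res$r_start, r_end = res$r_end,
                 strand = ch$strand)
    if (is.null(best) ||
        cand$score > best$score ||
        (cand$score == best$score && cand$identity > best$identity) ||
        (cand$score == best$score && cand$identity == best$identity &&
         cand$virus_id < best$virus_id) ||
        (cand$score == best$score && cand$identity == best$identity &&
         cand$virus_id == best$virus_id && cand$strand == "+" &&
         best$strand == "-")) {
      best <- cand
    }
  }
  if (is.null(best)) return(no_hit)
  as_tibble(best)
}

#' Align many queries to the panel
#'
#' @param queries Tibble with columns `query_id`, `seq`.
#' @param index A [build_kmer_index()] object.
#' @param ... Passed to [align_to_panel()].
#' @return Hit table (one row per query with a reported hit) with a
#'   `query_id` column prepended.
#' @export
align_many <- function(queries, index, ...) {
  if (nrow(queries) == 0) {
    return(tibble(query_id = character(), virus_id = character(),
                  score = integer(), identity = numeric(),
                  q_start = integer(), q_end = integer(),
                  r_start = integer(), r_end = integer(),
                  strand = character()))
  }
  res <- map(seq_len(nrow(queries)), function(i) {
    h <- align_to_panel(queries$seq[i], index, ...)
    if (nrow(h) == 0) return(NULL)
    bind_cols(tibble(query_id = queries$query_id[i]), h)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0) {
    return(tibble(query_id = character(), virus_id = character(),
                  score = integer(), identity = numeric(),
                  q_start = integer(), q_end = integer(),
                  r_start = integer(), r_end = integer(),
                  strand = character()))
  }
  list_rbind(res)
}

#' Per-virus read counting and screening cutoff
#'
#' Assigns every candidate read and soft-clip fragment to its best panel
#' virus and screens viruses by read count: only viruses supported by at
#' least `min_virus_reads` assigned reads in the sample are retained for
#' breakpoint calling (the screening cutoff applied at sample level).
#'
#' @param candidate_hits,fragment_hits Hit tables from [align_many()] for
#'   unmapped candidate reads and soft-clip fragments.
#' @param min_virus_reads Retention cutoff (closed bound: a virus with
#'   exactly `min_virus_reads` assigned reads is retained).
#' @param sample_id Sample label carried into the result.
#' @return A tibble of class `viral_screen`: `sample_id`, `virus_id`,
#'   `read_count`, `retained`, sorted by count descending.
#' @export
screen_sample <- function(candidate_hits, fragment_hits = NULL,
                          min_virus_reads = 1000L, sample_id = "sample") {
  hits <- bind_rows(candidate_hits, fragment_hits)
  if (nrow(hits) == 0) {
    out <- tibble(sample_id = character(), virus_id = character(),
                  read_count = integer(), retained = logical())
  } else {
    out <- hits |>
      count(.data$virus_id, name = "read_count") |>
      mutate(sample_id = sample_id,
             retained = .data$read_count >= min_virus_reads) |>
      select("sample_id", "virus_id", "read_count", "retained") |>
      arrange(desc(.data$read_count), .data$virus_id)
  }
  class(out) <- c("viral_screen", class(out))
  out
}
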