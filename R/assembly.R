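# Fixed-k de Bruijn graph assembly of viral reads, with canonical k-mers
# (each k-mer stored as min(kmer, revcomp)) and unitig-only contig
# extraction: maximal non-branching paths, no bubble popping or
# scaffolding. Adequate for desk-scale viral genomes.

#' Build a de Bruijn graph from reads
#'
#' Counts canonical k-mers (reads are strandless, so each k-mer and its
#' reverse complement are one object) and prunes k-mers seen fewer than
#' `min_kmer_count` times, which suppresses sequencing-error branches.
#' Reads shorter than `k` are skipped; reads containing N are split at the
#' N runs first.
#'
#' @param reads Character vector of read sequences.
#' @param k K-mer size.
#' @param min_kmer_count Minimum multiplicity for a k-mer to survive.
#' @return A `dbg` object: list with `k` and a tibble `kmers` (canonical
#'   `kmer`, `count`). Empty input yields an empty graph, not an error.
#' @export
build_dbg <- function(reads, k = 33L, min_kmer_count = 2L) {
  k <- as.integer(k)
  pieces <- unlist(strsplit(toupper(reads), "N+"), use.names = FALSE)
  pieces <- pieces[nchar(pieces) >= k]
  if (length(pieces) == 0) {
    return(structure(list(k = k, kmers = tibble(kmer = character(),
                                                count = integer())),
                     class = "dbg"))
  }
  kms <- unlist(map(pieces, function(s) {
    n <- nchar(s) - k + 1L
    substring(s, 1:n, k:(k + n - 1L))
  }), use.names = FALSE)
  rc <- revcomp(kms)
  canon <- ifelse(kms <= rc, kms, rc)
  tab <- tibble(kmer = canon) |>
    count(.data$kmer, name = "count") |>
    filter(.data$count >= min_kmer_count)
  structure(list(k = k, kmers = tab), class = "dbg")
}

#' @export
print.dbg <- function(x, ...) {
  cat("<dbg> k=", x$k, ", ", nrow(x$kmers), " canonical k-mers\n", sep = "")
  invisible(x)
}

#' Extract unitig contigs from a de Bruijn graph
#'
#' Emits maximal non-branching paths over (k-1)-mer nodes. Each underlying
#' canonical k-mer is traversed once; contig sequences are canonicalized
#' (the lexicographically smaller of the sequence and its reverse
#' complement) and contigs shorter than `2k` are dropped. Output is ordered
#' by length descending, ties by sequence.
#'
#' @param graph A [build_dbg()] object.
#' @param min_contig_len Minimum contig length (default `2 * k`).
#' @return Tibble with columns `contig_id`, `seq`, `length`,
#'   `n_reads_supporting` (the minimum k-mer multiplicity along the path, a
#'   conservative support estimate).
#' @export
assemble_contigs <- function(graph, min_contig_len = 2L * graph$k) {
  empty <- tibble(contig_id = character(), seq = character(),
                  length = integer(), n_reads_supporting = integer())
  if (nrow(graph$kmers) == 0) return(empty)
  k <- graph$k
  canon <- graph$kmers$kmer
  counts <- setNames(graph$kmers$count, canon)
  rc <- revcomp(canon)
  oriented <- unique(c(canon, rc))          # both orientations of each edge
  from <- substr(oriented, 1L, k - 1L)
  to <- substr(oriented, 2L, k)
  # node degrees over distinct oriented edges
  out_deg <- table(from)
  in_deg <- table(to)
  odeg <- function(n) { v <- out_deg[n]; ifelse(is.na(v), 0L, as.integer(v)) }
  ideg <- function(n) { v <- in_deg[n]; ifelse(is.na(v), 0L, as.integer(v)) }
  next_edge <- split(seq_along(oriented), from)
  canon_of <- function(e) { km <- oriented[e]; r <- revcomp(km)
    if (km <= r) km else r }
  used <- new.env(parent = emptyenv())
  mark_used <- function(e) {
    km <- oriented[e]
    assign(km, TRUE, envir = used)
    assign(revcomp(km), TRUE, envir = used)
  }
  is_used <- function(e) !is.null(get0(oriented[e], envir = used,
                                       inherits = FALSE))
  walk <- function(e0) {
    path <- e0
    mark_used(e0)
    repeat {
      v <- to[path[length(path)]]
      if (odeg(v) != 1L || ideg(v) != 1L) break
      nxt <- next_edge[[v]]
      if (is.null(nxt) || length(nxt) != 1L) break
      if (is_used(nxt)) break
      path <- c(path, nxt)
      mark_used(nxt)
    }
    path
  }
  emit <- function(path) {
    seq <- paste0(from[path[1]],
                  paste(substr(oriented[path], k, k), collapse = ""))
    sup <- min(counts[vapply(path, canon_of, character(1))])
    list(seq = seq, support = as.integer(sup))
  }
  contigs <- list()
  # pass 1: paths starting at branching nodes
  start_edges <- which(!(odeg(from) == 1L & ideg(from) == 1L))
  for (e in start_edges[order(oriented[start_edges])]) {
    if (is_used(e)) next
    contigs[[length(contigs) + 1L]] <- emit(walk(e))
  }
  # pass 2: remaining edges lie on simple cycles
  for (e in order(oriented)) {
    if (is_used(e)) next
    contigs[[length(contigs) + 1L]] <- emit(walk(e))
  }
  if (length(contigs) == 0) return(empty)
  seqs <- vapply(contigs, `[[`, character(1), "seq")
  rcs <- revcomp(seqs)
  seqs <- ifelse(seqs <= rcs, seqs, rcs)
  out <- tibble(seq = seqs,
                length = nchar(seqs),
                n_reads_supporting = vapply(contigs, `[[`, integer(1),
                                            "support")) |>
    distinct(.data$seq, .keep_all = TRUE) |>
    filter(.data$length >= min_contig_len) |>
    arrange(desc(.data$length), .data$seq) |>
    mutate(contig_id = sprintf("contig_%04d", row_number()),
           .before = 1)
  out
}

#' Viral genome completeness of assembled contigs
#'
#' Assigns each contig to its best panel virus with [align_to_panel()] and
#' reports, per virus, the longest assigned contig as a percentage of the
#' viral genome length (capped at 100). A virus passes the completeness
#' screen only when this percentage strictly exceeds
#' `min_completeness_pct`. Contigs with no panel hit are excluded.
#'
#' @param contigs Tibble from [assemble_contigs()].
#' @param panel Viral panel tibble (columns `id`, `seq`).
#' @param index Optional prebuilt [build_kmer_index()] for `panel`.
#' @param min_completeness_pct Strict retention bound, in percent.
#' @param sample_id Sample label.
#' @param viruses Viruses to report (defaults to every virus with an
#'   assigned contig; screened viruses without contigs report 0).
#' @return Tibble: `sample_id`, `virus_id`, `genome_length`,
#'   `longest_contig_length`, `completeness_pct`, `retained`.
#' @export
completeness <- function(contigs, panel, index = NULL,
                         min_completeness_pct = 5, sample_id = "sample",
                         viruses = NULL) {
  if (is.null(index)) index <- build_kmer_index(panel)
  glen <- setNames(nchar(panel$seq), panel$id)
  hits <- align_many(
    tibble(query_id = contigs[["contig_id"]] %||% character(),
           seq = contigs[["seq"]] %||% character()),
    index)
  assigned <- if (nrow(hits) == 0) {
    tibble(virus_id = character(), longest_contig_length = integer())
  } else {
    hits |>
      left_join(tibble(query_id = contigs$contig_id,
                       contig_len = contigs$length),
                by = "query_id") |>
      group_by(virus_id = .data$virus_id) |>
      summarise(longest_contig_length = max(.data$contig_len),
                .groups = "drop")
  }
  if (!is.null(viruses)) {
    assigned <- tibble(virus_id = viruses) |>
      left_join(assigned, by = "virus_id") |>
      mutate(longest_contig_length =
               coalesce(.data$longest_contig_length, 0L))
  }
  assigned |>
    mutate(sample_id = sample_id,
           genome_length = unname(glen[.data$virus_id]),
           completeness_pct = 100 *
             pmin(.data$longest_contig_length, .data$genome_length) /
             .data$genome_length,
           retained = .data$completeness_pct > min_completeness_pct) |>
    select("sample_id", "virus_id", "genome_length",
           "longest_contig_length", "completeness_pct", "retained") |>
    arrange(desc(.data$completeness_pct), .data$virus_id)
}
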