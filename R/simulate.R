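# Synthetic-data generator: host genome, proviral insertions with a truth
# table, paired-end reads with a calibrated base-error model, truth
# alignments in host coordinates (junction-spanning reads soft-clipped,
# fully-viral reads unmapped), and synthetic annotation tracks. This is
# the test substrate for every other module: its defaults emulate a
# human-WGS integration study at desk scale (2x150 bp pairs, ~9.5 kb
# provirus, 30x coverage, 0.5% base error).

#' Simulation configuration
#'
#' @param seed RNG seed; every simulator output is deterministic under it.
#' @param host_length Host genome length (nt).
#' @param gc Host GC fraction.
#' @param n_insertions Number of proviral insertions to plant.
#' @param virus_length Length of the simulated provirus when no viral
#'   sequence is supplied (HERV-K provirus scale).
#' @param virus_gc GC fraction of the simulated provirus.
#' @param coverage Mean sequencing depth over the augmented genome.
#' @param read_len Read length (2 x `read_len` pairs).
#' @param insert_mean,insert_sd Fragment-size distribution (truncated below
#'   at `2 * read_len`).
#' @param error_rate Mean per-base substitution error rate.
#' @param fraction_partial Fraction of insertions that carry a partial
#'   provirus.
#' @param min_spacing Minimum distance between insertion sites.
#' @param end_margin Minimum distance of insertion sites from genome ends.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, host_length = 200000L, gc = 0.41,
                              n_insertions = 5L, virus_length = 9500L,
                              virus_gc = 0.45, coverage = 30,
                              read_len = 150L, insert_mean = 400,
                              insert_sd = 60, error_rate = 0.005,
                              fraction_partial = 0.4,
                              min_spacing = 2000L, end_margin = 1000L) {
  stopifnot(coverage > 0, error_rate >= 0, error_rate < 0.1,
            read_len >= 50, host_length >= 10 * read_len,
            insert_mean >= 2 * read_len)
  structure(list(seed = as.integer(seed),
                 host_length = as.integer(host_length), gc = gc,
                 n_insertions = as.integer(n_insertions),
                 virus_length = as.integer(virus_length),
                 virus_gc = virus_gc, coverage = coverage,
                 read_len = as.integer(read_len),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 error_rate = error_rate,
                 fraction_partial = fraction_partial,
                 min_spacing = as.integer(min_spacing),
                 end_margin = as.integer(end_margin)),
            class = "simulation_config")
}

#' Simulate a random genome sequence
#'
#' I.i.d. bases at the requested GC content. Uses the current RNG state;
#' seed via `set.seed()` or [simulate_dataset()].
#'
#' @param length Sequence length.
#' @param gc GC fraction.
#' @param id Sequence id.
#' @return Tibble with columns `id`, `seq`.
#' @export
simulate_host <- function(length, gc = 0.41, id = "chr1") {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                      prob = p), collapse = "")
  tibble(id = id, seq = seq)
}

#' Plant proviral insertions into a host genome
#'
#' Splices full- or partial-length proviruses (random orientation per
#' event) into a host sequence at rejection-sampled sites at least
#' `min_spacing` apart and `end_margin` from the ends. Insertions are clean
#' (no target-site duplication): in pre-insertion host coordinates the left
#' junction is the last host base before the virus and the right junction
#' the first host base after it, so `right_junction == left_junction + 1`.
#'
#' @param host One-row tibble from [simulate_host()] (or `id`/`seq`).
#' @param virus One-row tibble with the proviral sequence.
#' @param config A [simulation_config()].
#' @return List with `genome` (augmented sequence tibble), `truth` (one row
#'   per insertion: junctions, virus span, strand, `full_length`) and
#'   `segments` (the augmented-to-source coordinate map).
#' @export
plant_integrations <- function(host, virus, config) {
  L <- nchar(host$seq)
  n <- config$n_insertions
  Lv <- nchar(virus$seq)
  usable <- L - 2L * config$end_margin
  if (n > 0 && usable < (n - 1L) * config$min_spacing + 1L) {
    vl_abort("host too short for the requested insertions under spacing
constraints", "viralint_input_error")
  }
  if (n == 0) {
    segs <- tibble(seg_type = "host", aug_start = 1L, aug_end = L,
                   src_start = 1L, src_end = L, strand = "+",
                   insertion_id = NA_character_)
    return(list(genome = tibble(id = host$id, seq = host$seq),
                truth = empty_truth(), segments = segs))
  }
  sites <- NULL
  for (try in 1:1000) {
    cand <- sort(sample(seq(config$end_margin + 1L, L - config$end_margin),
                        n))
    if (n == 1 || all(diff(cand) >= config$min_spacing)) {
      sites <- cand
      break
    }
  }
  if (is.null(sites)) {
    vl_abort("could not place insertion sites under spacing constraints",
             "viralint_input_error")
  }
  n_partial <- round(n * config$fraction_partial)
  is_partial <- seq_len(n) %in% sample(n, n_partial)
  ins <- map(seq_len(n), function(i) {
    if (is_partial[i]) {
      len <- round(runif(1, min(1000, Lv - 1), 0.7 * Lv))
      r_start <- sample.int(Lv - len + 1L, 1L)
      r_end <- r_start + len - 1L
    } else {
      r_start <- 1L
      r_end <- Lv
    }
    strand <- sample(c("+", "-"), 1L)
    piece <- substr(virus$seq, r_start, r_end)
    if (strand == "-") piece <- revcomp(piece)
    list(r_start = as.integer(r_start), r_end = as.integer(r_end),
         strand = strand, piece = piece)
  })
  truth <- tibble(
    insertion_id = sprintf("ins_%02d", seq_len(n)),
    host_chrom = host$id,
    left_junction = as.integer(sites),
    right_junction = as.integer(sites) + 1L,
    virus_id = virus$id,
    r_start = map_int(ins, "r_start"),
    r_end = map_int(ins, "r_end"),
    strand = map_chr(ins, "strand"),
    full_length = !is_partial
  )
  # build augmented sequence and the coordinate map
  host_bounds <- cbind(c(1L, sites + 1L), c(sites, L))
  pieces <- character(0)
  segs <- list()
  aug_at <- 1L
  for (i in seq_len(n + 1L)) {
    hs <- host_bounds[i, 1]; he <- host_bounds[i, 2]
    pieces <- c(pieces, substr(host$seq, hs, he))
    segs[[length(segs) + 1L]] <- tibble(
      seg_type = "host", aug_start = aug_at, aug_end = aug_at + (he - hs),
      src_start = hs, src_end = he, strand = "+",
      insertion_id = NA_character_)
    aug_at <- aug_at + (he - hs) + 1L
    if (i <= n) {
      piece <- ins[[i]]$piece
      pieces <- c(pieces, piece)
      segs[[length(segs) + 1L]] <- tibble(
        seg_type = "virus", aug_start = aug_at,
        aug_end = aug_at + nchar(piece) - 1L,
        src_start = ins[[i]]$r_start, src_end = ins[[i]]$r_end,
        strand = ins[[i]]$strand, insertion_id = truth$insertion_id[i])
      aug_at <- aug_at + nchar(piece)
    }
  }
  list(genome = tibble(id = host$id, seq = paste(pieces, collapse = "")),
       truth = truth, segments = list_rbind(segs))
}

empty_truth <- function() {
  tibble(insertion_id = character(), host_chrom = character(),
         left_junction = integer(), right_junction = integer(),
         virus_id = character(), r_start = integer(), r_end = integer(),
         strand = character(), full_length = logical())
}

# Base-call error model: a two-component quality mixture (Q38 / Q12)
# weighted so that the mean per-base error probability equals error_rate;
# errors are then drawn per base at its own quality. This keeps simulated
# FASTQ survivable by a Q30 sliding-window filter, as real HiSeq data is.
draw_qualities <- function(n_bases, error_rate) {
  q_hi <- 38L; q_lo <- 12L
  if (error_rate <= 0) return(rep(40L, n_bases))
  e_hi <- 10^(-q_hi / 10); e_lo <- 10^(-q_lo / 10)
  w <- (error_rate - e_hi) / (e_lo - e_hi)
  w <- min(max(w, 0), 1)
  ifelse(runif(n_bases) < w, q_lo, q_hi)
}

#' Simulate paired-end reads from a genome
#'
#' Fragments are drawn with Normal(insert_mean, insert_sd) lengths
#' (truncated at `2 * read_len`), uniform start positions and FR
#' orientation (which physical end becomes R1 is random). Per-base
#' qualities follow a two-level mixture calibrated to `error_rate`;
#' substitution errors are drawn per base at its own quality, so qualities
#' reflect the error model.
#'
#' @param genome One-row tibble (`id`, `seq`).
#' @param config A [simulation_config()].
#' @param n_pairs Number of pairs; default from coverage.
#' @return List with `r1`, `r2` (tibbles `id`, `seq`, `qual`) and `frags`
#'   (per-pair provenance: `pair_id`, `frag_start`, `frag_end`, `flip`).
#' @export
simulate_reads <- function(genome, config, n_pairs = NULL) {
  G <- nchar(genome$seq)
  rl <- config$read_len
  if (is.null(n_pairs)) {
    n_pairs <- round(config$coverage * G / (2 * rl))
  }
  frag <- pmin(G, pmax(2L * rl,
                       round(rnorm(n_pairs, config$insert_mean,
                                   config$insert_sd))))
  start <- floor(runif(n_pairs) * (G - frag + 1)) + 1L
  end <- start + frag - 1L
  flip <- runif(n_pairs) < 0.5
  left_fwd <- substring(genome$seq, start, start + rl - 1L)
  right_fwd <- substring(genome$seq, end - rl + 1L, end)
  right_rc <- revcomp(right_fwd)
  r1_seq <- ifelse(flip, right_rc, left_fwd)
  r2_seq <- ifelse(flip, left_fwd, right_rc)
  apply_errors <- function(seqs) {
    qs <- draw_qualities(length(seqs) * rl, config$error_rate)
    err <- runif(length(qs)) < 10^(-qs / 10)
    qmat <- matrix(qs, nrow = rl)
    if (any(err)) {
      pos <- which(err)
      read_i <- (pos - 1L) %/% rl + 1L
      base_i <- (pos - 1L) %% rl + 1L
      for (j in seq_along(pos)) {
        old <- substr(seqs[read_i[j]], base_i[j], base_i[j])
        new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
        substr(seqs[read_i[j]], base_i[j], base_i[j]) <- new
      }
    }
    quals <- vapply(seq_along(seqs), function(i) {
      phred_to_qual(qmat[, i])
    }, character(1))
    list(seq = seqs, qual = quals)
  }
  e1 <- apply_errors(r1_seq)
  e2 <- apply_errors(r2_seq)
  ids <- sprintf("sim_%06d", seq_len(n_pairs))
  list(
    r1 = tibble(id = ids, seq = e1$seq, qual = e1$qual),
    r2 = tibble(id = ids, seq = e2$seq, qual = e2$qual),
    frags = tibble(pair_id = ids, frag_start = start, frag_end = end,
                   flip = flip)
  )
}

#' Truth alignment of simulated reads against the host-only reference
#'
#' Maps each read by provenance, not by alignment: reads wholly within host
#' sequence are mapped with a full-match CIGAR; junction-spanning reads are
#' mapped on their host side with the viral side soft-clipped at the exact
#' junction; fully-viral reads are unmapped (with mapped-mate flags when
#' the mate is host-anchored, which is exactly the single-mate-unmapped
#' population the candidate filter extracts).
#'
#' @param reads Output of [simulate_reads()].
#' @param segments Coordinate map from [plant_integrations()].
#' @param host One-row host tibble (pre-insertion reference).
#' @param config A [simulation_config()].
#' @return SAM record tibble (with header attribute), ready for
#'   [write_sam()].
#' @export
emit_truth_alignment <- function(reads, segments, host, config) {
  rl <- config$read_len
  fr <- reads$frags
  n <- nrow(fr)
  # per-read genome intervals and orientations; the left fragment end is
  # genome-forward, the right end reverse-complemented
  read_tbl <- bind_rows(
    tibble(pair_id = fr$pair_id, which = 1L,
           s = ifelse(fr$flip, fr$frag_end - rl + 1L, fr$frag_start),
           rev = fr$flip,
           seq = reads$r1$seq, qual = reads$r1$qual),
    tibble(pair_id = fr$pair_id, which = 2L,
           s = ifelse(fr$flip, fr$frag_start, fr$frag_end - rl + 1L),
           rev = !fr$flip,
           seq = reads$r2$seq, qual = reads$r2$qual)
  ) |>
    mutate(e = .data$s + rl - 1L)
  segs <- segments
  si <- findInterval(read_tbl$s, segs$aug_start)
  spans <- read_tbl$e > segs$aug_end[si]
  t1 <- segs$seg_type[si]
  t2 <- ifelse(spans, segs$seg_type[pmin(si + 1L, nrow(segs))], t1)
  host_off <- function(aug_pos, seg_i) {
    segs$src_start[seg_i] + (aug_pos - segs$aug_start[seg_i])
  }
  pos <- integer(nrow(read_tbl)); cig <- character(nrow(read_tbl))
  mapped <- logical(nrow(read_tbl))
  # wholly host
  w <- !spans & t1 == "host"
  pos[w] <- host_off(read_tbl$s[w], si[w])
  cig[w] <- paste0(rl, "M")
  mapped[w] <- TRUE
  # host then virus: right side clipped
  w <- spans & t1 == "host" & t2 == "virus"
  m <- segs$aug_end[si[w]] - read_tbl$s[w] + 1L
  pos[w] <- host_off(read_tbl$s[w], si[w])
  cig[w] <- paste0(m, "M", rl - m, "S")
  mapped[w] <- TRUE
  # virus then host: left side clipped
  w <- spans & t1 == "virus" & t2 == "host"
  m <- read_tbl$e[w] - segs$aug_start[si[w] + 1L] + 1L
  pos[w] <- host_off(segs$aug_start[si[w] + 1L], si[w] + 1L)
  cig[w] <- paste0(rl - m, "S", m, "M")
  mapped[w] <- TRUE
  # assemble SAM fields pairwise
  read_tbl$mapped <- mapped
  read_tbl$pos <- pos
  read_tbl$cig <- cig
  r1 <- read_tbl[read_tbl$which == 1L, ]
  r2 <- read_tbl[read_tbl$which == 2L, ]
  mk <- function(self, mate, first) {
    flag <- 1L +
      (if (first) 64L else 128L) +
      ifelse(self$mapped, 0L, 4L) +
      ifelse(mate$mapped, 0L, 8L) +
      ifelse(self$mapped & self$rev, 16L, 0L) +
      ifelse(mate$mapped & mate$rev, 32L, 0L) +
      ifelse(self$mapped & mate$mapped, 2L, 0L)
    rname <- ifelse(self$mapped | mate$mapped, host$id, "*")
    posf <- ifelse(self$mapped, self$pos, ifelse(mate$mapped, mate$pos, 0L))
    span_self <- cigar_ref_span(self$cig)
    span_mate <- cigar_ref_span(mate$cig)
    tlen <- ifelse(
      self$mapped & mate$mapped,
      {
        lo <- pmin(self$pos, mate$pos)
        hi <- pmax(self$pos + span_self - 1L, mate$pos + span_mate - 1L)
        ifelse(self$pos <= mate$pos, hi - lo + 1L, -(hi - lo + 1L))
      }, 0L)
    # SEQ is reference-forward for mapped reverse-strand reads
    seq_out <- self$seq
    qual_out <- self$qual
    idx <- which(self$mapped & self$rev)
    if (length(idx)) {
      seq_out[idx] <- revcomp(seq_out[idx])
      qual_out[idx] <- as.character(
        Biostrings::reverse(Biostrings::BStringSet(qual_out[idx])))
    }
    tibble(
      qname = self$pair_id, flag = flag, rname = rname,
      pos = as.integer(posf), mapq = ifelse(self$mapped, 60L, 0L),
      cigar = ifelse(self$mapped, self$cig, "*"),
      mrnm = ifelse(mate$mapped | self$mapped, "=", "*"),
      mpos = as.integer(ifelse(mate$mapped, mate$pos,
                               ifelse(self$mapped, self$pos, 0L))),
      tlen = as.integer(tlen), seq = seq_out, qual = qual_out,
      tags = "")
  }
  out <- bind_rows(mk(r1, r2, TRUE), mk(r2, r1, FALSE)) |>
    arrange(.data$qname, .data$flag)
  attr(out, "header") <- c("@HD\tVN:1.6\tSO:unsorted",
                           paste0("@SQ\tSN:", host$id, "\tLN:",
                                  nchar(host$seq)))
  out
}

#' Simulate a complete integration dataset
#'
#' Runs the full generator under `config$seed`: host genome, provirus,
#' planted insertions, paired reads, truth alignment and the truth
#' breakpoint table. With `out_dir` set, writes host.fasta, virus.fasta,
#' genome_augmented.fasta, reads_R1/R2.fastq, truth.sam and
#' truth_breakpoints.tsv.
#'
#' @param config A [simulation_config()].
#' @param virus Optional viral sequence tibble (`id`, `seq`); simulated at
#'   `virus_length` when NULL.
#' @param out_dir Optional output directory.
#' @param sample_id Sample label used in the truth breakpoint table.
#' @return List: `config`, `host`, `virus`, `genome`, `truth`, `segments`,
#'   `reads`, `sam`, `truth_breakpoints`.
#' @export
simulate_dataset <- function(config = simulation_config(), virus = NULL,
                             out_dir = NULL, sample_id = "sim_sample") {
  set.seed(config$seed)
  host <- simulate_host(config$host_length, config$gc, id = "chr1")
  if (is.null(virus)) {
    virus <- simulate_host(config$virus_length, config$virus_gc,
                           id = "simvirus_1")
  }
  planted <- plant_integrations(host, virus, config)
  reads <- simulate_reads(planted$genome, config)
  sam <- emit_truth_alignment(reads, planted$segments, host, config)
  truth_bp <- planted$truth |>
    tidyr::pivot_longer(c("left_junction", "right_junction"),
                        names_to = "junction", values_to = "pos") |>
    transmute(sample_id = sample_id, chrom = .data$host_chrom,
              pos = .data$pos,
              orientation = if_else(.data$junction == "left_junction",
                                    "HV", "VH"),
              virus_id = .data$virus_id,
              insertion_id = .data$insertion_id)
  out <- list(config = config, host = host, virus = virus,
              genome = planted$genome, truth = planted$truth,
              segments = planted$segments, reads = reads, sam = sam,
              truth_breakpoints = truth_bp)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(host, file.path(out_dir, "host.fasta"))
    write_fasta(virus, file.path(out_dir, "virus.fasta"))
    write_fasta(planted$genome |> mutate(id = paste0(.data$id, "_augmented")),
                file.path(out_dir, "genome_augmented.fasta"))
    write_fastq(reads$r1, file.path(out_dir, "reads_R1.fastq"))
    write_fastq(reads$r2, file.path(out_dir, "reads_R2.fastq"))
    write_sam(sam, file.path(out_dir, "truth.sam"))
    readr::write_tsv(truth_bp, file.path(out_dir, "truth_breakpoints.tsv"))
  }
  out
}

#' Synthetic annotation tracks with known junction context
#'
#' Places a synthetic gene/repeat/DNase context around each insertion (both
#' junctions of a clean insertion are adjacent, so they share one planted
#' context), cycling through a fixed palette of region classes, repeat
#' classes and DNase states. The expected annotation of every junction is
#' returned alongside the tracks, which makes annotation results checkable
#' against construction. Contexts require insertions at least 3 kb apart so
#' that one junction's features (including implied promoter windows) cannot
#' reach another junction; closer spacing is a conflict error.
#'
#' @param truth Truth table from [plant_integrations()].
#' @param host One-row host tibble.
#' @param promoter_up,promoter_down Promoter window used for placement.
#' @return List: `genes` (GTF-style feature tibble), `repeats` and `dnase`
#'   (BED tibbles), `expected` (per-junction truth labels).
#' @export
simulate_tracks <- function(truth, host, promoter_up = 2000L,
                            promoter_down = 200L) {
  if (nrow(truth) == 0) {
    return(list(genes = tibble(), repeats = tibble(), dnase = tibble(),
                expected = tibble()))
  }
  sites <- sort(truth$left_junction)
  if (nrow(truth) > 1 && min(diff(sites)) < 3000) {
    vl_abort("insertions closer than 3 kb: synthetic track contexts would
overlap", "viralint_track_conflict")
  }
  palette <- tibble(
    region_class = c("promoter", "exon", "intron", "intergenic",
                     "five_prime_utr", "three_prime_utr", "intergenic",
                     "intron", "intergenic", "exon"),
    dnase = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE,
              TRUE),
    repeat_class = c("none", "none", "LTR", "LINE", "none", "SINE",
                     "Retroposon", "Simple_repeat", "none", "LTR"))
  chrom <- truth$host_chrom[1]
  genes <- list(); repeats <- list(); dnase <- list(); expected <- list()
  for (i in seq_len(nrow(truth))) {
    p <- truth$left_junction[i]
    ctx <- palette[(i - 1L) %% nrow(palette) + 1L, ]
    gname <- sprintf("SYNGENE%02d", i)
    gtype <- "none"; greg <- ctx$region_class
    if (ctx$region_class == "promoter") {
      gtype <- "lncRNA"
      genes[[length(genes) + 1L]] <- tibble(
        chrom = chrom, type = c("gene", "exon"),
        start = p + 800L, end = p + 1200L, strand = "+",
        gene_name = gname, gene_type = "lncRNA")
    } else if (ctx$region_class == "exon") {
      gtype <- "protein_coding"
      genes[[length(genes) + 1L]] <- tibble(
        chrom = chrom, type = c("gene", "exon", "CDS"),
        start = c(p - 300L, p - 100L, p - 100L),
        end = c(p + 300L, p + 101L, p + 101L), strand = "+",
        gene_name = gname, gene_type = "protein_coding")
    } else if (ctx$region_class == "intron") {
      gtype <- "protein_coding"
      genes[[length(genes) + 1L]] <- tibble(
        chrom = chrom, type = c("gene", "exon"),
        start = c(p - 500L, p - 500L), end = c(p + 500L, p - 400L),
        strand = "+", gene_name = gname, gene_type = "protein_coding")
    } else if (ctx$region_class == "five_prime_utr") {
      gtype <- "protein_coding"
      genes[[length(genes) + 1L]] <- tibble(
        chrom = chrom, type = c("gene", "exon", "CDS"),
        start = c(p - 300L, p - 300L, p + 300L),
        end = c(p + 800L, p + 800L, p + 700L), strand = "+",
        gene_name = gname, gene_type = "protein_coding")
    } else if (ctx$region_class == "three_prime_utr") {
      gtype <- "protein_coding"
      genes[[length(genes) + 1L]] <- tibble(
        chrom = chrom, type = c("gene", "exon", "CDS"),
        start = c(p - 800L, p - 800L, p - 700L),
        end = c(p + 300L, p + 300L, p - 300L), strand = "+",
        gene_name = gname, gene_type = "protein_coding")
    }
    if (ctx$repeat_class != "none") {
      sub <- c(LTR = "LTR/ERVK", LINE = "LINE/L1", SINE = "SINE/Alu",
               Retroposon = "Retroposon/SVA",
               Simple_repeat = "Simple_repeat")[[ctx$repeat_class]]
      repeats[[length(repeats) + 1L]] <- tibble(
        chrom = chrom, start = p - 51L, end = p + 51L, name = sub,
        score = 500, strand = "+")
    }
    if (ctx$dnase) {
      dnase[[length(dnase) + 1L]] <- tibble(
        chrom = chrom, start = p - 101L, end = p + 100L,
        name = sprintf("dnase_%02d", i), score = 1000, strand = ".")
    }
    expected[[length(expected) + 1L]] <- tibble(
      insertion_id = truth$insertion_id[i],
      pos = c(p, p + 1L),
      region_class = greg,
      gene_name = if (greg %in% c("intergenic")) NA_character_ else gname,
      gene_type = if (greg %in% c("intergenic")) "none" else gtype,
      dnase = ctx$dnase,
      repeat_class = ctx$repeat_class)
  }
  list(genes = list_rbind(genes), repeats = list_rbind(repeats),
       dnase = list_rbind(dnase), expected = list_rbind(expected))
}

#' Write synthetic tracks to BED / GTF files
#'
#' @param tracks Output of [simulate_tracks()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_tracks <- function(tracks, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bed_lines <- function(b) {
    paste(b$chrom, b$start, b$end, b$name, b$score, b$strand, sep = "\t")
  }
  readr::write_lines(if (nrow(tracks$dnase)) bed_lines(tracks$dnase)
                     else character(),
                     file.path(dir, "dnase.bed"))
  readr::write_lines(if (nrow(tracks$repeats)) bed_lines(tracks$repeats)
                     else character(),
                     file.path(dir, "repeats.bed"))
  g <- tracks$genes
  gtf <- if (nrow(g)) {
    paste(g$chrom, "viralint_sim", g$type, g$start, g$end, ".", g$strand,
          ".", sprintf('gene_name "%s"; gene_type "%s";', g$gene_name,
                       g$gene_type), sep = "\t")
  } else character()
  readr::write_lines(gtf, file.path(dir, "genes.gtf"))
  invisible(dir)
}
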