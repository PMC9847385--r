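# Breakpoint coordinate rules (derived by constructing chimeras by hand)
# and cluster behaviour.

# build a host/virus chimera read and the SAM record a host aligner would
# emit for it, returning the pieces for coordinate verification
make_chimera <- function(panel) {
  host <- withr::with_seed(61, random_dna(3000))
  list(host = host, virus = panel$seq[1])
}

test_that("soft-clip breakpoints use the junction-adjacency rule", {
  panel <- tiny_panel()
  ch <- make_chimera(panel)
  # left clip: virus bases 501..550 abut host starting at chr1:1001
  clip <- substr(ch$virus, 501, 550)
  readseq <- paste0(clip, substr(ch$host, 1001, 1100))
  recs <- sam_tbl(sam_line("L", 0L, "chr1", 1001L, 60L, "50S100M", "=", 0L,
                           0L, readseq, strrep("I", 150)))
  fr <- extract_softclip_fragments(recs) |>
    dplyr::mutate(query_id = "f1")
  hits <- align_many(tibble::tibble(query_id = "f1",
                                    seq = fr$clipped_seq),
                     build_kmer_index(panel))
  bp <- breakpoints_from_softclips(fr, hits, sample_id = "s")
  expect_equal(bp$pos, 1001L)
  expect_equal(bp$virus_id, "virusA")
  expect_equal(bp$precision, "exact")
  expect_equal(bp$orientation, "VH")
  expect_equal(bp$virus_pos, 550L)  # r_end adjacent to the junction

  # right clip, clip is the reverse complement of virus bases 1..50
  clip2 <- revcomp(substr(ch$virus, 1, 50))
  readseq2 <- paste0(substr(ch$host, 1001, 1100), clip2)
  recs2 <- sam_tbl(sam_line("R", 0L, "chr1", 1001L, 60L, "100M50S", "=", 0L,
                            0L, readseq2, strrep("I", 150)))
  fr2 <- extract_softclip_fragments(recs2) |>
    dplyr::mutate(query_id = "f2")
  hits2 <- align_many(tibble::tibble(query_id = "f2",
                                     seq = fr2$clipped_seq),
                      build_kmer_index(panel))
  bp2 <- breakpoints_from_softclips(fr2, hits2, sample_id = "s")
  expect_equal(bp2$pos, 1100L)
  expect_equal(bp2$virus_strand, "-")
  expect_equal(bp2$orientation, "HV")
  expect_equal(bp2$virus_pos, 50L)  # strand mirror of the r_start rule
})

test_that("weak clip alignments produce no breakpoint", {
  panel <- tiny_panel()
  idx <- build_kmer_index(panel)
  # clip at ~85% identity: below the 0.90 acceptance gate
  clip <- substr(panel$seq[1], 101, 160)
  cv <- strsplit(clip, "")[[1]]
  at <- seq(3, 57, by = 7)
  cv[at] <- c("A", "C", "G", "T")[(match(cv[at], c("C", "G", "T", "A")))]
  clip <- paste(cv, collapse = "")
  hits <- align_many(tibble::tibble(query_id = "f", seq = clip), idx)
  fr <- tibble::tibble(query_id = "f", source_qname = "x",
                       anchor_chrom = "chr1", anchor_pos = 500L,
                       side = "left", clipped_seq = clip,
                       clipped_qual = NA_character_, anchor_mapq = 60L)
  expect_equal(nrow(breakpoints_from_softclips(fr, hits)), 0L)
})

test_that("discordant breakpoints sit one base beyond the mapped mate", {
  cand <- tibble::tibble(
    query_id = c("a", "b", "c"), qname = c("a", "b", "c"),
    seq = "N", qual = "I",
    mate_chrom = "chr1", mate_pos = c(500L, 500L, 1L),
    mate_strand = c("+", "-", "-"),
    mate_end = c(599L, 599L, 1L), mate_end_exact = TRUE,
    mate_mapq = 60L)
  hits <- tibble::tibble(query_id = c("a", "b", "c"), virus_id = "v",
                         score = 50L, identity = 1,
                         q_start = 1L, q_end = 50L,
                         r_start = 1L, r_end = 50L, strand = "+")
  expect_warning(bp <- breakpoints_from_discordant(cand, hits),
                 "before position 1")
  expect_equal(nrow(bp), 2L)
  expect_equal(bp$pos[bp$source_qname == "a"], 600L)
  expect_equal(bp$pos[bp$source_qname == "b"], 499L)
  expect_true(all(bp$precision == "approximate"))
})

test_that("clustering merges within the window and attaches approximates", {
  mk <- function(pos, precision = "exact", orientation = "HV") {
    tibble::tibble(sample_id = "s", chrom = "chr1", pos = pos,
                   virus_id = "v", evidence = ifelse(precision == "exact",
                                                     "softclip",
                                                     "discordant"),
                   orientation = orientation, precision = precision,
                   support = 1L, virus_pos = NA_integer_,
                   virus_strand = "+", source_qname = as.character(pos))
  }
  cl <- cluster_breakpoints(mk(c(1100L, 1102L, 1103L)))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$pos, 1102L)  # median of three

  cl <- cluster_breakpoints(mk(c(1100L, 1200L)), cluster_window = 10)
  expect_equal(nrow(cl), 2L)

  bp <- dplyr::bind_rows(mk(c(1100L, 1102L, 1103L)),
                         mk(1500L, precision = "approximate"))
  cl <- cluster_breakpoints(bp, cluster_window = 10, max_insert = 1000)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$pos, 1102L)  # representative stays on the exact median
  expect_equal(cl$support, 4L)
  expect_equal(cl$evidence, "both")

  # an approximate far beyond max_insert forms its own cluster
  bp <- dplyr::bind_rows(mk(c(1100L, 1102L)),
                         mk(9000L, precision = "approximate"))
  cl <- cluster_breakpoints(bp, max_insert = 1000)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$precision, c("exact", "approximate"))
})

test_that("cluster supports account for every contributing read", {
  set.seed(65)
  pos <- sample(c(1000L, 1003L, 5000L, 5001L), 40, replace = TRUE)
  bp <- tibble::tibble(sample_id = "s", chrom = "chr1", pos = pos,
                       virus_id = "v", evidence = "softclip",
                       orientation = "HV", precision = "exact",
                       support = 1L, virus_pos = NA_integer_,
                       virus_strand = "+",
                       source_qname = as.character(seq_along(pos)))
  cl <- cluster_breakpoints(bp)
  expect_equal(sum(cl$support), nrow(bp))
})

test_that("calling is permutation-invariant and gates unretained viruses", {
  cfg <- simulation_config(seed = 7, host_length = 40000, n_insertions = 2,
                           virus_length = 2500, coverage = 15,
                           min_spacing = 5000, error_rate = 0)
  sim <- simulate_dataset(cfg)
  pcfg <- pipeline_config(screen = list(min_virus_reads = 5))
  res <- call_sample(sim$sam, sim$virus, pcfg, sample_id = "s")
  expect_gt(nrow(res$clusters), 0L)

  # shuffled record order produces the identical table
  set.seed(1)
  shuf <- sim$sam[sample(nrow(sim$sam)), ]
  attr(shuf, "header") <- attr(sim$sam, "header")
  res2 <- call_sample(shuf, sim$virus, pcfg, sample_id = "s")
  expect_equal(res2$clusters, res$clusters)

  # a read-count gate above the sample's viral support silences everything
  pcfg2 <- pipeline_config(screen = list(min_virus_reads = 100000))
  res3 <- call_sample(sim$sam, sim$virus, pcfg2, sample_id = "s")
  expect_false(any(res3$screen$retained))
  expect_equal(nrow(res3$clusters), 0L)
  expect_gt(sum(res3$screen$read_count), 0L)

  # an alignment with no candidate evidence yields an empty table
  host_only <- sim$sam[bitwAnd(sim$sam$flag, 4L) == 0L &
                         bitwAnd(sim$sam$flag, 8L) == 0L &
                         !grepl("S", sim$sam$cigar), ]
  attr(host_only, "header") <- attr(sim$sam, "header")
  res4 <- call_sample(host_only, sim$virus, pcfg, sample_id = "s")
  expect_equal(nrow(res4$clusters), 0L)
})
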