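# Generator invariants: determinism, splice arithmetic, read and truth-
# alignment construction.

test_that("simulation is fully deterministic under a seed", {
  cfg <- simulation_config(seed = 5, host_length = 20000, n_insertions = 1,
                           virus_length = 1500, coverage = 5,
                           min_spacing = 2000)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$genome$seq, s2$genome$seq)
  expect_identical(s1$reads$r1, s2$reads$r1)
  expect_identical(s1$reads$r2, s2$reads$r2)
  expect_identical(s1$sam, s2$sam)
  expect_identical(s1$truth, s2$truth)
})

test_that("host composition follows the requested GC", {
  set.seed(81)
  h <- simulate_host(100000, gc = 0.5)
  gc <- sum(strsplit(h$seq, "")[[1]] %in% c("G", "C")) / 100000
  expect_gt(gc, 0.49); expect_lt(gc, 0.51)
  at_only <- simulate_host(2000, gc = 0)
  expect_false(grepl("[GC]", at_only$seq))
})

test_that("insertion splicing conserves sequence and records clean junctions", {
  set.seed(82)
  host <- simulate_host(30000, id = "chr1")
  virus <- simulate_host(2000, id = "v1")
  cfg <- simulation_config(seed = 82, host_length = 30000, n_insertions = 3,
                           virus_length = 2000, coverage = 1,
                           min_spacing = 3000, fraction_partial = 1 / 3)
  pl <- plant_integrations(host, virus, cfg)
  ins_len <- sum(pl$truth$r_end - pl$truth$r_start + 1L)
  expect_equal(nchar(pl$genome$seq), 30000L + ins_len)
  expect_equal(pl$truth$right_junction, pl$truth$left_junction + 1L)
  expect_true(all(diff(sort(pl$truth$left_junction)) >= 3000))

  # each inserted piece is the stated virus span (reverse complement on -)
  segs <- pl$segments[pl$segments$seg_type == "virus", ]
  for (i in seq_len(nrow(segs))) {
    piece <- substr(pl$genome$seq, segs$aug_start[i], segs$aug_end[i])
    want <- substr(virus$seq, segs$src_start[i], segs$src_end[i])
    if (segs$strand[i] == "-") want <- revcomp(want)
    expect_identical(piece, want)
  }

  # no insertions: genome unchanged, empty truth
  cfg0 <- simulation_config(seed = 1, host_length = 30000, n_insertions = 0)
  pl0 <- plant_integrations(host, virus, cfg0)
  expect_identical(pl0$genome$seq, host$seq)
  expect_equal(nrow(pl0$truth), 0L)

  # infeasible spacing errors out
  cfg_bad <- simulation_config(seed = 1, host_length = 30000,
                               n_insertions = 20, min_spacing = 3000)
  expect_error(plant_integrations(host, virus, cfg_bad),
               class = "viralint_input_error")
})

test_that("read counts follow coverage and error-free reads are substrings", {
  set.seed(83)
  genome <- simulate_host(50000)
  cfg <- simulation_config(seed = 83, host_length = 50000, coverage = 10,
                           error_rate = 0)
  reads <- simulate_reads(genome, cfg)
  expect_equal(nrow(reads$r1), round(10 * 50000 / 300))
  for (i in sample(nrow(reads$r1), 25)) {
    ok1 <- grepl(reads$r1$seq[i], genome$seq, fixed = TRUE) ||
      grepl(revcomp(reads$r1$seq[i]), genome$seq, fixed = TRUE)
    expect_true(ok1)
  }
  expect_true(all(nchar(reads$r1$seq) == 150))
  expect_true(all(reads$r1$qual == strrep(phred_to_qual(40L), 150)))
})

test_that("simulated base errors occur at roughly the configured rate", {
  set.seed(84)
  genome <- simulate_host(40000)
  cfg <- simulation_config(seed = 84, host_length = 40000, coverage = 10,
                           error_rate = 0.01)
  reads <- simulate_reads(genome, cfg)
  # count mismatches of fragment-forward reads against the genome
  n_err <- 0L; n_base <- 0L
  for (i in sample(nrow(reads$r1), 50)) {
    s <- reads$frags$frag_start[i]
    fwd <- if (reads$frags$flip[i]) reads$r2$seq[i] else reads$r1$seq[i]
    ref <- substr(genome$seq, s, s + 149)
    n_err <- n_err + sum(strsplit(fwd, "")[[1]] != strsplit(ref, "")[[1]])
    n_base <- n_base + 150L
  }
  expect_gt(n_err / n_base, 0.003)
  expect_lt(n_err / n_base, 0.025)
})

test_that("truth alignments encode junctions, flags and mates consistently", {
  cfg <- simulation_config(seed = 85, host_length = 30000, n_insertions = 2,
                           virus_length = 2000, coverage = 20,
                           min_spacing = 4000, error_rate = 0)
  sim <- simulate_dataset(cfg)
  sam <- sim$sam

  # junction-spanning reads: soft-clip at the exact junction coordinate
  clipped <- sam[grepl("S", sam$cigar), ]
  expect_gt(nrow(clipped), 0)
  lc <- cigar_clip_len(clipped$cigar, "left")
  rc <- cigar_clip_len(clipped$cigar, "right")
  span <- cigar_ref_span(clipped$cigar)
  anchor <- ifelse(lc > 0, clipped$pos, clipped$pos + span - 1L)
  junctions <- c(sim$truth$left_junction, sim$truth$right_junction)
  expect_true(all(anchor %in% junctions))
  expect_true(all(lc + rc + viralint:::cigar_op_sum(clipped$cigar, "M") ==
                    150))

  # fully-viral reads with host-anchored mates: unmapped, mate mapped
  cand <- sam[passes_single_mate_unmapped_filter(sam$flag), ]
  expect_gt(nrow(cand), 0)
  expect_true(all(bitwAnd(cand$flag, 4L) == 4L))
  expect_true(all(bitwAnd(cand$flag, 8L) == 0L))
  expect_true(all(cand$mrnm == "="))

  # fully-host pairs at error 0: both mapped full-length, no clips
  host_pairs <- sam[bitwAnd(sam$flag, 12L) == 0L & !grepl("S", sam$cigar), ]
  expect_true(all(host_pairs$cigar == "150M"))
  expect_true(all(bitwAnd(host_pairs$flag, 2L) == 2L))

  # mapped SEQ matches the host reference at error 0 (reference-forward)
  host <- sim$host$seq
  idx <- sample(which(sam$cigar == "150M"), 20)
  for (i in idx) {
    expect_identical(sam$seq[i], substr(host, sam$pos[i], sam$pos[i] + 149L))
  }

  # the SAM round-trips through its own writer/reader
  p <- tempfile(fileext = ".sam")
  write_sam(sam, p)
  back <- read_sam(p)
  expect_equal(back$flag, sam$flag)
  expect_equal(back$cigar, sam$cigar)
})

test_that("written dataset files are byte-stable across reruns", {
  cfg <- simulation_config(seed = 86, host_length = 15000, n_insertions = 1,
                           virus_length = 1200, coverage = 4,
                           min_spacing = 2000)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  simulate_dataset(cfg, out_dir = d1)
  simulate_dataset(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})
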