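# Region classification, DNase / repeat point queries, summary partitions.

mini_gene_model <- function() {
  p <- tempfile(fileext = ".gtf")
  attr1 <- 'gene_name "PLUS1"; gene_type "protein_coding";'
  attr2 <- 'gene_name "MINUS1"; gene_type "lncRNA";'
  writeLines(c(
    paste("chr1\tx\tgene\t10000\t16000\t.\t+\t.", attr1, sep = "\t"),
    paste("chr1\tx\texon\t10000\t11000\t.\t+\t.", attr1, sep = "\t"),
    paste("chr1\tx\texon\t14000\t16000\t.\t+\t.", attr1, sep = "\t"),
    paste("chr1\tx\tCDS\t10500\t15500\t.\t+\t.", attr1, sep = "\t"),
    paste("chr1\tx\tgene\t30000\t34000\t.\t-\t.", attr2, sep = "\t"),
    paste("chr1\tx\texon\t30000\t34000\t.\t-\t.", attr2, sep = "\t")), p)
  read_gene_model(p)
}

test_that("region classes follow precedence and strand-aware windows", {
  gm <- mini_gene_model()
  got <- classify_region(
    rep("chr1", 7),
    c(10700,   # inside exon and CDS
      8500,    # 1500 upstream of the + TSS: promoter
      12500,   # inside gene, between exons: intron
      10300,   # exonic, before the CDS start, past the promoter: 5' UTR
      15800,   # exonic, after CDS end: 3' UTR
      34500,   # 500 "upstream" of the - strand TSS (34000): promoter
      500000), # nowhere
    gm)
  expect_equal(got$region_class,
               c("exon", "promoter", "intron", "five_prime_utr",
                 "three_prime_utr", "promoter", "intergenic"))
  expect_equal(got$gene_name[1:6],
               c("PLUS1", "PLUS1", "PLUS1", "PLUS1", "PLUS1", "MINUS1"))
  expect_true(is.na(got$gene_name[7]))
  expect_equal(got$gene_type[c(1, 6, 7)],
               c("protein_coding", "lncRNA", "none"))
})

test_that("chr prefixes unify across queries and tracks", {
  gm <- mini_gene_model()
  got <- classify_region("1", 10700, gm)  # bare name vs chr-prefixed track
  expect_equal(got$region_class, "exon")
})

test_that("DNase point queries respect the half-open BED convention", {
  dnase <- tibble::tibble(chrom = "chr1", start = 100L, end = 200L,
                          name = "d", score = 1, strand = ".")
  expect_equal(annotate_dnase(rep("chr1", 4), c(150, 200, 201, 100), dnase),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_false(annotate_dnase("chr2", 150, dnase))
})

test_that("repeat overlaps resolve by score then class priority", {
  reps <- tibble::tibble(
    chrom = "chr1",
    start = c(100L, 100L, 500L, 900L),
    end = c(300L, 300L, 700L, 1000L),
    name = c("LINE/L1", "SINE/Alu", "Simple_repeat", "LTR/ERVK"),
    score = c(10, 10, 5, 2), strand = "+")
  expect_equal(annotate_repeat("chr1", 200, reps), "LINE")  # tie: priority
  expect_equal(annotate_repeat("chr1", 600, reps), "Simple_repeat")
  expect_equal(annotate_repeat("chr1", 950, reps), "LTR")
  expect_equal(annotate_repeat("chr1", 5000, reps), "none")
  # higher score beats priority
  reps$score[2] <- 99
  expect_equal(annotate_repeat("chr1", 200, reps), "SINE")
  # unknown labels warn and map to none
  bad <- tibble::tibble(chrom = "chr1", start = 1L, end = 100L,
                        name = "Satellite/centr", score = 1, strand = "+")
  expect_warning(got <- annotate_repeat("chr1", 50, bad), "unrecognised")
  expect_equal(got, "none")
})

test_that("annotation summaries partition to 100% and count accounting holds", {
  gm <- mini_gene_model()
  bp <- tibble::tibble(
    sample_id = rep(c("s1", "s2"), each = 5),
    chrom = "chr1",
    pos = c(10700, 8500, 12500, 500000, 600000,
            10200, 15800, 34500, 700000, 800000),
    virus_id = "v", evidence = "softclip", support = 1L)
  ann <- annotate_breakpoints(bp, gene_model = gm)
  expect_s3_class(ann, "annotated_breakpoints")
  smry <- breakpoint_summary(ann)
  expect_lte(abs(sum(smry$region_distribution$pct) - 100), 0.03)
  expect_equal(sum(smry$region_distribution$n), nrow(bp))
  expect_equal(sum(smry$gene_table$n_breakpoints),
               sum(!is.na(ann$gene_name)))
  expect_equal(smry$dnase_per_sample$n_breakpoints, c(5L, 5L))
  # all-intergenic input gives a pure intergenic distribution
  ann2 <- annotate_breakpoints(bp, gene_model = NULL)
  smry2 <- breakpoint_summary(ann2)
  expect_equal(
    smry2$region_distribution$pct[
      smry2$region_distribution$region_class == "intergenic"], 100)
})

test_that("point queries are independent of track row order", {
  gm <- mini_gene_model()
  reps <- tibble::tibble(
    chrom = "chr1", start = c(100L, 150L), end = c(300L, 350L),
    name = c("LINE/L1", "LTR/ERVK"), score = c(5, 5), strand = "+")
  a <- annotate_repeat("chr1", 200, reps)
  b <- annotate_repeat("chr1", 200, reps[2:1, ])
  expect_equal(a, b)
})

test_that("simulated track contexts are recovered exactly at planted junctions", {
  cfg <- simulation_config(seed = 19, host_length = 80000, n_insertions = 4,
                           virus_length = 2000, coverage = 1,
                           min_spacing = 8000)
  sim <- simulate_dataset(cfg)
  tracks <- simulate_tracks(sim$truth, sim$host)
  gm_path <- tempfile(); dir.create(gm_path)
  write_tracks(tracks, gm_path)
  gm <- read_gene_model(file.path(gm_path, "genes.gtf"))
  dn <- read_bed(file.path(gm_path, "dnase.bed"))
  rp <- read_bed(file.path(gm_path, "repeats.bed"))
  ann <- annotate_breakpoints(
    tibble::tibble(sample_id = "s", chrom = "chr1",
                   pos = tracks$expected$pos, virus_id = "v",
                   evidence = "softclip", support = 1L),
    gene_model = gm, dnase = dn, repeats = rp)
  expect_equal(ann$region_class, tracks$expected$region_class)
  expect_equal(ann$dnase, tracks$expected$dnase)
  expect_equal(ann$repeat_class, tracks$expected$repeat_class)
  expect_equal(ann$gene_type, tracks$expected$gene_type)
})

test_that("close insertions are a track-construction conflict", {
  truth <- tibble::tibble(
    insertion_id = c("i1", "i2"), host_chrom = "chr1",
    left_junction = c(10000L, 11000L), right_junction = c(10001L, 11001L),
    virus_id = "v", r_start = 1L, r_end = 100L, strand = "+",
    full_length = TRUE)
  expect_error(simulate_tracks(truth, tibble::tibble(id = "chr1", seq = "A")),
               class = "viralint_track_conflict")
})
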