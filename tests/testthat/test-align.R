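# Seed-and-extend viral aligner vs the full-matrix local alignment oracle.

test_that("k-mer index counts forward positions and validates inputs", {
  panel <- tibble::tibble(id = "v", seq = strrep("ACGTG", 4))  # 20-mer
  idx <- build_kmer_index(panel, k = 15)
  fwd <- 0L
  for (km in ls(idx$env)) {
    ent <- get(km, envir = idx$env)
    fwd <- fwd + sum(ent[, "minus"] == 0L)
  }
  expect_equal(fwd, 6L)  # 20 - 15 + 1

  expect_error(build_kmer_index(panel, k = 25), "exceeds")
  expect_error(build_kmer_index(tibble::tibble(id = character(),
                                               seq = character())),
               "empty")
})

test_that("palindromic k-mers are indexed once per strand occurrence", {
  pal <- "ACGCGT"  # 6-mer, its own reverse complement
  expect_equal(revcomp(pal), pal)
  panel <- tibble::tibble(id = "v", seq = paste0("TTTTT", pal, "TTTTT"))
  idx <- build_kmer_index(panel, k = 6)
  ent <- get(pal, envir = idx$env)
  expect_equal(nrow(ent), 2L)  # one + and one - entry at the same site
  expect_setequal(ent[, "minus"], c(0L, 1L))
})

test_that("exact panel substrings align perfectly on both strands", {
  panel <- tiny_panel()
  idx <- build_kmer_index(panel)
  q <- substr(panel$seq[2], 201, 300)
  hit <- align_to_panel(q, idx)
  expect_equal(hit$virus_id, "virusB")
  expect_equal(hit$identity, 1)
  expect_equal(hit$score, 100L)
  expect_equal(c(hit$r_start, hit$r_end), c(201L, 300L))
  expect_equal(hit$strand, "+")

  rc <- align_to_panel(revcomp(q), idx)
  expect_equal(rc$strand, "-")
  expect_equal(c(rc$r_start, rc$r_end), c(201L, 300L))
  expect_equal(rc$score, hit$score)
})

test_that("random queries find no qualifying hit", {
  panel <- tiny_panel()
  idx <- build_kmer_index(panel)
  set.seed(21)
  for (i in 1:10) {
    q <- random_dna(100)
    hit <- align_to_panel(q, idx)
    if (nrow(hit) > 0) {
      # any reported hit must genuinely satisfy the thresholds
      expect_gte(hit$identity, 0.9)
    } else {
      succeed()
    }
    # oracle: the best local alignment against either virus is far below a
    # 90%-identity, >=30-column alignment (score >= 0.8 * 30 under +1/-1)
    best <- max(Biostrings::score(oracle_local_score(q, panel$seq[1])),
                Biostrings::score(oracle_local_score(q, panel$seq[2])))
    if (best < 24) expect_equal(nrow(hit), 0L)
  }
})

test_that("banded scores equal the full-matrix oracle when in band", {
  set.seed(31)
  band <- 15L
  n_checked <- 0L
  for (i in 1:60) {
    rlen <- sample(60:120, 1)
    ref <- random_dna(rlen)
    qlen <- sample(40:min(rlen, 120), 1)
    off <- sample(1:(rlen - qlen + 1), 1)
    q <- substr(ref, off, off + qlen - 1)
    # plant 0-10% divergence: substitutions plus occasional 1-base indels
    nmut <- rbinom(1, qlen, runif(1, 0, 0.10))
    qv <- strsplit(q, "")[[1]]
    if (nmut > 0) {
      at <- sample(qlen, nmut)
      qv[at] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
    }
    if (runif(1) < 0.3) qv <- qv[-sample(length(qv), 1)]   # deletion
    if (runif(1) < 0.3) {
      ins <- sample(length(qv), 1)
      qv <- append(qv, sample(c("A", "C", "G", "T"), 1), after = ins)
    }
    q <- paste(qv, collapse = "")
    d0 <- off - 1L  # planted diagonal
    res <- viralint:::banded_local_align(q, ref, d0 - band, d0 + band)
    pa <- oracle_local_score(q, ref)
    dr <- oracle_diag_range(pa)
    in_band <- dr[1] >= d0 - band && dr[2] <= d0 + band
    if (in_band) {
      expect_equal(res$score, Biostrings::score(pa), info = paste("case", i))
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 40L)  # the planted construction is mostly in-band
})

test_that("alignment is strand-symmetric and deterministic", {
  panel <- tiny_panel()
  idx <- build_kmer_index(panel)
  set.seed(41)
  for (i in 1:10) {
    start <- sample(1:500, 1)
    q <- substr(panel$seq[1], start, start + 79)
    # a couple of substitutions
    substr(q, 10, 10) <- "A"
    substr(q, 50, 50) <- "T"
    h1 <- align_to_panel(q, idx)
    h2 <- align_to_panel(revcomp(q), idx)
    expect_equal(h1$score, h2$score)
    expect_equal(c(h1$r_start, h1$r_end), c(h2$r_start, h2$r_end))
    expect_false(h1$strand == h2$strand)
  }
  q <- substr(panel$seq[1], 101, 220)
  expect_identical(align_to_panel(q, idx), align_to_panel(q, idx))
})

test_that("screening applies the closed read-count bound per virus", {
  hits <- tibble::tibble(
    query_id = paste0("q", 1:1999),
    virus_id = c(rep("virusA", 999), rep("virusB", 1000)))
  scr <- screen_sample(hits, min_virus_reads = 1000, sample_id = "s")
  expect_false(scr$retained[scr$virus_id == "virusA"])  # 999 < 1000
  expect_true(scr$retained[scr$virus_id == "virusB"])   # exactly 1000

  empty <- screen_sample(hits[0, ], min_virus_reads = 1000)
  expect_equal(nrow(empty), 0L)
})
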