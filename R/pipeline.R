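# Pipeline configuration and orchestration. Every stage threshold lives in
# one nested config object so a run's parameters can be serialized into its
# outputs (provenance) and overridden in one place.

#' Pipeline configuration
#'
#' Central registry of every stage parameter with the method's standard
#' values as defaults: Q30/50 nt read filter, include-flag 4 / exclude-flag
#' 264 candidate extraction, 1,000-read per-virus screening cutoff, k = 33
#' assembly with the >5% genome-completeness screen, and the annotation,
#' clustering and statistics settings. Any element can be overridden via
#' named nested lists, e.g. `pipeline_config(screen = list(min_virus_reads
#' = 50))`.
#'
#' @param ... Named nested overrides per stage (`trim`, `flags`, `clip`,
#'   `screen`, `assembly`, `calling`, `annotation`, `stats`, `seed`).
#' @return A validated `pipeline_config` object.
#' @export
#' @examples
#' cfg <- pipeline_config(screen = list(min_virus_reads = 50))
#' cfg$screen$min_virus_reads
pipeline_config <- function(...) {
  defaults <- list(
    trim = list(window = 4L, mean_q = 30, min_len = 50L),
    flags = list(include = 4L, exclude = 264L),
    clip = list(min_clip_len = 20L, min_mapq = 20L),
    screen = list(min_virus_reads = 1000L, min_identity = 0.90,
                  min_aln_len = 30L, seed_k = 15L, band = 15L),
    assembly = list(k = 33L, min_kmer_count = 2L, min_completeness_pct = 5,
                    run = TRUE, gate = FALSE),
    calling = list(cluster_window = 10L, max_insert = 1000L,
                   min_support = 1L),
    annotation = list(promoter_up = 2000L, promoter_down = 200L),
    stats = list(alpha = 0.05, two_sided = TRUE),
    seed = 1L
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) {
    vl_abort(paste0("unknown config section(s): ",
                    paste(bad, collapse = ", ")), "viralint_config_error")
  }
  cfg <- defaults
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]])) {
      bad <- setdiff(names(overrides[[nm]]), names(defaults[[nm]]))
      if (length(bad)) {
        vl_abort(paste0("unknown config key(s) in ", nm, ": ",
                        paste(bad, collapse = ", ")),
                 "viralint_config_error")
      }
      cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  validate_config(structure(cfg, class = "pipeline_config"))
}

validate_config <- function(cfg) {
  chk <- function(ok, what) {
    if (!ok) vl_abort(paste0("invalid config: ", what),
                      "viralint_config_error")
  }
  chk(cfg$trim$window >= 1, "trim$window must be >= 1")
  chk(cfg$trim$min_len >= 1, "trim$min_len must be >= 1")
  chk(cfg$trim$mean_q >= 0, "trim$mean_q must be >= 0")
  chk(cfg$clip$min_clip_len >= 1, "clip$min_clip_len must be >= 1")
  chk(cfg$screen$min_virus_reads >= 1, "screen$min_virus_reads must be >= 1")
  chk(cfg$screen$min_identity > 0 && cfg$screen$min_identity <= 1,
      "screen$min_identity must be in (0, 1]")
  chk(cfg$assembly$k >= 3, "assembly$k must be >= 3")
  chk(cfg$calling$cluster_window >= 0, "calling$cluster_window must be >= 0")
  chk(cfg$stats$alpha > 0 && cfg$stats$alpha < 1,
      "stats$alpha must be in (0, 1)")
  cfg
}

#' Read / write a pipeline config as YAML
#'
#' @param path YAML file path.
#' @return `read_config()` returns a `pipeline_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config A `pipeline_config` object.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Call integration breakpoints for one sample
#'
#' The core composition: extract candidate reads and soft-clip fragments
#' from the host alignment, align them to the viral panel, screen viruses
#' by read count (and optionally by assembly genome completeness), derive
#' per-read breakpoints for retained viruses, and cluster them. Output
#' ordering is deterministic (chrom, pos).
#'
#' @param alignment SAM tibble from [read_sam()] or a path to a SAM file.
#' @param panel Viral panel tibble from [read_fasta()] or a path.
#' @param config A [pipeline_config()].
#' @param sample_id Sample label.
#' @return List: `clusters` (breakpoint cluster tibble), `breakpoints`
#'   (per-read evidence), `screen`, `completeness` (NULL unless assembly
#'   ran), `candidates`, `fragments`.
#' @export
call_sample <- function(alignment, panel, config = pipeline_config(),
                        sample_id = "sample") {
  if (is.character(alignment)) alignment <- read_sam(alignment)
  if (is.character(panel)) panel <- read_fasta(panel)
  index <- build_kmer_index(panel, k = config$screen$seed_k)

  candidates <- extract_candidates(alignment,
                                   min_mapq = config$clip$min_mapq) |>
    mutate(query_id = paste0(.data$qname, "|unmapped"))
  fragments <- extract_softclip_fragments(
    alignment, min_clip_len = config$clip$min_clip_len,
    min_mapq = config$clip$min_mapq) |>
    mutate(query_id = paste0(.data$source_qname, "|", .data$anchor_chrom,
                             "|", .data$anchor_pos, "|", .data$side))

  aln_args <- list(index = index, band = config$screen$band,
                   min_identity = config$screen$min_identity,
                   min_aln_len = config$screen$min_aln_len)
  cand_hits <- do.call(align_many, c(list(
    tibble(query_id = candidates$query_id, seq = candidates$seq)), aln_args))
  frag_hits <- do.call(align_many, c(list(
    tibble(query_id = fragments$query_id, seq = fragments$clipped_seq)),
    aln_args))

  screen <- screen_sample(cand_hits, frag_hits,
                          min_virus_reads = config$screen$min_virus_reads,
                          sample_id = sample_id)
  retained <- screen$virus_id[screen$retained]

  comp <- NULL
  if (isTRUE(config$assembly$run)) {
    reads_for_asm <- c(candidates$seq, fragments$clipped_seq)
    graph <- build_dbg(reads_for_asm, k = config$assembly$k,
                       min_kmer_count = config$assembly$min_kmer_count)
    contigs <- assemble_contigs(graph)
    comp <- completeness(
      contigs, panel, index = index,
      min_completeness_pct = config$assembly$min_completeness_pct,
      sample_id = sample_id,
      viruses = if (length(retained)) retained else NULL)
    if (isTRUE(config$assembly$gate)) {
      retained <- intersect(retained, comp$virus_id[comp$retained])
    }
  }

  cand_hits <- filter(cand_hits, .data$virus_id %in% retained)
  frag_hits <- filter(frag_hits, .data$virus_id %in% retained)
  bps <- bind_rows(
    breakpoints_from_softclips(fragments, frag_hits,
                               min_mapq = config$clip$min_mapq,
                               sample_id = sample_id),
    breakpoints_from_discordant(candidates, cand_hits,
                                sample_id = sample_id))
  clusters <- cluster_breakpoints(
    bps, cluster_window = config$calling$cluster_window,
    max_insert = config$calling$max_insert) |>
    filter(.data$support >= config$calling$min_support)

  list(clusters = clusters, breakpoints = bps, screen = screen,
       completeness = comp, candidates = candidates, fragments = fragments)
}

#' Run the full pipeline and write stage outputs
#'
#' File-level wrapper around [call_sample()] plus annotation and the run
#' manifest. Writes `screen.tsv`, `completeness.tsv`, `breakpoints.tsv`
#' (and `annotated.tsv` when tracks are given) plus `manifest.yaml`
#' (package version, effective config, input checksums) into `out_dir`.
#' Identical inputs and config give byte-identical outputs.
#'
#' @param sam Path to the host-aligned SAM file.
#' @param panel Path to the viral panel FASTA.
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @param sample_id Sample label.
#' @param dnase,repeats,genes Optional paths to DNase BED, repeat BED and
#'   gene-model GTF tracks.
#' @return The [call_sample()] result (plus `annotated`), invisibly.
#' @export
run_all <- function(sam, panel, out_dir, config = pipeline_config(),
                    sample_id = "sample", dnase = NULL, repeats = NULL,
                    genes = NULL) {
  for (p in c(sam, panel, dnase, repeats, genes)) {
    if (!file.exists(p)) {
      vl_abort(paste0("input file not found: ", p),
               "viralint_missing_input")
    }
  }
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, "viralint_error")) stop(e)
      vl_abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
               "viralint_stage_error")
    })
  }
  res <- stage("call", call_sample(sam, panel, config, sample_id))
  readr::write_tsv(as_tibble(res$screen), file.path(out_dir, "screen.tsv"))
  if (!is.null(res$completeness)) {
    readr::write_tsv(res$completeness,
                     file.path(out_dir, "completeness.tsv"))
  }
  write_breakpoints(res$clusters, file.path(out_dir, "breakpoints.tsv"))
  annotated <- NULL
  if (!is.null(genes) || !is.null(dnase) || !is.null(repeats)) {
    gm <- if (!is.null(genes)) stage("annotate", read_gene_model(genes))
    dn <- if (!is.null(dnase)) stage("annotate", read_bed(dnase))
    rp <- if (!is.null(repeats)) stage("annotate", read_bed(repeats))
    annotated <- stage("annotate", annotate_breakpoints(
      res$clusters, gene_model = gm, dnase = dn, repeats = rp,
      promoter_up = config$annotation$promoter_up,
      promoter_down = config$annotation$promoter_down))
    write_breakpoints(annotated, file.path(out_dir, "annotated.tsv"))
  }
  manifest <- list(
    package = "viralint",
    version = as.character(packageVersion("viralint")),
    sample_id = sample_id,
    inputs = lapply(
      setNames(c(sam, panel), c("sam", "panel")),
      function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
    config = unclass(config))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  res$annotated <- annotated
  invisible(res)
}
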