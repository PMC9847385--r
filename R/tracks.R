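# Annotation-track input: BED3-6 intervals and GENCODE-dialect GTF gene
# models. Dedicated readers (rather than a generic importer) so that format
# violations surface with the offending line number and outputs are plain
# tibbles in the package's coordinate conventions.

#' Read a BED3-6 file
#'
#' Intervals are returned exactly as stored in the file: 0-based,
#' half-open `[start, end)`. `track`/`browser`/comment header lines are
#' skipped. Columns 4-6 (`name`, `score`, `strand`) are populated when
#' present.
#'
#' @param path Path to a BED file.
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  keep <- nzchar(lines) &
    !grepl("^(track|browser|#)", lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = numeric(), strand = character()))
  }
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    i <- which(nf < 3)[1]
    vl_abort(sprintf("BED line %d has %d columns; at least 3 required",
                     idx[i], nf[i]), "viralint_format_error")
  }
  col <- function(k, default = NA_character_) {
    vapply(parts, function(p) if (length(p) >= k) p[[k]] else default,
           character(1))
  }
  start <- suppressWarnings(as.integer(col(2)))
  end <- suppressWarnings(as.integer(col(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    vl_abort(sprintf("BED line %d: non-numeric start/end", idx[bad[1]]),
             "viralint_format_error")
  }
  bad <- which(start >= end | start < 0)
  if (length(bad)) {
    vl_abort(sprintf("BED line %d: invalid interval [%d, %d)",
                     idx[bad[1]], start[bad[1]], end[bad[1]]),
             "viralint_format_error")
  }
  strand <- col(6)
  strand[!strand %in% c("+", "-")] <- "."
  tibble(
    chrom = col(1), start = start, end = end,
    name = col(4),
    score = suppressWarnings(as.numeric(col(5))),
    strand = strand
  )
}

#' Convert between BED and 1-based inclusive coordinates
#'
#' Breakpoints and gene models inside the package use 1-based inclusive
#' coordinates (the SAM convention); BED tracks are 0-based half-open.
#' `bed_to_1based()` and `to_bed()` are exact inverses.
#'
#' @param intervals Tibble with `start`/`end` columns.
#' @return The same tibble with converted coordinates.
#' @export
bed_to_1based <- function(intervals) {
  mutate(intervals, start = .data$start + 1L)
}

#' @rdname bed_to_1based
#' @export
to_bed <- function(intervals) {
  mutate(intervals, start = .data$start - 1L)
}

# map a GENCODE biotype to the reporting vocabulary; anything containing
# "pseudogene" is a pseudogene
map_gene_type <- function(gene_type) {
  out <- rep("other", length(gene_type))
  out[gene_type == "protein_coding"] <- "protein_coding"
  out[gene_type == "lncRNA"] <- "lncRNA"
  out[grepl("pseudogene", gene_type)] <- "pseudogene"
  out
}

gtf_attr <- function(attrs, key) {
  str_match(attrs, paste0(key, ' "([^"]*)"'))[, 2]
}

#' Read a GENCODE-style GTF into a gene model
#'
#' Parses `gene`, `exon` and `CDS` features carrying `gene_name` and
#' `gene_type` attributes. Exons are merged per gene; the TSS is the gene
#' start on the + strand and the gene end on the - strand. Biotypes outside
#' protein_coding / lncRNA are mapped to "pseudogene" when the label
#' contains "pseudogene" and to "other" otherwise.
#'
#' @param path Path to a GTF file.
#' @return A `gene_model` object: a list of tibbles `genes` (with 1-based
#'   inclusive `start`/`end`, `tss`, `gene_type`, mapped `gene_class`),
#'   `exons` and `cds`.
#' @export
read_gene_model <- function(path) {
  lines <- readr::read_lines(path)
  idx <- which(nzchar(lines) & !startsWith(lines, "#"))
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 9)) {
    i <- which(nf < 9)[1]
    vl_abort(sprintf("GTF line %d has %d columns; 9 required", idx[i], nf[i]),
             "viralint_format_error")
  }
  feat <- tibble(
    chrom = vapply(parts, `[[`, character(1), 1),
    type = vapply(parts, `[[`, character(1), 3),
    start = as.integer(vapply(parts, `[[`, character(1), 4)),
    end = as.integer(vapply(parts, `[[`, character(1), 5)),
    strand = vapply(parts, `[[`, character(1), 7),
    attrs = vapply(parts, `[[`, character(1), 9),
    line = idx
  ) |>
    filter(.data$type %in% c("gene", "exon", "CDS"))
  feat$gene_name <- gtf_attr(feat$attrs, "gene_name")
  feat$gene_type <- gtf_attr(feat$attrs, "gene_type")
  bad <- which(is.na(feat$gene_name))
  if (length(bad)) {
    vl_abort(sprintf("GTF line %d: cannot parse gene_name attribute",
                     feat$line[bad[1]]), "viralint_format_error")
  }
  genes <- feat |>
    filter(.data$type == "gene") |>
    transmute(
      gene_name = .data$gene_name,
      gene_type = .data$gene_type %||% NA_character_,
      gene_class = map_gene_type(.data$gene_type),
      chrom = .data$chrom, strand = .data$strand,
      start = .data$start, end = .data$end,
      tss = if_else(.data$strand == "-", .data$end, .data$start)
    )
  exons <- feat |>
    filter(.data$type == "exon") |>
    select("gene_name", "chrom", "start", "end") |>
    merge_intervals_by_gene()
  cds <- feat |>
    filter(.data$type == "CDS") |>
    select("gene_name", "chrom", "start", "end") |>
    merge_intervals_by_gene()
  structure(list(genes = genes, exons = exons, cds = cds),
            class = "gene_model")
}

# merge overlapping/adjacent 1-based inclusive intervals within each gene
merge_intervals_by_gene <- function(tbl) {
  if (nrow(tbl) == 0) return(tbl)
  tbl |>
    arrange(.data$gene_name, .data$chrom, .data$start, .data$end) |>
    group_by(.data$gene_name, .data$chrom) |>
    mutate(grp = cumsum(.data$start > lag(cummax(.data$end), default = -1L) + 1L)) |>
    group_by(.data$gene_name, .data$chrom, .data$grp) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    select(-"grp") |>
    select("gene_name", "chrom", "start", "end")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", nrow(x$genes), " genes, ", nrow(x$exons),
      " merged exon blocks, ", nrow(x$cds), " CDS blocks\n", sep = "")
  invisible(x)
}

BREAKPOINT_COLS <- c("sample_id", "chrom", "pos", "virus_id", "evidence",
                     "support", "region_class", "dnase", "repeat_class",
                     "gene_name", "gene_type")

#' Read / write the breakpoint table
#'
#' The tab-separated exchange format for called (and optionally annotated)
#' integration breakpoints: columns `sample_id`, `chrom`, `pos` (1-based),
#' `virus_id`, `evidence` (softclip/discordant/both), `support`,
#' `region_class`, `dnase` (0/1), `repeat_class`, `gene_name`, `gene_type`.
#' Annotation columns may be `NA` for unannotated tables.
#'
#' @param path Path to a TSV file.
#' @return Tibble with the columns above.
#' @export
read_breakpoints <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    sample_id = "c", chrom = "c", pos = "i", virus_id = "c",
                    evidence = "c", support = "i", region_class = "c",
                    dnase = "i", repeat_class = "c", gene_name = "c",
                    gene_type = "c"))
}

#' @rdname read_breakpoints
#' @param breakpoints Tibble of breakpoints to write.
#' @export
write_breakpoints <- function(breakpoints, path) {
  out <- as_tibble(breakpoints)
  for (cc in BREAKPOINT_COLS) if (is.null(out[[cc]])) out[[cc]] <- NA
  if (is.logical(out$dnase)) out$dnase <- as.integer(out$dnase)
  readr::write_tsv(out[BREAKPOINT_COLS], path)
  invisible(path)
}
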