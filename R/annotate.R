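# Breakpoint annotation: genomic region class (promoter / UTRs / exon /
# intron / intergenic), DNase-I hypersensitivity, and repeat class.
# Breakpoints are annotated as points at their 1-based representative
# coordinate.

REGION_LEVELS <- c("promoter", "five_prime_utr", "exon", "intron",
                   "three_prime_utr", "intergenic")
REPEAT_LEVELS <- c("LTR", "LINE", "SINE", "Retroposon", "Simple_repeat")

# Build the point-query feature table from a gene model. All coordinates
# 1-based inclusive. Rank encodes precedence: promoter > 5'UTR > 3'UTR >
# exon > intron (spans below are checked in rank order).
region_features <- function(gene_model, promoter_up = 2000L,
                            promoter_down = 200L) {
  g <- gene_model$genes |>
    mutate(chrom_n = normalize_chrom(.data$chrom),
           span = .data$end - .data$start + 1L)
  promoters <- g |>
    transmute(
      chrom_n = .data$chrom_n, gene_name = .data$gene_name,
      gene_class = .data$gene_class, span = .data$span,
      start = if_else(.data$strand == "-",
                      .data$tss - promoter_down, .data$tss - promoter_up),
      end = if_else(.data$strand == "-",
                    .data$tss + promoter_up, .data$tss + promoter_down),
      region_class = "promoter", rank = 1L)
  ginfo <- g |>
    select("gene_name", "gene_class", "chrom_n", "strand", "span",
           g_start = "start", g_end = "end")
  exons <- gene_model$exons |>
    inner_join(ginfo, by = "gene_name") |>
    mutate(region_class = "exon", rank = 4L)
  cds_rng <- if (nrow(gene_model$cds) == 0) {
    tibble(gene_name = character(), cds_start = integer(),
           cds_end = integer())
  } else {
    gene_model$cds |>
      group_by(.data$gene_name) |>
      summarise(cds_start = min(.data$start), cds_end = max(.data$end),
                .groups = "drop")
  }
  # UTRs: exonic sequence outside the CDS span, sided by strand
  utr <- exons |>
    inner_join(cds_rng, by = "gene_name") |>
    mutate(
      up_start = .data$start, up_end = pmin(.data$end, .data$cds_start - 1L),
      dn_start = pmax(.data$start, .data$cds_end + 1L), dn_end = .data$end)
  utr5 <- bind_rows(
    utr |> filter(.data$strand == "+", .data$up_start <= .data$up_end) |>
      mutate(start = .data$up_start, end = .data$up_end),
    utr |> filter(.data$strand == "-", .data$dn_start <= .data$dn_end) |>
      mutate(start = .data$dn_start, end = .data$dn_end)) |>
    mutate(region_class = "five_prime_utr", rank = 2L)
  utr3 <- bind_rows(
    utr |> filter(.data$strand == "+", .data$dn_start <= .data$dn_end) |>
      mutate(start = .data$dn_start, end = .data$dn_end),
    utr |> filter(.data$strand == "-", .data$up_start <= .data$up_end) |>
      mutate(start = .data$up_start, end = .data$up_end)) |>
    mutate(region_class = "three_prime_utr", rank = 3L)
  introns <- g |>
    transmute(chrom_n = .data$chrom_n, gene_name = .data$gene_name,
              gene_class = .data$gene_class, span = .data$span,
              start = .data$start, end = .data$end,
              region_class = "intron", rank = 5L)
  cols <- c("chrom_n", "start", "end", "region_class", "rank",
            "gene_name", "gene_class", "span")
  bind_rows(promoters[cols], utr5[cols], utr3[cols], exons[cols],
            introns[cols])
}

#' Classify breakpoint positions against a gene model
#'
#' Assigns each position exactly one region class with precedence
#' promoter > 5' UTR > 3' UTR > exon > intron > intergenic. The promoter is
#' the window `[TSS - promoter_up, TSS + promoter_down]` in transcription
#' orientation; UTRs are derived from exon vs CDS geometry on genes with a
#' CDS. When several genes overlap a point the higher-precedence feature
#' wins, then the smaller gene span, then the lexicographically smaller
#' gene name.
#'
#' @param chrom,pos Vectors of chromosome names and 1-based positions.
#' @param gene_model A [read_gene_model()] object.
#' @param promoter_up,promoter_down Promoter window, bases upstream /
#'   downstream of the TSS.
#' @return Tibble with columns `region_class`, `gene_name`, `gene_type`
#'   (the mapped class: protein_coding / lncRNA / pseudogene / other /
#'   none), one row per input position.
#' @export
classify_region <- function(chrom, pos, gene_model, promoter_up = 2000L,
                            promoter_down = 200L) {
  feats <- region_features(gene_model, promoter_up, promoter_down)
  q <- tibble(.row = seq_along(pos), chrom_n = normalize_chrom(chrom),
              pos = as.integer(pos))
  hit <- q |>
    inner_join(feats, by = join_by(chrom_n, between(x$pos, y$start,
                                                      y$end))) |>
    group_by(.data$.row) |>
    arrange(.data$rank, .data$span, .data$gene_name, .by_group = TRUE) |>
    slice(1L) |>
    ungroup()
  out <- q |>
    left_join(hit |> select(".row", "region_class", "gene_name",
                            "gene_class"),
              by = ".row") |>
    transmute(region_class = coalesce(.data$region_class, "intergenic"),
              gene_name = .data$gene_name,
              gene_type = coalesce(.data$gene_class, "none"))
  out
}

#' DNase-I hypersensitivity annotation
#'
#' A 1-based position falls in a BED interval `[start, end)` iff
#' `start < pos <= end`.
#'
#' @param chrom,pos Vectors of chromosome names and 1-based positions.
#' @param dnase Tibble from [read_bed()].
#' @return Logical vector.
#' @export
annotate_dnase <- function(chrom, pos, dnase) {
  if (is.null(dnase) || nrow(dnase) == 0) return(rep(FALSE, length(pos)))
  q <- tibble(.row = seq_along(pos), chrom_n = normalize_chrom(chrom),
              pos = as.integer(pos))
  d <- dnase |> mutate(chrom_n = normalize_chrom(.data$chrom))
  hit <- q |>
    inner_join(d, by = join_by(chrom_n, x$pos > y$start, x$pos <= y$end))
  q$.row %in% hit$.row
}

# map raw repeat labels (e.g. "LTR/ERVK", "LINE/L1") to the reporting
# vocabulary; unknown labels map to none with one warning
map_repeat_class <- function(label) {
  fam <- sub("/.*$", "", label)
  fam[fam == "Simple repeat"] <- "Simple_repeat"
  out <- ifelse(fam %in% REPEAT_LEVELS, fam, "none")
  unknown <- unique(label[out == "none" & !is.na(label) & nzchar(label)])
  if (length(unknown)) {
    warn(paste0("unrecognised repeat class label(s) mapped to none: ",
                paste(head(unknown, 5), collapse = ", ")))
  }
  out
}

#' Repeat-class annotation
#'
#' Overlapping repeats are resolved by highest annotation score, then by
#' class priority LTR > LINE > SINE > Retroposon > Simple_repeat. Positions
#' outside all repeats return "none".
#'
#' @param chrom,pos Vectors of chromosome names and 1-based positions.
#' @param repeats Tibble from [read_bed()]; the repeat class is the BED
#'   `name` column (RepeatMasker-style `family/subfamily` labels accepted).
#' @return Character vector of repeat classes.
#' @export
annotate_repeat <- function(chrom, pos, repeats) {
  if (is.null(repeats) || nrow(repeats) == 0)
    return(rep("none", length(pos)))
  q <- tibble(.row = seq_along(pos), chrom_n = normalize_chrom(chrom),
              pos = as.integer(pos))
  r <- repeats |>
    mutate(chrom_n = normalize_chrom(.data$chrom),
           class = map_repeat_class(.data$name),
           prio = match(.data$class, REPEAT_LEVELS),
           score = coalesce(.data$score, 0)) |>
    filter(.data$class != "none")
  hit <- q |>
    inner_join(r, by = join_by(chrom_n, x$pos > y$start, x$pos <= y$end)) |>
    group_by(.data$.row) |>
    arrange(desc(.data$score), .data$prio, .by_group = TRUE) |>
    slice(1L) |>
    ungroup()
  out <- rep("none", length(pos))
  out[hit$.row] <- hit$class
  out
}

#' Annotate breakpoints against all tracks
#'
#' Adds region class, gene, DNase-I and repeat annotations to a breakpoint
#' (cluster) table. Chromosomes present in the breakpoints but absent from
#' every track are annotated intergenic/none with a warning.
#'
#' @param breakpoints Tibble with at least `chrom` and `pos` columns.
#' @param gene_model A [read_gene_model()] object, or NULL.
#' @param dnase,repeats Interval tibbles from [read_bed()], or NULL.
#' @param promoter_up,promoter_down Promoter window (see
#'   [classify_region()]).
#' @return The input with columns `region_class`, `gene_name`, `gene_type`,
#'   `dnase`, `repeat_class` appended; class `annotated_breakpoints`.
#' @export
annotate_breakpoints <- function(breakpoints, gene_model = NULL,
                                 dnase = NULL, repeats = NULL,
                                 promoter_up = 2000L, promoter_down = 200L) {
  bp <- as_tibble(breakpoints)
  track_chroms <- normalize_chrom(unique(c(
    if (!is.null(gene_model)) gene_model$genes$chrom,
    if (!is.null(dnase)) dnase$chrom,
    if (!is.null(repeats)) repeats$chrom)))
  missing <- setdiff(normalize_chrom(unique(bp$chrom)), track_chroms)
  if (length(missing) && length(track_chroms)) {
    warn(paste0("chromosome(s) absent from all annotation tracks: ",
                paste(missing, collapse = ", ")))
  }
  if (!is.null(gene_model)) {
    reg <- classify_region(bp$chrom, bp$pos, gene_model, promoter_up,
                           promoter_down)
    bp$region_class <- reg$region_class
    bp$gene_name <- reg$gene_name
    bp$gene_type <- reg$gene_type
  } else {
    bp$region_class <- "intergenic"
    bp$gene_name <- NA_character_
    bp$gene_type <- "none"
  }
  bp$dnase <- annotate_dnase(bp$chrom, bp$pos, dnase)
  bp$repeat_class <- annotate_repeat(bp$chrom, bp$pos, repeats)
  class(bp) <- c("annotated_breakpoints", class(bp))
  bp
}

#' Summary tables over annotated breakpoints
#'
#' Reproduces the standard reporting shapes: per-chromosome counts, the
#' region-class percentage distribution (percentages printed to 2 decimals
#' sum to 100 up to rounding), per-sample DNase-I counts, the repeat-class
#' table, and the gene list with breakpoint frequencies.
#'
#' @param annotated Tibble from [annotate_breakpoints()].
#' @return List of tibbles: `per_chromosome`, `region_distribution`,
#'   `dnase_per_sample`, `repeat_table`, `gene_table`.
#' @export
breakpoint_summary <- function(annotated) {
  a <- as_tibble(annotated)
  per_chrom <- a |> count(.data$chrom, name = "n_breakpoints")
  region <- a |>
    count(region_class = factor(.data$region_class,
                                levels = REGION_LEVELS), .drop = FALSE,
          name = "n") |>
    mutate(region_class = as.character(.data$region_class),
           pct = round(100 * .data$n / max(1L, sum(.data$n)), 2))
  dnase <- a |>
    group_by(.data$sample_id) |>
    summarise(n_breakpoints = n(), n_dnase = sum(.data$dnase),
              .groups = "drop")
  repeats <- a |>
    filter(.data$repeat_class != "none") |>
    count(repeat_class = factor(.data$repeat_class,
                                levels = REPEAT_LEVELS), .drop = FALSE,
          name = "n_breakpoints") |>
    mutate(repeat_class = as.character(.data$repeat_class))
  genes <- a |>
    filter(!is.na(.data$gene_name)) |>
    group_by(.data$gene_name, .data$gene_type, .data$chrom) |>
    summarise(n_breakpoints = n(),
              n_samples = n_distinct(.data$sample_id), .groups = "drop") |>
    arrange(desc(.data$n_breakpoints), .data$gene_name)
  list(per_chromosome = per_chrom, region_distribution = region,
       dnase_per_sample = dnase, repeat_table = repeats,
       gene_table = genes)
}
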