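---
title: "Detecting viral integration breakpoints from host WGS alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting viral integration breakpoints from host WGS alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viralint)
library(dplyr)
```

## The problem

When a virus — an exogenous agent such as HPV or HBV, or an endogenous
retrovirus such as HERV-K reactivated in the germ line — integrates into a
host genome, whole-genome sequencing of that host carries two kinds of
direct evidence:

* **soft-clipped reads**: a read straddling the integration junction aligns
  to the host on one side and carries unaligned ("clipped") terminal bases
  that derive from the viral genome;
* **single-mate-unmapped pairs**: one mate falls entirely inside the
  integrated viral sequence (and fails to align to the host reference)
  while its mate anchors in flanking host sequence.

`viralint` turns a host-aligned read set (SAM) plus a viral reference panel
(FASTA) into a table of *integration breakpoints* — host-genome coordinates
where host sequence abuts viral sequence — and then characterises those
breakpoints against regulatory (DNase-I hypersensitivity), repeat and gene
annotation, with cohort-level statistics on top.

## The procedure

1. **Read filtering** (`sliding_window_trim()`, for raw FASTQ input): a
   5'→3' sliding window of 4 bases; at the first window whose mean Phred
   score drops below 30 the read is cut at the window start, extended past
   any individual bases still ≥ 30 so the kept prefix ends where base
   quality actually drops; reads shorter than 50 nt are removed. We read
   the quality threshold as a *base-call* quality: the filter runs before
   any alignment exists, so a mapping-quality reading would be
   inoperable.
2. **Candidate extraction** (`extract_candidates()`,
   `extract_softclip_fragments()`): single-mate-unmapped reads are selected
   by SAM flag arithmetic — include mask 4 (read unmapped), exclude mask
   264 (mate unmapped; secondary) — which exactly 512 of the 4,096 possible
   flag values satisfy. Soft-clip fragments of at least 20 nt are taken
   from primary mapped records; a leading clip anchors at the first aligned
   base, a trailing clip at the last. Anchors below mapping quality 20 are
   discarded as ambiguous.
3. **Viral search** (`align_to_panel()`): a 15-mer seed index over both
   strands of the panel, seeds chained per (virus, strand, diagonal), and a
   banded local Smith-Waterman-Gotoh extension (match +1, mismatch −1,
   first gap base −2, extension −1; band half-width 15). A hit requires
   identity ≥ 0.90 over ≥ 30 alignment columns. Each read or fragment is
   assigned to its single best virus; a virus is retained for breakpoint
   calling only with ≥ 1,000 assigned reads in the sample (the screening
   cutoff; configurable, and scaled down in desk-scale simulations, where
   total candidate counts are orders of magnitude below WGS scale).
4. **Assembly screen** (`build_dbg()`, `assemble_contigs()`,
   `completeness()`): a fixed-k de Bruijn graph (k = 33, canonical k-mers,
   error edges pruned below multiplicity 2) emits unitig contigs; per virus
   the longest assigned contig as a percentage of the viral genome must
   strictly exceed 5% to pass the completeness screen. The screen is
   reported always and *gates* calling only when `assembly$gate = TRUE`:
   the single-mate-unmapped population only samples the ends of an
   integrated provirus (within one insert length of each junction), so at
   desk scale a mandatory completeness gate would suppress true calls.
5. **Breakpoint calling** (`breakpoints_from_softclips()`,
   `breakpoints_from_discordant()`, `cluster_breakpoints()`): the
   breakpoint is the host base adjacent to the first viral base — for soft
   clips the anchor base itself (*exact* evidence); for discordant pairs
   one base beyond the mapped mate in its 3' direction (*approximate*).
   Every breakpoint carries a junction orientation — HV (host left of
   virus) or VH — derived from the clip side or mate strand. Clustering is
   single-linkage within (sample, virus, chromosome, orientation): gap ≤ 10
   for exact members, approximate members attaching to the nearest exact
   cluster within 1,000 bp (an insert length). The orientation key matters:
   a clean insertion's two junctions are *adjacent* host coordinates
   (p and p+1) and would otherwise merge into one cluster.
6. **Annotation** (`annotate_breakpoints()`): point queries against a
   promoter/UTR/exon/intron/intergenic partition (precedence in that
   order), DNase-I intervals (a 1-based position p is inside BED
   `[start, end)` iff start < p ≤ end) and repeat classes (LTR > LINE >
   SINE > Retroposon > Simple_repeat after score). The promoter is defined
   as TSS −2,000/+200 in transcription orientation — a reported promoter
   category is only reproducible given an explicit window, so one is fixed
   and exposed (`annotation$promoter_up/down`).
7. **Cohort statistics** (`mann_whitney_u()`, `two_sample_t()`,
   `summarize_cohorts()`): two-sided tests at α = 0.05. The Mann-Whitney U
   statistic is min(U_a, U_b) with midrank ties; p is exact (full labeling
   enumeration) for tieless samples with n_a + n_b ≤ 16 and otherwise a
   normal approximation with tie and continuity correction. Per-chromosome
   t tests are unadjusted by default, with Benjamini-Hochberg behind
   `p_adjust = "BH"`.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `trim$window`, `trim$mean_q`, `trim$min_len` | 4, 30, 50 | nt, Phred, nt | the standard sliding-window trimming recipe |
| `flags$include`, `flags$exclude` | 4, 264 | flag bits | single-mate-unmapped primary records |
| `clip$min_clip_len` | 20 | nt | clips shorter than this cannot align specifically to a viral panel at 150 bp read length |
| `clip$min_mapq` | 20 | Phred-scaled | suppress breakpoints anchored in ambiguous host regions |
| `screen$min_virus_reads` | 1000 | reads | the per-virus, per-sample screening cutoff (closed bound) |
| `screen$min_identity`, `screen$min_aln_len` | 0.90, 30 | fraction, columns | conservative local-alignment acceptance at 150 bp scale |
| `screen$seed_k`, `screen$band` | 15, 15 | nt, diagonals | seed specificity vs sensitivity; band covers realistic indel drift |
| `assembly$k`, `assembly$min_kmer_count` | 33, 2 | nt, count | fixed-k assembly; prune singleton error k-mers |
| `assembly$min_completeness_pct` | 5 | % | strict longest-contig completeness bound |
| `calling$cluster_window`, `calling$max_insert` | 10, 1000 | bp | exact-evidence scatter vs insert-size uncertainty |
| `annotation$promoter_up/down` | 2000, 200 | bp | conventional TSS window |
| `stats$alpha` | 0.05 | — | significance level |

## The simulator

`simulate_dataset()` is first-class, tested code — the substrate on which
every other module's guarantees are demonstrated. It generates an i.i.d.
host genome (GC 0.41, human-like), a provirus (9.5 kb by default, the
scale of a full-length HERV-K provirus), clean insertions (no target-site
duplication, so junction coordinates are exact by construction; partial
proviruses take a uniform [1 kb, 0.7 × genome] span, random orientation),
2×150 bp FR pairs with Normal(400, 60) fragment lengths, and a truth
alignment derived from read provenance: junction reads soft-clipped at the
exact junction, fully-viral reads unmapped with correct mate flags. Base
errors follow a two-level quality mixture (Q38/Q12) whose weights are
calibrated so the mean per-base error equals the configured rate; errors
are then drawn per base at its own quality, so quality strings genuinely
reflect the error process and survive a Q30 trimming filter the way real
HiSeq data does. Fragment-size mean/sd and GC contents are not prescribed
anywhere upstream; the values above were fixed once as typical of human
HiSeq X WGS.

What the simulator deliberately does *not* emulate: repetitive host
sequence (every simulated 33-mer is essentially unique, so mapping
ambiguity and mapq filtering are barely exercised), target-site
duplications (available via construction but off by default to keep the
coordinate oracle exact), indel sequencing errors, GC bias, PCR
duplicates, and multi-copy endogenous elements — the hardest confounder in
real endogenous-retrovirus profiling. Passing the end-to-end recovery test
therefore demonstrates the correctness of the *machinery* (coordinate
arithmetic, flag logic, alignment, clustering), not field performance on
repeat-rich genomes.

`simulate_tracks()` plants a known annotation context (region class, DNase
state, repeat class) at every insertion and returns the expected label per
junction, making annotation exactly checkable against construction. It
requires insertions ≥ 3 kb apart so one junction's features — including
the implied promoter window of a placed gene — cannot reach a neighbour.

## Numerical and design choices

* **Junction-base convention**: the breakpoint is the host base adjacent
  to the first viral base; left clips report the first aligned host base,
  right clips the last. Printed coordinates from other tools may differ by
  ±1 depending on their (usually undocumented) convention.
* **Gap model**: the first gapped base costs −2 and each additional −1;
  this is the affine model with gapOpening = gapExtension = 1 in
  `Biostrings::pairwiseAlignment` terms, which the test suite uses as the
  independent full-matrix oracle.
* **Tie-breaks** are total everywhere so identical inputs give
  byte-identical outputs: best-hit ties fall to identity, then virus id,
  then + strand; DP traceback prefers diagonal moves; contigs are ordered
  by length then sequence; cluster representatives take the lower median.
* **Degenerate inputs** follow stated contracts rather than erroring
  mid-pipeline: empty graphs assemble to empty contig sets, zero-candidate
  alignments yield empty cluster tables, zero-variance t tests return
  p ∈ {0, 1}, single-observation Mann-Whitney returns p = 1.
* **Exact vs approximate Mann-Whitney**: the exact branch enumerates all
  C(n, n_a) labelings (at most 12,870 at the n_a + n_b ≤ 16 bound). The
  normal approximation deviates from the exact distribution by up to
  ≈ 0.011 at n_a = n_b = 8 (and far more at n ≤ 3), which is why the
  implementation prefers the exact branch throughout that regime.
* **Problem sizes in the test suite** were chosen to exercise each claim
  at the smallest scale that still proves it: the end-to-end recovery run
  uses the full 200 kb / 30× study conditions; unit tests use 2-80 kb
  hosts and 1.2-3 kb viruses.

## Limitations

* Plain SAM is the tested alignment path; BAM input should be converted
  upstream (e.g. `samtools view`).
* Breakpoints are called against a single host reference; translocation
  between host chromosomes, viral rearrangements, micro-homology analysis
  and copy-number consequences are out of scope.
* The read-count screening cutoff and completeness screen are sample-level
  heuristics inherited from the method being implemented; on small panels
  or shallow data they must be scaled (`screen$min_virus_reads`).
* Per-chromosome tests are reported unadjusted by default (matching the
  upstream presentation); use `p_adjust = "BH"` for any confirmatory
  claim.
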