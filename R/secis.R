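# SECIS-like hairpin detection downstream of in-frame UGA codons.

#' Default SECIS scan parameters
#'
#' The hairpin must begin within `max_offset` nt of the recoded UGA and fit
#' inside a `window_nt` window; the stem-loop is scored
#' `2 * WC + 1 * G.U - 2 * mismatch` and a hit requires
#' `score >= threshold`. The default threshold was calibrated on random
#' windows so that fewer than ~5% of decoy UGA genes produce a hit (see the
#' package vignette); planted benchmark hairpins score well above it.
#'
#' @return Named list of defaults.
#' @export
secis_defaults <- function() {
  list(window_nt = 75L, max_offset = 40L, min_stem = 7L,
       loop_range = c(3L, 14L), max_mismatch = 1L, threshold = 32L)
}

#' Find the best stem-loop (hairpin) in a short window
#'
#' Exhaustive scan over all (start, stem, loop) placements; mismatched stem
#' positions are allowed up to `max_mismatch` and scored -2 each, with +2
#' per Watson-Crick and +1 per G.U pair. Ties are broken deterministically:
#' fewer mismatches, then leftmost start, then longer stem, then smaller
#' loop. Bulges are not modeled.
#'
#' @param seq DNA string, at most 200 nt.
#' @param min_stem Minimum stem length in bp.
#' @param loop_range Length-2 integer vector `(lo, hi)` of allowed loop
#'   sizes in nt.
#' @param max_mismatch Maximum mismatched stem positions.
#' @param max_start Optional bound on the 1-based hairpin start position.
#' @return A list (`start`, `stem_bp`, `loop_nt`, `wc_pairs`, `gu_pairs`,
#'   `mismatches`, `span_nt`, `score`) or `NULL` when no placement
#'   satisfies the constraints.
#' @export
find_hairpin <- function(seq, min_stem = 7L, loop_range = c(3L, 14L),
                         max_mismatch = 1L, max_start = NULL) {
  seq <- .check_rna_dna(seq)
  if (nchar(seq) > 200L)
    stop("window longer than 200 nt")
  stopifnot(min_stem >= 1L, length(loop_range) == 2L,
            loop_range[1] <= loop_range[2])
  if (is.null(max_start)) max_start <- 0L
  .find_hairpin_cpp(seq, as.integer(min_stem), as.integer(loop_range[1]),
                    as.integer(loop_range[2]), as.integer(max_mismatch),
                    as.integer(max_start))
}

#' Scan a gene call for SECIS-like hairpins downstream of its UGA codons
#'
#' For every selenocysteine readthrough event (letter `U`) in the gene, the
#' genomic window downstream of the UGA codon's 3' end is extracted in
#' reading direction (strand-aware) and searched with [find_hairpin()]. A
#' hit is emitted when the best hairpin starts within `max_offset` nt of
#' the UGA and scores at least `threshold`. The terminal stop codon is
#' never an event, so it is never scanned.
#'
#' @param gene A single row of a [find_orfs()] result (data.frame or list).
#' @param genome Named character vector of contigs (or `DNAStringSet`).
#' @param window_nt Window length in nt (default 75).
#' @param params List of scan parameters, see [secis_defaults()].
#' @return data.frame with one row per passing event: `gene_id`,
#'   `uga_protein_pos`, `offset_nt` (nt between UGA 3' end and hairpin
#'   start), `stem_bp`, `loop_nt`, `mismatches`, `span_nt`, `score`.
#' @export
scan_secis <- function(gene, genome, window_nt = NULL,
                       params = secis_defaults()) {
  genome <- .as_genome(genome)
  if (is.data.frame(gene)) {
    stopifnot(nrow(gene) == 1L)
    gene <- as.list(gene)
    gene$events <- gene$events[[1]]
  }
  if (is.null(window_nt)) window_nt <- params$window_nt
  empty <- data.frame(gene_id = character(0), uga_protein_pos = integer(0),
                      offset_nt = integer(0), stem_bp = integer(0),
                      loop_nt = integer(0), mismatches = integer(0),
                      span_nt = integer(0), score = integer(0),
                      stringsAsFactors = FALSE)
  ev <- gene$events
  if (is.null(ev) || !nrow(ev)) return(empty)
  ev <- ev[ev$letter == "U", , drop = FALSE]
  if (!nrow(ev)) return(empty)
  contig <- genome[[gene$contig]]
  L <- nchar(contig)
  out <- empty
  for (k in seq_len(nrow(ev))) {
    p <- ev$protein_pos[k]
    if (gene$strand == "+") {
      cod3 <- gene$start + 3L * (p - 1L) + 2L   # 3' end of the UGA codon
      lo <- cod3 + 1L
      hi <- min(L, cod3 + window_nt)
      if (lo > hi) next
      win <- substr(contig, lo, hi)
    } else {
      cod3 <- gene$end - 3L * (p - 1L) - 2L
      hi <- cod3 - 1L
      lo <- max(1L, cod3 - window_nt)
      if (lo > hi) next
      win <- reverse_complement(substr(contig, lo, hi))
    }
    hp <- find_hairpin(win, min_stem = params$min_stem,
                       loop_range = params$loop_range,
                       max_mismatch = params$max_mismatch,
                       max_start = params$max_offset + 1L)
    if (is.null(hp)) next
    if (hp$score < params$threshold) next
    if (hp$start - 1L > params$max_offset) next
    out <- rbind(out, data.frame(
      gene_id = gene$gene_id, uga_protein_pos = p,
      offset_nt = hp$start - 1L, stem_bp = hp$stem_bp,
      loop_nt = hp$loop_nt, mismatches = hp$mismatches,
      span_nt = hp$span_nt, score = hp$score, stringsAsFactors = FALSE))
  }
  out
}

#' Scan every gene of a call set for SECIS hits
#'
#' @param genes A [find_orfs()] result.
#' @inheritParams scan_secis
#' @return Combined data.frame of [scan_secis()] hits for all genes.
#' @export
scan_secis_all <- function(genes, genome, window_nt = NULL,
                           params = secis_defaults()) {
  empty <- data.frame(gene_id = character(0), uga_protein_pos = integer(0),
                      offset_nt = integer(0), stem_bp = integer(0),
                      loop_nt = integer(0), mismatches = integer(0),
                      span_nt = integer(0), score = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(genes)) return(empty)
  hits <- lapply(seq_len(nrow(genes)), function(i)
    scan_secis(genes[i, ], genome, window_nt = window_nt, params = params))
  do.call(rbind, c(list(empty), hits))
}
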