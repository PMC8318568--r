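# Readthrough-aware exhaustive ORF enumeration.

.START_CODONS <- c("ATG", "GTG", "TTG")

# normalize genome input to a named uppercase character vector
.as_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) genome <- as.character(genome)
  if (is.character(genome) && is.null(names(genome)) && length(genome) == 1L)
    names(genome) <- "contig_1"
  if (!is.character(genome) || length(genome) == 0L || is.null(names(genome)))
    stop("genome must be a named character vector or DNAStringSet")
  if (anyDuplicated(names(genome)))
    stop("contig ids must be unique")
  genome <- toupper(genome)
  for (i in seq_along(genome)) .check_dna(genome[[i]], names(genome)[i])
  genome
}

#' Enumerate open reading frames under a readthrough-aware table
#'
#' Scans all six frames of every contig for ORFs that begin at a bacterial
#' start codon (ATG/GTG/TTG), end at a non-readthrough stop codon, and pass
#' through at most `max_readthrough` readthrough codons. One ORF is reported
#' per terminal stop: the one with the leftmost qualifying start in reading
#' direction. Readthrough codons inside an ORF are recorded as events and
#' appear as `O`/`U` in the protein.
#'
#' @param genome Named character vector of contig sequences (or a
#'   `DNAStringSet`); a single unnamed string is accepted.
#' @param table A [translation_table()].
#' @param min_len_codons Minimum protein length in amino acids (terminal
#'   stop excluded). Default 60.
#' @param max_readthrough Maximum number of readthrough codons per ORF.
#' @return A data.frame of class `gce_gene_calls` with columns `gene_id`,
#'   `contig`, `start`, `end` (1-based inclusive genomic coordinates, stop
#'   codon included), `strand`, `protein`, `n_events`, and a list-column
#'   `events` (each a data.frame with `genomic_pos` of the codon's first
#'   base in reading direction, `codon`, `letter`, `protein_pos`), sorted
#'   by (contig, start).
#' @export
find_orfs <- function(genome, table = translation_table(),
                      min_len_codons = 60L, max_readthrough = 2L) {
  genome <- .as_genome(genome)
  stopifnot(inherits(table, "gce_translation_table"),
            min_len_codons >= 2L, max_readthrough >= 0L)
  lookup <- .codon_lookup(table)
  codid <- function(cod) sum(c(16L, 4L, 1L) * .encode_dna(cod))
  start_ids <- vapply(.START_CODONS, codid, integer(1))
  stop_ids <- vapply(c("TAA", "TAG", "TGA"), codid, integer(1))
  rt_ids <- if (length(table$readthrough))
    vapply(names(table$readthrough), codid, integer(1)) else integer(0)
  term_ids <- setdiff(stop_ids, rt_ids)
  id2codon <- names(sort(c(start_ids, stop_ids)))  # only needed for rt codons
  codon_str <- character(65)
  for (cod in names(table$readthrough)) codon_str[codid(cod) + 1L] <- cod

  rows <- list()
  for (cname in names(genome)) {
    L <- nchar(genome[[cname]])
    for (strand in c("+", "-")) {
      sseq <- if (strand == "+") genome[[cname]] else
        reverse_complement(genome[[cname]])
      enc <- .encode_dna(sseq)
      for (f in 0:2) {
        if (L - f < 6L) next
        ids <- .codon_ids(enc, f)
        ncod <- length(ids)
        aa <- lookup[ids + 1L]
        starts <- which(ids %in% start_ids)
        terms <- which(ids %in% term_ids)
        rts <- which(ids %in% rt_ids)
        if (!length(terms) || !length(starts)) next
        prev <- 0L
        for (tj in terms) {
          barrier <- prev
          prev <- tj
          ri_lo <- findInterval(barrier, rts) + 1L
          ri_hi <- findInterval(tj - 1L, rts)
          nrt <- ri_hi - ri_lo + 1L
          minallowed <- if (nrt > max_readthrough)
            rts[ri_hi - max_readthrough] + 1L else barrier + 1L
          si <- findInterval(minallowed - 1L, starts) + 1L
          if (si > length(starts)) next
          i <- starts[si]
          plen <- tj - i
          if (i >= tj || plen < min_len_codons) next
          ev_lo <- findInterval(i, rts) + 1L
          ev <- if (ev_lo <= ri_hi) rts[ev_lo:ri_hi] else integer(0)
          str_start <- f + 3L * (i - 1L) + 1L
          str_end <- f + 3L * tj
          if (strand == "+") {
            gs <- str_start; ge <- str_end
            ev_gpos <- f + 3L * (ev - 1L) + 1L
          } else {
            gs <- L - str_end + 1L; ge <- L - str_start + 1L
            ev_gpos <- L - (f + 3L * (ev - 1L) + 1L) + 1L
          }
          events <- data.frame(
            genomic_pos = ev_gpos,
            codon = codon_str[ids[ev] + 1L],
            letter = aa[ev],
            protein_pos = ev - i + 1L,
            stringsAsFactors = FALSE)
          rows[[length(rows) + 1L]] <- list(
            contig = cname, start = gs, end = ge, strand = strand,
            protein = paste(aa[i:(tj - 1L)], collapse = ""),
            n_events = nrow(events), events = events)
        }
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(gene_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), protein = character(0),
                      n_events = integer(0), stringsAsFactors = FALSE)
    out$events <- list()
    class(out) <- c("gce_gene_calls", "data.frame")
    return(out)
  }
  out <- data.frame(
    contig = vapply(rows, `[[`, character(1), "contig"),
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    protein = vapply(rows, `[[`, character(1), "protein"),
    n_events = vapply(rows, `[[`, integer(1), "n_events"),
    stringsAsFactors = FALSE)
  out$events <- lapply(rows, `[[`, "events")
  ord <- order(out$contig, out$start, out$end, out$strand)
  out <- out[ord, , drop = FALSE]
  out$gene_id <- sprintf("%s_g%05d", out$contig, seq_len(nrow(out)))
  rownames(out) <- NULL
  out <- out[, c("gene_id", "contig", "start", "end", "strand", "protein",
                 "n_events", "events")]
  class(out) <- c("gce_gene_calls", "data.frame")
  out
}

# genomic span of one gene call, in reading direction
.gene_cds <- function(gene, genome) {
  s <- substr(genome[[gene$contig]], gene$start, gene$end)
  if (gene$strand == "-") s <- reverse_complement(s) else s
}
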