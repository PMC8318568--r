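# Fragment-based ANI and reciprocal-best-hit AAI, Goris-style conventions:
# 1020-nt non-overlapping fragments, 70% identity over 70% of the fragment.

.ANI_DEFAULTS <- list(fragment = 1020L, k = 15L, stride = 60L,
                      min_identity = 70, min_coverage = 0.7, pad = 30L)

# chop contigs into consecutive full-length fragments
.fragments <- function(genome, fragment) {
  out <- character(0)
  for (cname in names(genome)) {
    L <- nchar(genome[[cname]])
    nfrag <- L %/% fragment
    if (nfrag < 1L) next
    starts <- (seq_len(nfrag) - 1L) * fragment + 1L
    fr <- substring(genome[[cname]], starts, starts + fragment - 1L)
    names(fr) <- sprintf("%s|%d", cname, starts)
    out <- c(out, fr)
  }
  out
}

# ungapped identity of `frag` at every position of `subject`; returns
# best list(identity, pos) -- the exhaustive oracle path
.best_match_exhaustive <- function(frag, subject_set) {
  n <- nchar(frag)
  fr <- strsplit(frag, "")[[1]]
  best <- list(identity = -1, pos = NA_integer_, contig = NA_character_,
               strand = NA_character_)
  for (cname in names(subject_set)) {
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") subject_set[[cname]] else
        reverse_complement(subject_set[[cname]])
      L <- nchar(subj)
      if (L < n) next
      sv <- strsplit(subj, "")[[1]]
      for (p in seq_len(L - n + 1L)) {
        id <- 100 * sum(fr == sv[p:(p + n - 1L)]) / n
        if (id > best$identity)
          best <- list(identity = id, pos = p, contig = cname,
                       strand = strand)
      }
    }
  }
  if (best$identity < 0) NULL else best
}

# gapped global(fragment)-local(window) extension around a seed diagonal
.extend_identity <- function(frag, subj, diag, pars) {
  n <- nchar(frag)
  lo <- max(1L, diag + 1L - pars$pad)
  hi <- min(length(subj), diag + n + pars$pad)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(frag), subj[lo:hi], type = "global-local",
    substitutionMatrix = .dna_submat(), gapOpening = 6, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  list(identity = 100 * sum(pa == sa & pa != "-") / length(pa), pos = lo)
}

# seed-and-extend best matches for all fragments at once: one dictionary
# of every fragment's k-mer seeds, one matchPDict per contig and strand,
# diagonal voting per fragment, then a gapped extension of the top
# diagonal of each (fragment, contig, strand) with seed hits
.best_matches_seeded <- function(frags, gb, pars) {
  nfrag <- length(frags)
  if (!nfrag) return(list())
  offs <- seq(1L, pars$fragment - pars$k + 1L, by = pars$stride)
  seed_frag <- rep(seq_len(nfrag), each = length(offs))
  seed_off <- rep(offs, nfrag)
  seeds <- unname(substring(frags[seed_frag], seed_off,
                            seed_off + pars$k - 1L))
  ok <- !grepl("N", seeds, fixed = TRUE)
  if (!any(ok)) return(vector("list", nfrag))
  seeds <- seeds[ok]; seed_frag <- seed_frag[ok]; seed_off <- seed_off[ok]
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
  best <- vector("list", nfrag)
  for (strand in c("+", "-")) {
    for (cname in names(gb)) {
      subj <- Biostrings::DNAString(
        if (strand == "+") gb[[cname]] else
          reverse_complement(gb[[cname]]))
      mh <- Biostrings::matchPDict(pd, subj)
      nhit <- lengths(mh)
      if (!sum(nhit)) next
      hit_seed <- rep(seq_along(nhit), nhit)
      hit_start <- unlist(lapply(which(nhit > 0), function(i)
        BiocGenerics::start(mh[[i]])), use.names = FALSE)
      hit_frag <- seed_frag[hit_seed]
      hit_diag <- hit_start - seed_off[hit_seed]
      for (f in unique(hit_frag)) {
        dtab <- sort(table(hit_diag[hit_frag == f]), decreasing = TRUE)
        ext <- .extend_identity(frags[[f]], subj,
                                as.integer(names(dtab)[1]), pars)
        cand <- list(identity = ext$identity, pos = ext$pos,
                     contig = cname, strand = strand)
        if (is.null(best[[f]]) || cand$identity > best[[f]]$identity)
          best[[f]] <- cand
      }
    }
  }
  best
}

.dna_submat <- function() {
  if (!is.null(.gce_env$dnamat)) return(.gce_env$dnamat)
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(b, b))
  diag(m) <- 1
  m["N", ] <- -1; m[, "N"] <- -1
  .gce_env$dnamat <- m
  m
}

.direction_ani <- function(ga, gb, pars, exhaustive) {
  frags <- .fragments(ga, pars$fragment)
  matches <- if (exhaustive) lapply(frags, .best_match_exhaustive, gb) else
    .best_matches_seeded(frags, gb, pars)
  ids <- numeric(0)
  for (best in matches) {
    if (is.null(best)) next
    if (best$identity >= pars$min_identity) ids <- c(ids, best$identity)
  }
  list(total = length(frags), used = length(ids),
       value = if (length(ids)) mean(ids) else NA_real_)
}

#' Fragment-based average nucleotide identity between two genomes
#'
#' Chops each genome into consecutive 1020-nt fragments and finds each
#' fragment's best match in the other genome (exact 15-mer seeds with
#' diagonal voting and a gapped extension; `exhaustive = TRUE` scans every
#' position, for small inputs and validation). A fragment counts when its
#' best match reaches 70% identity over at least 70% of its length
#' (fragments are aligned end-to-end, so coverage is complete whenever a
#' match is found). The two-way ANI is the mean of the two direction
#' values weighted by their fragment counts. When no fragment qualifies
#' the result is undefined (`NA`), never 0.
#'
#' @param genome_a,genome_b Named character vectors of contigs (or
#'   `DNAStringSet`s).
#' @param exhaustive Use the all-positions oracle search instead of seeded
#'   search.
#' @param params Parameter list (fragment length, seed k, stride,
#'   identity/coverage filters).
#' @return Object of class `gce_comparison` with `ani_percent`,
#'   `fragments_total`, `fragments_used`, `direction_values`.
#' @export
ani <- function(genome_a, genome_b, exhaustive = FALSE,
                params = .ANI_DEFAULTS) {
  ga <- .as_genome(genome_a)
  gb <- .as_genome(genome_b)
  ab <- .direction_ani(ga, gb, params, exhaustive)
  ba <- .direction_ani(gb, ga, params, exhaustive)
  tot_used <- ab$used + ba$used
  ani_val <- if (tot_used == 0L) NA_real_ else
    (ifelse(ab$used, ab$value, 0) * ab$used +
     ifelse(ba$used, ba$value, 0) * ba$used) / tot_used
  structure(list(
    ani_percent = ani_val,
    fragments_total = ab$total + ba$total,
    fragments_used = tot_used,
    direction_values = c(a_to_b = ab$value, b_to_a = ba$value),
    direction_counts = c(a_to_b = ab$used, b_to_a = ba$used)),
    class = "gce_comparison")
}

# identity/coverage of best hits of each query against a target proteome
.best_hits <- function(qa, tb, min_identity, min_coverage) {
  hits <- data.frame(query = character(0), target = character(0),
                     identity = numeric(0), stringsAsFactors = FALSE)
  for (qn in names(qa)) {
    best_id <- -1; best_t <- NA_character_
    for (tn in names(tb)) {
      aln <- global_align(qa[[qn]], tb[[tn]])
      a <- strsplit(aln$aligned_a, "")[[1]]
      b <- strsplit(aln$aligned_b, "")[[1]]
      cov <- sum(a != "-" & b != "-") /
        min(nchar(qa[[qn]]), nchar(tb[[tn]]))
      if (cov < min_coverage) next
      if (aln$percent_identity < min_identity) next
      if (aln$percent_identity > best_id) {
        best_id <- aln$percent_identity; best_t <- tn
      }
    }
    if (!is.na(best_t))
      hits <- rbind(hits, data.frame(query = qn, target = best_t,
                                     identity = best_id,
                                     stringsAsFactors = FALSE))
  }
  hits
}

#' Reciprocal-best-hit average amino acid identity between two proteomes
#'
#' Best hits are computed in both directions by global alignment identity
#' (qualifying hits need at least 30% identity over at least 70% of the
#' shorter sequence); mutual best hits define the RBH set, and the two-way
#' AAI is the mean identity over RBHs (equivalently, the hit-count-weighted
#' mean of the two direction values). Undefined (`NA`) when no RBH passes
#' the filters.
#'
#' @param proteome_a,proteome_b Named character vectors of protein
#'   sequences (letters `O`/`U` legal).
#' @param min_identity,min_coverage Qualifying filters (percent identity,
#'   fraction of the shorter sequence aligned).
#' @return Object of class `gce_comparison` with `aai_percent`,
#'   `rbh_count`, `direction_values`.
#' @export
aai <- function(proteome_a, proteome_b, min_identity = 30,
                min_coverage = 0.7) {
  if (!length(proteome_a) || !length(proteome_b))
    stop("proteomes must be non-empty")
  pa <- setNames(toupper(proteome_a), names(proteome_a))
  pb <- setNames(toupper(proteome_b), names(proteome_b))
  ab <- .best_hits(pa, pb, min_identity, min_coverage)
  ba <- .best_hits(pb, pa, min_identity, min_coverage)
  rbh <- merge(ab, ba, by.x = c("query", "target"),
               by.y = c("target", "query"))
  rbh_count <- nrow(rbh)
  structure(list(
    aai_percent = if (rbh_count) mean(rbh$identity.x) else NA_real_,
    rbh_count = rbh_count,
    direction_values = c(a_to_b = if (nrow(ab)) mean(ab$identity) else
      NA_real_, b_to_a = if (nrow(ba)) mean(ba$identity) else NA_real_),
    direction_counts = c(a_to_b = nrow(ab), b_to_a = nrow(ba))),
    class = "gce_comparison")
}

#' @export
print.gce_comparison <- function(x, ...) {
  if (!is.null(x$ani_percent))
    cat(sprintf("ANI: %s over %d/%d fragments\n",
                ifelse(is.na(x$ani_percent), "undefined",
                       sprintf("%.2f%%", x$ani_percent)),
                x$fragments_used, x$fragments_total))
  if (!is.null(x$aai_percent))
    cat(sprintf("AAI: %s over %d reciprocal best hits\n",
                ifelse(is.na(x$aai_percent), "undefined",
                       sprintf("%.2f%%", x$aai_percent)), x$rbh_count))
  invisible(x)
}
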