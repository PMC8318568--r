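# Rule-based cloverleaf folding and Pyl/Sec tRNA classification.
#
# Search windows bracket canonical tRNA dimensions plus the deviations seen
# in natural Pyl and Sec tRNAs: acceptor stem 6-9 bp, acceptor-to-D spacer
# 1-3 nt, D stem 3-4 bp, D loop 4-12 nt, anticodon stem 5-6 bp, anticodon
# loop 7 nt (anticodon at loop positions 3-5), variable region 3-23 nt
# (called an arm when >= 10 nt with an internal stem >= 3 bp), T stem
# 4-5 bp, T loop 5-9 nt. All stem positions must close with Watson-Crick
# or G.U wobble pairs; pair_score counts paired nucleotides of the four
# canonical stems (2 per bp, wobble included); the variable-arm stem is
# reported for classification but not scored.

.TRNA_DEFAULTS <- list(min_len = 60L, max_len = 120L, min_score = 48L)

.check_rna_dna <- function(seq, what = "seq") {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq) || !nzchar(seq))
    stop(what, " must be a single non-empty string")
  if (grepl("[^ACGTUN]", toupper(seq)))
    stop(what, " contains characters outside {A,C,G,T,U,N}")
  toupper(seq)
}

#' Fold a candidate sequence into the best-scoring cloverleaf
#'
#' Exhaustive search over all arm-length windows; a layout is legal only if
#' every stem position closes with a Watson-Crick or G.U pair. Returns the
#' layout maximizing `pair_score` (total paired nucleotides; ties broken by
#' fewer wobble pairs), or `NULL` when no legal layout exists.
#'
#' DNA input is treated as the coding strand; the anticodon is reported as
#' RNA (T read as U).
#'
#' @param seq DNA or RNA string, 60-120 nt.
#' @return A list with arm lengths (`acceptor_stem`, `acc_d_spacer`,
#'   `d_stem`, `d_loop`, `ac_stem`, `ac_loop`, `var_region`, `var_arm`,
#'   `var_stem`, `t_stem`, `t_loop`), `pair_score`, `gu_pairs`, and
#'   `anticodon`, or `NULL`.
#' @export
fold_cloverleaf <- function(seq) {
  seq <- .check_rna_dna(seq)
  n <- nchar(seq)
  if (n < 60L || n > 120L)
    stop("sequence must be 60-120 nt, got ", n)
  .fold_cloverleaf_cpp(seq)
}

#' Classify a folded tRNA candidate as standard, pyl, sec or ambiguous
#'
#' Pyl tRNA: CUA anticodon together with its structural hallmark (6-bp
#' anticodon stem, i.e. one extra nucleotide, or a single-nucleotide spacer
#' between the acceptor and D arms). Sec tRNA: UCA anticodon together with
#' a variable arm (variable region >= 10 nt containing a stem >= 3 bp)
#' replacing the short variable loop. A reassigned anticodon without its
#' hallmark is `ambiguous`; any other anticodon is `standard`.
#'
#' @param cand A layout as returned by [fold_cloverleaf()] (a list with at
#'   least `anticodon`, `ac_stem`, `acc_d_spacer`, `var_region`, `var_arm`,
#'   `var_stem`).
#' @return One of `"standard"`, `"pyl"`, `"sec"`, `"ambiguous"`.
#' @export
classify_trna <- function(cand) {
  stopifnot(is.list(cand), !is.null(cand$anticodon))
  ac <- toupper(chartr("T", "U", cand$anticodon))
  if (ac == "CUA") {
    if (isTRUE(cand$ac_stem == 6L) || isTRUE(cand$acc_d_spacer == 1L))
      return("pyl")
    return("ambiguous")
  }
  if (ac == "UCA") {
    if (isTRUE(cand$var_arm) && cand$var_region >= 10L &&
        cand$var_stem >= 3L)
      return("sec")
    return("ambiguous")
  }
  "standard"
}

#' Scan a genome for tRNA genes by constrained cloverleaf folding
#'
#' Slides 60-120 nt windows over both strands of every contig, folds each
#' window, and reports non-overlapping candidates with
#' `pair_score >= min_score`, selected greedily by descending score (ties:
#' fewer wobble pairs, then leftmost). Candidates on opposite strands may
#' overlap; candidates on the same strand never do.
#'
#' @param genome Named character vector of contigs (or `DNAStringSet`).
#' @param min_score Minimum pair score (paired nucleotides). Default 48.
#' @param min_len,max_len Window length bounds in nt.
#' @return data.frame with columns `contig`, `start`, `end`, `strand`,
#'   `anticodon`, `class`, `pair_score`, `gu_pairs` and the arm-layout
#'   columns of [fold_cloverleaf()].
#' @export
scan_genome_trnas <- function(genome,
                              min_score = .TRNA_DEFAULTS$min_score,
                              min_len = .TRNA_DEFAULTS$min_len,
                              max_len = .TRNA_DEFAULTS$max_len) {
  genome <- .as_genome(genome)
  hits <- list()
  for (cname in names(genome)) {
    L <- nchar(genome[[cname]])
    for (strand in c("+", "-")) {
      sseq <- if (strand == "+") genome[[cname]] else
        reverse_complement(genome[[cname]])
      df <- .scan_trna_cpp(sseq, min_len, max_len, min_score)
      if (!nrow(df)) next
      layouts <- attr(df, "layouts")
      for (k in seq_len(nrow(df))) {
        lay <- layouts[[k]]
        s <- df$start[k]; e <- df$start[k] + df$length[k] - 1L
        if (strand == "-") { gs <- L - e + 1L; ge <- L - s + 1L }
        else { gs <- s; ge <- e }
        hits[[length(hits) + 1L]] <- c(
          list(contig = cname, start = gs, end = ge, strand = strand),
          lay[c("anticodon", "pair_score", "gu_pairs", "acceptor_stem",
                "acc_d_spacer", "d_stem", "d_loop", "ac_stem", "ac_loop",
                "var_region", "var_arm", "var_stem", "t_stem", "t_loop")])
      }
    }
  }
  cols <- c("contig", "start", "end", "strand", "anticodon", "class",
            "pair_score", "gu_pairs", "acceptor_stem", "acc_d_spacer",
            "d_stem", "d_loop", "ac_stem", "ac_loop", "var_region",
            "var_arm", "var_stem", "t_stem", "t_loop")
  if (!length(hits)) {
    out <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      anticodon = character(0), class = character(0),
                      pair_score = integer(0), gu_pairs = integer(0),
                      acceptor_stem = integer(0), acc_d_spacer = integer(0),
                      d_stem = integer(0), d_loop = integer(0),
                      ac_stem = integer(0), ac_loop = integer(0),
                      var_region = integer(0), var_arm = logical(0),
                      var_stem = integer(0), t_stem = integer(0),
                      t_loop = integer(0), stringsAsFactors = FALSE)
    return(out)
  }
  df <- do.call(rbind, lapply(hits, function(h)
    as.data.frame(h, stringsAsFactors = FALSE)))
  df$class <- vapply(seq_len(nrow(df)), function(k)
    classify_trna(as.list(df[k, ])), character(1))
  # greedy non-overlap selection per contig/strand
  ord <- order(-df$pair_score, df$gu_pairs, df$contig, df$start)
  df <- df[ord, , drop = FALSE]
  keep <- logical(nrow(df))
  for (k in seq_len(nrow(df))) {
    sel <- which(keep & df$contig == df$contig[k] &
                   df$strand == df$strand[k])
    if (!length(sel) || all(df$start[sel] > df$end[k] |
                            df$end[sel] < df$start[k]))
      keep[k] <- TRUE
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$contig, df$start), cols, drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Construct a tRNA gene sequence from an explicit cloverleaf layout
#'
#' Builds a DNA sequence whose stems close perfectly (Watson-Crick, with an
#' optional number of G.U wobble pairs in the acceptor stem) and whose loop
#' and spacer nucleotides are drawn at random, with the given anticodon at
#' loop positions 3-5. Used by the synthetic-genome generator and by
#' round-trip folding tests.
#'
#' @param layout List with `acceptor_stem`, `acc_d_spacer`, `d_stem`,
#'   `d_loop`, `ac_stem`, `var_region`, `t_stem`, `t_loop`, and for a
#'   variable arm `var_stem` plus `var_loop`.
#' @param anticodon 3-letter anticodon (RNA or DNA spelling).
#' @param gu_acceptor Number of wobble pairs to place in the acceptor stem.
#' @return DNA string.
#' @export
make_trna_seq <- function(layout, anticodon = "CAU", gu_acceptor = 0L) {
  l <- layout
  need <- c("acceptor_stem", "acc_d_spacer", "d_stem", "d_loop", "ac_stem",
            "var_region", "t_stem", "t_loop")
  stopifnot(all(need %in% names(l)))
  anticodon <- chartr("U", "T", toupper(anticodon))
  stopifnot(nchar(anticodon) == 3L)
  rand <- function(n) if (n > 0)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    else ""
  # left arm avoiding accidental reassigned-anticodon content is not
  # needed; stems pair perfectly by construction
  stem <- function(n) rand(n)
  comp <- function(s) if (nzchar(s)) reverse_complement(s) else ""
  acc <- stem(l$acceptor_stem)
  accp <- comp(acc)
  if (gu_acceptor > 0L) {
    # turn the first gu_acceptor G or C positions of the 5' arm into G.U
    ch <- strsplit(acc, "")[[1]]
    chp <- strsplit(accp, "")[[1]]  # chp[k] pairs ch[n+1-k]
    n <- length(ch)
    placed <- 0L
    for (k in seq_len(n)) {
      if (placed >= gu_acceptor) break
      if (ch[k] == "G") { chp[n + 1L - k] <- "T"; placed <- placed + 1L }
      else if (ch[k] == "T") { chp[n + 1L - k] <- "G"; placed <- placed + 1L }
      else if (ch[k] == "C") { ch[k] <- "T"; chp[n + 1L - k] <- "G"
        placed <- placed + 1L }
      else { ch[k] <- "G"; chp[n + 1L - k] <- "T"; placed <- placed + 1L }
    }
    acc <- paste(ch, collapse = ""); accp <- paste(chp, collapse = "")
  }
  d <- stem(l$d_stem)
  ac <- stem(l$ac_stem)
  t <- stem(l$t_stem)
  acloop <- paste0(rand(2), anticodon, rand(2))
  varreg <- if (!is.null(l$var_stem) && !is.null(l$var_loop) &&
                l$var_stem >= 3L) {
    vs <- stem(l$var_stem)
    pad <- l$var_region - 2L * l$var_stem - l$var_loop
    stopifnot(pad >= 0L)
    paste0(vs, rand(l$var_loop), comp(vs), rand(pad))
  } else rand(l$var_region)
  paste0(acc, rand(l$acc_d_spacer), d, rand(l$d_loop), comp(d),
         ac, acloop, comp(ac), varreg, t, rand(l$t_loop), comp(t), accp)
}
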