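# Seeded synthetic genomes with planted genetic-code-expansion features,
# decoys and machine-readable truth tables.
#
# The default benchmark emulates the study conditions of a recoded
# deltaproteobacterial MAG: 200-kb contig at 41% GC, trimethylamine
# methyltransferase genes carrying pyrrolysine at residue 327 of 485
# (archaeal-style reference: 334 of 483), selenoprotein genes with an
# in-frame UGA followed by a SECIS-like hairpin, atypical Sec/Pyl tRNAs,
# a machinery cassette with the cognate corrinoid within <10 genes of the
# methyltransferase anchor, and decoys: UGA genes with shuffled downstream
# windows and pyrrolysine-free glycine betaine methyltransferase homologs.

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")

#' Specification of a synthetic benchmark genome
#'
#' @param genome_length Total contig length in nt (default 200 kb).
#' @param gc_fraction Background GC content (default 0.41).
#' @param n_selenoproteins Planted selenoprotein genes (U event + SECIS).
#' @param n_pyl Planted pyrrolysine methyltransferase genes.
#' @param n_decoy_uga Decoy genes with an in-frame UGA but no hairpin.
#' @param n_decoy_gbmt Decoy methyltransferase homologs without an amber
#'   codon.
#' @param n_sec_trna,n_pyl_trna,n_std_trna Planted tRNA gene counts.
#' @param machinery Plant the Sec/Pyl machinery cassette in the annotation
#'   table.
#' @param pyl_pos,pyl_len Pyrrolysine residue position and protein length
#'   of planted methyltransferases (default 327 of 485).
#' @param ref_pyl_pos,ref_pyl_len Same for the archaeal-style reference
#'   (default 334 of 483).
#' @param sel_len,sel_u_pos Selenoprotein length and Sec position.
#' @param secis_offset,secis_stem,secis_loop Planted hairpin geometry (nt
#'   downstream of the UGA, stem bp, loop nt).
#' @param seed Integer seed; every downstream draw is reproducible from it.
#' @return List of class `gce_plant_spec`.
#' @export
plant_spec <- function(genome_length = 200000L, gc_fraction = 0.41,
                       n_selenoproteins = 10L, n_pyl = 5L,
                       n_decoy_uga = 5L, n_decoy_gbmt = 3L,
                       n_sec_trna = 1L, n_pyl_trna = 1L, n_std_trna = 3L,
                       machinery = TRUE,
                       pyl_pos = 327L, pyl_len = 485L,
                       ref_pyl_pos = 334L, ref_pyl_len = 483L,
                       sel_len = 240L, sel_u_pos = 120L,
                       secis_offset = 18L, secis_stem = 18L,
                       secis_loop = 6L, seed = 1L) {
  stopifnot(gc_fraction > 0, gc_fraction < 1, genome_length > 0,
            n_selenoproteins >= 0, n_pyl >= 0, n_decoy_uga >= 0,
            n_decoy_gbmt >= 0, pyl_pos < pyl_len, sel_u_pos < sel_len,
            secis_offset %% 3L == 0L, (2L * secis_stem + secis_loop) %% 3L
            == 0L)
  structure(as.list(environment()), class = "gce_plant_spec")
}

.rand_dna <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.rand_protein <- function(n) paste(sample(.AA20, n, replace = TRUE),
                                   collapse = "")

# codons per amino acid, stop codons excluded; O -> TAG, U -> TGA
.codon_choices <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc <- Biostrings::GENETIC_CODE
    by_aa <- split(names(gc), unname(gc))
    by_aa[["*"]] <- NULL
    by_aa[["O"]] <- "TAG"
    by_aa[["U"]] <- "TGA"
    cache <<- by_aa
    cache
  }
})

# reverse-translate with synonymous codons weighted toward the target GC
.reverse_translate <- function(protein, gc) {
  choices <- .codon_choices()
  aas <- strsplit(protein, "")[[1]]
  cod <- vapply(aas, function(a) {
    cs <- choices[[a]]
    if (is.null(cs)) stop("cannot reverse-translate letter ", a)
    if (length(cs) == 1L) return(cs)
    gcc <- vapply(strsplit(cs, ""), function(b)
      sum(b %in% c("G", "C")), numeric(1))
    w <- gc^gcc * (1 - gc)^(3 - gcc)
    sample(cs, 1L, prob = w)
  }, character(1), USE.NAMES = FALSE)
  paste(cod, collapse = "")
}

# substitute a fraction of residues, never touching `protect` positions or
# O/U residues
.mutate_protein_string <- function(p, rate, protect = integer(0)) {
  a <- strsplit(p, "")[[1]]
  ok <- which(!(seq_along(a) %in% protect) & a %in% .AA20)
  hit <- ok[runif(length(ok)) < rate]
  for (i in hit) a[i] <- sample(setdiff(.AA20, a[i]), 1L)
  paste(a, collapse = "")
}

# build a selenoprotein (or decoy-UGA) CDS; returns list(seq, protein)
.build_sel_gene <- function(spec, with_hairpin) {
  gc <- spec$gc_fraction
  u <- spec$sel_u_pos
  offset_res <- spec$secis_offset %/% 3L
  hp_res <- (2L * spec$secis_stem + spec$secis_loop) %/% 3L
  for (try in 1:200) {
    front <- paste0("M", .rand_protein(u - 2L))
    nt_front <- paste0("ATG", .reverse_translate(substr(front, 2L,
                                                        nchar(front)), gc))
    nt_off <- .reverse_translate(.rand_protein(offset_res), gc)
    if (with_hairpin) {
      repeat {
        stem <- .rand_dna(spec$secis_stem, gc)
        hp <- paste0(stem, .rand_dna(spec$secis_loop, gc),
                     reverse_complement(stem))
        cods <- substring(hp, seq(1L, nchar(hp) - 2L, 3L),
                          seq(3L, nchar(hp), 3L))
        if (!any(cods %in% c("TAA", "TAG", "TGA"))) break
      }
    } else {
      hp <- .reverse_translate(.rand_protein(hp_res), gc)
    }
    tail_res <- spec$sel_len - u - offset_res - hp_res
    nt_tail <- .reverse_translate(.rand_protein(tail_res), gc)
    cds <- paste0(nt_front, "TGA", nt_off, hp, nt_tail, "TAA")
    if (!with_hairpin) break
    # validate the planted hairpin geometry against the scan defaults
    win_start <- nchar(nt_front) + 3L + 1L
    win <- substr(cds, win_start, win_start + secis_defaults()$window_nt
                  - 1L)
    got <- find_hairpin(win, max_start = secis_defaults()$max_offset + 1L)
    geom_ok <- !is.null(got) && got$start == spec$secis_offset + 1L &&
      got$stem_bp == spec$secis_stem && got$mismatches == 0L &&
      got$score == 2L * spec$secis_stem  # perfect Watson-Crick stem
    # a stem-loop is strand-symmetric, so forbid chance UGA triggers that
    # would let off-frame or reverse-strand ORFs claim the planted hairpin:
    # the only TGA trinucleotide within 43 nt upstream of the hairpin must
    # be the planted codon, and no TCA (a reverse-strand TGA) may occur
    # within 44 nt downstream of it
    hs <- win_start + spec$secis_offset
    he <- hs + 2L * spec$secis_stem + spec$secis_loop - 1L
    upstream <- substr(cds, max(1L, hs - 43L), hs + 1L)
    n_tga_up <- length(gregexpr("(?=TGA)", upstream, perl = TRUE)[[1]]) -
      (gregexpr("(?=TGA)", upstream, perl = TRUE)[[1]][1] == -1L)
    downstream <- substr(cds, he - 1L, min(nchar(cds), he + 44L))
    has_tca_down <- grepl("TCA", downstream, fixed = TRUE)
    if (geom_ok && n_tga_up == 1L && !has_tca_down) break
    if (try == 200) stop("failed to plant a clean SECIS hairpin")
  }
  prot <- translate(substr(cds, 1L, nchar(cds) - 3L), translation_table("opal"))
  list(seq = cds, protein = prot)
}

.build_pyl_gene <- function(template, spec) {
  # position 1 is protected so the planted ATG start survives mutation
  prot <- .mutate_protein_string(template, 0.04,
                                 protect = c(1L, (spec$pyl_pos - 5L):
                                               (spec$pyl_pos + 25L)))
  list(seq = paste0(.reverse_translate(prot, spec$gc_fraction), "TAA"),
       protein = prot)
}

.build_gbmt_gene <- function(template, spec) {
  a <- strsplit(template, "")[[1]]
  a[a == "O"] <- "K"
  prot <- .mutate_protein_string(paste(a, collapse = ""), 0.10,
                                 protect = 1L)
  list(seq = paste0(.reverse_translate(prot, spec$gc_fraction), "TAA"),
       protein = prot)
}

# archaeal-style reference: insertions before the Pyl site and deletions
# after the conserved window shift 327/485 to 334/483
.build_pyl_reference <- function(template, spec) {
  ins_n <- spec$ref_pyl_pos - spec$pyl_pos
  del_n <- spec$pyl_len + ins_n - spec$ref_pyl_len
  stopifnot(ins_n >= 0L, del_n >= 0L)
  a <- strsplit(template, "")[[1]]
  ins_at <- spec$pyl_pos - 60L
  del_at <- spec$pyl_pos + 60L
  out <- c(a[1:(ins_at - 1L)], sample(.AA20, ins_n, replace = TRUE),
           a[ins_at:del_at], a[(del_at + del_n + 1L):length(a)])
  ref <- paste(out, collapse = "")
  stopifnot(nchar(ref) == spec$ref_pyl_len,
            substr(ref, spec$ref_pyl_pos, spec$ref_pyl_pos) == "O")
  .mutate_protein_string(ref, 0.15,
                         protect = (spec$ref_pyl_pos - 10L):(spec$ref_pyl_pos
                                                             + 25L))
}

.TRNA_LAYOUTS <- list(
  pyl = list(acceptor_stem = 9L, acc_d_spacer = 1L, d_stem = 4L,
             d_loop = 8L, ac_stem = 6L, var_region = 4L, t_stem = 5L,
             t_loop = 7L),
  sec = list(acceptor_stem = 9L, acc_d_spacer = 2L, d_stem = 4L,
             d_loop = 8L, ac_stem = 6L, var_region = 16L, var_stem = 5L,
             var_loop = 6L, t_stem = 5L, t_loop = 7L),
  standard = list(acceptor_stem = 9L, acc_d_spacer = 2L, d_stem = 4L,
                  d_loop = 8L, ac_stem = 6L, var_region = 4L, t_stem = 5L,
                  t_loop = 7L))

.build_trna <- function(class) {
  layout <- .TRNA_LAYOUTS[[class]]
  anticodon <- switch(class, pyl = "CUA", sec = "UCA",
                      standard = sample(c("CAU", "GAA", "UGC", "GGU",
                                          "UUU"), 1L))
  for (try in 1:100) {
    s <- make_trna_seq(layout, anticodon)
    f <- fold_cloverleaf(s)
    if (is.null(f)) next
    if (chartr("T", "U", f$anticodon) != chartr("T", "U", anticodon)) next
    if (classify_trna(f) != class) next
    if (f$pair_score < .TRNA_DEFAULTS$min_score) next
    return(list(seq = s, fold = f, anticodon = anticodon))
  }
  stop("failed to construct a ", class, " tRNA")
}

#' Generate a synthetic benchmark genome with planted features and truth
#'
#' Background sequence is drawn i.i.d. at the requested GC; features are
#' planted at non-overlapping loci (>= 100 nt spacers) on random strands.
#' Every planted coding gene is preceded by an in-frame TAA barrier so the
#' readthrough-aware caller recovers exactly the planted span; planted
#' hairpins and tRNAs are validated against the package's own detectors at
#' construction time. Fully reproducible from `spec$seed`.
#'
#' @param spec A [plant_spec()].
#' @return Object of class `gce_benchmark`: list with `genome` (named
#'   character), `proteins` (planted proteins, letters O/U), `references`
#'   (labeled reference proteins: archaeal-style Pyl methyltransferase and
#'   selenoprotein families), `annotations` (annotation table with the
#'   machinery cassette), `truth` (truth table data.frame), `spec`.
#' @export
generate <- function(spec = plant_spec()) {
  stopifnot(inherits(spec, "gce_plant_spec"))
  set.seed(spec$seed)
  gc <- spec$gc_fraction
  contig <- "synthetic_contig_1"

  pyl_template <- local({
    a <- strsplit(.rand_protein(spec$pyl_len), "")[[1]]
    a[1] <- "M"; a[spec$pyl_pos] <- "O"
    paste(a, collapse = "")
  })

  feats <- list()
  add <- function(class, seq, protein = NA_character_, u_pos = NA_integer_,
                  o_pos = NA_integer_, secis_offset = NA_integer_,
                  trna_class = NA_character_, pair_score = NA_integer_,
                  anticodon = NA_character_) {
    feats[[length(feats) + 1L]] <<- list(
      class = class, seq = seq, protein = protein, u_pos = u_pos,
      o_pos = o_pos, secis_offset = secis_offset, trna_class = trna_class,
      pair_score = pair_score, anticodon = anticodon)
  }
  for (i in seq_len(spec$n_selenoproteins)) {
    g <- .build_sel_gene(spec, with_hairpin = TRUE)
    add("selenoprotein", paste0("TAA", g$seq), g$protein,
        u_pos = spec$sel_u_pos, secis_offset = spec$secis_offset)
  }
  for (i in seq_len(spec$n_pyl)) {
    g <- .build_pyl_gene(pyl_template, spec)
    add("pyl_mtt", paste0("TAA", g$seq), g$protein, o_pos = spec$pyl_pos)
  }
  for (i in seq_len(spec$n_decoy_uga)) {
    g <- .build_sel_gene(spec, with_hairpin = FALSE)
    add("decoy_uga", paste0("TAA", g$seq), g$protein,
        u_pos = spec$sel_u_pos)
  }
  for (i in seq_len(spec$n_decoy_gbmt)) {
    g <- .build_gbmt_gene(pyl_template, spec)
    add("decoy_gbmt", paste0("TAA", g$seq), g$protein)
  }
  for (i in seq_len(spec$n_sec_trna)) {
    t <- .build_trna("sec")
    add("sec_trna", t$seq, trna_class = "sec",
        pair_score = t$fold$pair_score, anticodon = t$anticodon)
  }
  for (i in seq_len(spec$n_pyl_trna)) {
    t <- .build_trna("pyl")
    add("pyl_trna", t$seq, trna_class = "pyl",
        pair_score = t$fold$pair_score, anticodon = t$anticodon)
  }
  for (i in seq_len(spec$n_std_trna)) {
    t <- .build_trna("standard")
    add("std_trna", t$seq, trna_class = "standard",
        pair_score = t$fold$pair_score, anticodon = t$anticodon)
  }

  lens <- vapply(feats, function(f) nchar(f$seq), integer(1))
  n <- length(feats)
  spacer <- 100L
  need <- sum(lens) + spacer * (n + 1L)
  if (need > spec$genome_length)
    stop("genome_length ", spec$genome_length, " cannot hold ", n,
         " features needing ", need, " nt")
  ord <- sample.int(n)
  slack <- spec$genome_length - need
  cuts <- sort(sample.int(slack + 1L, n + 1L, replace = TRUE) - 1L)
  extra <- diff(c(0L, cuts))[seq_len(n + 1L)]
  extra[n + 1L] <- slack - sum(extra[seq_len(n)])
  pieces <- character(0)
  pos <- 0L
  truth <- list()
  strands <- sample(c("+", "-"), n, replace = TRUE)
  for (j in seq_len(n)) {
    i <- ord[j]
    gap <- spacer + extra[j]
    pieces <- c(pieces, .rand_dna(gap, gc))
    pos <- pos + gap
    f <- feats[[i]]
    fs <- if (strands[j] == "+") f$seq else reverse_complement(f$seq)
    pieces <- c(pieces, fs)
    flen <- nchar(f$seq)
    coding <- f$class %in% c("selenoprotein", "pyl_mtt", "decoy_uga",
                             "decoy_gbmt")
    if (coding) {
      # strip the 3-nt in-frame TAA barrier from the reported span
      if (strands[j] == "+") { gs <- pos + 4L; ge <- pos + flen }
      else { gs <- pos + 1L; ge <- pos + flen - 3L }
    } else {
      gs <- pos + 1L; ge <- pos + flen
    }
    truth[[length(truth) + 1L]] <- data.frame(
      feature_id = sprintf("feat_%03d", i), class = f$class,
      contig = contig, start = gs, end = ge, strand = strands[j],
      protein = f$protein, u_pos = f$u_pos, o_pos = f$o_pos,
      secis_offset = f$secis_offset, trna_class = f$trna_class,
      pair_score = f$pair_score, anticodon = f$anticodon,
      stringsAsFactors = FALSE)
    pos <- pos + flen
  }
  pieces <- c(pieces, .rand_dna(spec$genome_length - pos, gc))
  genome <- setNames(paste(pieces, collapse = ""), contig)
  stopifnot(nchar(genome) == spec$genome_length)
  if (length(truth)) {
    truth <- do.call(rbind, truth)
    truth <- truth[order(truth$start), , drop = FALSE]
    rownames(truth) <- NULL
  } else {
    truth <- data.frame(feature_id = character(0), class = character(0),
                        contig = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        protein = character(0), u_pos = integer(0),
                        o_pos = integer(0), secis_offset = integer(0),
                        trna_class = character(0), pair_score = integer(0),
                        anticodon = character(0), stringsAsFactors = FALSE)
  }

  proteins <- local({
    sel <- !is.na(truth$protein)
    setNames(truth$protein[sel], truth$feature_id[sel])
  })

  references <- c()
  if (spec$n_pyl > 0L)
    references["archaeal_mttB_ref"] <- .build_pyl_reference(pyl_template,
                                                            spec)
  sel_ids <- truth$feature_id[truth$class == "selenoprotein"]
  n_known <- ceiling(length(sel_ids) / 2)
  for (i in seq_len(n_known)) {
    p <- proteins[[sel_ids[i]]]
    upos <- regexpr("U", p, fixed = TRUE)[1]
    references[sprintf("sel_family_%02d", i)] <-
      .mutate_protein_string(p, 0.08, protect = upos)
  }
  truth$sel_group <- ifelse(
    truth$class == "selenoprotein",
    ifelse(truth$feature_id %in% sel_ids[seq_len(n_known)],
           "known_family", "novel"), NA_character_)

  annotations <- .build_annotations(truth, spec, contig)

  structure(list(genome = genome, proteins = proteins,
                 references = references, annotations = annotations,
                 truth = truth, spec = spec),
            class = "gce_benchmark")
}

# annotation table in genomic order, with the machinery cassette and
# filler genes interleaved around the first pyl methyltransferase anchor
.build_annotations <- function(truth, spec, contig) {
  rows <- list()
  emit <- function(gene_id, labels) {
    rows[[length(rows) + 1L]] <<- list(gene_id = gene_id,
                                       family_accessions = labels)
  }
  filler <- local({
    k <- 0L
    function() {
      k <<- k + 1L
      emit(sprintf("virt_%03d", k), "hypothetical")
    }
  })
  coding <- truth[truth$class %in% c("selenoprotein", "pyl_mtt",
                                     "decoy_uga", "decoy_gbmt"), ,
                  drop = FALSE]
  pyl_ids <- coding$feature_id[coding$class == "pyl_mtt"]
  anchor_id <- if (length(pyl_ids)) pyl_ids[1] else NA_character_
  for (i in seq_len(nrow(coding))) {
    f <- coding[i, ]
    if (spec$machinery && identical(f$feature_id, anchor_id)) {
      emit("mach_pylB", "pylB"); emit("mach_pylC", "pylC")
      emit("mach_pylD", "pylD"); emit("mach_pylS", "pylS")
      emit("mach_selA", "selA"); emit("mach_selB", "selB")
      emit("mach_selD", "selD"); filler()
      emit(f$feature_id, "mttB")          # anchor, index d
      filler()                             # d+1
      emit("mach_metH", "metH")            # d+2
      filler(); filler()                   # d+3, d+4
      emit("mach_cysA1", "TIGR00968")      # d+5
      emit("mach_cysA2", "TIGR00968")      # d+6
      emit("mach_corrinoid", "corrinoid")  # d+7
      emit("mach_ramA", "ramA")            # d+8
    } else {
      lab <- switch(f$class,
                    pyl_mtt = "mttB",
                    decoy_gbmt = "gbmt",
                    selenoprotein = "selenoprotein_family",
                    decoy_uga = "hypothetical")
      emit(f$feature_id, lab)
      if (i %% 2L == 0L) filler()
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(0), contig_id = character(0),
                      gene_index = integer(0),
                      family_accessions = character(0),
                      stringsAsFactors = FALSE))
  data.frame(
    gene_id = vapply(rows, `[[`, character(1), "gene_id"),
    contig_id = contig,
    gene_index = seq_along(rows),
    family_accessions = vapply(rows, `[[`, character(1),
                               "family_accessions"),
    stringsAsFactors = FALSE)
}

#' Mutate a genome copy by independent per-site substitutions
#'
#' Each position independently substitutes to a uniformly chosen different
#' base with probability `substitution_rate`; no indels.
#'
#' @param genome Named character vector of contigs (or `DNAStringSet`).
#' @param substitution_rate Per-site substitution probability in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return Mutated genome, same names and lengths.
#' @export
mutate_copy <- function(genome, substitution_rate, seed = NULL) {
  stopifnot(substitution_rate >= 0, substitution_rate < 1)
  genome <- .as_genome(genome)
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  out <- vapply(genome, function(s) {
    a <- strsplit(s, "")[[1]]
    hit <- which(runif(length(a)) < substitution_rate & a %in% bases)
    for (i in hit) a[i] <- sample(setdiff(bases, a[i]), 1L)
    paste(a, collapse = "")
  }, character(1))
  setNames(out, names(genome))
}

#' Mutate a proteome copy by per-residue substitutions
#'
#' Canonical residues substitute to a uniformly chosen different canonical
#' residue with probability `substitution_rate`; O, U and X are preserved.
#'
#' @param proteome Named character vector of proteins.
#' @param substitution_rate Per-residue substitution probability.
#' @param seed Optional integer seed.
#' @return Mutated proteome.
#' @export
mutate_proteins <- function(proteome, substitution_rate, seed = NULL) {
  stopifnot(substitution_rate >= 0, substitution_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  setNames(vapply(proteome, .mutate_protein_string, character(1),
                  rate = substitution_rate), names(proteome))
}
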