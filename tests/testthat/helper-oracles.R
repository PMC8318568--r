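# Independent oracles used to check the package implementations.

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rand_protein <- function(n) {
  paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], n,
               replace = TRUE), collapse = "")
}

# --- six-frame ORF oracle: forward-looking per start codon ---------------
# For every start codon, walk forward to the first non-readthrough stop;
# the span qualifies if the readthrough count is within bounds; per
# terminal stop keep the leftmost qualifying start. Structurally different
# from find_orfs (which works backwards per stop).
oracle_orfs <- function(genome, table, min_len_codons, max_readthrough) {
  codmap <- Biostrings::GENETIC_CODE
  rt <- names(table$readthrough)
  stops <- c("TAA", "TAG", "TGA")
  terms <- setdiff(stops, rt)
  starts3 <- c("ATG", "GTG", "TTG")
  res <- list()
  for (cname in names(genome)) {
    L <- nchar(genome[[cname]])
    for (strand in c("+", "-")) {
      s <- if (strand == "+") genome[[cname]] else
        reverse_complement(genome[[cname]])
      for (f in 0:2) {
        ncod <- (L - f) %/% 3
        if (ncod < 2) next
        pos <- f + 3 * (seq_len(ncod) - 1) + 1
        cods <- substring(s, pos, pos + 2)
        is_term <- cods %in% terms
        is_rt <- cods %in% rt
        is_start <- cods %in% starts3
        nxt <- rep(NA_integer_, ncod)   # next terminal stop at/after i
        nextt <- NA_integer_
        for (i in ncod:1) {
          if (is_term[i]) nextt <- i
          nxt[i] <- nextt
        }
        crt <- cumsum(is_rt)
        cand <- which(is_start)
        for (i in cand) {
          j <- nxt[i]
          if (is.na(j) || j == i) next
          nev <- crt[j - 1] - if (i > 1) crt[i - 1] else 0
          if (nev > max_readthrough) next
          if (j - i < min_len_codons) next
          str_start <- f + 3 * (i - 1) + 1
          str_end <- f + 3 * j
          key <- paste(cname, strand, f, j)
          if (is.null(res[[key]]) || str_start < res[[key]]$str_start)
            res[[key]] <- list(contig = cname, strand = strand,
                               str_start = str_start, str_end = str_end)
        }
      }
    }
  }
  if (!length(res)) return(data.frame(contig = character(0),
                                      start = integer(0), end = integer(0),
                                      strand = character(0)))
  df <- do.call(rbind, lapply(res, function(r) {
    L <- nchar(genome[[r$contig]])
    if (r$strand == "+") data.frame(contig = r$contig, start = r$str_start,
                                    end = r$str_end, strand = "+",
                                    stringsAsFactors = FALSE)
    else data.frame(contig = r$contig, start = L - r$str_end + 1,
                    end = L - r$str_start + 1, strand = "-",
                    stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df[order(df$contig, df$start, df$end, df$strand), ]
}

orf_key_set <- function(df) {
  sort(paste(df$contig, df$start, df$end, df$strand))
}

# --- quadratic-space affine DP oracle for global alignment scores --------
# Same scoring convention as global_align: gap of length L costs
# open + L * ext, terminal gaps penalized. Score only, no traceback.
oracle_align_score <- function(a, b, sub, open = 10, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + (i - 1) * ext)
  for (j in 2:(m + 1)) Y[1, j] <- -(open + (j - 1) * ext)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      M[i, j] <- sub[av[i - 1], bv[j - 1]] +
        max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                     Y[i - 1, j] - open - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, X[i, j - 1] - open - ext,
                     Y[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# --- exhaustive hairpin placement oracle ---------------------------------
oracle_hairpin_best <- function(seq, min_stem = 7, loop_lo = 3,
                                loop_hi = 14, max_mm = 1,
                                max_start = NULL) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  if (is.null(max_start)) max_start <- n
  pscore <- function(x, y) {
    wc <- (x == "A" & y == "T") | (x == "T" & y == "A") |
      (x == "G" & y == "C") | (x == "C" & y == "G")
    gu <- (x == "G" & y == "T") | (x == "T" & y == "G")
    ifelse(wc, 2L, ifelse(gu, 1L, -2L))
  }
  best <- NULL
  for (i in seq_len(min(max_start, n))) {
    for (loop in loop_lo:loop_hi) {
      smax <- (n - i + 1 - loop) %/% 2
      if (smax < min_stem) next
      for (st in min_stem:smax) {
        left <- s[i:(i + st - 1)]
        right <- rev(s[(i + st + loop):(i + 2 * st + loop - 1)])
        ps <- pscore(left, right)
        mm <- sum(ps == -2L)
        if (mm > max_mm) next
        sc <- sum(ps)
        if (is.null(best) || sc > best$score)
          best <- list(score = sc, start = i, stem = st, loop = loop,
                       mm = mm)
      }
    }
  }
  best
}

# --- counting oracles for consensus / conserved columns ------------------
oracle_consensus <- function(rows, threshold) {
  m <- do.call(rbind, strsplit(rows, ""))
  paste(vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j][m[, j] != "-"]
    if (!length(col)) return("-")
    cnt <- table(col)
    top <- names(cnt)[which.max(cnt)]
    if (max(cnt) / length(col) > threshold) top else "X"
  }, character(1)), collapse = "")
}

# substitute a fraction of residues with different canonical letters
.mutate_near <- function(p, rate) {
  a <- strsplit(p, "")[[1]]
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  hit <- which(runif(length(a)) < rate)
  for (i in hit) a[i] <- sample(setdiff(aa, a[i]), 1)
  paste(a, collapse = "")
}

# well-behaved hairpin fixture: stem from {A,C} so the complement arm is
# from {G,T} (no wobble ambiguity), flanks and loop are all-A so the stem
# cannot extend inward or outward
make_hairpin_window <- function(stem_len = 12, loop = 6, lead = 4,
                                trail = 4) {
  stem <- paste(sample(c("A", "C"), stem_len, replace = TRUE),
                collapse = "")
  list(seq = paste0(strrep("A", lead), stem, strrep("A", loop),
                    reverse_complement(stem), strrep("A", trail)),
       stem = stem, start = lead + 1L)
}
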