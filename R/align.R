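# Global protein alignment over the 20 canonical amino acids plus the
# reassigned residues pyrrolysine (O) and selenocysteine (U), and X.

.AA_ALLOWED <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "O", "U", "X")

.gce_env <- new.env(parent = emptyenv())

#' Substitution matrix extended for pyrrolysine and selenocysteine
#'
#' BLOSUM62 over the 20 canonical residues, extended with `O`, `U` and `X`:
#' `O-O` and `U-U` score as the maximum BLOSUM62 diagonal (11); `O-K` and
#' `U-C` score at half that value, reflecting the chemistry (pyrrolysine is
#' a lysine derivative, selenocysteine the selenium analog of cysteine);
#' every other pairing involving `O` or `U` scores -4 (the BLOSUM62
#' minimum); `X` scores 0 against everything.
#'
#' @return 23 x 23 numeric matrix with dimnames.
#' @export
gce_substitution_matrix <- function() {
  if (!is.null(.gce_env$submat)) return(.gce_env$submat)
  b62 <- NULL
  data("BLOSUM62", package = "Biostrings", envir = environment())
  b62 <- get("BLOSUM62", envir = environment())
  aa20 <- .AA_ALLOWED[1:20]
  m <- matrix(-4, nrow = 23, ncol = 23,
              dimnames = list(.AA_ALLOWED, .AA_ALLOWED))
  m[aa20, aa20] <- b62[aa20, aa20]
  dmax <- max(diag(b62[aa20, aa20]))
  m["O", "O"] <- dmax
  m["U", "U"] <- dmax
  m["O", "K"] <- m["K", "O"] <- dmax / 2
  m["U", "C"] <- m["C", "U"] <- dmax / 2
  m["X", ] <- 0
  m[, "X"] <- 0
  .gce_env$submat <- m
  m
}

.check_protein <- function(seq, what = "sequence") {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq) || !nzchar(seq))
    stop(what, " must be a single non-empty protein string")
  seq <- toupper(seq)
  bad <- setdiff(strsplit(seq, "")[[1]], .AA_ALLOWED)
  if (length(bad))
    stop(what, " contains illegal letters: ", paste(unique(bad),
                                                    collapse = ""))
  seq
}

# identity over residue-residue columns (gap columns excluded), x100
.alignment_identity <- function(aligned_a, aligned_b) {
  a <- strsplit(aligned_a, "")[[1]]
  b <- strsplit(aligned_b, "")[[1]]
  both <- a != "-" & b != "-"
  if (!any(both)) return(0)
  100 * sum(a[both] == b[both]) / sum(both)
}

#' Optimal global alignment of two protein sequences
#'
#' Needleman-Wunsch alignment with affine gaps (open 10, extend 1) under
#' [gce_substitution_matrix()]. Terminal gaps are penalized in the score
#' but excluded from the identity, which is computed over residue-residue
#' columns only. Traceback tie-breaks are deterministic: substitution is
#' preferred over a gap, and a gap in `b` over a gap in `a`.
#'
#' @param a,b Protein strings over the 20 canonical letters plus `O`, `U`,
#'   `X`.
#' @param substitution Optional substitution matrix (dimnames must cover
#'   all letters used).
#' @param gap_open,gap_ext Affine gap parameters; a gap of length L costs
#'   `gap_open + L * gap_ext`.
#' @return Object of class `gce_alignment`: list with `aligned_a`,
#'   `aligned_b`, `score`, `percent_identity`.
#' @export
global_align <- function(a, b, substitution = NULL, gap_open = 10,
                         gap_ext = 1) {
  a <- .check_protein(a, "a")
  b <- .check_protein(b, "b")
  if (is.null(substitution)) substitution <- gce_substitution_matrix()
  r <- .nw_align_cpp(a, b, substitution, gap_open, gap_ext)
  structure(list(aligned_a = r$aligned_a, aligned_b = r$aligned_b,
                 score = r$score,
                 percent_identity = .alignment_identity(r$aligned_a,
                                                        r$aligned_b)),
            class = "gce_alignment")
}

#' @export
print.gce_alignment <- function(x, ...) {
  cat("Global alignment: score", x$score,
      sprintf("identity %.1f%%\n", x$percent_identity))
  cat(substr(x$aligned_a, 1, 60), "\n", substr(x$aligned_b, 1, 60), "\n",
      sep = "")
  invisible(x)
}

#' Majority-rule consensus of a gapped protein alignment
#'
#' Per column, emits the letter whose frequency among non-gap letters
#' strictly exceeds `threshold`; columns failing the threshold (including
#' exact ties at it) emit `"X"`; all-gap columns emit `"-"`.
#'
#' @param alignment Character vector of equal-length gapped rows.
#' @param threshold Fraction in (0, 1); strict inequality.
#' @return Consensus string.
#' @export
consensus_sequence <- function(alignment, threshold = 0.5) {
  stopifnot(length(alignment) >= 1L, threshold > 0, threshold < 1)
  w <- unique(nchar(alignment))
  if (length(w) != 1L) stop("alignment rows have unequal lengths")
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  cons <- vapply(seq_len(w), function(j) {
    col <- m[, j]
    col <- col[col != "-"]
    if (!length(col)) return("-")
    tab <- sort(table(col), decreasing = TRUE)
    if (tab[1] / length(col) > threshold) names(tab)[1] else "X"
  }, character(1))
  paste(cons, collapse = "")
}

#' Columns of an alignment conserved above an identity threshold
#'
#' @inheritParams consensus_sequence
#' @return 1-based indices of columns where one letter's frequency among
#'   non-gap letters strictly exceeds `threshold`.
#' @export
conserved_columns <- function(alignment, threshold = 0.75) {
  stopifnot(length(alignment) >= 1L)
  w <- unique(nchar(alignment))
  if (length(w) != 1L) stop("alignment rows have unequal lengths")
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  which(vapply(seq_len(w), function(j) {
    col <- m[, j]
    col <- col[col != "-"]
    if (!length(col)) return(FALSE)
    max(table(col)) / length(col) > threshold
  }, logical(1)))
}

#' Greedy dereplication of a protein set at a global identity threshold
#'
#' CD-HIT-style greedy clustering: sequences are sorted by decreasing
#' length (stable); each sequence joins the first (earliest-founded)
#' representative whose global alignment identity is at least
#' `identity_threshold`, otherwise founds a new cluster.
#'
#' @param seqs Named character vector of protein sequences.
#' @param identity_threshold Fraction, default 0.9.
#' @return List with `representatives` (named character vector) and
#'   `membership` (named character vector mapping every input id to its
#'   representative's id).
#' @export
dereplicate <- function(seqs, identity_threshold = 0.9) {
  stopifnot(length(seqs) >= 1L)
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("seq%04d", seq_along(seqs))
  ord <- order(-nchar(seqs))
  reps <- integer(0)
  member <- character(length(seqs))
  names(member) <- names(seqs)
  for (i in ord) {
    assigned <- FALSE
    for (r in reps) {
      pid <- global_align(seqs[[i]], seqs[[r]])$percent_identity
      if (pid >= identity_threshold * 100) {
        member[names(seqs)[i]] <- names(seqs)[r]
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      member[names(seqs)[i]] <- names(seqs)[i]
    }
  }
  list(representatives = seqs[reps], membership = member)
}
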