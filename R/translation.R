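#' Build a translation table with optional stop-codon readthrough
#'
#' Returns the bacterial genetic code (the standard 64-codon map; bacterial
#' table 11 differs from the standard code only in permitted starts) with
#' optional stop-codon reassignments: amber mode reassigns TAG to
#' pyrrolysine (letter `O`), opal mode reassigns TGA to selenocysteine
#' (letter `U`), and dual mode applies both. TAA is never reassigned.
#'
#' @param mode One of `"standard"`, `"amber"`, `"opal"`, `"dual"`.
#' @return An object of class `gce_translation_table`: a list with
#'   `base_map` (named character vector over all 64 codons, `*` marks stop),
#'   `readthrough` (named character vector, e.g. `c(TAG = "O")`), and
#'   `mode`.
#' @examples
#' tt <- translation_table("amber")
#' translate("ATGAAATAG", tt)  # "MKO"
#' @export
translation_table <- function(mode = c("standard", "amber", "opal", "dual")) {
  mode <- match.arg(mode)
  base_map <- Biostrings::GENETIC_CODE
  readthrough <- switch(mode,
    standard = character(0),
    amber = c(TAG = "O"),
    opal = c(TGA = "U"),
    dual = c(TAG = "O", TGA = "U")
  )
  stopifnot(length(base_map) == 64L,
            all(names(readthrough) %in% c("TAG", "TGA", "TAA")),
            all(base_map[names(readthrough)] == "*"))
  structure(list(base_map = base_map, readthrough = readthrough,
                 mode = mode),
            class = "gce_translation_table")
}

# integer encoding A=0 C=1 G=2 T=3 N=4; anything else -1
.encode_dna <- function(seq) {
  map <- integer(256) - 1L
  map[utf8ToInt("A") + 1L] <- 0L
  map[utf8ToInt("C") + 1L] <- 1L
  map[utf8ToInt("G") + 1L] <- 2L
  map[utf8ToInt("T") + 1L] <- 3L
  map[utf8ToInt("N") + 1L] <- 4L
  map[utf8ToInt(seq) + 1L]
}

.check_dna <- function(seq, what = "seq") {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq) || !nzchar(seq))
    stop(what, " must be a single non-empty DNA string")
  if (grepl("[^ACGTN]", seq))
    stop(what, " contains characters outside {A,C,G,T,N}")
  invisible(seq)
}

# 64-entry lookup of amino acids indexed by codon id 16*b1 + 4*b2 + b3,
# plus slot 65 = "X" for any codon containing N
.codon_lookup <- function(table) {
  bases <- c("A", "C", "G", "T")
  id <- 0:63
  cods <- paste0(bases[id %/% 16L + 1L], bases[(id %/% 4L) %% 4L + 1L],
                 bases[id %% 4L + 1L])
  aa <- character(65)
  aa[id + 1L] <- unname(table$base_map[cods])
  for (cod in names(table$readthrough)) {
    id <- sum(c(16L, 4L, 1L) * .encode_dna(cod))
    aa[id + 1L] <- unname(table$readthrough[[cod]])
  }
  aa[65L] <- "X"
  aa
}

# codon ids for an encoded sequence starting at `offset` (0-based frame);
# codons containing N (or trailing partial codons) get id 64 (-> "X")
.codon_ids <- function(enc, offset = 0L) {
  n <- length(enc)
  p <- seq.int(offset + 1L, n - 2L, by = 3L)
  b1 <- enc[p]; b2 <- enc[p + 1L]; b3 <- enc[p + 2L]
  id <- 16L * b1 + 4L * b2 + b3
  id[b1 > 3L | b2 > 3L | b3 > 3L] <- 64L
  id
}

#' Translate a DNA sequence under a (possibly readthrough) table
#'
#' Codons are mapped through the table's base map; readthrough codons yield
#' `O`/`U` rather than terminating; any codon containing `N` yields `X`.
#' Translation never terminates mid-sequence: the caller supplies the exact
#' ORF span, and stop codons translate to `*`.
#'
#' @param seq DNA string, length divisible by 3.
#' @param table A [translation_table()].
#' @return Amino-acid string (may contain `O`, `U`, `X`, `*`).
#' @export
translate <- function(seq, table = translation_table()) {
  .check_dna(seq)
  stopifnot(inherits(table, "gce_translation_table"))
  if (nchar(seq) %% 3L != 0L)
    stop("sequence length must be divisible by 3")
  enc <- .encode_dna(seq)
  ids <- .codon_ids(enc, 0L)
  paste(.codon_lookup(table)[ids + 1L], collapse = "")
}

#' Reverse complement of a DNA string
#'
#' `N` maps to `N`; the operation is an involution.
#'
#' @param seq DNA string over `{A,C,G,T,N}`.
#' @return The reverse complement, same length.
#' @export
reverse_complement <- function(seq) {
  .check_dna(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
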