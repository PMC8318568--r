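# Standard-format input/output: FASTA via Biostrings, GFF3 via rtracklayer.

#' Read a genome FASTA into a named character vector
#'
#' @param path Multi-record DNA FASTA (wrapped or unwrapped).
#' @return Named uppercase character vector of contigs.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  .as_genome(setNames(as.character(x), nm))
}

#' Write a genome FASTA
#' @param genome Named character vector of contigs.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  genome <- .as_genome(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read a protein FASTA (letters O and U legal)
#' @param path Protein FASTA path.
#' @return Named character vector.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a protein FASTA (letters O and U legal)
#' @param proteins Named character vector.
#' @param path Output path.
#' @export
write_protein_fasta <- function(proteins, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteins), path)
  invisible(path)
}

#' Write gene calls as GFF3
#'
#' Feature type `CDS`; readthrough events are carried in a `readthrough`
#' attribute as semicolon-free `pos:codon:letter` triples joined with
#' commas.
#'
#' @param genes A [find_orfs()] result.
#' @param path Output path.
#' @export
write_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$phase <- 0L  # spans start at their own codon 1
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$readthrough <- vapply(genes$events, function(ev) {
    if (is.null(ev) || !nrow(ev)) return("")
    paste(sprintf("%d:%s:%s", ev$protein_pos, ev$codon, ev$letter),
          collapse = ",")
  }, character(1))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a gene-call GFF3 written by [write_gff3()]
#'
#' @param path GFF3 path.
#' @return data.frame with `gene_id`, `contig`, `start`, `end`, `strand`,
#'   `readthrough` (the attribute string).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(
    gene_id = as.character(S4Vectors::mcols(gr)$ID),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    readthrough = if (!is.null(S4Vectors::mcols(gr)$readthrough))
      as.character(S4Vectors::mcols(gr)$readthrough) else "",
    stringsAsFactors = FALSE)
}

#' Write a truth table (or any feature data.frame) as GFF3
#' @param truth Truth table from [generate()].
#' @param path Output path.
#' @export
write_truth_gff3 <- function(truth, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = truth$contig,
    ranges = IRanges::IRanges(start = truth$start, end = truth$end),
    strand = truth$strand)
  S4Vectors::mcols(gr)$type <- "region"
  S4Vectors::mcols(gr)$ID <- truth$feature_id
  S4Vectors::mcols(gr)$class <- truth$class
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a benchmark bundle to disk
#'
#' Writes `genome.fasta`, `proteins.faa`, `references.faa`,
#' `annotations.tsv`, `truth.gff3` and `truth.json` under `dir`.
#'
#' @param bench A [generate()] result.
#' @param dir Output directory (created if needed).
#' @export
write_benchmark <- function(bench, dir) {
  stopifnot(inherits(bench, "gce_benchmark"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(bench$genome, file.path(dir, "genome.fasta"))
  write_protein_fasta(bench$proteins, file.path(dir, "proteins.faa"))
  if (length(bench$references))
    write_protein_fasta(bench$references, file.path(dir, "references.faa"))
  write.table(bench$annotations, file.path(dir, "annotations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_truth_gff3(bench$truth, file.path(dir, "truth.gff3"))
  jsonlite::write_json(bench$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", na = "null")
  invisible(dir)
}

#' Read an annotation TSV (gene_id, contig_id, gene_index, accessions)
#' @param path TSV path with semicolon-joined `family_accessions`.
#' @return Annotation data.frame.
#' @export
read_annotations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  .check_annotations(df)
}
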