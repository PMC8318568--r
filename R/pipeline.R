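# Whole-genome orchestration: ORFs -> tRNAs -> SECIS -> recoding calls ->
# machinery -> dual-GCE flag.

#' Pipeline configuration with full defaults
#'
#' @param mode Readthrough mode: `"amber"`, `"opal"` or `"dual"`.
#' @param orf_min_len Minimum protein length (aa) for ORF calls.
#' @param max_readthrough Maximum readthrough events per ORF.
#' @param trna_min_score Minimum tRNA pair score.
#' @param secis Parameter list for the SECIS scan, see [secis_defaults()].
#' @param known_identity,known_coverage Selenoprotein `known_family`
#'   thresholds (percent).
#' @param pyl_window Downstream conservation window for Pyl verification.
#' @param pyl_min_downstream Minimum downstream-window identity (percent)
#'   for a verified pyrrolysine call.
#' @param seed Seed recorded in reports.
#' @return List of class `gce_config`.
#' @export
gce_config <- function(mode = c("dual", "amber", "opal"),
                       orf_min_len = 60L, max_readthrough = 2L,
                       trna_min_score = .TRNA_DEFAULTS$min_score,
                       secis = secis_defaults(),
                       known_identity = 30, known_coverage = 50,
                       pyl_window = 20L, pyl_min_downstream = 50,
                       seed = 1L) {
  mode <- match.arg(mode)
  structure(list(mode = mode, orf_min_len = orf_min_len,
                 max_readthrough = max_readthrough,
                 trna_min_score = trna_min_score, secis = secis,
                 known_identity = known_identity,
                 known_coverage = known_coverage,
                 pyl_window = pyl_window,
                 pyl_min_downstream = pyl_min_downstream, seed = seed),
            class = "gce_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The file round-trips losslessly: unspecified keys take defaults.
#' @param path YAML path.
#' @return A [gce_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- do.call(gce_config, y[setdiff(names(y), "secis")])
  if (!is.null(y$secis)) cfg$secis <- modifyList(secis_defaults(), y$secis)
  cfg
}

#' @rdname read_config
#' @param config A [gce_config()] to serialize.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full genetic-code-expansion scan on one genome
#'
#' Executes, in order: readthrough-aware ORF calling (standard table plus
#' the configured readthrough mode), tRNA scanning, SECIS scanning of
#' opal-readthrough genes, selenoprotein and pyrrolysine calling, and --
#' when an annotation table is supplied -- the machinery inventory. A
#' genome is flagged dual-GCE iff both machinery sets are complete and at
#' least one selenoprotein and one verified pyrrolysine protein are
#' called.
#'
#' @param genome Named character vector of contigs, `DNAStringSet`, or a
#'   FASTA path.
#' @param config A [gce_config()].
#' @param annotations Optional annotation table (or TSV path) for the
#'   machinery inventory.
#' @param references Optional named character vector (or FASTA path) of
#'   reference proteins; entries containing `O` verify pyrrolysine sites,
#'   all entries serve as selenoprotein family references.
#' @return Object of class `gce_report`.
#' @export
run_scan <- function(genome, config = gce_config(), annotations = NULL,
                     references = NULL) {
  if (is.character(genome) && length(genome) == 1L &&
      file.exists(genome) && is.null(names(genome)))
    genome <- read_genome_fasta(genome)
  genome <- .as_genome(genome)
  if (is.character(annotations) && length(annotations) == 1L)
    annotations <- read_annotations(annotations)
  if (is.character(references) && length(references) == 1L &&
      file.exists(references) && is.null(names(references)))
    references <- read_protein_fasta(references)
  if (is.null(references)) references <- character(0)

  tbl_std <- translation_table("standard")
  tbl_mode <- translation_table(config$mode)
  genes_std <- find_orfs(genome, tbl_std, config$orf_min_len,
                         config$max_readthrough)
  genes <- find_orfs(genome, tbl_mode, config$orf_min_len,
                     config$max_readthrough)
  trnas <- scan_genome_trnas(genome, min_score = config$trna_min_score)
  secis_hits <- scan_secis_all(genes, genome, params = config$secis)
  sel_refs <- references
  sel <- call_selenoproteins(genes, secis_hits, sel_refs,
                             min_identity = config$known_identity,
                             min_coverage = config$known_coverage)
  pyl_refs <- references[vapply(references, grepl, logical(1),
                                pattern = "O", fixed = TRUE)]
  pyl <- call_pyl_proteins(genes, pyl_refs, window = config$pyl_window,
                           min_downstream_identity =
                             config$pyl_min_downstream)
  machinery <- if (!is.null(annotations))
    inventory(annotations, trna_classes = trnas) else NULL
  dual <- !is.null(machinery) && machinery$sec_complete &&
    machinery$pyl_complete && nrow(sel) >= 1L && nrow(pyl$calls) >= 1L
  structure(list(
    gene_counts = c(standard = nrow(genes_std),
                    mode = nrow(genes)),
    mode = config$mode,
    genes = genes,
    trnas = trnas,
    secis_hits = secis_hits,
    selenoproteins = sel,
    pyl = pyl,
    machinery = machinery,
    trna_class_counts = c(sec = sum(trnas$class == "sec"),
                          pyl = sum(trnas$class == "pyl"),
                          standard = sum(trnas$class == "standard"),
                          ambiguous = sum(trnas$class == "ambiguous")),
    dual_gce = dual,
    config = unclass(config)),
    class = "gce_report")
}

#' @export
print.gce_report <- function(x, ...) {
  cat("GCE scan (mode ", x$mode, "): ", x$gene_counts["mode"],
      " genes (", x$gene_counts["standard"], " under the standard table)\n",
      "selenoproteins: ", nrow(x$selenoproteins),
      "  pyl proteins: ", nrow(x$pyl$calls),
      "  tRNAs sec/pyl: ", x$trna_class_counts["sec"], "/",
      x$trna_class_counts["pyl"], "\n",
      "dual GCE: ", x$dual_gce, "\n", sep = "")
  invisible(x)
}

#' Compare two genomes (ANI) and proteomes (AAI)
#'
#' @param genome_a,genome_b Genomes (named character vectors,
#'   `DNAStringSet`s, or FASTA paths).
#' @param proteome_a,proteome_b Optional proteomes for AAI.
#' @param exhaustive Use the all-positions ANI search.
#' @return List with `ani` and (when proteomes given) `aai`
#'   `gce_comparison` objects.
#' @export
run_compare <- function(genome_a, genome_b, proteome_a = NULL,
                        proteome_b = NULL, exhaustive = FALSE) {
  rd <- function(g) if (is.character(g) && length(g) == 1L &&
                        is.null(names(g)) && file.exists(g))
    read_genome_fasta(g) else g
  rp <- function(p) if (is.character(p) && length(p) == 1L &&
                        is.null(names(p)) && file.exists(p))
    read_protein_fasta(p) else p
  out <- list(ani = ani(rd(genome_a), rd(genome_b),
                        exhaustive = exhaustive))
  if (!is.null(proteome_a) && !is.null(proteome_b))
    out$aai <- aai(rp(proteome_a), rp(proteome_b))
  out
}

#' Write a scan report to disk
#'
#' Writes `report.json` (summary counts, machinery checklist, effective
#' configuration), `calls.tsv` (selenoprotein and pyl calls),
#' `features.gff3` (gene calls) and `proteins.faa`.
#'
#' @param report A [run_scan()] result.
#' @param dir Output directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "gce_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(
    mode = report$mode,
    gene_counts = as.list(report$gene_counts),
    selenoprotein_count = nrow(report$selenoproteins),
    selenoprotein_groups = as.list(table(report$selenoproteins$group)),
    pyl_count = nrow(report$pyl$calls),
    trna_class_counts = as.list(report$trna_class_counts),
    machinery = if (!is.null(report$machinery)) list(
      sec_complete = report$machinery$sec_complete,
      pyl_complete = report$machinery$pyl_complete,
      missing = report$machinery$missing,
      copy_counts = as.list(report$machinery$copy_counts)) else NULL,
    dual_gce = report$dual_gce,
    config = report$config)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  calls <- merge(report$selenoproteins,
                 data.frame(gene_id = report$pyl$calls$gene_id,
                            pyl_pos = report$pyl$calls$pyl_protein_pos,
                            stringsAsFactors = FALSE),
                 by = "gene_id", all = TRUE)
  write.table(calls, file.path(dir, "calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_gff3(report$genes, file.path(dir, "features.gff3"))
  write_protein_fasta(setNames(report$genes$protein,
                               report$genes$gene_id),
                      file.path(dir, "proteins.faa"))
  invisible(dir)
}
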