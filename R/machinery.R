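# Sec/Pyl machinery inventory from functional annotation tables and
# gene-neighborhood analysis. Annotation is an input (e.g. HMM-based family
# assignments), never recomputed here.

.SEC_COMPONENTS <- c("selA", "selB", "selC", "selD")
.PYL_COMPONENTS <- c("pylB", "pylC", "pylD", "pylS", "pylT")

#' Default mapping from annotation labels to machinery components
#'
#' Maps family accessions or free-text labels to the named components of
#' the Sec and Pyl translation machinery and to adjacent proteins of the
#' methylamine-utilization locus. Includes the sulfate/thiosulfate import
#' ATP-binding protein CysA (TIGR00968), the trimethylamine
#' methyltransferase (mttB family), its cognate corrinoid protein, ramA,
#' and the glycine betaine methyltransferase, a homolog commonly
#' mis-annotated as a trimethylamine methyltransferase although it does not
#' use pyrrolysine. Fully editable: supply your own map to [inventory()].
#'
#' @return Named character vector: annotation label -> component name.
#' @export
default_component_map <- function() {
  c(selA = "selA", selB = "selB", selD = "selD",
    pylB = "pylB", pylC = "pylC", pylD = "pylD",
    pylS = "pylS", pylRS = "pylS",
    mttB = "tma_methyltransferase",
    mtbB = "dma_methyltransferase",
    mtmB = "mma_methyltransferase",
    corrinoid = "cognate_corrinoid",
    TIGR02370 = "cognate_corrinoid",
    ramA = "ramA",
    metH = "metH_methyltransferase",
    gbmt = "glycine_betaine_mt",
    TIGR00968 = "cysA",
    cysA = "cysA")
}

.check_annotations <- function(annotations) {
  need <- c("gene_id", "contig_id", "gene_index", "family_accessions")
  if (!is.data.frame(annotations) || !all(need %in% names(annotations)))
    stop("annotations must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(annotations$gene_id))
    stop("gene_id values must be unique")
  for (ct in unique(annotations$contig_id)) {
    gi <- annotations$gene_index[annotations$contig_id == ct]
    if (any(diff(sort(gi)) == 0L))
      stop("gene_index must be strictly increasing within a contig")
  }
  annotations
}

# split semicolon-joined accessions into a list column if necessary
.accession_list <- function(annotations) {
  fa <- annotations$family_accessions
  if (is.list(fa)) fa else strsplit(as.character(fa), ";", fixed = TRUE)
}

#' Inventory the Sec and Pyl machinery from an annotation table
#'
#' Marks each machinery component present when any annotation row maps to
#' it through `component_map`; the tRNA components (selC, pylT) are taken
#' from the classes of a [scan_genome_trnas()] result. Unknown labels are
#' ignored. Copy counts tally every mapped occurrence.
#'
#' @param annotations data.frame with `gene_id`, `contig_id`, `gene_index`,
#'   `family_accessions` (semicolon-joined string or list column).
#' @param trna_classes Optional data.frame with a `class` column
#'   (`"sec"`/`"pyl"` rows mark selC/pylT presence).
#' @param component_map Named character vector, label -> component.
#' @return Object of class `gce_machinery`: list with `sec_components`,
#'   `pyl_components` (named logical vectors), `sec_complete`,
#'   `pyl_complete`, `missing`, `copy_counts`.
#' @export
inventory <- function(annotations, trna_classes = NULL,
                      component_map = default_component_map()) {
  stopifnot(length(component_map) > 0L)
  annotations <- .check_annotations(annotations)
  labs <- unlist(.accession_list(annotations), use.names = FALSE)
  comp <- unname(component_map[labs])
  comp <- comp[!is.na(comp)]
  counts <- table(comp)
  copy_counts <- setNames(as.integer(counts), names(counts))
  sec <- setNames(.SEC_COMPONENTS %in% names(copy_counts), .SEC_COMPONENTS)
  pyl <- setNames(.PYL_COMPONENTS %in% names(copy_counts), .PYL_COMPONENTS)
  if (!is.null(trna_classes) && nrow(trna_classes)) {
    if (any(trna_classes$class == "sec")) {
      sec["selC"] <- TRUE
      copy_counts["selC"] <- sum(trna_classes$class == "sec")
    }
    if (any(trna_classes$class == "pyl")) {
      pyl["pylT"] <- TRUE
      copy_counts["pylT"] <- sum(trna_classes$class == "pyl")
    }
  }
  structure(list(
    sec_components = sec, pyl_components = pyl,
    sec_complete = all(sec), pyl_complete = all(pyl),
    missing = c(names(sec)[!sec], names(pyl)[!pyl]),
    copy_counts = copy_counts), class = "gce_machinery")
}

#' @export
print.gce_machinery <- function(x, ...) {
  cat("Sec machinery:", ifelse(x$sec_complete, "complete", "incomplete"),
      "-", paste(names(x$sec_components)[x$sec_components], collapse = " "),
      "\nPyl machinery:", ifelse(x$pyl_complete, "complete", "incomplete"),
      "-", paste(names(x$pyl_components)[x$pyl_components], collapse = " "),
      "\n")
  invisible(x)
}

#' Genes in the neighborhood of an anchor gene
#'
#' Returns the annotation rows on the anchor's contig whose gene-index
#' distance from the anchor is strictly less than `radius_genes`
#' (anchor excluded). Neighborhoods never cross contig boundaries.
#'
#' @param annotations Annotation table, see [inventory()].
#' @param anchor_gene_id Gene id of the anchor; must exist.
#' @param radius_genes Strict gene-index radius, default 10.
#' @return data.frame subset of `annotations`, ordered by gene_index.
#' @export
neighborhood <- function(annotations, anchor_gene_id, radius_genes = 10L) {
  annotations <- .check_annotations(annotations)
  k <- match(anchor_gene_id, annotations$gene_id)
  if (is.na(k)) stop("anchor gene '", anchor_gene_id, "' not found")
  ct <- annotations$contig_id[k]
  ai <- annotations$gene_index[k]
  sel <- annotations$contig_id == ct &
    abs(annotations$gene_index - ai) < radius_genes &
    annotations$gene_id != anchor_gene_id
  out <- annotations[sel, , drop = FALSE]
  out[order(out$gene_index), , drop = FALSE]
}

#' Conservation of a gene cluster around an anchor across genomes
#'
#' For each genome, reports which components of `component_set` occur
#' within the anchor's neighborhood and their relative order along the
#' contig. Genomes lacking the anchor component yield all-absent rows.
#'
#' @param genomes Named list of annotation tables.
#' @param anchor_component Component name whose first occurrence anchors
#'   the neighborhood.
#' @param component_set Character vector of component names to report.
#' @param component_map Label -> component map.
#' @param radius_genes Neighborhood radius (strict), default 10.
#' @return List with `presence` (logical genome x component matrix) and
#'   `order` (named character vector: components in gene order, or "" when
#'   the anchor is absent).
#' @export
cluster_conservation <- function(genomes, anchor_component, component_set,
                                 component_map = default_component_map(),
                                 radius_genes = 10L) {
  stopifnot(length(genomes) >= 1L, !is.null(names(genomes)))
  presence <- matrix(FALSE, nrow = length(genomes),
                     ncol = length(component_set),
                     dimnames = list(names(genomes), component_set))
  ord <- setNames(character(length(genomes)), names(genomes))
  for (g in names(genomes)) {
    ann <- .check_annotations(genomes[[g]])
    acc <- .accession_list(ann)
    comp_per_gene <- lapply(acc, function(a) {
      m <- unname(component_map[a]); unique(m[!is.na(m)])
    })
    has_anchor <- vapply(comp_per_gene, function(cc)
      anchor_component %in% cc, logical(1))
    if (!any(has_anchor)) next
    anchor_id <- ann$gene_id[which(has_anchor)[1]]
    nb <- neighborhood(ann, anchor_id, radius_genes)
    nb_comp <- lapply(.accession_list(nb), function(a) {
      m <- unname(component_map[a]); unique(m[!is.na(m)])
    })
    # anchor itself counts as present at its own position
    ids <- c(nb$gene_id, anchor_id)
    idx <- c(nb$gene_index, ann$gene_index[match(anchor_id, ann$gene_id)])
    comps <- c(nb_comp, list(anchor_component))
    o <- order(idx)
    found <- character(0)
    for (i in o) {
      inset <- intersect(comps[[i]], component_set)
      found <- c(found, inset)
    }
    presence[g, intersect(found, component_set)] <- TRUE
    ord[g] <- paste(found, collapse = ">")
  }
  list(presence = presence, order = ord)
}
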