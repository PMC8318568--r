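# Integration of ORF, tRNA and SECIS evidence into selenoprotein and
# pyrrolysine-protein calls, plus active-site verification.

#' Verify that a candidate's pyrrolysine site aligns with a reference
#'
#' Globally aligns a pyrrolysine-containing candidate to a
#' pyrrolysine-containing reference (e.g. an archaeal methylamine
#' methyltransferase) and reports whether the two `O` residues fall in the
#' same alignment column, together with the identity over the `window`
#' residues following the site. The first `O` of each sequence is taken as
#' the active site.
#'
#' @param candidate,reference Protein strings, each containing `O`.
#' @param window Number of candidate residues after the site over which
#'   downstream identity is computed (default 20).
#' @return List of class `gce_pyl_site`: `candidate_pyl_pos`,
#'   `candidate_length`, `reference_pyl_pos`, `reference_length`,
#'   `site_aligned`, `downstream_window_identity`, `alignment`.
#' @export
verify_pyl_site <- function(candidate, reference, window = 20L) {
  candidate <- .check_protein(candidate, "candidate")
  reference <- .check_protein(reference, "reference")
  cpos <- regexpr("O", candidate, fixed = TRUE)[1]
  rpos <- regexpr("O", reference, fixed = TRUE)[1]
  if (cpos < 0) stop("candidate contains no pyrrolysine (O) residue")
  if (rpos < 0) stop("reference contains no pyrrolysine (O) residue")
  aln <- global_align(candidate, reference)
  a <- strsplit(aln$aligned_a, "")[[1]]
  b <- strsplit(aln$aligned_b, "")[[1]]
  ocol_a <- which(cumsum(a != "-") == cpos & a != "-")[1]
  site_aligned <- b[ocol_a] == "O"
  # identity over the next `window` columns in which the candidate has a
  # residue, truncated at the end of the alignment
  after <- seq_len(length(a)) > ocol_a & a != "-"
  cols <- which(after)
  cols <- head(cols, window)
  dwi <- if (length(cols)) 100 * sum(a[cols] == b[cols]) / length(cols)
         else NA_real_
  structure(list(candidate_pyl_pos = as.integer(cpos),
                 candidate_length = nchar(candidate),
                 reference_pyl_pos = as.integer(rpos),
                 reference_length = nchar(reference),
                 site_aligned = site_aligned,
                 downstream_window_identity = dwi,
                 alignment = aln),
            class = "gce_pyl_site")
}

# best-scoring reference for a query; returns NULL when references empty
.best_reference <- function(query, references) {
  if (!length(references)) return(NULL)
  best <- NULL
  for (id in names(references)) {
    aln <- global_align(query, references[[id]])
    if (is.null(best) || aln$percent_identity > best$identity) {
      a <- strsplit(aln$aligned_a, "")[[1]]
      b <- strsplit(aln$aligned_b, "")[[1]]
      cov <- 100 * sum(a != "-" & b != "-") / nchar(references[[id]])
      best <- list(id = id, identity = aln$percent_identity,
                   coverage = cov, alignment = aln)
    }
  }
  best
}

#' Call selenoproteins from gene calls and SECIS hits
#'
#' Every gene with at least one selenocysteine readthrough event and at
#' least one passing SECIS hit becomes a call. Calls are split into two
#' groups: `known_family` when the best reference alignment reaches the
#' identity and coverage thresholds (reference coverage = residue-residue
#' columns / reference length), else `novel`.
#'
#' @param genes A [find_orfs()] result.
#' @param secis_hits A [scan_secis_all()] result.
#' @param references Named character vector of labeled reference
#'   selenoproteins (may be empty; letters `O`/`U` legal).
#' @param min_identity,min_coverage Percent thresholds for `known_family`
#'   membership (defaults 30 and 50).
#' @return data.frame with `gene_id`, `uga_protein_pos` (first documented
#'   event), `n_secis`, `group`, `family_label`,
#'   `best_reference_identity`.
#' @export
call_selenoproteins <- function(genes, secis_hits, references = character(0),
                                min_identity = 30, min_coverage = 50) {
  out <- data.frame(gene_id = character(0), uga_protein_pos = integer(0),
                    n_secis = integer(0), group = character(0),
                    family_label = character(0),
                    best_reference_identity = numeric(0),
                    stringsAsFactors = FALSE)
  if (!nrow(genes) || !nrow(secis_hits)) return(out)
  for (i in seq_len(nrow(genes))) {
    ev <- genes$events[[i]]
    if (is.null(ev) || !nrow(ev) || !any(ev$letter == "U")) next
    hits <- secis_hits[secis_hits$gene_id == genes$gene_id[i], ,
                       drop = FALSE]
    if (!nrow(hits)) next
    best <- .best_reference(genes$protein[i], references)
    known <- !is.null(best) && best$identity >= min_identity &&
      best$coverage >= min_coverage
    out <- rbind(out, data.frame(
      gene_id = genes$gene_id[i],
      uga_protein_pos = hits$uga_protein_pos[1],
      n_secis = nrow(hits),
      group = if (known) "known_family" else "novel",
      family_label = if (known) best$id else "",
      best_reference_identity = if (is.null(best)) NA_real_ else
        best$identity,
      stringsAsFactors = FALSE))
  }
  out
}

#' Call pyrrolysine proteins and verify their active sites
#'
#' Candidates are genes with at least one amber readthrough event (letter
#' `O`). When a reference set is supplied, each candidate is verified with
#' [verify_pyl_site()] against its best-aligning reference, and only
#' candidates whose `O` column pairs with the reference `O` column
#' (`site_aligned`) *and* whose downstream window identity reaches
#' `min_downstream_identity` are called. Both gates are needed: a global
#' aligner facing a large length difference can place the surplus gap
#' almost anywhere, so it pairs the two rare `O` residues nearly for free,
#' and only conservation of the residues following the site separates true
#' methyltransferases from chance amber readthrough. Without references no
#' candidate can be verified: `calls` is empty and the candidates are
#' listed separately.
#'
#' @param genes A [find_orfs()] result.
#' @param references Named character vector of pyrrolysine-containing
#'   reference proteins (each must contain `O`).
#' @param window Downstream conservation window, see [verify_pyl_site()].
#' @param min_downstream_identity Minimum percent identity over the
#'   `window` residues after the site (default 50).
#' @param min_coverage Minimum percent of the reference covered by
#'   residue-residue alignment columns (default 50): pyrrolysine proteins
#'   are full-length methyltransferases, and short chance-readthrough ORFs
#'   whose tails align to one corner of the reference must not qualify.
#' @return List with `calls` (data.frame of verified calls: `gene_id`,
#'   `pyl_protein_pos`, `protein_length`, `reference`, `site_aligned`,
#'   `downstream_window_identity`), `candidates` (data.frame of all genes
#'   with an `O` event: `gene_id`, `pyl_protein_pos`, `protein_length`),
#'   and `site_reports` (list of `gce_pyl_site` objects, named by gene
#'   id).
#' @export
call_pyl_proteins <- function(genes, references = character(0),
                              window = 20L,
                              min_downstream_identity = 50,
                              min_coverage = 50) {
  calls <- data.frame(gene_id = character(0), pyl_protein_pos = integer(0),
                      protein_length = integer(0), reference = character(0),
                      site_aligned = logical(0),
                      downstream_window_identity = numeric(0),
                      stringsAsFactors = FALSE)
  candidates <- data.frame(gene_id = character(0),
                           pyl_protein_pos = integer(0),
                           protein_length = integer(0),
                           stringsAsFactors = FALSE)
  reports <- list()
  if (!nrow(genes))
    return(list(calls = calls, candidates = candidates,
                site_reports = reports))
  for (i in seq_len(nrow(genes))) {
    ev <- genes$events[[i]]
    if (is.null(ev) || !nrow(ev)) next
    oev <- ev[ev$letter == "O", , drop = FALSE]
    if (!nrow(oev)) next
    gid <- genes$gene_id[i]
    candidates <- rbind(candidates, data.frame(
      gene_id = gid, pyl_protein_pos = oev$protein_pos[1],
      protein_length = nchar(genes$protein[i]), stringsAsFactors = FALSE))
    if (!length(references)) next
    best <- .best_reference(genes$protein[i], references)
    if (best$coverage < min_coverage) next
    rep <- verify_pyl_site(genes$protein[i], references[[best$id]],
                           window = window)
    if (!isTRUE(rep$site_aligned)) next
    if (is.na(rep$downstream_window_identity) ||
        rep$downstream_window_identity < min_downstream_identity) next
    reports[[gid]] <- rep
    calls <- rbind(calls, data.frame(
      gene_id = gid, pyl_protein_pos = rep$candidate_pyl_pos,
      protein_length = rep$candidate_length, reference = best$id,
      site_aligned = rep$site_aligned,
      downstream_window_identity = rep$downstream_window_identity,
      stringsAsFactors = FALSE))
  }
  list(calls = calls, candidates = candidates, site_reports = reports)
}
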