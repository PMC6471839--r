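# Pathway-level spectral-count contrasts: map annotated metaclusters to
# pathways via a local gene-to-pathway table, deduplicate peptide
# evidence at the genus level, and contrast a treated subject (group)
# against the untreated rest.

#' Metacluster counts with peptide redundancy removed at the genus level
#'
#' Within a metacluster and subject, each spectrum contributes one count
#' per distinct genus whose member proteins contain the peptide — a
#' peptide matching several same-genus proteins inside the metacluster
#' contributes its spectra once for that genus, not once per protein.
#' With the redundant (per-protein) convention the same spectrum would
#' count once per matching protein, so deduplicated counts never exceed
#' redundant ones.
#'
#' @param metaclusters \code{metaclusters}.
#' @param groups the \code{protein_groups} the metaclusters were built
#'   from (supplies member accessions per peptide).
#' @param psms retained PSM data.frame.
#' @param database \code{protein_db} (genus of each accession).
#' @return metacluster x subject numeric matrix of deduplicated counts.
#' @export
deduplicate_at_genus <- function(metaclusters, groups, psms, database) {
  subjects <- sort(unique(psms$subject_id))
  out <- matrix(0, nrow = nrow(metaclusters), ncol = length(subjects),
                dimnames = list(metaclusters$metacluster_id, subjects))
  map <- peptide_to_metacluster(metaclusters)
  # peptide -> distinct genera among metacluster member proteins
  # containing it; all groups sharing a peptide sit in one metacluster,
  # so pooling across groups stays within that metacluster
  pep_genera <- new.env(parent = emptyenv())
  for (gi in seq_len(nrow(groups))) {
    genera <- unique(database$genus[match(groups$members[[gi]],
                                          database$accession)])
    for (p in groups$peptides[[gi]]) {
      pep_genera[[p]] <- unique(c(pep_genera[[p]], genera))
    }
  }
  n_genera <- vapply(psms$peptide, function(p) {
    g <- pep_genera[[p]]
    if (is.null(g)) 0L else length(g)
  }, integer(1))
  mc_of <- map[psms$peptide]
  known <- !is.na(mc_of) & n_genera > 0L
  for (i in which(known)) {
    j <- match(psms$subject_id[i], subjects)
    out[mc_of[i], j] <- out[mc_of[i], j] + n_genera[i]
  }
  out
}

#' Map annotated metaclusters to pathways
#'
#' A metacluster joins a pathway when any of its characterized gene
#' names appears in the pathway's gene set (case-insensitive).  Only
#' metaclusters with useful annotation participate; multi-pathway
#' membership is allowed.
#'
#' @param metaclusters \code{metaclusters}.
#' @param pathway_table data.frame with columns \code{pathway_id},
#'   \code{gene_name} (one row per pathway-gene pair); must be
#'   non-empty.
#' @return data.frame with columns \code{pathway_id},
#'   \code{metacluster_id}, \code{gene_name} (the matching gene).
#' @export
map_to_pathways <- function(metaclusters, pathway_table) {
  if (is.null(pathway_table) || nrow(pathway_table) == 0L)
    stopf("pathway table is empty")
  ann <- metaclusters[metaclusters$has_useful_annotation, , drop = FALSE]
  rows <- list()
  pt_gene <- tolower(pathway_table$gene_name)
  for (i in seq_len(nrow(ann))) {
    hit <- pt_gene %in% tolower(ann$gene_names[[i]])
    if (any(hit))
      rows[[length(rows) + 1L]] <- data.frame(
        pathway_id = pathway_table$pathway_id[hit],
        metacluster_id = ann$metacluster_id[i],
        gene_name = pathway_table$gene_name[hit],
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(pathway_id = character(0),
                      metacluster_id = character(0),
                      gene_name = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$pathway_id, out$metacluster_id), , drop = FALSE]
}

#' Contrast pathway spectral counts between subject groups
#'
#' For every member metacluster of every pathway: the treated count (the
#' treated subject's count, summed if the treated group has several
#' subjects), and the mean and standard deviation (n - 1 denominator)
#' over the untreated subjects.  A pathway's verdict is "higher" when
#' the treated count exceeds mean + 1 SD for more than
#' \code{majority} of its members, "lower" symmetrically, else
#' "equivalent".
#'
#' @param membership pathway membership from
#'   \code{\link{map_to_pathways}}.
#' @param counts metacluster x subject count matrix (typically the
#'   genus-deduplicated one).
#' @param treated,untreated disjoint, non-empty subject id sets.
#' @param majority fraction of members that must cross the mean +/- 1 SD
#'   band (default 0.5, strict majority).
#' @return list: \code{per_member} data.frame (pathway_id,
#'   metacluster_id, gene_name, treated_count, untreated_mean,
#'   untreated_sd, direction) and \code{verdicts} data.frame
#'   (pathway_id, n_members, n_higher, n_lower, verdict).
#' @export
contrast_groups <- function(membership, counts, treated, untreated,
                            majority = 0.5) {
  if (!length(treated) || !length(untreated))
    stopf("treated and untreated subject sets must be non-empty")
  if (length(intersect(treated, untreated)))
    stopf("treated and untreated subject sets overlap: %s",
          paste(intersect(treated, untreated), collapse = ", "))
  missing <- setdiff(c(treated, untreated), colnames(counts))
  if (length(missing))
    stopf("subject(s) absent from count matrix: %s",
          paste(missing, collapse = ", "))
  mem <- unique(membership[, c("pathway_id", "metacluster_id",
                               "gene_name")])
  mem <- mem[mem$metacluster_id %in% rownames(counts), , drop = FALSE]
  tr <- rowSums(counts[mem$metacluster_id, treated, drop = FALSE])
  un <- counts[mem$metacluster_id, untreated, drop = FALSE]
  un_mean <- rowMeans(un)
  un_sd <- apply(un, 1, stats::sd)
  if (length(untreated) == 1L) un_sd <- rep(0, nrow(un))
  direction <- rep("within", nrow(mem))
  direction[tr > un_mean + un_sd] <- "above"
  direction[tr < un_mean - un_sd] <- "below"
  per_member <- data.frame(
    pathway_id = mem$pathway_id, metacluster_id = mem$metacluster_id,
    gene_name = mem$gene_name, treated_count = unname(tr),
    untreated_mean = unname(un_mean), untreated_sd = unname(un_sd),
    direction = direction, stringsAsFactors = FALSE)
  verdicts <- do.call(rbind, lapply(split(per_member,
                                          per_member$pathway_id),
                                    function(d) {
    n <- nrow(d)
    nh <- sum(d$direction == "above")
    nl <- sum(d$direction == "below")
    verdict <- if (nh / n > majority) "higher"
    else if (nl / n > majority) "lower" else "equivalent"
    data.frame(pathway_id = d$pathway_id[1], n_members = n,
               n_higher = nh, n_lower = nl, verdict = verdict,
               stringsAsFactors = FALSE)
  }))
  rownames(verdicts) <- NULL
  list(per_member = per_member, verdicts = verdicts)
}
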