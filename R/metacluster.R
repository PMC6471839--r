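# Homology metaclustering: partition inferred protein groups into
# connected components under three relations — shared characterized gene
# name, shared peptide evidence, shared UniRef50 id — with transitive
# closure across mixed relation types.  Host and microbial groups are
# clustered in separate strata.

group_annotations <- function(groups, database) {
  idx <- match(unlist(groups$members), database$accession)
  if (anyNA(idx))
    stopf("group member accessions absent from database")
  per <- rep(seq_len(nrow(groups)), lengths(groups$members))
  list(
    genes = lapply(split(database$gene_name[idx], per), function(g)
      sort(unique(g[is_characterized_gene(g)]))),
    urefs = lapply(split(database$uniref50_id[idx], per), function(u)
      sort(unique(u[nzchar(u)]))),
    host = vapply(split(database$is_host[idx], per), all, logical(1)),
    any_host = vapply(split(database$is_host[idx], per), any, logical(1)))
}

#' Build metaclusters from inferred protein groups
#'
#' Two groups are linked when any of their members share a characterized
#' gene name (case-insensitive), when their peptide sets intersect in at
#' least \code{min_shared_peptides} sequences, or when any members share
#' a UniRef50 id.  Metaclusters are the connected components of this
#' mixed-relation graph.  Host groups (all members host) form their own
#' stratum: host evidence never bridges into microbial clusters.
#' Metacluster ids are deterministic, ordered by the smallest member
#' accession.
#'
#' @param groups \code{protein_groups}.
#' @param database \code{protein_db} supplying gene names, UniRef50 ids
#'   and host flags for member accessions.
#' @param min_shared_peptides minimum peptide-set intersection forming a
#'   peptide-evidence edge (default 1 = any intersection).
#' @return \code{metaclusters}: data.frame with columns
#'   \code{metacluster_id}, \code{anchor} (smallest member accession),
#'   \code{has_useful_annotation}, \code{is_host}, and list-columns
#'   \code{members} (group ids), \code{gene_names}, \code{uniref50_ids},
#'   \code{peptides}.
#' @export
build_metaclusters <- function(groups, database, min_shared_peptides = 1L) {
  if (nrow(groups) == 0L) stopf("no protein groups to cluster")
  ann <- group_annotations(groups, database)
  n <- nrow(groups)
  stratum <- ifelse(ann$host, "host", "microbial")

  # connect all groups sharing a key with a path (enough for components)
  edges <- integer(0)
  add_key_edges <- function(keys, owners) {
    for (g in split(owners, keys)) {
      g <- unique(g)
      if (length(g) > 1L)
        edges <<- c(edges, rbind(g[-length(g)], g[-1L]))
    }
  }
  gene_keys <- lapply(ann$genes, tolower)
  add_key_edges(paste(rep(stratum, lengths(gene_keys)),
                      unlist(gene_keys)),
                rep(seq_len(n), lengths(gene_keys)))
  add_key_edges(paste(rep(stratum, lengths(ann$urefs)),
                      unlist(ann$urefs)),
                rep(seq_len(n), lengths(ann$urefs)))
  if (min_shared_peptides <= 1L) {
    add_key_edges(paste(rep(stratum, lengths(groups$peptides)),
                        unlist(groups$peptides)),
                  rep(seq_len(n), lengths(groups$peptides)))
  } else {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (stratum[i] == stratum[j] &&
          sum(groups$peptides[[i]] %in% groups$peptides[[j]]) >=
            min_shared_peptides)
        edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_graph(edges = edges, n = n, directed = FALSE)
  comp <- igraph::components(g)$membership

  mc <- split(seq_len(n), comp)
  anchor <- vapply(mc, function(m)
    min(unlist(groups$members[m])), character(1))
  mc <- mc[order(anchor)]
  anchor <- sort(anchor)
  out <- data.frame(
    metacluster_id = sprintf("MC%05d", seq_along(mc)),
    anchor = anchor,
    stringsAsFactors = FALSE)
  out$members <- lapply(mc, function(m) groups$group_id[m])
  out$gene_names <- lapply(mc, function(m)
    sort(unique(unlist(ann$genes[m]))))
  out$uniref50_ids <- lapply(mc, function(m)
    sort(unique(unlist(ann$urefs[m]))))
  out$peptides <- lapply(mc, function(m)
    sort(unique(unlist(groups$peptides[m]))))
  out$has_useful_annotation <- lengths(out$gene_names) > 0L
  out$is_host <- vapply(mc, function(m) all(ann$host[m]), logical(1))
  mixed <- vapply(mc, function(m)
    any(ann$any_host[m]) && !all(ann$host[m]), logical(1))
  attr(out, "mixed_host") <- mixed
  rownames(out) <- NULL
  class(out) <- c("metaclusters", "data.frame")
  out
}

# peptide -> metacluster row index; a function because shared-peptide
# edges were absorbed into components
peptide_to_metacluster <- function(metaclusters) {
  map <- split(rep(seq_len(nrow(metaclusters)),
                   lengths(metaclusters$peptides)),
               unlist(metaclusters$peptides))
  amb <- vapply(map, function(x) length(unique(x)) > 1L, logical(1))
  if (any(amb))
    stopf("peptide(s) map to more than one metacluster: %s",
          paste(utils::head(names(map)[amb], 5), collapse = ", "))
  vapply(map, `[[`, integer(1), 1)
}

#' Per-subject metacluster spectral counts
#'
#' A PSM contributes one count to the metacluster owning its peptide.
#' Because metaclusters absorb all shared-peptide edges, each peptide
#' belongs to exactly one metacluster and column totals equal the number
#' of retained PSMs.
#'
#' @param metaclusters \code{metaclusters}.
#' @param psms retained PSM data.frame.
#' @return \code{\link{abundance_matrix}} (metacluster x subject, method
#'   "proteomics").
#' @export
count_metacluster_spectra <- function(metaclusters, psms) {
  subjects <- sort(unique(psms$subject_id))
  map <- peptide_to_metacluster(metaclusters)
  mc_of <- map[psms$peptide]
  known <- !is.na(mc_of)
  tab <- table(factor(metaclusters$metacluster_id[mc_of[known]],
                      levels = metaclusters$metacluster_id),
               factor(psms$subject_id[known], levels = subjects))
  mat <- matrix(as.integer(tab), nrow = nrow(metaclusters),
                dimnames = list(metaclusters$metacluster_id, subjects))
  abundance_matrix(mat, method = "proteomics")
}

#' Accounting of spectra, unique peptides and metaclusters by stratum
#'
#' Tallies each metacluster's spectral counts and distinct peptide
#' sequences under its source (Bacterial or Human) and annotation
#' stratum (with/without a characterized gene name), in the layout of a
#' study accounting table.  A metacluster mixing host and microbial
#' members is a hard error.
#'
#' @param metaclusters \code{metaclusters}.
#' @param counts metacluster x subject count matrix from
#'   \code{\link{count_metacluster_spectra}}.
#' @return data.frame with columns \code{source}, \code{annotation},
#'   \code{spectral_counts}, \code{unique_peptide_sequences},
#'   \code{metaclusters}.
#' @export
annotation_summary <- function(metaclusters, counts) {
  mixed <- attr(metaclusters, "mixed_host")
  if (!is.null(mixed) && any(mixed))
    stopf("metacluster(s) mix host and microbial members: %s",
          paste(metaclusters$metacluster_id[mixed], collapse = ", "))
  spectra <- if (nrow(metaclusters))
    rowSums(counts)[metaclusters$metacluster_id] else numeric(0)
  strata <- expand.grid(
    annotation = c("With useful annotation", "Without useful annotation"),
    source = c("Bacterial", "Human"),
    stringsAsFactors = FALSE)[, c("source", "annotation")]
  rows <- lapply(seq_len(nrow(strata)), function(k) {
    sel <- (metaclusters$is_host == (strata$source[k] == "Human")) &
      (metaclusters$has_useful_annotation ==
         (strata$annotation[k] == "With useful annotation"))
    data.frame(
      source = strata$source[k], annotation = strata$annotation[k],
      spectral_counts = sum(spectra[sel]),
      unique_peptide_sequences =
        length(unique(unlist(metaclusters$peptides[sel]))),
      metaclusters = sum(sel), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Arithmetic roll-up of an accounting table
#'
#' Recomputes the derived totals and shares implied by an accounting
#' table (as produced by \code{\link{annotation_summary}}, or loaded
#' from a published table): total and per-source spectra, peptides and
#' metacluster counts, the host spectra share, the annotated share of
#' bacterial metaclusters, and the host metacluster count relative to
#' the bacterial one.
#'
#' @param accounting data.frame with columns source, annotation,
#'   spectral_counts, unique_peptide_sequences, metaclusters.
#' @return named list of totals (percentages on the 0-100 scale).
#' @export
accounting_totals <- function(accounting) {
  need <- c("source", "annotation", "spectral_counts",
            "unique_peptide_sequences", "metaclusters")
  stopifnot(all(need %in% names(accounting)))
  bact <- accounting$source == "Bacterial"
  host <- accounting$source == "Human"
  annot <- accounting$annotation == "With useful annotation"
  tot <- function(col, sel = TRUE) sum(accounting[[col]][sel])
  list(
    total_spectral_counts = tot("spectral_counts"),
    bacterial_spectral_counts = tot("spectral_counts", bact),
    host_spectral_counts = tot("spectral_counts", host),
    total_unique_peptides = tot("unique_peptide_sequences"),
    bacterial_unique_peptides = tot("unique_peptide_sequences", bact),
    bacterial_metaclusters = tot("metaclusters", bact),
    host_metaclusters = tot("metaclusters", host),
    total_metaclusters = tot("metaclusters"),
    host_spectra_percent =
      100 * tot("spectral_counts", host) / tot("spectral_counts"),
    bacterial_annotated_metacluster_percent =
      100 * tot("metaclusters", bact & annot) / tot("metaclusters", bact),
    host_metacluster_percent_of_bacterial =
      100 * tot("metaclusters", host) / tot("metaclusters", bact))
}
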