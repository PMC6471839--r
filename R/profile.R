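# Per-rank taxonomic profiling from uniquely assignable peptides.
# Uniqueness is evaluated independently at each rank against the full
# non-decoy database: a peptide is unique at a rank iff all non-decoy
# proteins containing it fall in a single taxon of that rank.

#' Rank-level uniqueness of a peptide
#'
#' @param peptide stripped peptide sequence.
#' @param database \code{protein_db}.
#' @param rank one of "family", "genus", "species", "strain".
#' @param index optional peptide index from
#'   \code{\link{build_peptide_index}} (built on demand otherwise —
#'   expensive, pass one when calling repeatedly).
#' @return the unique taxon name, or \code{NA_character_} when the
#'   peptide is shared between taxa at this rank.  A peptide absent from
#'   every non-decoy protein is an error.
#' @export
peptide_uniqueness <- function(peptide, database, rank, index = NULL) {
  rank <- match.arg(rank, TAX_RANKS)
  if (is.null(index)) index <- build_peptide_index(database)
  accs <- index_lookup(index, peptide)
  accs <- accs[!database$is_decoy[match(accs, database$accession)]]
  if (!length(accs))
    stopf("peptide %s does not occur in any non-decoy database protein",
          peptide)
  taxa <- unique(database[[rank]][match(accs, database$accession)])
  if (length(taxa) == 1L) taxa else NA_character_
}

#' Build a per-rank abundance profile from unique peptides
#'
#' Every retained spectrum whose peptide is unique at \code{rank} adds
#' one spectral count to its taxon/subject cell; spectra of peptides
#' shared between taxa at this rank contribute nothing.  Host taxa are
#' kept out of the microbial matrix and reported separately for QC.
#'
#' @param psms retained (FDR-filtered) PSM data.frame.
#' @param database \code{protein_db}.
#' @param rank taxonomic rank.
#' @param index optional prebuilt peptide index.
#' @return object of class \code{rank_profile}: list with \code{rank},
#'   \code{spectra} (microbial taxon x subject spectral counts),
#'   \code{peptides} (distinct unique-peptide tallies) and
#'   \code{host_spectra} (per-subject host spectral counts).
#' @export
build_rank_profile <- function(psms, database, rank, index = NULL) {
  rank <- match.arg(rank, TAX_RANKS)
  if (is.null(index)) index <- build_peptide_index(database)
  subjects <- sort(unique(psms$subject_id))
  peps <- unique(psms$peptide)
  taxon <- vapply(peps, peptide_uniqueness, character(1),
                  database = database, rank = rank, index = index)
  host_taxa <- unique(database[[rank]][database$is_host])
  is_host_taxon <- !is.na(taxon) & taxon %in% host_taxa
  mic_taxa <- sort(unique(taxon[!is.na(taxon) & !is_host_taxon]))

  pep_taxon <- taxon[match(psms$peptide, peps)]
  sub_f <- factor(psms$subject_id, levels = subjects)
  mic_sel <- !is.na(pep_taxon) & !(pep_taxon %in% host_taxa)
  spectra <- table(factor(pep_taxon[mic_sel], levels = mic_taxa),
                   sub_f[mic_sel])
  spectra <- matrix(as.integer(spectra), nrow = length(mic_taxa),
                    dimnames = list(mic_taxa, subjects))
  # distinct unique peptides per cell
  cell <- unique(data.frame(t = pep_taxon[mic_sel],
                            s = psms$subject_id[mic_sel],
                            p = psms$peptide[mic_sel],
                            stringsAsFactors = FALSE))
  pept <- table(factor(cell$t, levels = mic_taxa),
                factor(cell$s, levels = subjects))
  pept <- matrix(as.integer(pept), nrow = length(mic_taxa),
                 dimnames = list(mic_taxa, subjects))
  host_sel <- !is.na(pep_taxon) & (pep_taxon %in% host_taxa)
  host_spectra <- as.integer(table(sub_f[host_sel]))
  names(host_spectra) <- subjects
  structure(list(rank = rank, spectra = spectra, peptides = pept,
                 host_spectra = host_spectra), class = "rank_profile")
}

#' @export
print.rank_profile <- function(x, ...) {
  cat(sprintf("rank_profile (%s): %d taxa x %d subjects, %d spectra (+%d host)\n",
              x$rank, nrow(x$spectra), ncol(x$spectra), sum(x$spectra),
              sum(x$host_spectra)))
  invisible(x)
}

#' Strain detection tiers
#'
#' Counts, per subject, the strains detected with at least 1, 2 and 5
#' unique spectra — the confidence tiers used when claiming a strain's
#' presence.
#'
#' @param profile a strain-rank \code{rank_profile}.
#' @param thresholds increasing integer thresholds.
#' @return thresholds x subject matrix of strain counts (monotone
#'   non-increasing down the rows).
#' @export
strain_detection_tiers <- function(profile, thresholds = c(1L, 2L, 5L)) {
  stopifnot(inherits(profile, "rank_profile"))
  m <- profile$spectra
  out <- vapply(thresholds, function(th) colSums(m >= th),
                numeric(ncol(m)))
  out <- t(matrix(out, ncol = length(thresholds),
                  dimnames = list(colnames(m), NULL)))
  rownames(out) <- sprintf(">=%d", thresholds)
  out
}

#' Roll strain-level counts up to species
#'
#' Species counts are the sum of their strains' counts.  With a genus
#' restriction the matrix is limited to that genus' species and each
#' subject column is normalized to fractions (columns with no spectra
#' stay zero).
#'
#' @param profile strain-rank \code{rank_profile}.
#' @param taxonomy strain-level taxonomy table.
#' @param genus optional genus name to restrict (and normalize) to.
#' @return species x subject matrix (counts, or fractions under a genus
#'   restriction).
#' @export
species_rollup <- function(profile, taxonomy, genus = NULL) {
  stopifnot(inherits(profile, "rank_profile"), profile$rank == "strain")
  strains <- rownames(profile$spectra)
  unknown <- setdiff(strains, taxonomy$strain)
  if (length(unknown))
    stopf("profile strain(s) missing from taxonomy: %s",
          paste(utils::head(unknown, 5), collapse = ", "))
  sp <- strain_rank(taxonomy, strains, "species")
  mat <- rollup_rows(profile$spectra, sp)
  if (!is.null(genus)) {
    if (!genus %in% taxonomy$genus) stopf("unknown genus: %s", genus)
    keep <- rownames(mat) %in%
      unique(taxonomy$species[taxonomy$genus == genus])
    mat <- mat[keep, , drop = FALSE]
    tot <- colSums(mat)
    mat <- sweep(mat, 2, ifelse(tot > 0, tot, 1), "/")
  }
  mat
}

#' Filter strains by maximum per-subject spectral count
#'
#' Keeps strains reaching at least \code{min_spectra} unique spectra in
#' at least one subject.
#'
#' @param profile strain-rank \code{rank_profile}.
#' @param min_spectra threshold (default 20).
#' @return character vector of retained strain names.
#' @export
abundant_strain_filter <- function(profile, min_spectra = 20L) {
  stopifnot(inherits(profile, "rank_profile"))
  m <- profile$spectra
  rownames(m)[apply(m, 1, max) >= min_spectra]
}
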