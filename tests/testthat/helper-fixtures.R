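# Programmatic fixtures shared across test files.

# build a protein_db data.frame from per-record arguments
make_db <- function(accession, sequence,
                    gene_name = "", uniref50_id = "",
                    family = "Fam01", genus = "Genus01",
                    species = "Genus01 sp01", strain = "Genus01 sp01 st01",
                    is_decoy = FALSE, is_host = FALSE) {
  n <- length(accession)
  rep_n <- function(x) if (length(x) == 1L) rep(x, n) else x
  db <- data.frame(accession = accession, sequence = rep_n(sequence),
                   gene_name = rep_n(gene_name),
                   uniref50_id = rep_n(uniref50_id),
                   family = rep_n(family), genus = rep_n(genus),
                   species = rep_n(species), strain = rep_n(strain),
                   is_decoy = rep_n(is_decoy), is_host = rep_n(is_host),
                   stringsAsFactors = FALSE)
  class(db) <- c("protein_db", "data.frame")
  db
}

# build a PSM table: peptides + their matched accession lists
make_psms <- function(peptides, accessions, subjects = "A", scores = 50,
                      ids = NULL) {
  n <- length(peptides)
  rep_n <- function(x) if (length(x) == 1L) rep(x, n) else x
  data.frame(
    spectrum_id = ids %||% sprintf("sp%04d", seq_len(n)),
    subject_id = rep_n(subjects),
    peptide = peptides,
    accessions = vapply(accessions, paste, character(1), collapse = ";"),
    score = rep_n(scores),
    stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# build a protein_groups object directly from member/peptide lists
make_groups <- function(members, peptides) {
  rep_acc <- vapply(members, function(m) sort(m)[1], character(1))
  out <- data.frame(group_id = paste0("PG:", rep_acc),
                    representative = rep_acc, stringsAsFactors = FALSE)
  out$members <- lapply(members, sort)
  out$peptides <- lapply(peptides, sort)
  class(out) <- c("protein_groups", "data.frame")
  out
}

# a small fully-specified two-genus community for end-to-end tests
tiny_community <- function(seed = 1L, depth = 400L,
                           host_spectrum_fraction = 0.1,
                           decoy_hit_rate = 0.02) {
  tx <- build_taxonomy(2, 2, 2, seed = seed)
  db <- synthesize_proteomes(tx, proteins_per_strain = 4L,
                             homolog_family_count = 12L,
                             gene_annotation_rate = 0.5, seed = seed,
                             host_protein_count = 5L)
  strains <- tx$strain
  prof_a <- stats::setNames(rep(1 / length(strains), length(strains)),
                            strains)
  prof_b <- stats::setNames(rev(seq_along(strains)) /
                              sum(seq_along(strains)), strains)
  spec <- community_spec(
    subjects = c("A", "B"),
    profiles = list(A = prof_a, B = prof_b),
    host_spectrum_fraction = host_spectrum_fraction, depth = depth,
    decoy_hit_rate = decoy_hit_rate, homolog_family_count = 12L,
    gene_annotation_rate = 0.5, seed = seed)
  list(spec = spec, taxonomy = tx, database = db)
}
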