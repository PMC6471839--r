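#' Declarative specification of a synthetic community experiment
#'
#' Collects every knob of the synthetic-data generator: the subjects,
#' their strain-level abundance profiles, sampling depth, the host
#' protein contribution, the decoy hit rate and the search-score model.
#'
#' @param subjects character vector of subject ids.
#' @param profiles named list (one entry per subject) of named numeric
#'   vectors mapping strain name to relative abundance; each profile must
#'   sum to 1 over microbial strains.
#' @param host_spectrum_fraction fraction in [0, 1) of spectra drawn from
#'   host proteins.
#' @param depth target number of spectra per subject (positive integer);
#'   either a single value or one per subject.
#' @param decoy_hit_rate fraction in [0, 0.1] of spectra assigned to a
#'   decoy-only match (search-engine noise).
#' @param homolog_family_count number of UniRef50-like homolog families
#'   in the generated database.
#' @param gene_annotation_rate fraction of homolog families that carry a
#'   characterized gene name.
#' @param seed integer random seed; identical spec + seed gives
#'   byte-identical outputs.
#' @param noise_sd_16s standard deviation of the log-scale multiplicative
#'   noise linking true genus abundance to 16S read counts.
#' @param score_mean_target,score_mean_decoy,score_sd Gaussian
#'   search-score model for correct and decoy/noise matches
#'   (\code{score_mean_target > score_mean_decoy}).
#' @return object of class \code{community_spec}.
#' @export
community_spec <- function(subjects, profiles,
                           host_spectrum_fraction = 0.18,
                           depth = 3000L,
                           decoy_hit_rate = 0.01,
                           homolog_family_count = 60L,
                           gene_annotation_rate = 0.6,
                           seed = 1L,
                           noise_sd_16s = 0.25,
                           score_mean_target = 60,
                           score_mean_decoy = 40,
                           score_sd = 6) {
  stopifnot(is.character(subjects), length(subjects) >= 1,
            !anyDuplicated(subjects))
  if (!all(subjects %in% names(profiles)))
    stopf("profiles missing for subject(s): %s",
          paste(setdiff(subjects, names(profiles)), collapse = ", "))
  for (s in subjects) {
    p <- profiles[[s]]
    if (is.null(names(p)) || any(p < 0))
      stopf("profile for subject %s must be a named non-negative vector", s)
    if (abs(sum(p) - 1) > 1e-9)
      stopf("profile for subject %s must sum to 1 (got %.12f)", s, sum(p))
  }
  if (host_spectrum_fraction < 0 || host_spectrum_fraction >= 1)
    stopf("host_spectrum_fraction must be in [0, 1)")
  if (decoy_hit_rate < 0 || decoy_hit_rate > 0.1)
    stopf("decoy_hit_rate must be in [0, 0.1]")
  depth <- as.integer(depth)
  if (length(depth) == 1L) depth <- rep(depth, length(subjects))
  if (length(depth) != length(subjects) || any(depth < 1))
    stopf("depth must be a positive integer, one value or one per subject")
  if (homolog_family_count < 1) stopf("homolog_family_count must be >= 1")
  if (gene_annotation_rate < 0 || gene_annotation_rate > 1)
    stopf("gene_annotation_rate must be in [0, 1]")
  if (score_mean_target <= score_mean_decoy)
    stopf("score_mean_target must exceed score_mean_decoy")
  structure(list(
    subjects = subjects,
    profiles = profiles[subjects],
    host_spectrum_fraction = host_spectrum_fraction,
    depth = stats::setNames(depth, subjects),
    decoy_hit_rate = decoy_hit_rate,
    homolog_family_count = as.integer(homolog_family_count),
    gene_annotation_rate = gene_annotation_rate,
    seed = as.integer(seed),
    noise_sd_16s = noise_sd_16s,
    score_mean_target = score_mean_target,
    score_mean_decoy = score_mean_decoy,
    score_sd = score_sd), class = "community_spec")
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein_sequence <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

mutate_sequence <- function(sequence, rate) {
  if (rate <= 0) return(sequence)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(res)) < rate
  if (any(hit)) res[hit] <- sample(AA20, sum(hit), replace = TRUE)
  paste(res, collapse = "")
}

random_gene_names <- function(n) {
  # characterized-looking bacterial gene symbols: three lowercase + one
  # uppercase letter (gltB style), unique within the call
  out <- character(0)
  while (length(out) < n) {
    cand <- paste0(
      apply(matrix(sample(letters, 3 * n, replace = TRUE), ncol = 3),
            1, paste, collapse = ""),
      sample(LETTERS, n, replace = TRUE))
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

#' Synthesize a protein sequence database for a community
#'
#' Generates \code{proteins_per_strain} proteins for every strain in the
#' taxonomy, organised into UniRef50-like homolog families: each family
#' has a template sequence and members are point-mutated copies (>= 80
#' percent identity), so tryptic peptides are frequently shared within a
#' family — the cross-taxon homology structure that metaclustering
#' exploits.  A fraction \code{gene_annotation_rate} of families carries
#' a characterized gene name shared by all members; the remainder get an
#' uninformative locus tag or no name.  A disjoint set of host proteins
#' is appended, and every target record receives a reversed-sequence
#' decoy twin.
#'
#' @param taxonomy strain-level taxonomy data.frame
#'   (\code{\link{build_taxonomy}}).
#' @param proteins_per_strain proteins generated per strain.
#' @param homolog_family_count number of homolog families (>= 1).
#' @param gene_annotation_rate fraction of families with a characterized
#'   gene name.
#' @param seed integer random seed.
#' @param host_protein_count host proteins appended (0 for none).
#' @param mutation_rate per-residue substitution rate within a family
#'   (<= 0.2 keeps members above 80 percent identity).
#' @param cross_genus_fraction fraction of families whose members span
#'   genera; the rest stay within their home genus.
#' @param length_range protein length range (residues).
#' @param genus_gene_pools optional named list mapping genus -> character
#'   vector of gene names; annotated families homed in a listed genus
#'   draw their name from that pool (in order) before falling back to
#'   random names, and a pool named \code{"*"} feeds the cross-genus
#'   families.  Used to give genera distinctive pathway repertoires.
#' @return a \code{protein_db} data.frame with columns accession,
#'   sequence, gene_name, uniref50_id, family, genus, species, strain,
#'   is_decoy, is_host.
#' @export
synthesize_proteomes <- function(taxonomy, proteins_per_strain = 6L,
                                 homolog_family_count = 60L,
                                 gene_annotation_rate = 0.6,
                                 seed = 1L,
                                 host_protein_count = 30L,
                                 mutation_rate = 0.03,
                                 cross_genus_fraction = 0.3,
                                 length_range = c(200L, 320L),
                                 genus_gene_pools = NULL) {
  if (nrow(taxonomy) == 0L) stopf("taxonomy must contain at least one strain")
  if (homolog_family_count < 1) stopf("homolog_family_count must be >= 1")
  if (mutation_rate > 0.2)
    stopf("mutation_rate above 0.2 breaks the 80%% family identity floor")
  with_seed(seed, {
    genera <- unique(taxonomy$genus)
    nf <- as.integer(homolog_family_count)
    # family richness scales with how many strains a genus contributes
    gsize <- as.numeric(table(taxonomy$genus)[genera])
    home_genus <- sample(genera, nf, replace = TRUE, prob = gsize)
    # every genus hosts at least one family (when there are enough)
    missing <- setdiff(genera, home_genus)
    if (length(missing) && length(missing) <= nf)
      home_genus[seq_along(missing)] <- missing
    is_cross <- stats::runif(nf) < cross_genus_fraction
    templates <- vapply(seq_len(nf), function(i)
      random_protein_sequence(sample(length_range[1]:length_range[2], 1L)),
      character(1))
    annotated <- stats::runif(nf) < gene_annotation_rate
    # draw names: genus pools first (for genus-restricted families), then
    # unique random symbols
    fam_gene <- character(nf)
    pool_used <- stats::setNames(integer(length(genus_gene_pools)),
                                 names(genus_gene_pools))
    rnd <- random_gene_names(nf)
    for (i in seq_len(nf)) {
      if (!annotated[i]) {
        fam_gene[i] <- if (stats::runif(1) < 0.5)
          sprintf("%s_%04d", paste(sample(LETTERS, 2), collapse = ""),
                  sample(1000:9999, 1)) else ""
        next
      }
      g <- if (is_cross[i]) "*" else home_genus[i]
      pool <- genus_gene_pools[[g]]
      if (!is.null(pool) && pool_used[[g]] < length(pool)) {
        pool_used[[g]] <- pool_used[[g]] + 1L
        fam_gene[i] <- pool[[pool_used[[g]]]]
      } else {
        fam_gene[i] <- rnd[i]
      }
    }
    fam_ur <- sprintf("UR%04d", seq_len(nf))

    # allocate each strain's protein slots to eligible families
    recs <- vector("list", nrow(taxonomy))
    for (k in seq_len(nrow(taxonomy))) {
      g <- taxonomy$genus[k]
      eligible <- which(is_cross | home_genus == g)
      if (!length(eligible)) eligible <- seq_len(nf)
      fams <- if (length(eligible) >= proteins_per_strain)
        sample(eligible, proteins_per_strain)
      else sample(eligible, proteins_per_strain, replace = TRUE)
      recs[[k]] <- data.frame(
        fam = fams, strain_row = k, stringsAsFactors = FALSE)
    }
    alloc <- do.call(rbind, recs)
    seqs <- vapply(alloc$fam, function(f)
      mutate_sequence(templates[f], mutation_rate), character(1))
    db <- data.frame(
      accession = sprintf("P%05d", seq_len(nrow(alloc))),
      sequence = seqs,
      gene_name = fam_gene[alloc$fam],
      uniref50_id = fam_ur[alloc$fam],
      family = taxonomy$family[alloc$strain_row],
      genus = taxonomy$genus[alloc$strain_row],
      species = taxonomy$species[alloc$strain_row],
      strain = taxonomy$strain[alloc$strain_row],
      is_decoy = FALSE, is_host = FALSE,
      stringsAsFactors = FALSE)

    if (host_protein_count > 0) {
      n <- as.integer(host_protein_count)
      host_annot <- stats::runif(n) < gene_annotation_rate
      host_names <- ifelse(host_annot, toupper(random_gene_names(n)), "")
      host <- data.frame(
        accession = sprintf("H%05d", seq_len(n)),
        sequence = vapply(seq_len(n), function(i)
          random_protein_sequence(
            sample(length_range[1]:length_range[2], 1L)), character(1)),
        gene_name = host_names,
        uniref50_id = sprintf("URH%04d", seq_len(n)),
        family = HOST_LINEAGE[["family"]],
        genus = HOST_LINEAGE[["genus"]],
        species = HOST_LINEAGE[["species"]],
        strain = HOST_LINEAGE[["strain"]],
        is_decoy = FALSE, is_host = TRUE,
        stringsAsFactors = FALSE)
      db <- rbind(db, host)
    }

    decoys <- db
    decoys$accession <- paste0("DECOY_", db$accession)
    decoys$sequence <- vapply(db$sequence, function(s)
      paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
      character(1), USE.NAMES = FALSE)
    decoys$gene_name <- ""
    decoys$uniref50_id <- ""
    decoys$is_decoy <- TRUE
    out <- rbind(db, decoys)
    rownames(out) <- NULL
    class(out) <- c("protein_db", "data.frame")
    out
  })
}
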