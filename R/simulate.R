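# Synthetic spectral sampling: draws PSM tables and 16S read counts from
# a community_spec against a synthesized protein database, recording the
# ground truth used by parameter-recovery tests.

digest_all <- function(database) {
  lapply(database$sequence, tryptic_digest)
}

index_from_lists <- function(database, pep_lists) {
  idx <- new.env(parent = emptyenv(), hash = TRUE,
                 size = max(29L, nrow(database) * 32L))
  for (i in seq_along(pep_lists)) {
    acc <- database$accession[i]
    for (p in pep_lists[[i]]) idx[[p]] <- c(idx[[p]], acc)
  }
  idx
}

# true abundance matrices at every rank from strain-level profiles
truth_from_profiles <- function(spec, taxonomy) {
  strains <- taxonomy$strain
  mat <- matrix(0, nrow = length(strains), ncol = length(spec$subjects),
                dimnames = list(strains, spec$subjects))
  for (s in spec$subjects) {
    p <- spec$profiles[[s]]
    unknown <- setdiff(names(p), strains)
    if (length(unknown))
      stopf("profile for %s names unknown strain(s): %s", s,
            paste(unknown, collapse = ", "))
    mat[names(p), s] <- p
  }
  ranks <- list(strain = mat)
  for (r in c("species", "genus", "family"))
    ranks[[r]] <- rollup_rows(mat, strain_rank(taxonomy, strains, r))
  ranks
}

rollup_rows <- function(mat, groups) {
  agg <- rowsum(mat, group = groups, reorder = TRUE)
  agg[order(rownames(agg)), , drop = FALSE]
}

#' Draw per-subject PSM tables from a synthetic community
#'
#' For every subject, \code{depth} spectra are drawn.  Each spectrum is a
#' decoy-only noise match with probability \code{decoy_hit_rate};
#' otherwise it comes from a host protein with probability
#' \code{host_spectrum_fraction}, else from a microbial strain chosen by
#' the subject's abundance profile.  Within the source protein a tryptic
#' peptide is drawn uniformly, and the PSM's matched accessions list
#' every database protein (target or decoy) sharing that exact tryptic
#' peptide.  Scores are Gaussian: correct matches around
#' \code{score_mean_target}, decoy/noise matches around
#' \code{score_mean_decoy}.
#'
#' @param spec a \code{\link{community_spec}}.
#' @param database a \code{protein_db} from
#'   \code{\link{synthesize_proteomes}} (must contain at least one
#'   microbial protein; host records only if
#'   \code{host_spectrum_fraction > 0}).
#' @param taxonomy the strain-level taxonomy the profiles refer to.
#' @return list with elements \code{psms} (data.frame: spectrum_id,
#'   subject_id, peptide, accessions (semicolon-joined), score) and
#'   \code{truth} (class \code{synthetic_truth}: per-rank true abundance
#'   matrices and the true protein-to-family partition).
#' @export
sample_psms <- function(spec, database, taxonomy) {
  stopifnot(inherits(spec, "community_spec"))
  if (!any(!database$is_decoy & !database$is_host))
    stopf("database contains no microbial target proteins")
  if (spec$host_spectrum_fraction > 0 && !any(database$is_host &
                                              !database$is_decoy))
    stopf("host_spectrum_fraction > 0 but database has no host proteins")
  pep_lists <- digest_all(database)
  index <- index_from_lists(database, pep_lists)
  lens <- lengths(pep_lists)

  target_rows <- which(!database$is_decoy & lens > 0L)
  host_rows <- target_rows[database$is_host[target_rows]]
  decoy_rows <- which(database$is_decoy & lens > 0L)
  rows_by_strain <- split(
    target_rows[!database$is_host[target_rows]],
    database$strain[target_rows[!database$is_host[target_rows]]])

  truth <- truth_from_profiles(spec, taxonomy)
  per_subject <- vector("list", length(spec$subjects))
  with_seed(spec$seed, {
    for (k in seq_along(spec$subjects)) {
      s <- spec$subjects[k]
      n <- spec$depth[[s]]
      is_decoy_hit <- stats::runif(n) < spec$decoy_hit_rate
      is_host_hit <- !is_decoy_hit &
        stats::runif(n) < spec$host_spectrum_fraction
      src_row <- integer(n)
      # microbial spectra: strain by abundance, protein uniform in strain
      mic <- which(!is_decoy_hit & !is_host_hit)
      if (length(mic)) {
        prof <- spec$profiles[[s]]
        prof <- prof[prof > 0]
        pick <- sample(names(prof), length(mic), replace = TRUE, prob = prof)
        for (st in unique(pick)) {
          rows <- rows_by_strain[[st]]
          if (is.null(rows) || !length(rows))
            stopf("strain %s has no digestible proteins", st)
          sel <- which(pick == st)
          src_row[mic[sel]] <- rows[sample.int(length(rows), length(sel),
                                               replace = TRUE)]
        }
      }
      hh <- which(is_host_hit)
      if (length(hh))
        src_row[hh] <- host_rows[sample.int(length(host_rows), length(hh),
                                            replace = TRUE)]
      dd <- which(is_decoy_hit)
      if (length(dd))
        src_row[dd] <- decoy_rows[sample.int(length(decoy_rows), length(dd),
                                             replace = TRUE)]
      pep_idx <- floor(stats::runif(n) * lens[src_row]) + 1L
      peptide <- vapply(seq_len(n), function(i)
        pep_lists[[src_row[i]]][pep_idx[i]], character(1))
      accessions <- vapply(seq_len(n), function(i) {
        acc <- index_lookup(index, peptide[i])
        if (is_decoy_hit[i])
          acc <- acc[startsWith(acc, "DECOY_")]
        paste(acc, collapse = ";")
      }, character(1))
      score <- ifelse(is_decoy_hit,
                      stats::rnorm(n, spec$score_mean_decoy, spec$score_sd),
                      stats::rnorm(n, spec$score_mean_target, spec$score_sd))
      per_subject[[k]] <- data.frame(
        spectrum_id = sprintf("%s_%06d", s, seq_len(n)),
        subject_id = s,
        peptide = peptide,
        accessions = accessions,
        score = round(score, 4),
        stringsAsFactors = FALSE)
    }
  })
  psms <- do.call(rbind, per_subject)
  rownames(psms) <- NULL
  mic_targets <- !database$is_decoy & !database$is_host
  truth_obj <- structure(list(
    abundance = truth,
    protein_partition = stats::setNames(
      database$uniref50_id[mic_targets],
      database$accession[mic_targets])), class = "synthetic_truth")
  list(psms = psms, truth = truth_obj)
}

#' Draw a 16S genus read-count table from the simulated truth
#'
#' Genus read probabilities are the true genus fractions perturbed by
#' per-cell lognormal noise, then multinomially sampled to
#' \code{read_depth} reads per subject.
#'
#' @param truth a \code{synthetic_truth} from \code{\link{sample_psms}}.
#' @param read_depth reads per subject (>= 1).
#' @param noise_sd_16s log-scale noise standard deviation (0 = noiseless).
#' @param seed integer random seed.
#' @return genus x subject integer matrix, method tag "16S" (see
#'   \code{\link{abundance_matrix}}).
#' @export
sample_16s <- function(truth, read_depth = 5000L, noise_sd_16s = 0.25,
                       seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (read_depth < 1) stopf("read_depth must be >= 1")
  g <- truth$abundance$genus
  g <- g[rownames(g) != HOST_LINEAGE[["genus"]], , drop = FALSE]
  with_seed(seed, {
    noisy <- g * exp(matrix(stats::rnorm(length(g), 0, noise_sd_16s),
                            nrow = nrow(g)))
    reads <- matrix(0, nrow(noisy), ncol(noisy), dimnames = dimnames(noisy))
    for (j in seq_len(ncol(noisy))) {
      p <- noisy[, j]
      if (sum(p) <= 0) stopf("subject %s has no genus abundance",
                             colnames(noisy)[j])
      reads[, j] <- stats::rmultinom(1, size = read_depth,
                                     prob = p / sum(p))[, 1]
    }
    abundance_matrix(reads, method = "16S")
  })
}

#' Infant fecal community preset
#'
#' Ships the default study conditions the package validates against: an
#' eight-subject infant cohort (ids C, T, B, P, M, N, E, R) with a
#' dominant \emph{Bifidobacterium} genus split over four species and two
#' strains each, a pair of monozygotic twins (M, N) with identical
#' profiles, an antibiotic-treated subject (R) dominated by
#' Enterobacteriaceae genera (\emph{Klebsiella}, \emph{Escherichia},
#' \emph{Citrobacter}), host protein spectra at 18 percent, and homolog
#' families giving \emph{Bifidobacterium} a urea-cycle/nitrogen gene
#' repertoire and the Enterobacteriaceae a fatty-acid-biosynthesis
#' repertoire (shared families carry TCA-cycle and housekeeping genes).
#'
#' @param depth spectra per subject.
#' @param proteins_per_strain,homolog_family_count,gene_annotation_rate,
#'   host_protein_count database generation knobs (see
#'   \code{\link{synthesize_proteomes}}).
#' @param host_spectrum_fraction,decoy_hit_rate,noise_sd_16s sampling
#'   knobs (see \code{\link{community_spec}}).
#' @param cross_genus_fraction fraction of homolog families spanning
#'   genera; 0 removes cross-genus homology (every peptide then resolves
#'   at genus rank up to chance collisions).
#' @param seed integer random seed.
#' @return list with elements \code{spec} (community_spec),
#'   \code{taxonomy} and \code{database}.
#' @export
infant_community <- function(depth = 3000L, proteins_per_strain = 6L,
                             homolog_family_count = 60L,
                             gene_annotation_rate = 0.6,
                             host_protein_count = 30L,
                             host_spectrum_fraction = 0.18,
                             decoy_hit_rate = 0.01,
                             noise_sd_16s = 0.25,
                             cross_genus_fraction = 0.3,
                             seed = 42L) {
  bif_sp <- c("Bifidobacterium breve", "Bifidobacterium longum",
              "Bifidobacterium bifidum", "Bifidobacterium pseudocatenulatum")
  sp <- c(rep(bif_sp, each = 2L),
          "Bacteroides fragilis", "Bacteroides vulgatus",
          "Parabacteroides distasonis", "Parabacteroides distasonis",
          "Veillonella parvula", "Lactobacillus rhamnosus",
          "Klebsiella pneumoniae", "Klebsiella pneumoniae",
          "Klebsiella oxytoca", "Escherichia coli", "Citrobacter freundii")
  genus <- sub(" .*", "", sp)
  fam_of <- c(Bifidobacterium = "Bifidobacteriaceae",
              Bacteroides = "Bacteroidaceae",
              Parabacteroides = "Tannerellaceae",
              Veillonella = "Veillonellaceae",
              Lactobacillus = "Lactobacillaceae",
              Klebsiella = "Enterobacteriaceae",
              Escherichia = "Enterobacteriaceae",
              Citrobacter = "Enterobacteriaceae")
  strain <- stats::ave(sp, sp, FUN = function(x)
    sprintf("%s str%02d", x, seq_along(x)))
  taxonomy <- taxonomy_table(family = unname(fam_of[genus]), genus = genus,
                             species = sp, strain = strain)

  genera <- c("Bifidobacterium", "Bacteroides", "Parabacteroides",
              "Veillonella", "Lactobacillus", "Klebsiella", "Escherichia",
              "Citrobacter")
  gw <- rbind(
    C = c(0.74, 0.06, 0.04, 0.04, 0.03, 0.04, 0.03, 0.02),
    T = c(0.55, 0.22, 0.06, 0.04, 0.03, 0.04, 0.04, 0.02),
    B = c(0.68, 0.09, 0.06, 0.05, 0.03, 0.04, 0.03, 0.02),
    P = c(0.36, 0.08, 0.33, 0.05, 0.03, 0.06, 0.05, 0.04),
    M = c(0.70, 0.08, 0.05, 0.04, 0.03, 0.05, 0.03, 0.02),
    N = c(0.70, 0.08, 0.05, 0.04, 0.03, 0.05, 0.03, 0.02),
    E = c(0.62, 0.10, 0.07, 0.06, 0.04, 0.05, 0.04, 0.02),
    R = c(0.04, 0.05, 0.03, 0.02, 0.01, 0.55, 0.18, 0.12))
  colnames(gw) <- genera
  bifw <- rbind(  # breve, longum, bifidum, pseudocatenulatum
    C = c(0.25, 0.55, 0.10, 0.10),
    T = c(0.60, 0.20, 0.10, 0.10),
    B = c(0.55, 0.15, 0.20, 0.10),
    P = c(0.25, 0.15, 0.10, 0.50),
    M = c(0.50, 0.10, 0.30, 0.10),
    N = c(0.50, 0.10, 0.30, 0.10),
    E = c(0.55, 0.20, 0.15, 0.10),
    R = c(0.40, 0.30, 0.20, 0.10))
  colnames(bifw) <- bif_sp

  profiles <- lapply(rownames(gw), function(s) {
    p <- stats::setNames(numeric(nrow(taxonomy)), taxonomy$strain)
    for (g in genera) {
      rows <- which(taxonomy$genus == g)
      if (g == "Bifidobacterium") {
        # species weight split equally over that species' strains
        n_str <- table(taxonomy$species[rows])
        w <- as.numeric(bifw[s, taxonomy$species[rows]] /
                          n_str[taxonomy$species[rows]])
        p[rows] <- gw[s, g] * w / sum(w)
      } else {
        p[rows] <- gw[s, g] / length(rows)
      }
    }
    p / sum(p)
  })
  names(profiles) <- rownames(gw)

  pools <- list(
    Bifidobacterium = c("argA", "argB", "argC", "argD", "argE", "argF",
                        "argG", "argH", "gdhA", "gltB", "ureC"),
    Klebsiella = c("fabA", "fabB", "fabD", "fabF", "fabG", "fabH"),
    Escherichia = c("fabI", "fabZ", "accA", "accB"),
    Citrobacter = c("accC", "accD"),
    "*" = c("sucA", "sucB", "sdhA", "mdh", "gltA", "icd", "fumA"))

  spec <- community_spec(
    subjects = rownames(gw), profiles = profiles,
    host_spectrum_fraction = host_spectrum_fraction, depth = depth,
    decoy_hit_rate = decoy_hit_rate,
    homolog_family_count = homolog_family_count,
    gene_annotation_rate = gene_annotation_rate, seed = seed,
    noise_sd_16s = noise_sd_16s)
  database <- synthesize_proteomes(
    taxonomy, proteins_per_strain = proteins_per_strain,
    homolog_family_count = homolog_family_count,
    gene_annotation_rate = gene_annotation_rate, seed = seed,
    host_protein_count = host_protein_count,
    cross_genus_fraction = cross_genus_fraction,
    genus_gene_pools = pools)
  list(spec = spec, taxonomy = taxonomy, database = database)
}

#' Generate a complete synthetic data set, optionally writing it to disk
#'
#' Runs \code{\link{sample_psms}} and \code{\link{sample_16s}} for a
#' community and, when \code{outdir} is given, writes the database FASTA,
#' one PSM TSV per subject, the 16S genus table and the truth JSON.
#' Outputs are byte-identical for identical spec + seed.
#'
#' @param community list with \code{spec}, \code{taxonomy},
#'   \code{database} (e.g. from \code{\link{infant_community}}).
#' @param read_depth_16s reads per subject for the 16S table.
#' @param outdir optional output directory (created if missing).
#' @return list: \code{psms}, \code{truth}, \code{reads_16s},
#'   \code{database}, \code{taxonomy}, \code{spec}.
#' @export
simulate_community <- function(community, read_depth_16s = 5000L,
                               outdir = NULL) {
  spec <- community$spec
  drawn <- sample_psms(spec, community$database, community$taxonomy)
  reads <- sample_16s(drawn$truth, read_depth = read_depth_16s,
                      noise_sd_16s = spec$noise_sd_16s,
                      seed = spec$seed + 1L)
  out <- list(psms = drawn$psms, truth = drawn$truth, reads_16s = reads,
              database = community$database, taxonomy = community$taxonomy,
              spec = spec)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_database(community$database, file.path(outdir, "database.fasta"))
    for (s in spec$subjects)
      write_psms(drawn$psms[drawn$psms$subject_id == s, ],
                 file.path(outdir, sprintf("psms_%s.tsv", s)))
    write_matrix_tsv(reads, file.path(outdir, "reads_16s.tsv"),
                     feature_col = "genus")
    truth_json <- list(
      abundance = lapply(drawn$truth$abundance, function(m)
        as.data.frame(as.table(m), stringsAsFactors = FALSE)),
      protein_partition = as.list(drawn$truth$protein_partition))
    jsonlite::write_json(truth_json, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
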