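#' Run the full metaproteomic analysis on a community
#'
#' End-to-end driver: simulate (or accept) the inputs, FDR-filter the
#' PSMs, infer parsimony protein groups, build metaclusters and their
#' count matrix, derive the accounting table, build strain and genus
#' rank profiles with detection tiers and a species roll-up, compare the
#' proteomic genus profile against the 16S read counts (with the
#' Enterobacteriaceae genera merged into one family row), compute all
#' pairwise between-subject metacluster correlations, and contrast
#' pathway-level counts between the treated subject and the rest.
#'
#' @param community list with \code{spec}, \code{taxonomy},
#'   \code{database} (see \code{\link{infant_community}}).
#' @param target_fdr PSM-level FDR target (default 0.016).
#' @param read_depth_16s 16S reads per subject.
#' @param top_k genera kept in the heat-map matrix.
#' @param pathway_table gene-to-pathway data.frame; defaults to the
#'   synthetic three-pathway table shipped with the package.
#' @param treated treated subject id(s) for the pathway contrast; NULL
#'   skips the contrast.
#' @param merge_genera,family_name genera collapsed into one family row
#'   before the cross-method comparison.
#' @return results list consumed by \code{\link{write_reports}}.
#' @export
run_pipeline <- function(community = infant_community(),
                         target_fdr = 0.016,
                         read_depth_16s = 5000L,
                         top_k = 12L,
                         pathway_table = NULL,
                         treated = "R",
                         merge_genera = c("Klebsiella", "Escherichia",
                                          "Citrobacter"),
                         family_name = "Enterobacteriaceae") {
  spec <- community$spec
  database <- community$database
  sim <- simulate_community(community, read_depth_16s = read_depth_16s)
  filt <- fdr_filter(sim$psms, target_fdr = target_fdr)
  res <- list(spec = spec, fdr = filt$fdr_result, truth = sim$truth,
              reads_16s = sim$reads_16s, psms_retained = filt$psms)

  if (nrow(filt$psms) == 0L) {
    res$accounting <- empty_accounting()
    return(res)
  }
  groups <- infer_protein_groups(filt$psms, database)
  res$groups <- groups
  res$group_counts <- assign_spectral_counts(groups, filt$psms)
  mcs <- build_metaclusters(groups, database)
  res$metaclusters <- mcs
  res$metacluster_counts <- count_metacluster_spectra(mcs, filt$psms)
  res$accounting <- annotation_summary(mcs, res$metacluster_counts)
  decoy_accs <- unique(unlist(strsplit(
    filt$decoy_psms_at_threshold$accessions, ";", fixed = TRUE)))
  res$protein_level_fdr <- length(decoy_accs) / max(nrow(groups), 1)

  index <- build_peptide_index(database)
  res$profiles <- list(
    strain = build_rank_profile(filt$psms, database, "strain", index),
    genus = build_rank_profile(filt$psms, database, "genus", index))
  res$tiers <- strain_detection_tiers(res$profiles$strain)
  if ("Bifidobacterium" %in% community$taxonomy$genus)
    res$bifidobacterium_species <- species_rollup(
      res$profiles$strain, community$taxonomy, genus = "Bifidobacterium")
  res$abundant_strains <- abundant_strain_filter(res$profiles$strain)

  prot_genus <- abundance_matrix(res$profiles$genus$spectra,
                                 method = "proteomics")
  prot_m <- merge_family(prot_genus, family_name, merge_genera)
  reads_m <- merge_family(sim$reads_16s, family_name, merge_genera)
  cmp <- cross_method_correlation(prot_m, reads_m)
  res$correlations <- data.frame(
    pair = cmp$pair, spearman_rho = cmp$spearman_rho,
    pearson_r = cmp$pearson_r, r_squared = cmp$r_squared, n = cmp$n,
    stringsAsFactors = FALSE)
  res$heatmap <- heatmap_matrix(prot_m, top_k = top_k)

  subjects <- spec$subjects
  pairs <- utils::combn(subjects, 2)
  res$pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    pc <- pairwise_metacluster_correlation(res$metacluster_counts,
                                           pairs[1, k], pairs[2, k])
    data.frame(subject_a = pairs[1, k], subject_b = pairs[2, k],
               pearson_r = pc$pearson_r, r_squared = pc$r_squared,
               n = pc$n, stringsAsFactors = FALSE)
  }))

  if (!is.null(treated)) {
    if (is.null(pathway_table))
      pathway_table <- read_pathway_table(system.file(
        "extdata", "pathways_synthetic.tsv", package = "metapep"))
    untreated <- setdiff(subjects, treated)
    dedup <- deduplicate_at_genus(mcs, groups, filt$psms, database)
    membership <- map_to_pathways(mcs, pathway_table)
    if (nrow(membership))
      res$pathway_contrasts <- contrast_groups(membership, dedup,
                                               treated, untreated)
  }
  res
}

empty_accounting <- function() {
  data.frame(
    source = rep(c("Bacterial", "Human"), each = 2),
    annotation = rep(c("With useful annotation",
                       "Without useful annotation"), 2),
    spectral_counts = 0, unique_peptide_sequences = 0L, metaclusters = 0L,
    stringsAsFactors = FALSE)
}
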