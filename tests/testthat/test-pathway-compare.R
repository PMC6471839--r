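test_that("genus-level deduplication collapses same-genus redundancy", {
  # one metacluster: three same-genus proteins sharing one peptide
  db <- make_db(c("A", "B", "C"), "X", uniref50_id = "U1",
                genus = "GenX")
  groups <- make_groups(list(c("A", "B", "C")), list("PEPSHARE"))
  mc <- build_metaclusters(groups, db)
  psms <- make_psms(rep("PEPSHARE", 4), as.list(rep("A;B;C", 4)))
  dd <- deduplicate_at_genus(mc, groups, psms, db)
  expect_equal(sum(dd), 4)  # 4 spectra counted once each, not x3

  # redundant per-protein counting would have given 12
  redundant <- 4 * 3
  expect_lte(sum(dd), redundant)
})

test_that("deduplication is a no-op when peptides hit single proteins", {
  comm <- tiny_community(seed = 91, depth = 300)
  drawn <- sample_psms(comm$spec, comm$database, comm$taxonomy)
  kept <- fdr_filter(drawn$psms, target_fdr = 0.05)$psms
  g <- infer_protein_groups(kept, comm$database)
  mc <- build_metaclusters(g, comm$database)
  dd <- deduplicate_at_genus(mc, g, kept, comm$database)
  # element-wise: dedup counts never fall below once-per-spectrum counts
  raw <- count_metacluster_spectra(mc, kept)
  expect_true(all(dd >= unclass(raw)[rownames(dd), colnames(dd)]))
  # and never exceed the per-protein redundant bound
  pep_prot <- lengths(strsplit(kept$accessions, ";"))
  expect_lte(sum(dd), sum(pep_prot))
})

test_that("only annotated metaclusters map to pathways, by gene name", {
  db <- make_db(c("A", "B"), "X",
                gene_name = c("gltB", ""), uniref50_id = c("U1", "U2"))
  groups <- make_groups(list("A", "B"), list("PEPAAA", "PEPBBB"))
  mc <- build_metaclusters(groups, db)
  pt <- data.frame(pathway_id = c("P1", "P2"),
                   gene_name = c("gltB", "fabH"),
                   stringsAsFactors = FALSE)
  mm <- map_to_pathways(mc, pt)
  expect_equal(nrow(mm), 1L)
  expect_equal(mm$pathway_id, "P1")
  # the unannotated metacluster never maps
  unann <- mc$metacluster_id[!mc$has_useful_annotation]
  expect_false(any(mm$metacluster_id %in% unann))
  expect_error(map_to_pathways(mc, pt[0, ]), "empty")
})

test_that("pathway join equals a brute-force cross-product filter", {
  set.seed(92)
  for (i in 1:10) {
    genes <- c("aaaA", "bbbB", "cccC", "dddD", "")
    db <- make_db(sprintf("P%02d", 1:6), "X",
                  gene_name = sample(genes, 6, replace = TRUE),
                  uniref50_id = sprintf("U%d", 1:6))
    groups <- make_groups(as.list(db$accession),
                          as.list(sprintf("PEPQ%02d", 1:6)))
    mc <- build_metaclusters(groups, db)
    pt <- data.frame(
      pathway_id = sample(c("P1", "P2"), 5, replace = TRUE),
      gene_name = sample(genes[nzchar(genes)], 5, replace = TRUE),
      stringsAsFactors = FALSE)
    mm <- map_to_pathways(mc, pt)
    # brute force over all (metacluster, pathway-row) pairs
    want <- 0L
    for (k in seq_len(nrow(mc))) {
      if (!mc$has_useful_annotation[k]) next
      for (r in seq_len(nrow(pt))) {
        if (tolower(pt$gene_name[r]) %in% tolower(mc$gene_names[[k]]))
          want <- want + 1L
      }
    }
    expect_equal(nrow(mm), want)
  }
})

test_that("group contrasts classify higher/lower/equivalent correctly", {
  counts <- matrix(c(0, 10, 11, 9, 10, 10,
                     10, 10, 10, 10, 10, 10), 2, 6, byrow = TRUE,
                   dimnames = list(c("MC1", "MC2"),
                                   c("R", "u1", "u2", "u3", "u4", "u5")))
  mm <- data.frame(pathway_id = c("P1", "P2"),
                   metacluster_id = c("MC1", "MC2"),
                   gene_name = c("g1", "g2"), stringsAsFactors = FALSE)
  out <- contrast_groups(mm, counts, treated = "R",
                         untreated = c("u1", "u2", "u3", "u4", "u5"))
  v <- stats::setNames(out$verdicts$verdict, out$verdicts$pathway_id)
  expect_equal(unname(v["P1"]), "lower")      # 0 vs 10 +/- 0.8
  expect_equal(unname(v["P2"]), "equivalent") # exactly the mean
  expect_error(contrast_groups(mm, counts, "R", c("R", "u1")), "overlap")
  expect_error(contrast_groups(mm, counts, character(0), "u1"),
               "non-empty")
})

test_that("untreated mean and SD match a two-pass oracle computation", {
  set.seed(93)
  for (i in 1:10) {
    counts <- matrix(rpois(24, 12), 4, 6,
                     dimnames = list(sprintf("MC%d", 1:4),
                                     c("R", sprintf("u%d", 1:5))))
    mm <- data.frame(pathway_id = "P1",
                     metacluster_id = rownames(counts),
                     gene_name = sprintf("g%d", 1:4),
                     stringsAsFactors = FALSE)
    out <- contrast_groups(mm, counts, "R", sprintf("u%d", 1:5))
    for (k in seq_len(4)) {
      x <- counts[k, sprintf("u%d", 1:5)]
      mu <- sum(x) / 5
      s2 <- sum((x - mu)^2) / 4  # n-1 denominator, two-pass
      row <- out$per_member[out$per_member$metacluster_id ==
                              rownames(counts)[k], ]
      expect_equal(row$untreated_mean, mu)
      expect_equal(row$untreated_sd, sqrt(s2))
    }
  }
})

test_that("verdicts are invariant under permutation of untreated subjects", {
  set.seed(94)
  counts <- matrix(rpois(18, 9), 3, 6,
                   dimnames = list(sprintf("MC%d", 1:3),
                                   c("R", sprintf("u%d", 1:5))))
  mm <- data.frame(pathway_id = rep("P1", 3),
                   metacluster_id = rownames(counts),
                   gene_name = sprintf("g%d", 1:3),
                   stringsAsFactors = FALSE)
  v1 <- contrast_groups(mm, counts, "R", sprintf("u%d", 1:5))$verdicts
  v2 <- contrast_groups(mm, counts, "R",
                        rev(sprintf("u%d", 1:5)))$verdicts
  expect_identical(v1, v2)
})

test_that("swapping gene-rich genera between subjects flips pathway verdicts", {
  # genus A carries urea-cycle genes, genus B fatty-acid genes; subject
  # T1 is A-dominated, subject T2 B-dominated -> opposite verdicts
  tx <- taxonomy_table(
    family = c("FamA", "FamB"), genus = c("GenA", "GenB"),
    species = c("GenA sp", "GenB sp"),
    strain = c("GenA sp st", "GenB sp st"))
  pools <- list(GenA = c("argA", "argB", "argG", "gdhA"),
                GenB = c("fabA", "fabB", "fabH", "accA"))
  db <- synthesize_proteomes(tx, proteins_per_strain = 8,
                             homolog_family_count = 10,
                             gene_annotation_rate = 1, seed = 95,
                             host_protein_count = 0,
                             cross_genus_fraction = 0,
                             genus_gene_pools = pools)
  profiles <- list(
    T1 = stats::setNames(c(0.9, 0.1), tx$strain),
    T2 = stats::setNames(c(0.1, 0.9), tx$strain),
    U1 = stats::setNames(c(0.9, 0.1), tx$strain),
    U2 = stats::setNames(c(0.88, 0.12), tx$strain),
    U3 = stats::setNames(c(0.92, 0.08), tx$strain))
  spec <- community_spec(subjects = names(profiles), profiles = profiles,
                         host_spectrum_fraction = 0, depth = 1500,
                         decoy_hit_rate = 0, seed = 95,
                         homolog_family_count = 10,
                         gene_annotation_rate = 1)
  kept <- fdr_filter(sample_psms(spec, db, tx)$psms, 0.05)$psms
  g <- infer_protein_groups(kept, db)
  mc <- build_metaclusters(g, db)
  dd <- deduplicate_at_genus(mc, g, kept, db)
  pt <- read_pathway_table(system.file("extdata",
                                       "pathways_synthetic.tsv",
                                       package = "metapep"))
  mm <- map_to_pathways(mc, pt)
  out <- contrast_groups(mm, dd, treated = "T2",
                         untreated = c("U1", "U2", "U3"))
  v <- stats::setNames(out$verdicts$verdict, out$verdicts$pathway_id)
  expect_equal(unname(v["UREA_CYCLE"]), "lower")
  expect_equal(unname(v["FATTY_ACID_BIOSYNTHESIS"]), "higher")
})
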