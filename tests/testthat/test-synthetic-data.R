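test_that("taxonomy generation respects counts, uniqueness and determinism", {
  t1 <- build_taxonomy(1, 1, 1, seed = 0)
  expect_equal(nrow(t1), 1L)
  expect_equal(lengths(lapply(t1, unique)), c(family = 1L, genus = 1L,
                                              species = 1L, strain = 1L))
  t2 <- build_taxonomy(2, 2, 2, seed = 1)
  expect_equal(nrow(t2), 8L)
  expect_equal(length(unique(t2$species)), 4L)
  expect_equal(length(unique(t2$genus)), 2L)
  # every strain has exactly one ancestor per rank
  expect_silent(metapep:::validate_taxonomy(t2))
  expect_identical(build_taxonomy(3, 2, 2, seed = 7),
                   build_taxonomy(3, 2, 2, seed = 7))
  expect_error(build_taxonomy(0, 1, 1), "counts")
})

test_that("tryptic digestion follows the K/R-not-before-P rule", {
  alpha <- "ACDEFGHIKLMNPQRSTVWYB"  # B as placeholder residue
  expect_setequal(
    tryptic_digest("AAKBBRCC", 0, min_len = 1, max_len = 10,
                   alphabet = alpha),
    c("AAK", "BBR", "CC"))
  expect_setequal(
    tryptic_digest("AAKPBBR", 0, min_len = 1, max_len = 10,
                   alphabet = alpha),
    "AAKPBBR")
  # [oracle] brute-force enumeration of cleavage-fragment runs
  expect_setequal(
    tryptic_digest("AAKBBR", 1, min_len = 1, max_len = 10,
                   alphabet = alpha),
    oracle_digest("AAKBBR", 1, 1, 10))
  expect_error(tryptic_digest("AAZ1K", 0), "invalid residue")
})

test_that("digestion matches the brute-force oracle on random sequences", {
  set.seed(11)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:25) {
    s <- paste(sample(aas, sample(5:40, 1), replace = TRUE), collapse = "")
    mc <- sample(0:2, 1)
    expect_setequal(tryptic_digest(s, mc, min_len = 2, max_len = 12),
                    oracle_digest(s, mc, 2, 12))
  }
})

test_that("proteome synthesis honours annotation rate, counts and decoys", {
  tx <- build_taxonomy(5, 1, 2, seed = 3)  # 10 strains
  none <- synthesize_proteomes(tx, proteins_per_strain = 5,
                               homolog_family_count = 8,
                               gene_annotation_rate = 0, seed = 3,
                               host_protein_count = 0)
  expect_false(any(is_characterized_gene(none$gene_name)))
  expect_equal(sum(!none$is_decoy), 50L)
  expect_equal(sum(none$is_decoy), 50L)

  full <- synthesize_proteomes(tx, proteins_per_strain = 5,
                               homolog_family_count = 8,
                               gene_annotation_rate = 1, seed = 3,
                               host_protein_count = 0)
  fam_genes <- split(full$gene_name[!full$is_decoy],
                     full$uniref50_id[!full$is_decoy])
  expect_true(all(vapply(fam_genes, function(g)
    length(unique(g)) == 1L && is_characterized_gene(g[1]), logical(1))))

  # decoys are exact reversals of their target twin
  i <- match(paste0("DECOY_", full$accession[1]), full$accession)
  expect_identical(full$sequence[i], paste(
    rev(strsplit(full$sequence[1], "")[[1]]), collapse = ""))

  # family members stay above 80% identity to each other
  fam <- split(full$sequence[!full$is_decoy],
               full$uniref50_id[!full$is_decoy])
  fam <- fam[lengths(fam) >= 2][1:3]
  for (seqs in fam) {
    a <- strsplit(seqs[1], "")[[1]]
    b <- strsplit(seqs[2], "")[[1]]
    expect_gte(mean(a == b), 0.8)
  }
  expect_error(synthesize_proteomes(tx[0, ], seed = 1), "taxonomy")
})

test_that("PSM sampling conserves depth and respects source fractions", {
  comm <- tiny_community(seed = 5, depth = 300)
  drawn <- sample_psms(comm$spec, comm$database, comm$taxonomy)
  expect_equal(as.vector(table(drawn$psms$subject_id)[c("A", "B")]),
               c(300L, 300L))

  # no host spectra when the host fraction is zero
  spec0 <- community_spec(subjects = comm$spec$subjects,
                          profiles = comm$spec$profiles,
                          host_spectrum_fraction = 0, depth = 200,
                          decoy_hit_rate = 0, seed = 2)
  d0 <- sample_psms(spec0, comm$database, comm$taxonomy)
  host_accs <- comm$database$accession[comm$database$is_host]
  hit_accs <- unlist(strsplit(d0$psms$accessions, ";"))
  expect_length(intersect(hit_accs, host_accs), 0L)
})

test_that("a single-strain community maps all spectra to that strain", {
  tx <- build_taxonomy(1, 1, 1, seed = 9)
  db <- synthesize_proteomes(tx, proteins_per_strain = 4,
                             homolog_family_count = 3,
                             gene_annotation_rate = 0.5, seed = 9,
                             host_protein_count = 0)
  prof <- stats::setNames(1, tx$strain)
  spec <- community_spec(subjects = "S", profiles = list(S = prof),
                         host_spectrum_fraction = 0, depth = 150,
                         decoy_hit_rate = 0, seed = 9)
  d <- sample_psms(spec, db, tx)
  accs <- unique(unlist(strsplit(d$psms$accessions, ";")))
  accs <- accs[!startsWith(accs, "DECOY_")]
  expect_true(all(accs %in% db$accession[!db$is_decoy]))
  expect_error(community_spec(subjects = "S", profiles = list(S = prof),
                              depth = 0), "depth")
})

test_that("host spectra land inside the analytic binomial interval", {
  comm <- tiny_community(seed = 21, depth = 1000,
                         host_spectrum_fraction = 0.18,
                         decoy_hit_rate = 0)
  spec <- comm$spec
  spec$subjects <- "A"
  spec$depth <- c(A = 1000L)
  d <- sample_psms(spec, comm$database, comm$taxonomy)
  host_accs <- comm$database$accession[comm$database$is_host &
                                         !comm$database$is_decoy]
  n_host <- sum(vapply(strsplit(d$psms$accessions, ";"), function(a)
    any(a %in% host_accs), logical(1)))
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.18)
  expect_gte(n_host, bounds[1])
  expect_lte(n_host, bounds[2])
})

test_that("truth abundances roll up consistently across ranks", {
  comm <- tiny_community(seed = 4, depth = 100)
  truth <- sample_psms(comm$spec, comm$database, comm$taxonomy)$truth
  ab <- truth$abundance
  tx <- comm$taxonomy
  for (sp in rownames(ab$species)) {
    strains <- tx$strain[tx$species == sp]
    expect_equal(ab$species[sp, ],
                 colSums(ab$strain[strains, , drop = FALSE]))
  }
  for (g in rownames(ab$genus)) {
    spp <- unique(tx$species[tx$genus == g])
    expect_equal(ab$genus[g, ],
                 colSums(ab$species[spp, , drop = FALSE]))
  }
  expect_equal(colSums(ab$strain), c(A = 1, B = 1))
})

test_that("16S sampling recovers true genus fractions in the noiseless limit", {
  tx <- build_taxonomy(4, 1, 1, seed = 6)
  db <- synthesize_proteomes(tx, proteins_per_strain = 3,
                             homolog_family_count = 6,
                             gene_annotation_rate = 0.5, seed = 6,
                             host_protein_count = 0)
  # all eight true cell values distinct so ranks are unambiguous
  profiles <- list(
    A = stats::setNames(c(0.4, 0.3, 0.2, 0.1), tx$strain),
    B = stats::setNames(c(0.44, 0.28, 0.17, 0.11), tx$strain))
  spec <- community_spec(subjects = c("A", "B"), profiles = profiles,
                         host_spectrum_fraction = 0, depth = 50,
                         decoy_hit_rate = 0, seed = 6)
  truth <- sample_psms(spec, db, tx)$truth
  reads <- sample_16s(truth, read_depth = 200000, noise_sd_16s = 0,
                      seed = 8)
  frac <- sweep(unclass(reads), 2, colSums(reads), "/")
  tg <- truth$abundance$genus[rownames(frac), ]
  expect_gte(cor(as.vector(frac), as.vector(tg), method = "spearman"),
             0.99)
  expect_true(all(abs(frac - tg) < 0.01))
  expect_identical(sample_16s(truth, 500, 0.2, seed = 3),
                   sample_16s(truth, 500, 0.2, seed = 3))
})

test_that("a one-genus community concentrates all 16S reads", {
  tx <- build_taxonomy(1, 2, 1, seed = 2)
  db <- synthesize_proteomes(tx, proteins_per_strain = 3,
                             homolog_family_count = 2,
                             gene_annotation_rate = 0, seed = 2,
                             host_protein_count = 0)
  prof <- stats::setNames(rep(0.5, 2), tx$strain)
  spec <- community_spec(subjects = "S", profiles = list(S = prof),
                         host_spectrum_fraction = 0, depth = 50,
                         decoy_hit_rate = 0, seed = 2)
  truth <- sample_psms(spec, db, tx)$truth
  reads <- sample_16s(truth, read_depth = 1000, noise_sd_16s = 0.3,
                      seed = 5)
  expect_equal(nrow(reads), 1L)
  expect_equal(sum(reads), 1000)
})

test_that("identical spec and seed give byte-identical output files", {
  comm <- tiny_community(seed = 12, depth = 120)
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_community(comm, read_depth_16s = 300, outdir = d1)
  simulate_community(comm, read_depth_16s = 300, outdir = d2)
  files <- list.files(d1)
  expect_true(length(files) >= 4)
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6),
                     label = f)
  }
})
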