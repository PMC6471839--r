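# Independent brute-force oracles used to validate the package's
# algorithmic paths.  These deliberately use naive enumeration.

# Enumerate tryptic peptides by brute force: find cleavage points, then
# take every contiguous run of fragments with <= mc internal boundaries.
oracle_digest <- function(seq, mc, min_len, max_len) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  cuts <- integer(0)
  for (i in seq_len(n - 1)) {
    if (res[i] %in% c("K", "R") && res[i + 1] != "P") cuts <- c(cuts, i)
  }
  bounds <- c(0L, cuts, n)
  out <- character(0)
  for (a in seq_len(length(bounds) - 1)) {
    for (b in (a + 1):length(bounds)) {
      if (b - a - 1 > mc) next
      pep <- substr(seq, bounds[a] + 1L, bounds[b])
      if (nchar(pep) >= min_len && nchar(pep) <= max_len)
        out <- c(out, pep)
    }
  }
  unique(out)
}

# Exhaustive minimal set cover: smallest number of sets covering the
# universe (union of all sets).  Only for <= 12 sets.
oracle_min_cover_size <- function(sets) {
  universe <- sort(unique(unlist(sets)))
  n <- length(sets)
  for (k in seq_len(n)) {
    combs <- utils::combn(n, k, simplify = FALSE)
    for (cc in combs) {
      if (setequal(intersect(universe, unlist(sets[cc])), universe))
        return(k)
    }
  }
  stop("no cover exists")
}

# Maximal antichain under subset order: drop sets that are strict
# subsets of another.
oracle_maximal_sets <- function(sets) {
  n <- length(sets)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      si <- sets[[i]]; sj <- sets[[j]]
      if (length(si) < length(sj) && all(si %in% sj)) keep[i] <- FALSE
    }
  }
  sets[keep]
}

# Exhaustive FDR threshold scan: lowest cutoff c (over observed scores)
# such that decoys/max(targets,1) among scores >= c is <= target.
oracle_fdr_threshold <- function(scores, is_decoy, target) {
  best <- Inf
  for (c in sort(unique(scores))) {
    keep <- scores >= c
    fdr <- sum(is_decoy[keep]) / max(sum(!is_decoy[keep]), 1)
    if (fdr <= target && c < best) best <- c
  }
  best
}

# Transitive closure of a direct-relation matrix by iterated boolean
# multiplication; returns component membership labels.
oracle_components <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  membership <- integer(n)
  label <- 0L
  for (i in seq_len(n)) {
    if (membership[i] == 0L) {
      label <- label + 1L
      membership[which(reach[i, ])] <- label
    }
  }
  membership
}

# random metaclustering instance: n singleton groups with random gene
# names, uniref ids and peptide sets over small pools
random_mc_instance <- function(n, seed) {
  set.seed(seed)
  genes <- c("", "", "gltB", "sucA", "fabH", "AB_1234")  # last is a locus tag
  urefs <- c("", sprintf("UR%02d", 1:4))
  accs <- sprintf("P%02d", seq_len(n))
  db <- make_db(accs, "X",
                gene_name = sample(genes, n, replace = TRUE),
                uniref50_id = sample(urefs, n, replace = TRUE))
  peps <- sprintf("PEPPOOL%02d", 1:8)
  groups <- make_groups(as.list(accs),
                        lapply(seq_len(n), function(i)
                          sample(peps, sample(1:2, 1))))
  list(db = db, groups = groups)
}

# direct-relation adjacency implied by the three sharing rules
direct_relation <- function(groups, db) {
  n <- nrow(groups)
  gene <- tolower(db$gene_name[match(unlist(groups$members),
                                     db$accession)])
  gene[!is_characterized_gene(db$gene_name[match(unlist(groups$members),
                                                 db$accession)])] <- NA
  ur <- db$uniref50_id[match(unlist(groups$members), db$accession)]
  ur[!nzchar(ur)] <- NA
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    share_gene <- !is.na(gene[i]) && !is.na(gene[j]) && gene[i] == gene[j]
    share_ur <- !is.na(ur[i]) && !is.na(ur[j]) && ur[i] == ur[j]
    share_pep <- length(intersect(groups$peptides[[i]],
                                  groups$peptides[[j]])) > 0
    adj[i, j] <- adj[j, i] <- share_gene || share_ur || share_pep
  }
  adj
}

# canonical form of a partition: sorted list of sorted member vectors
canonical_partition <- function(ids, membership) {
  parts <- lapply(split(as.character(ids), membership), sort)
  unname(parts[order(vapply(parts, `[`, character(1), 1))])
}
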