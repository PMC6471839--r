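# Target-decoy FDR filtering and parsimony protein inference.

psm_is_decoy <- function(psms, decoy_prefix = "DECOY_") {
  vapply(strsplit(psms$accessions, ";", fixed = TRUE),
         function(a) length(a) > 0 && all(startsWith(a, decoy_prefix)),
         logical(1))
}

#' Filter PSMs at a target false discovery rate
#'
#' A PSM is a decoy hit when every matched accession is a decoy.  The
#' filter scans score cutoffs and keeps the lowest score threshold at
#' which the estimated FDR among surviving PSMs is at or below
#' \code{target_fdr} (i.e. it retains as many PSMs as the target
#' allows); decoy PSMs are then removed from the retained set.  If no
#' threshold achieves the target, the retained set is empty and a
#' warning is raised.
#'
#' @param psms PSM data.frame with a \code{score} column.
#' @param target_fdr target FDR fraction (e.g. 0.016).
#' @param estimator \code{"ratio"} for n_decoy / n_target (default) or
#'   \code{"concatenated"} for 2 n_decoy / (n_target + n_decoy).
#' @param decoy_prefix accession prefix marking decoy records.
#' @return list: \code{psms} (retained, decoys removed),
#'   \code{fdr_result} (class \code{fdr_result}: score_threshold,
#'   n_target, n_decoy, fdr at the threshold), and
#'   \code{decoy_psms_at_threshold} (surviving decoy hits, for
#'   protein-level FDR reporting).
#' @export
fdr_filter <- function(psms, target_fdr = 0.016,
                       estimator = c("ratio", "concatenated"),
                       decoy_prefix = "DECOY_") {
  estimator <- match.arg(estimator)
  stopifnot(is.numeric(psms$score))
  if (target_fdr < 0) stopf("target_fdr must be non-negative")
  dec <- psm_is_decoy(psms, decoy_prefix)
  est <- function(t, d) {
    if (estimator == "ratio") d / max(t, 1) else 2 * d / max(t + d, 1)
  }
  ord <- order(psms$score, decreasing = TRUE)
  sc <- psms$score[ord]
  dc <- dec[ord]
  t_cum <- cumsum(!dc)
  d_cum <- cumsum(dc)
  # evaluate at each distinct score (cutoff = keep score >= value)
  last_of_score <- which(!duplicated(sc, fromLast = TRUE))
  fdr_at <- vapply(last_of_score, function(i) est(t_cum[i], d_cum[i]),
                   numeric(1))
  feasible <- which(fdr_at <= target_fdr)
  if (!length(feasible)) {
    warning("no score threshold achieves the target FDR; ",
            "returning an empty retained set")
    return(list(
      psms = psms[0, , drop = FALSE],
      fdr_result = structure(list(score_threshold = Inf, n_target = 0L,
                                  n_decoy = 0L, fdr = NA_real_),
                             class = "fdr_result"),
      decoy_psms_at_threshold = psms[0, , drop = FALSE]))
  }
  pick <- last_of_score[max(feasible)]  # lowest feasible score cutoff
  threshold <- sc[pick]
  keep <- psms$score >= threshold
  res <- structure(list(score_threshold = threshold,
                        n_target = t_cum[pick],
                        n_decoy = d_cum[pick],
                        fdr = est(t_cum[pick], d_cum[pick])),
                   class = "fdr_result")
  list(psms = psms[keep & !dec, , drop = FALSE],
       fdr_result = res,
       decoy_psms_at_threshold = psms[keep & dec, , drop = FALSE])
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf(
    "FDR filter: threshold %.4f, %d targets / %d decoys (FDR %.4f)\n",
    x$score_threshold, x$n_target, x$n_decoy, x$fdr))
  invisible(x)
}

# peptide -> non-decoy matched accessions, from retained PSM rows
observed_peptide_matches <- function(psms, decoy_prefix = "DECOY_") {
  peps <- unique(psms$peptide)
  acc_lists <- strsplit(psms$accessions[match(peps, psms$peptide)], ";",
                        fixed = TRUE)
  acc_lists <- lapply(acc_lists, function(a)
    sort(unique(a[!startsWith(a, decoy_prefix)])))
  empty <- lengths(acc_lists) == 0L
  if (any(empty))
    stopf("retained peptide(s) with no target protein match: %s",
          paste(utils::head(peps[empty], 5), collapse = ", "))
  stats::setNames(acc_lists, peps)
}

#' Parsimony protein inference
#'
#' Derives the simplest list of proteins explaining the observed
#' peptides: (1) proteins with identical observed-peptide sets are
#' merged into one indistinguishable group; (2) groups whose peptide set
#' is a strict subset of another group's are removed (their peptides
#' remain explained by the superset group); (3) a greedy set cover over
#' peptides — largest number of still-uncovered peptides first, ties
#' broken by lexicographically smallest member accession — selects the
#' reported groups.  Every retained peptide is covered by at least one
#' reported group.
#'
#' @param psms retained (FDR-filtered) PSM data.frame.
#' @param database \code{protein_db}; used to verify accessions resolve.
#' @return \code{protein_groups}: data.frame with columns
#'   \code{group_id}, \code{representative} and list-columns
#'   \code{members}, \code{peptides}, ordered by representative
#'   accession.
#' @export
infer_protein_groups <- function(psms, database = NULL) {
  if (nrow(psms) == 0L) {
    out <- data.frame(group_id = character(0),
                      representative = character(0),
                      stringsAsFactors = FALSE)
    out$members <- list()
    out$peptides <- list()
    class(out) <- c("protein_groups", "data.frame")
    return(out)
  }
  matches <- observed_peptide_matches(psms)
  if (!is.null(database)) {
    bad <- setdiff(unique(unlist(matches)), database$accession)
    if (length(bad))
      stopf("matched accessions absent from database: %s",
            paste(utils::head(bad, 10), collapse = ", "))
  }
  # protein -> observed peptide set
  prot_peps <- split(
    rep(names(matches), lengths(matches)), unlist(matches))
  prot_peps <- lapply(prot_peps, function(p) sort(unique(p)))
  # (1) merge proteins with identical peptide sets
  key <- vapply(prot_peps, paste, character(1), collapse = "\r")
  merged <- split(names(prot_peps), key)
  members <- lapply(merged, sort)
  peptides <- lapply(merged, function(m) prot_peps[[m[1]]])
  rep_acc <- vapply(members, `[[`, character(1), 1)
  o <- order(rep_acc)
  members <- members[o]; peptides <- peptides[o]; rep_acc <- rep_acc[o]
  # (2) drop strict-subset groups
  n <- length(peptides)
  keep <- rep(TRUE, n)
  sizes <- lengths(peptides)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || !keep[i]) next
      if (sizes[i] < sizes[j] && all(peptides[[i]] %in% peptides[[j]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  members <- members[keep]; peptides <- peptides[keep]
  rep_acc <- rep_acc[keep]
  # (3) greedy set cover, deterministic tie-break on representative
  uncovered <- unique(unlist(peptides))
  chosen <- logical(length(peptides))
  while (length(uncovered)) {
    gain <- vapply(seq_along(peptides), function(i)
      if (chosen[i]) -1L else sum(peptides[[i]] %in% uncovered), integer(1))
    best <- which(gain == max(gain))
    best <- best[order(rep_acc[best])][1]
    if (gain[best] <= 0L) break  # cannot happen: every peptide has a group
    chosen[best] <- TRUE
    uncovered <- setdiff(uncovered, peptides[[best]])
  }
  out <- data.frame(
    group_id = paste0("PG:", rep_acc[chosen]),
    representative = rep_acc[chosen],
    stringsAsFactors = FALSE)
  out$members <- members[chosen]
  out$peptides <- peptides[chosen]
  out <- out[order(out$representative), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("protein_groups", "data.frame")
  out
}

#' Assign spectral counts to inferred protein groups
#'
#' Each PSM contributes a count of one to every reported group whose
#' peptide set contains its peptide (shared peptides count in each
#' covering group); spectra of peptides belonging to exactly one group
#' are additionally tallied as unique-peptide counts.
#'
#' @param groups \code{protein_groups} from
#'   \code{\link{infer_protein_groups}}.
#' @param psms retained PSM data.frame.
#' @return list of two group x subject matrices: \code{counts} (all
#'   covering groups) and \code{unique_counts} (spectra of
#'   single-group peptides only).
#' @export
assign_spectral_counts <- function(groups, psms) {
  subjects <- sort(unique(psms$subject_id))
  counts <- matrix(0L, nrow = nrow(groups), ncol = length(subjects),
                   dimnames = list(groups$group_id, subjects))
  ucounts <- counts
  if (nrow(groups) == 0L || nrow(psms) == 0L)
    return(list(counts = counts, unique_counts = ucounts))
  pep2groups <- split(
    rep(seq_len(nrow(groups)), lengths(groups$peptides)),
    unlist(groups$peptides))
  for (i in seq_len(nrow(psms))) {
    gs <- pep2groups[[psms$peptide[i]]]
    if (is.null(gs)) next  # peptide not covered (cannot happen post-infer)
    j <- match(psms$subject_id[i], subjects)
    counts[gs, j] <- counts[gs, j] + 1L
    if (length(gs) == 1L) ucounts[gs, j] <- ucounts[gs, j] + 1L
  }
  list(counts = counts, unique_counts = ucounts)
}
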